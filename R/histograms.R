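# Histogram machinery for curvature-based threshold estimation.
#
# All thresholds are located as points of maximum discrete curvature of the
# histogram count polyline, searched behind (towards higher values) the
# biggest retardation peak and before (towards lower values) the biggest
# transmittance peak, with a 64 -> 128 -> 256 bin refinement chain that keeps
# the final estimate close to the coarse, outlier-resistant one.

hist_counts <- function(values, nbins) {
  idx <- pmin(pmax(floor(values * nbins) + 1L, 1L), nbins)
  tabulate(idx, nbins)
}

bin_centre <- function(bin, nbins) (bin - 0.5) / nbins

#' Bin of maximum discrete curvature within a search range
#'
#' The counts are rescaled affinely to `[0, 1]` and treated as a polyline on
#' a unit-spaced bin grid. Curvature is the plane-curve expression
#' `y'' / (1 + y'^2)^(3/2)` with central finite differences; the first and
#' last histogram bins carry no curvature. Ties break towards the lower bin
#' index.
#'
#' @param counts integer histogram counts.
#' @param search_range vector of bin indices to search (must span at least 3
#'   bins and lie inside the histogram).
#' @return the bin index maximising the curvature.
#' @export
max_curvature_point <- function(counts, search_range) {
  nb <- length(counts)
  search_range <- sort(unique(as.integer(search_range)))
  if (length(search_range) < 3L)
    stop("search range must span at least 3 bins ",
         "(second derivative undefined otherwise)")
  if (min(search_range) < 1L || max(search_range) > nb)
    stop("search range must lie inside the histogram")
  rng <- range(counts)
  if (rng[1L] == rng[2L]) {
    y <- rep(0, nb)  # flat histogram: zero curvature everywhere
  } else {
    y <- (counts - rng[1L]) / (rng[2L] - rng[1L])
  }
  i <- 2:(nb - 1L)
  d1 <- (y[i + 1L] - y[i - 1L]) / 2
  d2 <- y[i + 1L] - 2 * y[i] + y[i - 1L]
  kappa <- rep(-Inf, nb)
  kappa[i] <- d2 / (1 + d1^2)^1.5
  cand <- search_range[search_range >= 2L & search_range <= nb - 1L]
  if (length(cand) == 0L) cand <- search_range
  cand[which.max(kappa[cand])]
}

# Biggest peak (bin with the globally maximal count; ties towards the lower
# bin) and its full width at half maximum, measured by linear interpolation
# of the half-maximum crossings on the count polyline. If a side never drops
# below half maximum the histogram edge is used as the crossing.
peak_fwhm <- function(counts) {
  nb <- length(counts)
  peak <- which.max(counts)
  half <- counts[peak] / 2
  left <- 1
  if (peak > 1L) {
    below <- which(counts[1:(peak - 1L)] < half)
    if (length(below) > 0L) {
      i <- max(below)
      left <- i + (half - counts[i]) / (counts[i + 1L] - counts[i])
    }
  }
  right <- nb
  if (peak < nb) {
    below <- which(counts[(peak + 1L):nb] < half)
    if (length(below) > 0L) {
      j <- peak + min(below)
      right <- j - 1 + (half - counts[j - 1L]) / (counts[j] - counts[j - 1L])
    }
  }
  list(peak = peak, fwhm = max(right - left, 1))
}

# Refinement window at double resolution: a coarse result r maps to fine
# bins [2 (r - 1), 2 (r + 1)], clamped to the histogram and widened inward
# to keep at least 3 bins.
refine_window <- function(bin, nbins_fine) {
  lo <- max(2L * (bin - 1L), 1L)
  hi <- min(2L * (bin + 1L), nbins_fine)
  while (hi - lo < 2L) {
    if (lo > 1L) lo <- lo - 1L else hi <- hi + 1L
  }
  lo:hi
}

search_range_64 <- function(counts, peak_side, value_range = NULL) {
  nb <- length(counts)
  if (peak_side == "between") {
    centres <- bin_centre(seq_len(nb), nb)
    lo <- suppressWarnings(min(which(centres > value_range[1L])))
    # exclude the bin containing the upper bound and one guard bin below
    # it, so no curvature stencil touches the base of the background peak
    hi <- min(floor(value_range[2L] * nb) + 1L, nb) - 2L
    if (!is.finite(lo) || hi - lo < 2L)
      stop("value range too narrow for curvature search")
    return(lo:hi)
  }
  pf <- peak_fwhm(counts)
  if (peak_side == "behind_retardation_peak") {
    lo <- pf$peak + 1L
    hi <- min(pf$peak + as.integer(ceiling(20 * pf$fwhm)), nb)
  } else {  # before_transmittance_peak
    hi <- pf$peak - 1L
    lo <- max(pf$peak - as.integer(ceiling(10 * pf$fwhm)), 1L)
  }
  if (hi < lo) stop("empty curvature search range next to the biggest peak")
  while (hi - lo < 2L) {
    if (peak_side == "behind_retardation_peak") hi <- min(hi + 1L, nb)
    else lo <- max(lo - 1L, 1L)
    if (lo == 1L && hi == nb) break
  }
  lo:hi
}

#' Multi-resolution curvature threshold on a sample of values
#'
#' Locates a threshold as the point of maximum curvature of the histogram of
#' `values`, refined over three resolutions. At 64 bins the search range is
#' derived from the biggest peak: 20 x FWHM behind it for a retardation
#' histogram, 10 x FWHM before it for a transmittance histogram, or the bins
#' covering an explicit `(lo, hi)` value interval for the constrained search
#' used by the mid transmittance threshold. At 128 and 256 bins the search is
#' restricted to the window `[2 (r - 1), 2 (r + 1)]` around the previous
#' result `r`, so the refined threshold stays close to the coarse one while
#' gaining resolution.
#'
#' @param values numeric sample in `[0, 1]`.
#' @param peak_side `"behind_retardation_peak"`,
#'   `"before_transmittance_peak"`, or `"between"`.
#' @param value_range numeric `(lo, hi)` interval, only for
#'   `peak_side = "between"`.
#' @return the threshold as the selected 256-bin centre value.
#' @export
refine_threshold <- function(values, peak_side, value_range = NULL) {
  peak_side <- match.arg(peak_side, c("behind_retardation_peak",
                                      "before_transmittance_peak",
                                      "between"))
  if (length(values) == 0L) stop("empty sample")
  c64 <- hist_counts(values, 64L)
  if (sum(c64 > 0L) < 2L)
    stop("degenerate histogram: a single occupied bin carries no curvature ",
         "structure")
  bin <- max_curvature_point(c64, search_range_64(c64, peak_side, value_range))
  for (nb in c(128L, 256L)) {
    cn <- hist_counts(values, nb)
    bin <- max_curvature_point(cn, refine_window(bin, nb))
  }
  bin_centre(bin, 256L)
}
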