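# Region labels used throughout: background 0, low myelination 1, high
# myelination 2.

#' Region label codes
#' @export
PLI_BG <- 0L
#' @rdname PLI_BG
#' @export
PLI_LM <- 1L
#' @rdname PLI_BG
#' @export
PLI_HM <- 2L

#' Normalise a transmittance raster to the unit interval
#'
#' Affine rescaling so the image minimum maps to 0 and the maximum to 1.
#'
#' @param t_raw finite, non-negative numeric matrix, not all equal.
#' @return a matrix with values in `[0, 1]`.
#' @export
normalise_transmittance <- function(t_raw) {
  if (any(!is.finite(t_raw))) stop("transmittance must be finite")
  rng <- range(t_raw)
  if (rng[1L] == rng[2L])
    stop("constant transmittance image: normalisation undefined")
  (t_raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Circular median filter
#'
#' Median over a discrete disk footprint (pixels whose centre distance from
#' the centre pixel is at most `radius`). The footprint is truncated at the
#' image borders; no padding values are invented. With `labels` given, each
#' footprint is additionally restricted to pixels sharing the centre pixel's
#' label, and pixels labelled `PLI_BG` pass through unchanged and are
#' excluded from every footprint.
#'
#' @param image numeric matrix.
#' @param radius footprint radius in pixels (default 5).
#' @param labels optional integer label matrix (see [classify_regions()]).
#' @return the filtered matrix.
#' @export
median_filter_disk <- function(image, radius = 5L, labels = NULL) {
  if (is.null(labels)) {
    labels <- matrix(1L, nrow(image), ncol(image))
    exclude <- -1L
  } else {
    storage.mode(labels) <- "integer"
    exclude <- PLI_BG
  }
  .masked_median_cpp(image, labels, as.integer(radius), exclude)
}

#' Masked median filter over myelination regions
#'
#' Applies the circular median filter to HM and LM regions individually:
#' each pixel's footprint only contains pixels carrying the same label, and
#' background pixels are ignored everywhere (they pass through unchanged).
#' This retains sharp borders between HM and LM regions.
#'
#' @inheritParams median_filter_disk
#' @param labels integer label matrix from [classify_regions()].
#' @export
masked_median_filter <- function(image, labels, radius = 5L) {
  median_filter_disk(image, radius = radius, labels = labels)
}

#' Collapse background pixels before histogram analysis
#'
#' To keep the background from influencing the histogram-derived thresholds,
#' the retardation of background pixels (low retardation and transmittance
#' above the background threshold) is set to the image minimum retardation
#' and their transmittance to the image maximum transmittance.
#'
#' @param maps a [pli_maps()] object (normalised transmittance).
#' @param t_back background transmittance threshold.
#' @param r_thres retardation threshold delimiting high-birefringence tissue.
#' @return a [pli_maps()] object with collapsed background pixels.
#' @export
mask_background_for_histograms <- function(maps, t_back, r_thres) {
  stopifnot(inherits(maps, "pli_maps"))
  bg <- maps$transmittance > t_back & maps$retardation <= r_thres
  tr <- maps$transmittance
  rr <- maps$retardation
  tr[bg] <- max(maps$transmittance)
  rr[bg] <- min(maps$retardation)
  out <- pli_maps(tr, maps$direction, rr)
  attr(out, "bg_masked") <- bg
  out
}

#' Connected region of highest retardation at a target size
#'
#' Finds a connected set of pixels (8-connectivity, union-find labelling)
#' with the highest retardation values whose size is a prescribed fraction
#' of the eligible pixel count. A binary search on a retardation cut-off
#' thresholds the eligible pixels, labels the connected components above the
#' cut-off, and keeps the component with the highest mean retardation; the
#' cut-off is lowered or raised until that component's size fraction enters
#' the target window.
#'
#' If no cut-off yields a component inside the window (typical for small
#' images, where the window may contain no integer pixel count), the
#' smallest component above the window is returned with a warning.
#'
#' @param retardation numeric matrix.
#' @param valid_mask logical matrix of eligible pixels (whole image for the
#'   transmittance reference; HM pixels for the model parameters).
#' @param fraction_window target size window as a fraction of the eligible
#'   count, default `c(0.9e-4, 1.1e-4)` (0.009 to 0.011 percent).
#' @param max_iterations binary search iteration cap.
#' @return logical matrix marking the selected component, with attributes
#'   `cutoff` and `size`.
#' @export
find_reference_region <- function(retardation, valid_mask = NULL,
                                  fraction_window = c(0.9e-4, 1.1e-4),
                                  max_iterations = 64L) {
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, nrow(retardation), ncol(retardation))
  n_elig <- sum(valid_mask)
  if (n_elig == 0L) stop("no eligible pixels for the reference region")
  rv <- retardation[valid_mask]
  lo <- min(rv)
  hi <- max(rv)

  best_component <- function(cut) {
    mask <- valid_mask & retardation > cut
    if (!any(mask)) return(NULL)
    lab <- .label_components_cpp(mask, 8L)
    sizes <- tabulate(lab[lab > 0L])
    means <- vapply(seq_along(sizes), function(k)
      mean(retardation[lab == k]), numeric(1))
    k <- which.max(means)
    list(mask = lab == k, size = sizes[k], cutoff = cut)
  }

  fallback <- NULL  # smallest component seen above the window
  for (it in seq_len(max_iterations)) {
    cut <- (lo + hi) / 2
    comp <- best_component(cut)
    frac <- if (is.null(comp)) 0 else comp$size / n_elig
    if (frac >= fraction_window[1L] && frac <= fraction_window[2L]) {
      out <- comp$mask
      attr(out, "cutoff") <- comp$cutoff
      attr(out, "size") <- comp$size
      return(out)
    }
    if (frac > fraction_window[2L]) {
      if (is.null(fallback) || comp$size < fallback$size) fallback <- comp
      lo <- cut  # component too large: raise the cut-off
    } else {
      hi <- cut  # too small or empty: lower the cut-off
    }
  }
  if (is.null(fallback))
    stop("reference region search failed: no connected component above the ",
         "size window at any cut-off")
  warning("no connected component within the target size window ",
          "(fraction ", format(fraction_window[1L]), " to ",
          format(fraction_window[2L]), " of ", n_elig, " eligible pixels); ",
          "falling back to the smallest component above it (",
          fallback$size, " px)")
  out <- fallback$mask
  attr(out, "cutoff") <- fallback$cutoff
  attr(out, "size") <- fallback$size
  out
}

#' Threshold parameter set for the HM/LM/BG classification
#'
#' @param r_thres retardation threshold.
#' @param t_thres transmittance threshold separating HM from LM.
#' @param t_back transmittance threshold separating tissue from background.
#' @param t_ref mean transmittance of the densest in-plane fibre region.
#' @return an object of class `pli_thresholds`.
#' @export
pli_thresholds <- function(r_thres, t_thres, t_back, t_ref) {
  stopifnot(r_thres > 0, r_thres < 1, t_thres > 0, t_thres < 1,
            t_back > 0, t_back <= 1, t_ref > 0, t_ref < 1)
  if (t_thres > t_back) stop("t_thres must not exceed t_back")
  if (t_ref > t_back) stop("t_ref must not exceed t_back")
  structure(list(r_thres = r_thres, t_thres = t_thres,
                 t_back = t_back, t_ref = t_ref),
            class = "pli_thresholds")
}

#' @export
print.pli_thresholds <- function(x, ...) {
  cat(sprintf(
    "pli_thresholds: R_thres = %.4f, T_thres = %.4f, T_back = %.4f, T_ref = %.4f\n",
    x$r_thres, x$t_thres, x$t_back, x$t_ref))
  invisible(x)
}

#' Estimate the classification thresholds from the parameter maps
#'
#' Expects normalised transmittance to which the circular median filter has
#' been applied. Provisional retardation and background thresholds are
#' estimated from the raw histograms, the background is collapsed with
#' [mask_background_for_histograms()], and the final thresholds are
#' recomputed from the masked histograms: the retardation threshold behind
#' the biggest retardation peak (20 x FWHM search range, 64/128/256 bin
#' refinement), the background threshold before the biggest transmittance
#' peak (10 x FWHM), the reference transmittance as the mean transmittance
#' over the connected region of highest retardation (0.009 to 0.011 percent
#' of the image), and the mid transmittance threshold as the point of
#' maximum curvature between the reference and background thresholds.
#'
#' @param maps a [pli_maps()] object (normalised, median-filtered
#'   transmittance).
#' @return a [pli_thresholds()] object; the masked maps are attached as
#'   attribute `masked_maps`.
#' @export
estimate_thresholds <- function(maps) {
  stopifnot(inherits(maps, "pli_maps"))
  rv <- as.vector(maps$retardation)
  tv <- as.vector(maps$transmittance)

  r_prov <- refine_threshold(rv, "behind_retardation_peak")
  t_back_prov <- refine_threshold(tv, "before_transmittance_peak")

  masked <- mask_background_for_histograms(maps, t_back_prov, r_prov)
  rv <- as.vector(masked$retardation)
  tv <- as.vector(masked$transmittance)

  r_thres <- refine_threshold(rv, "behind_retardation_peak")
  t_back <- refine_threshold(tv, "before_transmittance_peak")

  ref <- find_reference_region(maps$retardation)
  t_ref <- mean(maps$transmittance[ref])

  if (t_ref >= t_back)
    stop("degenerate histograms: reference transmittance is not below the ",
         "background threshold")
  t_thres <- refine_threshold(tv, "between", value_range = c(t_ref, t_back))

  out <- pli_thresholds(r_thres, t_thres, t_back, t_ref)
  attr(out, "masked_maps") <- masked
  attr(out, "reference_region") <- ref
  out
}

#' Binary HM/LM/BG classification
#'
#' A pixel is highly myelinated (HM) if its retardation exceeds the
#' retardation threshold or its transmittance falls below the mid
#' transmittance threshold; among the remaining pixels, those brighter than
#' the background threshold are background (BG) and the rest are lowly
#' myelinated (LM). The three predicates partition the `(R, T)` plane.
#'
#' @param maps a [pli_maps()] object.
#' @param thresholds a [pli_thresholds()] object.
#' @return integer matrix with values [PLI_BG], [PLI_LM], [PLI_HM].
#' @export
classify_regions <- function(maps, thresholds) {
  stopifnot(inherits(maps, "pli_maps"), inherits(thresholds, "pli_thresholds"))
  r <- maps$retardation
  tr <- maps$transmittance
  hm <- r > thresholds$r_thres | tr < thresholds$t_thres
  bg <- !hm & tr > thresholds$t_back
  lab <- matrix(PLI_LM, nrow(r), ncol(r))
  lab[hm] <- PLI_HM
  lab[bg] <- PLI_BG
  lab
}
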