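# Bootstrap sensitivity of the retardation and mid transmittance thresholds.
#
# Both thresholds are recomputed from histograms of pixels resampled with
# replacement; the means of the recomputed values above/below the original
# threshold (the positive/negative means) set the width of the transition
# zone between LM and HM regions.

#' Transition-zone widths from bootstrapped thresholds
#'
#' @param r_plus,r_minus positive/negative mean of the bootstrapped
#'   retardation thresholds (values above/below the original threshold).
#' @param t_plus,t_minus the same for the mid transmittance threshold.
#' @param n_iterations,sample_fraction bookkeeping of the bootstrap run.
#' @return an object of class `pli_widths`.
#' @export
pli_widths <- function(r_plus, r_minus, t_plus, t_minus,
                       n_iterations, sample_fraction) {
  structure(list(r_plus = r_plus, r_minus = r_minus,
                 t_plus = t_plus, t_minus = t_minus,
                 n_iterations = as.integer(n_iterations),
                 sample_fraction = sample_fraction),
            class = "pli_widths")
}

#' @export
print.pli_widths <- function(x, ...) {
  cat(sprintf(
    "pli_widths: R+ = %.4f, R- = %.4f, T+ = %.4f, T- = %.4f (%d iterations at %.0f%%)\n",
    x$r_plus, x$r_minus, x$t_plus, x$t_minus,
    x$n_iterations, 100 * x$sample_fraction))
  invisible(x)
}

# One bootstrap recomputation of both thresholds from sampled pixel values.
# The full 64 -> 128 -> 256 refinement chain is reused per iteration; the
# reference and background transmittance thresholds stay fixed at their
# full-sample values.
boot_thresholds_once <- function(rv, tv, idx, t_ref, t_back) {
  c(r = refine_threshold(rv[idx], "behind_retardation_peak"),
    t = refine_threshold(tv[idx], "between", value_range = c(t_ref, t_back)))
}

side_mean <- function(values, original, side) {
  v <- if (side > 0) values[values > original] else values[values < original]
  if (length(v) == 0L) original else mean(v)
}

#' Bootstrap the threshold parameters to obtain transition-zone widths
#'
#' Each iteration draws `ceiling(sample_fraction * n_pixels)` pixels with
#' replacement (jointly for retardation and transmittance: one pixel index
#' stream), rebuilds both histograms from the sampled values and recomputes
#' the retardation and mid transmittance thresholds through the full
#' multi-resolution refinement. After all iterations the positive and
#' negative means are taken relative to the full-sample thresholds; a side
#' with no recomputed values defaults to the original threshold, making the
#' transition width zero on that side rather than undefined.
#'
#' @param maps a [pli_maps()] object (normalised, median-filtered
#'   transmittance).
#' @param sample_fraction fraction of pixels drawn per iteration, in
#'   `(0, 1]`; default 0.25.
#' @param n_iterations number of bootstrap iterations; default 200.
#' @param seed integer seed; a fixed seed gives bit-identical results.
#' @param thresholds optional precomputed [estimate_thresholds()] result
#'   (with its `masked_maps` attribute) to avoid recomputation.
#' @return a [pli_widths()] object with the per-iteration thresholds
#'   attached as attribute `samples`.
#' @export
bootstrap_thresholds <- function(maps, sample_fraction = 0.25,
                                 n_iterations = 200L, seed = 1L,
                                 thresholds = NULL) {
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must lie in (0, 1]")
  if (is.null(thresholds)) thresholds <- estimate_thresholds(maps)
  masked <- attr(thresholds, "masked_maps")
  rv <- as.vector(masked$retardation)
  tv <- as.vector(masked$transmittance)
  n <- length(rv)
  n_s <- as.integer(ceiling(sample_fraction * n))

  samples <- matrix(NA_real_, n_iterations, 2L,
                    dimnames = list(NULL, c("r", "t")))
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  for (it in seq_len(n_iterations)) {
    idx <- sample.int(n, n_s, replace = TRUE)
    samples[it, ] <- boot_thresholds_once(rv, tv, idx,
                                          thresholds$t_ref,
                                          thresholds$t_back)
  }

  out <- pli_widths(
    r_plus = side_mean(samples[, "r"], thresholds$r_thres, +1),
    r_minus = side_mean(samples[, "r"], thresholds$r_thres, -1),
    t_plus = side_mean(samples[, "t"], thresholds$t_thres, +1),
    t_minus = side_mean(samples[, "t"], thresholds$t_thres, -1),
    n_iterations = n_iterations, sample_fraction = sample_fraction)
  attr(out, "samples") <- samples
  attr(out, "thresholds") <- thresholds
  out
}

#' Convergence trace of the bootstrapped positive/negative means
#'
#' Runs the bootstrap for each sample fraction up to `max_iterations`,
#' recording the running positive/negative means after every iteration,
#' averaged over `n_repeats` independent repetitions (each repeat uses a
#' documented sub-stream of the seeded generator: `seed + repeat - 1`).
#'
#' @param maps a [pli_maps()] object.
#' @param sample_fractions numeric vector of fractions in `(0, 1]`.
#' @param max_iterations iterations per run.
#' @param n_repeats independent repetitions averaged per trace point.
#' @param seed integer seed.
#' @param thresholds optional precomputed [estimate_thresholds()] result.
#' @return a data frame with columns `fraction`, `iteration`, `r_plus`,
#'   `r_minus`, `t_plus`, `t_minus`.
#' @export
convergence_trace <- function(maps, sample_fractions = c(1, 0.25, 0.04, 0.01),
                              max_iterations = 500L, n_repeats = 10L,
                              seed = 1L, thresholds = NULL) {
  if (any(sample_fractions <= 0 | sample_fractions > 1))
    stop("sample fractions must lie in (0, 1]")
  if (is.null(thresholds)) thresholds <- estimate_thresholds(maps)
  masked <- attr(thresholds, "masked_maps")
  rv <- as.vector(masked$retardation)
  tv <- as.vector(masked$transmittance)
  n <- length(rv)

  running_sides <- function(vals, original) {
    # running positive/negative means after each iteration
    pos_n <- cumsum(vals > original)
    neg_n <- cumsum(vals < original)
    pos_s <- cumsum(ifelse(vals > original, vals, 0))
    neg_s <- cumsum(ifelse(vals < original, vals, 0))
    cbind(plus = ifelse(pos_n > 0, pos_s / pmax(pos_n, 1), original),
          minus = ifelse(neg_n > 0, neg_s / pmax(neg_n, 1), original))
  }

  rows <- list()
  for (frac in sample_fractions) {
    n_s <- as.integer(ceiling(frac * n))
    acc <- matrix(0, max_iterations, 4L)
    for (rep_i in seq_len(n_repeats)) {
      old <- local_rng_seed(seed + rep_i - 1L)
      vals <- matrix(NA_real_, max_iterations, 2L)
      for (it in seq_len(max_iterations)) {
        idx <- sample.int(n, n_s, replace = TRUE)
        vals[it, ] <- boot_thresholds_once(rv, tv, idx,
                                           thresholds$t_ref,
                                           thresholds$t_back)
      }
      restore_rng(old)
      acc <- acc + cbind(running_sides(vals[, 1L], thresholds$r_thres),
                         running_sides(vals[, 2L], thresholds$t_thres))
    }
    acc <- acc / n_repeats
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = frac, iteration = seq_len(max_iterations),
      r_plus = acc[, 1L], r_minus = acc[, 2L],
      t_plus = acc[, 3L], t_minus = acc[, 4L])
  }
  do.call(rbind, rows)
}

# Seed the RNG locally and hand back the previous state so callers can
# restore it; keeps package functions from disturbing the user's stream.
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
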