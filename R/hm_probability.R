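# HM-probability map: a sigmoid transition between lowly myelinated
# (p = 0) and highly myelinated (p = 1) tissue, whose width is set by the
# bootstrapped positive/negative threshold means.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# deviations beyond this magnitude are numerically saturated (erf is 1 to
# double precision long before)
.DEV_CAP <- 1e6

#' Scaled deviations from the classification thresholds
#'
#' The retardation deviation is `(R - R_thres)` divided by the transition
#' width on the matching side: the positive width `R_thres+ - R_thres` (mean
#' of the bootstrapped thresholds above the original, minus the original)
#' when above the threshold, the negative width `R_thres - R_thres-` when at
#' or below it; analogously for the transmittance deviation. The sign of the
#' numerator is retained so that deviation towards the HM corner (high R,
#' low T) can be told apart from deviation towards the LM corner. A zero
#' width (no bootstrap value on that side) saturates the deviation: the
#' pixel is assigned a hard 0/1 probability instead of overflowing.
#'
#' @param r,tr retardation and transmittance values (vectors or matrices).
#' @param thresholds a [pli_thresholds()] object.
#' @param widths a [pli_widths()] object.
#' @return list with elements `dr` and `dt`.
#' @export
scaled_deviations <- function(r, tr, thresholds, widths) {
  scale_one <- function(v, thr, w_plus, w_minus) {
    num <- v - thr
    den <- ifelse(num > 0, w_plus - thr, thr - w_minus)
    out <- ifelse(den > 0, num / den, sign(num) * .DEV_CAP)
    pmin(pmax(out, -.DEV_CAP), .DEV_CAP)
  }
  list(dr = scale_one(r, thresholds$r_thres, widths$r_plus, widths$r_minus),
       dt = scale_one(tr, thresholds$t_thres, widths$t_plus, widths$t_minus))
}

#' Sigmoid HM-probability from scaled deviations
#'
#' `p = 0.5 - 0.5 * erf(cos(3 pi / 4 - atan2(dT, dR)) * sqrt(dR^2 + dT^2))`.
#' The direction term projects the deviation vector onto the HM/LM axis of
#' the `(R, T)` plane: deep deviation towards high retardation or low
#' transmittance drives p to 1, towards low retardation or high
#' transmittance to 0, and conflicting or zero deviations give p = 0.5
#' (`atan2(0, 0)` is 0 by convention and the radius vanishes).
#'
#' The 0.5 offset makes the map span `(0, 1)` with p = 0.5 on the threshold
#' point, consistent with the 0.05/0.95 region cut-offs.
#'
#' @param dr,dt scaled deviations from [scaled_deviations()].
#' @return probabilities in `[0, 1]`, same shape as the inputs.
#' @export
hm_probability <- function(dr, dt) {
  theta <- atan2(dt, dr)
  radius <- sqrt(pmin(dr^2 + dt^2, .DEV_CAP^2))
  p <- 0.5 - 0.5 * erf(cos(3 * pi / 4 - theta) * radius)
  pmin(pmax(p, 0), 1)
}

#' Compute the HM-probability map
#'
#' Applies [scaled_deviations()] and [hm_probability()] per pixel.
#' Background pixels (per [classify_regions()]) are forced to probability
#' zero. Pixels above 0.95 are considered HM, below 0.05 LM, the rest
#' transition zone; the band is stored as metadata.
#'
#' @param maps a [pli_maps()] object (normalised, median-filtered
#'   transmittance).
#' @param thresholds a [pli_thresholds()] object.
#' @param widths a [pli_widths()] object.
#' @param band HM/LM probability cut-offs, default `c(0.05, 0.95)`.
#' @return an object of class `pli_pmap`: list with `p_hm`, `dr`, `dt`,
#'   `bg` (logical background mask) and `band`.
#' @export
compute_pmap <- function(maps, thresholds, widths, band = c(0.05, 0.95)) {
  stopifnot(inherits(maps, "pli_maps"), inherits(thresholds, "pli_thresholds"),
            inherits(widths, "pli_widths"))
  dev <- scaled_deviations(maps$retardation, maps$transmittance,
                           thresholds, widths)
  p <- hm_probability(dev$dr, dev$dt)
  labels <- classify_regions(maps, thresholds)
  # a zero width means the threshold is certain on that side: such pixels
  # take the hard 0/1 probability of the binary classification (the
  # zero-width limit of the sigmoid map)
  r <- maps$retardation
  tr <- maps$transmittance
  wr <- ifelse(r > thresholds$r_thres, widths$r_plus - thresholds$r_thres,
               thresholds$r_thres - widths$r_minus)
  wt <- ifelse(tr > thresholds$t_thres, widths$t_plus - thresholds$t_thres,
               thresholds$t_thres - widths$t_minus)
  hard <- wr <= 0 | wt <= 0
  p[hard] <- as.numeric(labels[hard] == PLI_HM)
  bg <- labels == PLI_BG
  p[bg] <- 0
  structure(list(p_hm = p, dr = dev$dr, dt = dev$dt, bg = bg, band = band,
                 labels = labels),
            class = "pli_pmap")
}

#' @export
print.pli_pmap <- function(x, ...) {
  n <- length(x$p_hm)
  cat(sprintf(
    "pli_pmap: %.1f%% HM (p > %.2f), %.1f%% LM (p < %.2f), %.1f%% transition, %.1f%% background\n",
    100 * sum(x$p_hm > x$band[2L] & !x$bg) / n, x$band[2L],
    100 * sum(x$p_hm < x$band[1L] & !x$bg) / n, x$band[1L],
    100 * sum(x$p_hm >= x$band[1L] & x$p_hm <= x$band[2L] & !x$bg) / n,
    100 * sum(x$bg) / n))
  invisible(x)
}
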