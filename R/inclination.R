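# Inclination models: the out-of-plane fibre angle alpha follows from the
# retardation R = |sin(2 pi / lambda * dn * d_m * cos^2 alpha)| once a
# reference retardation (and, for the transmittance-weighted model, the
# local myelin fraction inferred from Lambert-Beer attenuation) is known.

deg <- function(rad) rad * 180 / pi

#' Model parameters for the inclination computation
#'
#' @param r_ref_hm reference retardation of the densest in-plane fibre
#'   region inside HM tissue (expected retardation at zero inclination).
#' @param r_ref_lm reference retardation for LM tissue.
#' @param t_m transmittance of the densest fibre region (maximum myelin
#'   thickness).
#' @param t_c transmittance of tissue free of birefringent (myelinated)
#'   material.
#' @return an object of class `pli_params`.
#' @export
pli_params <- function(r_ref_hm, r_ref_lm, t_m, t_c) {
  stopifnot(r_ref_hm > 0, r_ref_hm <= 1, r_ref_lm > 0, r_ref_lm <= 1,
            t_m > 0, t_m < 1, t_c > 0, t_c <= 1)
  if (t_m >= t_c)
    stop("model ill-posed: the myelin-rich reference must be darker than ",
         "the non-birefringent reference (t_m < t_c)")
  if (r_ref_lm > r_ref_hm)
    stop("r_ref_lm must not exceed r_ref_hm")
  structure(list(r_ref_hm = r_ref_hm, r_ref_lm = r_ref_lm,
                 t_m = t_m, t_c = t_c),
            class = "pli_params")
}

#' @export
print.pli_params <- function(x, ...) {
  cat(sprintf(
    "pli_params: R_ref_HM = %.4f, R_ref_LM = %.4f, T_M = %.4f, T_c = %.4f\n",
    x$r_ref_hm, x$r_ref_lm, x$t_m, x$t_c))
  invisible(x)
}

#' Estimate the inclination model parameters
#'
#' The LM reference retardation is the maximum-curvature point of the
#' retardation histogram over LM pixels (probability below the lower band
#' edge). The HM reference retardation is the mean of the top 10 percent of
#' retardation values inside the connected region of highest retardation
#' within the HM pixels (0.009 to 0.011 percent of the HM count); the mean
#' transmittance of that same region gives the dense-fibre transmittance.
#' The non-birefringent transmittance is the mode (most frequent 256-bin
#' value) of the transmittance over LM pixels.
#'
#' @param maps a [pli_maps()] object whose transmittance has been
#'   median-filtered per region (see [masked_median_filter()]).
#' @param pmap a [compute_pmap()] result.
#' @return a [pli_params()] object with the HM reference region attached as
#'   attribute `reference_region`.
#' @export
compute_model_params <- function(maps, pmap) {
  stopifnot(inherits(maps, "pli_maps"), inherits(pmap, "pli_pmap"))
  lm <- pmap$p_hm < pmap$band[1L] & !pmap$bg
  hm <- pmap$p_hm >= pmap$band[2L] & !pmap$bg
  if (!any(lm))
    stop("no LM pixels: the histograms lack the tissue variety needed to ",
         "estimate the LM reference parameters")
  if (!any(hm))
    stop("no HM pixels: cannot estimate the dense-fibre reference")

  r_ref_lm <- refine_threshold(maps$retardation[lm],
                               "behind_retardation_peak")

  region <- find_reference_region(maps$retardation, valid_mask = hm)
  rv <- sort(maps$retardation[region], decreasing = TRUE)
  n_top <- max(1L, ceiling(0.1 * length(rv)))
  r_ref_hm <- mean(rv[seq_len(n_top)])
  t_m <- mean(maps$transmittance[region])

  tc_counts <- hist_counts(maps$transmittance[lm], 256L)
  t_c <- bin_centre(which.max(tc_counts), 256L)

  out <- pli_params(r_ref_hm, r_ref_lm, t_m, t_c)
  attr(out, "reference_region") <- region
  out
}

#' Clip transmittance to the dense-fibre reference
#'
#' Steeply inclined fibres scatter more and appear darker than in-plane
#' fibres of the same myelin content; transmittance below the dense-fibre
#' reference would otherwise be read as impossibly thick myelin. All values
#' below `t_m` are clipped to it.
#'
#' @param tr transmittance matrix (median-filtered).
#' @param t_m dense-fibre reference transmittance.
#' @return matrix with `tr >= t_m` everywhere.
#' @export
clip_transmittance <- function(tr, t_m) pmax(tr, t_m)

#' Unweighted inclination model
#'
#' `alpha = arccos(sqrt(arcsin(R) / arcsin(R_ref)))`, assuming the product
#' of birefringence and myelin thickness is constant across the section.
#' The ratio is clamped to `[0, 1]` before the square root; retardation
#' above the reference saturates to zero inclination.
#'
#' @param r retardation values in `[0, 1]`.
#' @param r_ref reference retardation in `(0, 1]`.
#' @return inclination angles in degrees `[0, 90]`, with a logical
#'   `saturated` attribute marking clamped pixels.
#' @export
inclination_unweighted <- function(r, r_ref) {
  if (any(r_ref <= 0)) stop("r_ref must be positive")
  ratio <- asin(pmin(pmax(r, 0), 1)) / asin(r_ref)
  sat <- ratio > 1
  alpha <- deg(acos(sqrt(pmin(pmax(ratio, 0), 1))))
  attr(alpha, "saturated") <- sat
  alpha
}

#' Transmittance-weighted inclination model
#'
#' `alpha = arccos(sqrt(arcsin(R) / arcsin(R_ref_HM) *
#' ln(T_c / T_M) / ln(T_c / T)))`. The logarithm ratio equals the inverse
#' local myelin fraction `d_M / d_m` under two-compartment Lambert-Beer
#' attenuation, so the retardation ratio is referred to the locally
#' available myelin rather than to the section-wide maximum. Expects
#' transmittance clipped so `T >= T_M`. The argument is clamped to
#' `[0, 1]`; pixels with `T >= T_c` (no detectable myelin attenuation, the
#' weight diverges) saturate to zero inclination and are flagged.
#'
#' @param r retardation values.
#' @param tr transmittance values (normalised, clipped).
#' @param params a [pli_params()] object.
#' @return inclination angles in degrees, with attribute `saturated`.
#' @export
inclination_weighted <- function(r, tr, params) {
  stopifnot(inherits(params, "pli_params"))
  log_ref <- log(params$t_c / params$t_m)
  log_loc <- log(params$t_c / pmax(tr, params$t_m))
  weight <- ifelse(log_loc > 0, log_ref / log_loc, Inf)
  arg <- asin(pmin(pmax(r, 0), 1)) / asin(params$r_ref_hm) * weight
  sat <- arg > 1 | !is.finite(arg)
  arg <- ifelse(is.finite(arg), arg, 1)
  alpha <- deg(acos(sqrt(pmin(pmax(arg, 0), 1))))
  attr(alpha, "saturated") <- sat
  alpha
}

#' Combined inclination model
#'
#' Linear combination of the transmittance-weighted model (HM branch) and
#' the unweighted model (LM branch) with the HM probability as the weight:
#' `alpha = p * alpha_HM + (1 - p) * alpha_LM`, where the LM branch uses the
#' interpolated reference `R_ref* = p * R_ref_HM + (1 - p) * R_ref_LM` so
#' the reference follows the tissue composition through the transition zone.
#'
#' @param r,tr retardation and (clipped) transmittance values.
#' @param p_hm HM probabilities in `[0, 1]`.
#' @param params a [pli_params()] object.
#' @return inclination angles in degrees, with attribute `saturated` (true
#'   where either branch saturated).
#' @export
inclination_combined <- function(r, tr, p_hm, params) {
  stopifnot(inherits(params, "pli_params"))
  a_hm <- inclination_weighted(r, tr, params)
  r_ref_star <- p_hm * params$r_ref_hm + (1 - p_hm) * params$r_ref_lm
  a_lm <- inclination_unweighted(r, r_ref_star)
  alpha <- p_hm * a_hm + (1 - p_hm) * a_lm
  attr(alpha, "saturated") <-
    (p_hm > 0 & attr(a_hm, "saturated")) |
    (p_hm < 1 & attr(a_lm, "saturated"))
  alpha
}

#' Compute an inclination map under one of four scenarios
#'
#' Scenario `"i"` applies the unweighted model to the whole section with the
#' section-wide highest-retardation reference; `"ii"` the
#' transmittance-weighted model to the whole section; `"iii"` both models
#' hard-split by the binary HM/LM labels; `"iv"` the combined model blended
#' by the HM-probability map. Background pixels are set to `NA`.
#'
#' @param maps a [pli_maps()] object whose transmittance is median-filtered
#'   and clipped (`T >= T_M`).
#' @param scenario one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param params a [pli_params()] object.
#' @param pmap a [compute_pmap()] result (needed for scenarios iii and iv;
#'   also provides the background mask).
#' @return an object of class `pli_inclination`: list with `alpha` (degrees,
#'   `NA` on background), `saturated` and `scenario`.
#' @export
run_scenario <- function(maps, scenario = c("iv", "i", "ii", "iii"),
                         params, pmap) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(maps, "pli_maps"), inherits(params, "pli_params"),
            inherits(pmap, "pli_pmap"))
  r <- maps$retardation
  tr <- maps$transmittance
  alpha <- switch(scenario,
    i = inclination_unweighted(r, params$r_ref_hm),
    ii = inclination_weighted(r, tr, params),
    iii = {
      hm <- pmap$labels == PLI_HM
      a_hm <- inclination_weighted(r, tr, params)
      a_lm <- inclination_unweighted(r, params$r_ref_lm)
      a <- ifelse(hm, a_hm, a_lm)
      attr(a, "saturated") <- ifelse(hm, attr(a_hm, "saturated"),
                                     attr(a_lm, "saturated"))
      a
    },
    iv = inclination_combined(r, tr, pmap$p_hm, params))
  sat <- attr(alpha, "saturated")
  alpha <- matrix(as.numeric(alpha), nrow(r), ncol(r))
  sat <- matrix(as.logical(sat), nrow(r), ncol(r))
  alpha[pmap$bg] <- NA_real_
  sat[pmap$bg] <- FALSE
  structure(list(alpha = alpha, saturated = sat, scenario = scenario),
            class = "pli_inclination")
}

#' @export
print.pli_inclination <- function(x, ...) {
  ok <- !is.na(x$alpha)
  cat(sprintf(
    "pli_inclination (scenario %s): alpha %.1f-%.1f deg over %d tissue pixels (%.1f%% saturated)\n",
    x$scenario, min(x$alpha[ok]), max(x$alpha[ok]), sum(ok),
    100 * mean(x$saturated[ok])))
  invisible(x)
}
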