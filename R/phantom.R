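# Synthetic 3D-PLI phantom with per-pixel ground truth.
#
# The phantom evaluates the measurement forward models on a brain-like
# layout: a dense in-plane fibre band (corpus-callosum-like, containing the
# maximum-retardation reference patch), a steep-fibre band, a cortex-like
# region of low myelination, fibre fans crossing the HM/LM boundary
# (ground-truth transition zones), fibre-bundle blobs in the low-myelination
# surround (putamen-like), and a background margin.

#' Phantom specification
#'
#' Optical and tissue parameters of the synthetic section. The defaults put
#' the maximum phase at `2 pi dn d_M / lambda = pi / 2`, so retardation is
#' strictly increasing in myelin thickness (no |sin| folding) and the
#' inclination models are invertible; `wrapped = TRUE` doubles the
#' birefringence for stress tests of the folded regime. Attenuation uses a
#' myelin coefficient well above the non-birefringent one, giving the
#' bimodal tissue transmittance with a background spike that the histogram
#' analysis expects.
#'
#' @param shape `(height, width)` in pixels.
#' @param lambda_nm wavelength of the incident light in nm.
#' @param d_um section thickness in micrometres.
#' @param d_max_um maximum myelin thickness in micrometres.
#' @param dn birefringence of myelin (dimensionless).
#' @param mu_m,mu_c attenuation coefficients of myelin and of
#'   non-birefringent tissue, per micrometre; `mu_m > mu_c`.
#' @param i0 incident intensity in camera units.
#' @param dark_steep_factor transmittance multiplier applied to densely
#'   myelinated pixels steeper than `dark_steep_alpha`, emulating the extra
#'   scattering of out-of-plane fibres (set to 1 to disable).
#' @param dark_steep_alpha inclination (degrees) above which the factor
#'   applies.
#' @param wrapped if `TRUE`, double the birefringence so the maximum phase
#'   exceeds `pi / 2` (retardation wrap-around stress test).
#' @param seed integer seed for the random tissue fields.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512L, 512L),
                         lambda_nm = 550,
                         d_um = 60,
                         d_max_um = 30,
                         dn = (lambda_nm / 1000) / 4 / d_max_um,
                         mu_m = 0.14,
                         mu_c = 1 / 150,
                         i0 = 1,
                         dark_steep_factor = 0.1,
                         dark_steep_alpha = 60,
                         wrapped = FALSE,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 32L),
            d_max_um > 0, d_max_um <= d_um,
            mu_m > mu_c, mu_c >= 0, i0 > 0,
            dark_steep_factor > 0, dark_steep_factor <= 1)
  if (wrapped) dn <- 2 * dn
  structure(list(shape = as.integer(shape), lambda_nm = lambda_nm,
                 d_um = d_um, d_max_um = d_max_um, dn = dn,
                 mu_m = mu_m, mu_c = mu_c, i0 = i0,
                 dark_steep_factor = dark_steep_factor,
                 dark_steep_alpha = dark_steep_alpha,
                 wrapped = wrapped, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Forward model: retardation of a myelinated fibre layer
#'
#' `R = |sin(2 pi / lambda * dn * d_m * cos^2(alpha))|`.
#'
#' @param d_m_um myelin thickness in micrometres.
#' @param alpha_deg fibre inclination in degrees.
#' @param dn birefringence.
#' @param lambda_nm wavelength in nm.
#' @return retardation in `[0, 1]`.
#' @export
forward_retardation <- function(d_m_um, alpha_deg, dn, lambda_nm) {
  delta <- 2 * pi / (lambda_nm / 1000) * dn * d_m_um *
    cos(alpha_deg * pi / 180)^2
  abs(sin(delta))
}

#' Forward model: two-compartment Lambert-Beer transmittance
#'
#' Light crosses a non-birefringent outer layer of thickness `d - d_M` and
#' a fibre layer of thickness `d_M` split into myelin (`d_m`, coefficient
#' `mu_m`) and non-birefringent tissue (`d_M - d_m`, coefficient `mu_c`):
#' `T = I0~ * exp(-mu_m d_m - mu_c (d_M - d_m))` with
#' `I0~ = I0 * exp(-mu_c (d - d_M))`. The identity
#' `ln(T_c / T) / ln(T_c / T_M) = d_m / d_M` follows for any parameters.
#'
#' @param d_m_um myelin thickness in micrometres.
#' @param spec a [phantom_spec()].
#' @return transmittance in camera units (`i0` scale).
#' @export
forward_transmittance <- function(d_m_um, spec) {
  i0_tilde <- spec$i0 * exp(-spec$mu_c * (spec$d_um - spec$d_max_um))
  i0_tilde * exp(-spec$mu_m * d_m_um -
                   spec$mu_c * (spec$d_max_um - d_m_um))
}

#' Forward model: polariser rotation series
#'
#' Evaluates `I(rho) = T/2 * (1 + R * sin(2 (rho - phi)))` at each rotation
#' angle, optionally adds Gaussian noise of standard deviation `sigma` and
#' floors the intensities at zero.
#'
#' @param tr,r,phi transmittance, retardation and direction matrices.
#' @param angles rotation angles in degrees.
#' @param sigma intensity noise standard deviation (camera units).
#' @param seed integer seed (used only when `sigma > 0`).
#' @return a [pli_series()] object.
#' @export
forward_series <- function(tr, r, phi, angles = seq(0, 170, by = 10),
                           sigma = 0, seed = 1L) {
  stopifnot(all(r >= 0), all(r <= 1))
  h <- nrow(tr); w <- ncol(tr)
  n <- length(angles)
  rho <- angles * pi / 180
  out <- array(0, dim = c(n, h, w))
  phr <- phi * pi / 180
  for (k in seq_len(n)) {
    out[k, , ] <- tr / 2 * (1 + r * sin(2 * (rho[k] - phr)))
  }
  if (sigma > 0) {
    old <- local_rng_seed(seed)
    out <- out + stats::rnorm(length(out), sd = sigma)
    restore_rng(old)
    out[out < 0] <- 0
  }
  pli_series(out, angles)
}

# Smooth random field in (0, 1): a sum of random-phase sinusoids, rank
# transformed so the marginal is exactly uniform (the tissue distributions
# derived from the field then hold for every seed).
smooth_field <- function(h, w, n_modes = 8L) {
  rr <- matrix(seq_len(h) / h, h, w)
  cc <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  g <- matrix(0, h, w)
  for (k in seq_len(n_modes)) {
    fr <- stats::runif(1, -5.5, 5.5)
    fc <- stats::runif(1, -5.5, 5.5)
    ph <- stats::runif(1, 0, 2 * pi)
    g <- g + sin(2 * pi * (fr * rr + fc * cc) + ph)
  }
  matrix(rank(g, ties.method = "first") / (length(g) + 1), h, w)
}

#' Ground-truth label codes of the phantom
#' @export
PLI_TRANSITION <- 3L

#' Generate a synthetic 3D-PLI section with ground truth
#'
#' Builds the brain-like layout described above, evaluates the retardation
#' and transmittance forward models per pixel and returns the parameter
#' maps together with the ground-truth rasters. The low-myelination cortex
#' carries smoothly varying myelin fraction (right-skewed, 1.5 to 8.5
#' percent of `d_M`) with inclinations that steepen with myelin content
#' (10 to 65 degrees, keeping the birefringence product in a narrow band,
#' as a radially organised cortex would); the dense band carries a
#' radial inclination field that reaches 0 degrees at the reference patch
#' (making the maximum-retardation region unique and connected) and myelin
#' fractions of 0.9 to 1; the fans ramp the myelin fraction from cortex
#' values to the band value with a bias towards high myelin (bundles thin
#' out only near their cortical end). Fan pixels are labelled transition
#' for myelin fractions in `[0.03, 0.97]` and LM/HM outside that range.
#'
#' @param spec a [phantom_spec()].
#' @param with_series also evaluate the rotation series ([forward_series()]).
#' @param series_sigma intensity noise for the series.
#' @return an object of class `pli_phantom`: list with `maps` (a
#'   [pli_maps()]; transmittance in `i0` camera units, not normalised),
#'   `truth` (list of `alpha`, `d_m`, `labels`, `myelin_fraction`), `spec`,
#'   and optionally `series`.
#' @export
generate_phantom <- function(spec = phantom_spec(), with_series = FALSE,
                             series_sigma = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1L]; w <- spec$shape[2L]
  sr <- h / 512; sc <- w / 512; sm <- min(sr, sc)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  u_x <- smooth_field(h, w)
  u_p <- smooth_field(h, w)
  u_phi <- smooth_field(h, w)

  # layout (reference geometry at 512 x 512, scaled to the actual shape):
  # a background frame, a thin tissue rim of tapering thickness without
  # myelin (section edge), and the tissue interior
  margin_r <- round(30 * sr); margin_c <- round(30 * sc)
  rim_w_r <- round(8 * sr); rim_w_c <- round(8 * sc)
  outside <- rows <= margin_r | rows > h - margin_r |
    cols <= margin_c | cols > w - margin_c
  interior <- rows > margin_r + rim_w_r & rows <= h - margin_r - rim_w_r &
    cols > margin_c + rim_w_c & cols <= w - margin_c - rim_w_c
  rim <- !outside & !interior
  fan1 <- interior & rows >= round(138 * sr) & rows <= round(177 * sr)
  band <- interior & rows >= round(178 * sr) & rows <= round(247 * sr)
  fan2 <- interior & rows >= round(248 * sr) & rows <= round(287 * sr)
  steep <- interior & rows >= round(320 * sr) & rows <= round(359 * sr) &
    cols >= round(126 * sc) & cols <= round(385 * sc)

  blob_def <- list(c(385, 150, 11, 10), c(395, 250, 12, 20),
                   c(380, 330, 10, 30), c(410, 200, 12, 40),
                   c(420, 300, 11, 50), c(400, 100, 10, 15))
  blobs <- matrix(FALSE, h, w)
  blob_alpha <- matrix(0, h, w)
  for (b in blob_def) {
    m <- (rows - b[1L] * sr)^2 + (cols - b[2L] * sc)^2 <= (b[3L] * sm)^2
    m <- m & interior
    blobs <- blobs | m
    blob_alpha[m] <- b[4L]
  }

  cortex <- interior & !fan1 & !band & !fan2 & !steep & !blobs
  bg <- outside

  # cortex fields. The myelin fraction is a mixture: a thin superficial
  # layer of nearly constant low myelin (the spatially coherent low tail
  # of the smooth field) and a bulk whose density rises softly from the
  # superficial value and ends in a well-populated deep edge; this gives a
  # transmittance histogram with a clear mode near the bright end (the
  # non-birefringent reference) and a sharp dark foot (the HM/LM
  # threshold). The inclination follows the myelin fraction (deeper cortex
  # carries more myelin and steeper fibres) so the birefringence product
  # d_m cos^2(alpha) stays in a narrow band and the retardation histogram
  # shows one compact low peak separated from the background bin.
  u_xc <- u_x  # rank-uniform within the cortex, so the mixture fractions
  idx <- which(cortex)  # hold exactly for any seed
  u_xc[idx] <- rank(u_x[idx], ties.method = "first") / (length(idx) + 1)
  x_cortex <- ifelse(u_xc < 0.12,
                     0.0135 + 0.0008 * (u_xc / 0.12),
                     0.0135 + 0.045 *
                       stats::qbeta(pmax((u_xc - 0.12) / 0.88, 0), 2.5, 1.45))
  p_cortex <- 0.012 * (1 + 0.18 * (u_p - 0.5))
  a_cortex <- acos(sqrt(pmin(p_cortex / x_cortex, 0.97))) * 180 / pi

  # dense band: radial inclination, zero at the reference patch centre;
  # myelin fraction 0.6..1, exactly 1 at the patch so the reference region
  # is unique and the transmittance of dense tissue is not a delta
  pr <- 220 * sr; pc <- 256 * sc
  dist <- sqrt((rows - pr)^2 + (cols - pc)^2)
  rad <- pmin(dist / (350 * sm), 1)^0.7
  a_band <- 25 * rad
  x_band <- 1 - 0.55 * rad * (0.4 + 0.6 * u_x)

  # steep band: 70 to 85 degrees along the columns
  c0 <- round(126 * sc); c1 <- round(385 * sc)
  a_steep <- 70 + 15 * (cols - c0) / max(c1 - c0, 1L)

  x <- x_cortex
  alpha <- a_cortex
  x[band] <- x_band[band]; alpha[band] <- a_band[band]
  x[steep] <- 1; alpha[steep] <- a_steep[steep]
  x[blobs] <- 1; alpha[blobs] <- blob_alpha[blobs]

  # fans: myelin fraction ramps from the local cortex value to 1 towards
  # the band; inclination interpolates cortex -> band, weighted by myelin
  for (fan in list(list(mask = fan1, from = round(138 * sr),
                        to = round(177 * sr), towards_band = TRUE),
                   list(mask = fan2, from = round(248 * sr),
                        to = round(287 * sr), towards_band = FALSE))) {
    m <- fan$mask
    if (!any(m)) next
    f <- (rows[m] - fan$from) / max(fan$to - fan$from, 1L)
    if (!fan$towards_band) f <- 1 - f
    xc <- x_cortex[m]
    xb <- x_band[m]
    xf <- xc + (xb - xc) * f
    x[m] <- xf
    # bundles dive towards the cortex at a moderate angle and flatten
    # into the in-plane band
    alpha[m] <- (1 - xf) * 45 + xf * a_band[m]
  }

  x[bg | rim] <- 0
  alpha[bg | rim] <- NA_real_
  d_m <- x * spec$d_max_um

  labels <- matrix(PLI_LM, h, w)
  labels[bg] <- PLI_BG
  labels[band | steep | blobs] <- PLI_HM
  fanmask <- fan1 | fan2
  labels[fanmask] <- ifelse(x[fanmask] < 0.03, PLI_LM,
                            ifelse(x[fanmask] > 0.97, PLI_HM,
                                   PLI_TRANSITION))

  r <- forward_retardation(d_m, ifelse(is.na(alpha), 0, alpha), spec$dn,
                           spec$lambda_nm)
  r[bg | rim] <- 0
  tr <- forward_transmittance(d_m, spec)
  tr[bg] <- spec$i0
  # section rim: myelin-free tissue whose thickness tapers to the edge
  # (Lambert-Beer with a scaled non-birefringent column)
  if (any(rim)) {
    depth <- pmin(rows - margin_r, h - margin_r - rows + 1L,
                  cols - margin_c, w - margin_c - cols + 1L)
    g <- 0.94 * pmax(depth - u_p, 0) / max(rim_w_r, rim_w_c, 1L)
    tr[rim] <- spec$i0 * exp(-spec$mu_c * spec$d_um * g[rim])
  }
  dark <- !bg & !rim & x > 0.999 & alpha > spec$dark_steep_alpha
  tr[dark] <- tr[dark] * spec$dark_steep_factor

  phi <- 180 * u_phi
  phi[phi >= 180] <- 0

  out <- list(maps = pli_maps(tr, phi, pmin(r, 1)),
              truth = list(alpha = alpha, d_m = d_m, labels = labels,
                           myelin_fraction = x),
              spec = spec)
  if (with_series)
    out$series <- forward_series(tr, pmin(r, 1), phi,
                                 sigma = series_sigma, seed = spec$seed)
  structure(out, class = "pli_phantom")
}

#' @export
print.pli_phantom <- function(x, ...) {
  lab <- x$truth$labels
  n <- length(lab)
  cat(sprintf(
    "pli_phantom %dx%d: %.1f%% HM, %.1f%% LM, %.1f%% transition, %.1f%% background\n",
    nrow(lab), ncol(lab), 100 * sum(lab == PLI_HM) / n,
    100 * sum(lab == PLI_LM) / n, 100 * sum(lab == PLI_TRANSITION) / n,
    100 * sum(lab == PLI_BG) / n))
  invisible(x)
}
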