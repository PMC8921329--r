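#' Construct a polariser rotation series
#'
#' Bundles a stack of intensity images recorded at successive rotation angles
#' of the polariser into a validated object. Per pixel the intensities follow
#' a second-harmonic sinusoid in the rotation angle; its mean, amplitude and
#' phase carry the transmittance, retardation and in-plane fibre direction.
#'
#' @param intensities numeric array of dimension `n_angles x height x width`,
#'   finite and non-negative, in arbitrary camera units.
#' @param angles numeric vector of polariser rotation angles in degrees,
#'   strictly increasing and equally spaced in `[0, 180)`. Defaults to the
#'   standard acquisition of 18 angles in 10 degree steps.
#' @return an object of class `pli_series`.
#' @export
pli_series <- function(intensities,
                       angles = seq(0, 170, by = 10)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array (n_angles x height x width)")
  n <- dim(intensities)[1L]
  if (length(angles) != n)
    stop("angle count (", length(angles), ") does not match stack depth (",
         n, ")")
  if (n < 3L)
    stop("at least 3 rotation angles are needed to resolve mean, amplitude ",
         "and phase of a second-harmonic sinusoid")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (any(angles < 0) || any(angles >= 180))
    stop("angles must lie in [0, 180)")
  step <- 180 / n
  if (any(abs(diff(angles) - step) > 1e-8))
    stop("angles must be equally spaced over [0, 180) (step ", step,
         " degrees); harmonic extraction assumes uniform sampling")
  structure(list(intensities = intensities, angles = as.numeric(angles)),
            class = "pli_series")
}

#' @export
print.pli_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat("pli_series:", d[1L], "angles,", d[2L], "x", d[3L], "pixels\n")
  invisible(x)
}

#' Construct a set of 3D-PLI parameter maps
#'
#' @param transmittance transmittance raster `T` (signal mean times two);
#'   camera units, or `[0, 1]` after normalisation.
#' @param direction in-plane fibre direction raster `phi`, degrees in
#'   `[0, 180)`.
#' @param retardation retardation raster `R = |sin(delta)|` in `[0, 1]`.
#' @return an object of class `pli_maps`.
#' @export
pli_maps <- function(transmittance, direction, retardation) {
  if (!is.matrix(transmittance) || !is.matrix(direction) ||
      !is.matrix(retardation))
    stop("all maps must be matrices")
  if (!identical(dim(transmittance), dim(direction)) ||
      !identical(dim(transmittance), dim(retardation)))
    stop("transmittance, direction and retardation must share one shape")
  if (any(retardation < -1e-12) || any(retardation > 1 + 1e-12))
    stop("retardation must lie in [0, 1]")
  if (any(transmittance < 0))
    stop("transmittance must be non-negative")
  structure(list(transmittance = transmittance,
                 direction = direction,
                 retardation = pmin(pmax(retardation, 0), 1)),
            class = "pli_maps")
}

#' @export
print.pli_maps <- function(x, ...) {
  d <- dim(x$transmittance)
  cat("pli_maps:", d[1L], "x", d[2L], "pixels; T in [",
      format(min(x$transmittance), digits = 4), ",",
      format(max(x$transmittance), digits = 4), "], R in [",
      format(min(x$retardation), digits = 4), ",",
      format(max(x$retardation), digits = 4), "]\n")
  invisible(x)
}

#' Extract transmittance, direction and retardation maps from a rotation series
#'
#' Fits, per pixel, the sinusoid
#' `I(rho) = T/2 * (1 + sin(delta) * sin(2 * (rho - phi)))`
#' by discrete Fourier analysis of orders 0 and 2 over the uniformly sampled
#' rotation angles, which is exact for this signal model. The transmittance is
#' twice the signal mean, the retardation is the second-harmonic amplitude
#' divided by the mean (clipped to `[0, 1]`), and the direction is the phase
#' of the second harmonic mapped to `[0, 180)` degrees.
#'
#' Pixels with zero mean intensity (and pixels with zero amplitude, where the
#' phase is undefined) yield `T = 0`/`R = 0` and `phi = 0` by convention.
#'
#' @param series a [pli_series()] object.
#' @return a [pli_maps()] object.
#' @export
extract_maps <- function(series) {
  stopifnot(inherits(series, "pli_series"))
  d <- dim(series$intensities)
  n <- d[1L]
  rho2 <- 2 * series$angles * pi / 180
  m <- matrix(series$intensities, nrow = n)
  mean_i <- colMeans(m)
  a <- as.vector(crossprod(m, cos(rho2))) * (2 / n)
  b <- as.vector(crossprod(m, sin(rho2))) * (2 / n)
  amp <- sqrt(a * a + b * b)

  tr <- 2 * mean_i
  r <- ifelse(mean_i > 0, pmin(amp / mean_i, 1), 0)
  # amplitudes at numerical-noise level (relative to the mean) carry no
  # phase information: zero retardation, direction 0 by convention
  r[r < 1e-12] <- 0
  # I = T/2 + (T/2) sin(delta) [sin(2 rho) cos(2 phi) - cos(2 rho) sin(2 phi)]
  # => a = -(T/2) sin(delta) sin(2 phi), b = (T/2) sin(delta) cos(2 phi)
  phi <- (atan2(-a, b) / 2) %% pi * 180 / pi
  phi[r == 0] <- 0

  pli_maps(matrix(tr, d[2L], d[3L]),
           matrix(phi, d[2L], d[3L]),
           matrix(r, d[2L], d[3L]))
}
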