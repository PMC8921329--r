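# Pipeline driver, chunked application of local operators, and raster I/O.

#' Run the full inclination pipeline
#'
#' From a rotation series or precomputed maps to an inclination map:
#' signal extraction (if a series is given), transmittance normalisation,
#' circular median filtering, threshold estimation, bootstrap of the
#' transition-zone widths, HM-probability map, model parameter estimation
#' on the region-masked median-filtered transmittance, transmittance
#' clipping, and the scenario evaluation.
#'
#' @param input a [pli_series()], [pli_maps()] or `pli_phantom` object.
#' @param scenario inclination scenario, see [run_scenario()].
#' @param sample_fraction,n_iterations bootstrap settings.
#' @param median_radius radius of the circular median filter in pixels.
#' @param band HM/LM probability cut-offs.
#' @param seed integer seed driving the bootstrap.
#' @return an object of class `pli_result`: list with `maps` (normalised,
#'   histogram-filtered transmittance), `thresholds`, `widths`, `pmap`,
#'   `labels`, `params`, `clipped_transmittance`, `inclination`, `config`.
#' @export
run_pipeline <- function(input, scenario = "iv",
                         sample_fraction = 0.25, n_iterations = 200L,
                         median_radius = 5L, band = c(0.05, 0.95),
                         seed = 1L) {
  if (inherits(input, "pli_phantom")) input <- input$maps
  if (inherits(input, "pli_series")) input <- extract_maps(input)
  stopifnot(inherits(input, "pli_maps"))

  t_norm <- normalise_transmittance(input$transmittance)
  t_hist <- median_filter_disk(t_norm, radius = median_radius)
  maps_hist <- pli_maps(t_hist, input$direction, input$retardation)

  thresholds <- estimate_thresholds(maps_hist)
  labels <- classify_regions(maps_hist, thresholds)
  widths <- bootstrap_thresholds(maps_hist, sample_fraction = sample_fraction,
                                 n_iterations = n_iterations, seed = seed,
                                 thresholds = thresholds)
  pmap <- compute_pmap(maps_hist, thresholds, widths, band = band)

  t_model <- masked_median_filter(t_norm, labels, radius = median_radius)
  maps_model <- pli_maps(t_model, input$direction, input$retardation)
  params <- compute_model_params(maps_model, pmap)
  t_clip <- clip_transmittance(t_model, params$t_m)
  maps_clip <- pli_maps(t_clip, input$direction, input$retardation)

  inclination <- run_scenario(maps_clip, scenario, params, pmap)

  structure(list(maps = maps_hist, thresholds = thresholds, widths = widths,
                 pmap = pmap, labels = labels, params = params,
                 clipped_transmittance = t_clip, inclination = inclination,
                 config = list(scenario = scenario,
                               sample_fraction = sample_fraction,
                               n_iterations = as.integer(n_iterations),
                               median_radius = as.integer(median_radius),
                               band = band, seed = as.integer(seed))),
            class = "pli_result")
}

#' @export
print.pli_result <- function(x, ...) {
  cat("pli_result (scenario", x$config$scenario, ")\n")
  print(x$thresholds)
  print(x$params)
  print(x$inclination)
  invisible(x)
}

#' JSON parameter report of a pipeline run
#'
#' @param result a [run_pipeline()] result.
#' @param path optional file to write to.
#' @return the report as a JSON string (invisibly when written to a file).
#' @export
pipeline_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pli_result"))
  rep <- list(
    thresholds = result$thresholds[c("r_thres", "t_thres", "t_back", "t_ref")],
    widths = result$widths[c("r_plus", "r_minus", "t_plus", "t_minus",
                             "n_iterations", "sample_fraction")],
    params = result$params[c("r_ref_hm", "r_ref_lm", "t_m", "t_c")],
    config = result$config,
    bins = 256L,
    region_size_fraction = c(0.9e-4, 1.1e-4))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Apply a local operator in overlapping tiles
#'
#' Splits the image into tiles, pads each tile with a halo of neighbouring
#' pixels, applies `op` and keeps the tile core. For any operator whose
#' output at a pixel depends only on inputs within `halo` pixels (e.g. the
#' median filter with `halo >= radius`), the result is identical to
#' whole-image application. Histogram-based global stages must never be
#' chunked; chunking is a memory tactic for local operators only.
#'
#' @param image numeric matrix.
#' @param op function taking and returning a matrix of the same shape.
#' @param chunk_shape `(rows, cols)` of the tile core.
#' @param halo overlap width in pixels; must cover the operator footprint.
#' @param footprint_radius declared footprint radius of `op`, checked
#'   against `halo`.
#' @return the processed matrix.
#' @export
chunked_apply <- function(image, op, chunk_shape = c(128L, 128L), halo = 5L,
                          footprint_radius = halo) {
  if (halo < footprint_radius)
    stop("halo (", halo, ") smaller than the operator footprint radius (",
         footprint_radius, ")")
  h <- nrow(image); w <- ncol(image)
  out <- matrix(NA_real_, h, w)
  for (r0 in seq(1L, h, by = chunk_shape[1L])) {
    for (c0 in seq(1L, w, by = chunk_shape[2L])) {
      r1 <- min(r0 + chunk_shape[1L] - 1L, h)
      c1 <- min(c0 + chunk_shape[2L] - 1L, w)
      rp0 <- max(r0 - halo, 1L); cp0 <- max(c0 - halo, 1L)
      rp1 <- min(r1 + halo, h); cp1 <- min(c1 + halo, w)
      tile <- op(image[rp0:rp1, cp0:cp1, drop = FALSE])
      out[r0:r1, c0:c1] <- tile[(r0 - rp0 + 1L):(r1 - rp0 + 1L),
                                (c0 - cp0 + 1L):(c1 - cp0 + 1L),
                                drop = FALSE]
    }
  }
  out
}

# ---- raster I/O -------------------------------------------------------------

#' Read and write 3D-PLI rasters as TIFF
#'
#' `read_series_tiff` reads a multi-page TIFF into a [pli_series()] (pages
#' are rotation angles). `write_maps_tiff` writes the three parameter maps
#' as separate single-page 32-bit float TIFFs named
#' `transmittance.tif`, `direction.tif`, `retardation.tif`;
#' `read_maps_tiff` reads them back. `write_raster_tiff` writes one matrix
#' as a 32-bit float TIFF. Values are stored unscaled.
#'
#' @param path file (series/raster) or directory (maps).
#' @param angles rotation angles for the series pages.
#' @return the read object, or (for writers) the written path, invisibly.
#' @export
read_series_tiff <- function(path, angles = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (is.null(angles)) angles <- seq(0, 180 - 180 / n, length.out = n)
  arr <- array(0, dim = c(n, nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (k in seq_len(n)) arr[k, , ] <- pages[[k]]
  pli_series(arr, angles)
}

#' @rdname read_series_tiff
#' @param series a [pli_series()] object.
#' @export
write_series_tiff <- function(series, path) {
  stopifnot(inherits(series, "pli_series"))
  d <- dim(series$intensities)
  pages <- lapply(seq_len(d[1L]), function(k)
    matrix(series$intensities[k, , ], d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname read_series_tiff
#' @param raster numeric matrix.
#' @export
write_raster_tiff <- function(raster, path) {
  tiff::writeTIFF(raster, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname read_series_tiff
#' @export
read_raster_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' @rdname read_series_tiff
#' @param maps a [pli_maps()] object.
#' @param dir output directory (created if missing).
#' @export
write_maps_tiff <- function(maps, dir) {
  stopifnot(inherits(maps, "pli_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_raster_tiff(maps$transmittance, file.path(dir, "transmittance.tif"))
  write_raster_tiff(maps$direction / 180, file.path(dir, "direction.tif"))
  write_raster_tiff(maps$retardation, file.path(dir, "retardation.tif"))
  invisible(dir)
}

#' @rdname read_series_tiff
#' @export
read_maps_tiff <- function(dir) {
  pli_maps(read_raster_tiff(file.path(dir, "transmittance.tif")),
           read_raster_tiff(file.path(dir, "direction.tif")) * 180,
           read_raster_tiff(file.path(dir, "retardation.tif")))
}

#' Write the region label map as an 8-bit TIFF
#'
#' Background 0, LM 1, HM 2 (stored as `value / 255`).
#'
#' @param labels integer label matrix.
#' @param path output file.
#' @export
write_labels_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}
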