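# Shared fixtures: phantoms are generated once per test run and reused.

phantom_512 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_phantom(phantom_spec(seed = 7))
    val
  }
})

pipeline_512 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_pipeline(phantom_512(), scenario = "iv",
                                           seed = 42)
    val
  }
})

# normalised + histogram-filtered maps for threshold-level tests
maps_512 <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ph <- phantom_512()
      tn <- normalise_transmittance(ph$maps$transmittance)
      val <<- pli_maps(median_filter_disk(tn, 5L), ph$maps$direction,
                       ph$maps$retardation)
    }
    val
  }
})

# small helper: series from closed-form parameters at the standard angles
series_from_params <- function(tr, r, phi, angles = seq(0, 170, by = 10)) {
  forward_series(matrix(tr, 1, 1), matrix(r, 1, 1), matrix(phi, 1, 1),
                 angles = angles)
}
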