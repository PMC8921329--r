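params0 <- pli_params(r_ref_hm = 0.95, r_ref_lm = 0.1, t_m = 0.3, t_c = 0.65)

test_that("masked median filter matches a brute-force oracle", {
  set.seed(31)
  brute <- function(img, labels, radius) {
    h <- nrow(img); w <- ncol(img)
    out <- img
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (labels[i, j] == PLI_BG) next
      vals <- c()
      for (di in -radius:radius) for (dj in -radius:radius) {
        if (di * di + dj * dj > radius * radius) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        if (labels[ii, jj] != labels[i, j]) next
        vals <- c(vals, img[ii, jj])
      }
      out[i, j] <- median(vals)
    }
    out
  }
  for (rep in 1:4) {
    img <- matrix(runif(32 * 32), 32)
    labels <- matrix(sample(0:2, 32 * 32, replace = TRUE), 32)
    got <- masked_median_filter(img, labels, radius = 3L)
    expect_identical(got, brute(img, labels, 3L))
  }
})

test_that("median filter leaves constants and fixes isolated outliers", {
  img <- matrix(5, 20, 20)
  lab <- matrix(PLI_HM, 20, 20)
  expect_equal(masked_median_filter(img, lab), img)
  img[10, 10] <- 100
  out <- masked_median_filter(img, lab)
  expect_equal(out[10, 10], 5)
})

test_that("background pixels pass through and are excluded from footprints", {
  img <- matrix(1, 11, 11)
  lab <- matrix(PLI_LM, 11, 11)
  img[6, 6] <- 50; lab[6, 6] <- PLI_BG
  out <- masked_median_filter(img, lab, radius = 2L)
  expect_equal(out[6, 6], 50)   # unchanged
  expect_equal(out[6, 5], 1)    # neighbour medians ignore the BG value
})

test_that("transmittance clipping is an elementwise floor", {
  tr <- matrix(c(0.1, 0.3, 0.5), 1)
  expect_equal(clip_transmittance(tr, 0.3), matrix(c(0.3, 0.3, 0.5), 1))
  expect_equal(min(clip_transmittance(matrix(runif(100), 10), 0.4)), 0.4)
})

test_that("unweighted model inverts the retardation relation", {
  expect_equal(as.numeric(inclination_unweighted(0.7, 0.7)), 0)
  expect_equal(as.numeric(inclination_unweighted(0, 0.7)), 90)
  # delta_max = pi/2: R = sin(pi/2 cos^2 60deg) inverts to 60deg
  r60 <- sin(pi / 2 * cos(60 * pi / 180)^2)
  expect_equal(as.numeric(inclination_unweighted(r60, 1)), 60,
               tolerance = 1e-10)
  expect_error(inclination_unweighted(0.5, 0), "positive")
})

test_that("weighted model reduces to the unweighted one at T = T_M", {
  r <- seq(0.001, 0.94, length.out = 100)
  a_w <- inclination_weighted(r, rep(params0$t_m, 100), params0)
  a_u <- inclination_unweighted(r, params0$r_ref_hm)
  expect_equal(as.numeric(a_w), as.numeric(a_u), tolerance = 1e-12)
})

test_that("weighted model recovers inclination through the forward model", {
  # pixel with half the maximum myelin at 30 degrees, consistent optics
  spec <- phantom_spec()
  d_m <- spec$d_max_um / 2
  r <- forward_retardation(d_m, 30, spec$dn, spec$lambda_nm)
  tr <- forward_transmittance(d_m, spec)
  t_m <- forward_transmittance(spec$d_max_um, spec)
  t_c <- forward_transmittance(0, spec)
  pars <- pli_params(1, 0.1, t_m, t_c)
  expect_equal(as.numeric(inclination_weighted(r, tr, pars)), 30,
               tolerance = 1)
})

test_that("saturation clamps to zero degrees and is flagged", {
  a <- inclination_weighted(0.94, 0.64, params0)  # weight diverges near t_c
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "saturated"))
  a2 <- inclination_unweighted(0.99, 0.5)
  expect_equal(as.numeric(a2), 0)
  expect_true(attr(a2, "saturated"))
})

test_that("combined model interpolates between its endpoint branches", {
  r <- 0.4; tr <- 0.45
  a1 <- inclination_combined(r, tr, 1, params0)
  expect_equal(as.numeric(a1),
               as.numeric(inclination_weighted(r, tr, params0)))
  a0 <- inclination_combined(r, tr, 0, params0)
  expect_equal(as.numeric(a0),
               as.numeric(inclination_unweighted(r, params0$r_ref_lm)))
  # p = 0.5: mean of the two branches with the midpoint reference (direct
  # independent evaluation)
  p <- 0.5
  r_star <- p * params0$r_ref_hm + (1 - p) * params0$r_ref_lm
  direct <- p * acos(sqrt(min(asin(r) / asin(params0$r_ref_hm) *
                                log(params0$t_c / params0$t_m) /
                                log(params0$t_c / tr), 1))) * 180 / pi +
    (1 - p) * acos(sqrt(min(asin(r) / asin(r_star), 1))) * 180 / pi
  expect_equal(as.numeric(inclination_combined(r, tr, p, params0)), direct,
               tolerance = 1e-12)
})

test_that("inclination is monotone in retardation and bounded", {
  r <- seq(0, 1, length.out = 200)
  for (a in list(inclination_unweighted(r, 0.9),
                 inclination_weighted(r, rep(0.4, 200), params0),
                 inclination_combined(r, rep(0.4, 200), rep(0.3, 200),
                                      params0))) {
    a <- as.numeric(a)
    expect_true(all(diff(a) <= 1e-9))
    expect_true(all(a >= 0 & a <= 90))
  }
  # convex combination bound
  a_h <- as.numeric(inclination_weighted(0.3, 0.45, params0))
  a_c <- as.numeric(inclination_combined(0.3, 0.45, 0.37, params0))
  r_star <- 0.37 * params0$r_ref_hm + 0.63 * params0$r_ref_lm
  a_l <- as.numeric(inclination_unweighted(0.3, r_star))
  expect_gte(a_c, min(a_h, a_l) - 1e-9)
  expect_lte(a_c, max(a_h, a_l) + 1e-9)
})

test_that("model parameter estimation recovers the phantom references", {
  ph <- phantom_512()
  res <- pipeline_512()
  pars <- res$params
  spec <- ph$spec
  # dense in-plane reference: retardation ~ 1, transmittance ~ T_M (in the
  # normalised scale)
  expect_gt(pars$r_ref_hm, 0.98)
  t_m_true <- forward_transmittance(spec$d_max_um, spec)
  mn <- min(ph$maps$transmittance); mx <- max(ph$maps$transmittance)
  expect_equal(pars$t_m, (t_m_true - mn) / (mx - mn), tolerance = 0.02)
  # non-birefringent reference: mode of the superficial cortex layer
  t_c_mode <- forward_transmittance(0.014 * spec$d_max_um, spec)
  expect_equal(pars$t_c, (t_c_mode - mn) / (mx - mn), tolerance = 0.02)
  expect_lt(pars$t_m, pars$t_c)
  expect_lte(pars$r_ref_lm, pars$r_ref_hm)
})

test_that("an image without LM pixels is rejected", {
  maps <- pli_maps(matrix(0.3, 20, 20), matrix(0, 20, 20),
                   matrix(0.8, 20, 20))
  pmap <- structure(list(p_hm = matrix(1, 20, 20),
                         bg = matrix(FALSE, 20, 20),
                         band = c(0.05, 0.95)), class = "pli_pmap")
  expect_error(compute_model_params(maps, pmap), "no LM pixels")
})

test_that("scenarios collapse onto each other at degenerate probabilities", {
  ph <- generate_phantom(phantom_spec(shape = c(128L, 128L), seed = 2))
  res <- suppressWarnings(run_pipeline(ph, scenario = "iv", seed = 3,
                                       n_iterations = 20L))
  maps_c <- pli_maps(res$clipped_transmittance, res$maps$direction,
                     res$maps$retardation)
  # hard-split map with p in {0, 1} everywhere
  pmap_hard <- res$pmap
  pmap_hard$p_hm <- matrix(as.numeric(res$labels == PLI_HM), 128L)
  a_iii <- run_scenario(maps_c, "iii", res$params, res$pmap)
  a_iv_hard <- run_scenario(maps_c, "iv", res$params, pmap_hard)
  expect_equal(a_iv_hard$alpha, a_iii$alpha, tolerance = 1e-12)
  # scenario ii equals iv when p = 1 everywhere
  pmap_one <- res$pmap
  pmap_one$p_hm <- matrix(1, 128L, 128L)
  a_ii <- run_scenario(maps_c, "ii", res$params, res$pmap)
  a_iv_one <- run_scenario(maps_c, "iv", res$params, pmap_one)
  expect_equal(a_iv_one$alpha, a_ii$alpha, tolerance = 1e-12)
})
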