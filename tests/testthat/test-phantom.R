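test_that("retardation forward model obeys its closed form", {
  spec <- phantom_spec()
  expect_equal(forward_retardation(10, 90, spec$dn, spec$lambda_nm), 0,
               tolerance = 1e-12)
  expect_equal(forward_retardation(0, 20, spec$dn, spec$lambda_nm), 0)
  # phase pi/2 at full myelin, in plane
  expect_equal(forward_retardation(spec$d_max_um, 0, spec$dn,
                                   spec$lambda_nm), 1, tolerance = 1e-12)
})

test_that("transmittance forward model hits the reference compartments", {
  spec <- phantom_spec()
  i0t <- spec$i0 * exp(-spec$mu_c * (spec$d_um - spec$d_max_um))
  expect_equal(forward_transmittance(0, spec),
               i0t * exp(-spec$mu_c * spec$d_max_um))
  expect_equal(forward_transmittance(spec$d_max_um, spec),
               i0t * exp(-spec$mu_m * spec$d_max_um))
})

test_that("the Lambert-Beer identity holds for random parameter draws", {
  set.seed(12)
  for (i in 1:200) {
    spec <- phantom_spec(d_um = runif(1, 40, 100),
                         d_max_um = runif(1, 10, 39),
                         mu_m = runif(1, 0.05, 0.3),
                         mu_c = runif(1, 0.001, 0.04))
    d_m <- runif(1, 1e-3, spec$d_max_um - 1e-3)
    t_c <- forward_transmittance(0, spec)
    t_m <- forward_transmittance(spec$d_max_um, spec)
    tr <- forward_transmittance(d_m, spec)
    expect_equal(log(t_c / tr) / log(t_c / t_m), d_m / spec$d_max_um,
                 tolerance = 1e-12)
  }
})

test_that("the identity holds for every generated tissue pixel", {
  ph <- generate_phantom(phantom_spec(shape = c(128L, 128L), seed = 3))
  spec <- ph$spec
  x <- ph$truth$myelin_fraction
  inner <- x > 0 & x < 1 & ph$truth$labels != PLI_BG &
    ph$truth$alpha <= spec$dark_steep_alpha
  t_c <- forward_transmittance(0, spec)
  t_m <- forward_transmittance(spec$d_max_um, spec)
  lhs <- log(t_c / ph$maps$transmittance[inner]) / log(t_c / t_m)
  expect_equal(lhs, x[inner], tolerance = 1e-12)
})

test_that("transmittance decreases strictly with myelin thickness", {
  spec <- phantom_spec()
  d <- seq(0, spec$d_max_um, length.out = 50)
  expect_true(all(diff(forward_transmittance(d, spec)) < 0))
  # default optics keep the phase below pi/2: retardation is monotone too
  r <- forward_retardation(d, 0, spec$dn, spec$lambda_nm)
  expect_true(all(diff(r) > 0))
  # wrapped regime folds
  spec_w <- phantom_spec(wrapped = TRUE)
  r_w <- forward_retardation(d, 0, spec_w$dn, spec_w$lambda_nm)
  expect_false(all(diff(r_w) > 0))
})

test_that("noise-free series round trip through the signal extraction", {
  ph <- generate_phantom(phantom_spec(shape = c(48L, 48L), seed = 5),
                         with_series = TRUE)
  m <- extract_maps(ph$series)
  expect_equal(m$transmittance, ph$maps$transmittance, tolerance = 1e-9)
  expect_equal(m$retardation, ph$maps$retardation, tolerance = 1e-9)
  keep <- ph$maps$retardation > 1e-3
  dphi <- abs(m$direction - ph$maps$direction)[keep]
  expect_lt(max(pmin(dphi, 180 - dphi)), 1e-6)
})

test_that("noisy series give unbiased mid-range retardation", {
  n <- 1000
  tr <- matrix(1, 1, n); r <- matrix(0.5, 1, n); phi <- matrix(70, 1, n)
  s <- forward_series(tr, r, phi, sigma = 0.02, seed = 13)
  m <- extract_maps(s)
  se <- sd(m$retardation) / sqrt(n)
  expect_lt(abs(mean(m$retardation) - 0.5), 3 * se + 1e-4)
})

test_that("the same seed reproduces the phantom bit for bit", {
  p1 <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 17))
  p2 <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 17))
  expect_identical(p1$maps$transmittance, p2$maps$transmittance)
  expect_identical(p1$maps$retardation, p2$maps$retardation)
  expect_identical(p1$truth$alpha, p2$truth$alpha)
})

test_that("default phantom histograms carry the expected mode structure", {
  ph <- phantom_512()
  tn <- normalise_transmittance(ph$maps$transmittance)
  c64 <- pliincline:::hist_counts(as.vector(tn), 64L)
  lab <- ph$truth$labels
  # background spike at the top bin is the global transmittance mode
  expect_equal(which.max(c64), 64L)
  # distinct HM (dark) and LM (bright tissue) transmittance modes
  hm_bin <- which.max(c64[1:20])
  lm_bin <- 20L + which.max(c64[21:60])
  expect_gt(c64[hm_bin], 0.02 * length(tn))
  expect_gt(c64[lm_bin], 0.03 * length(tn))
  # retardation: dominant low peak away from the lowest bin, HM tail high
  c64r <- pliincline:::hist_counts(as.vector(ph$maps$retardation), 64L)
  expect_equal(which.max(c64r), 2L)
  expect_gt(sum(c64r[40:64]), 0.05 * length(tn))
  # background fraction recovered end to end
  res <- pipeline_512()
  bg_est <- mean(res$labels == PLI_BG)
  bg_true <- mean(lab == PLI_BG)
  expect_lt(abs(bg_est - bg_true), 0.01)
})

test_that("ground-truth rasters are consistent", {
  ph <- generate_phantom(phantom_spec(shape = c(128L, 128L), seed = 8))
  x <- ph$truth$myelin_fraction
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(ph$truth$d_m, x * ph$spec$d_max_um)
  a <- ph$truth$alpha
  expect_true(all(is.na(a[ph$truth$labels == PLI_BG])))
  expect_true(all(a[!is.na(a)] >= 0 & a[!is.na(a)] <= 90))
})
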