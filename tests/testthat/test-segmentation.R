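test_that("transmittance normalisation maps extremes to the unit interval", {
  expect_equal(normalise_transmittance(matrix(c(0, 50, 100), 1)),
               matrix(c(0, 0.5, 1), 1))
  m <- matrix(c(0, 0.2, 1, 0.7), 2)
  expect_equal(normalise_transmittance(m), m)
  expect_equal(normalise_transmittance(matrix(c(10, 20, 30), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_error(normalise_transmittance(matrix(2, 3, 3)), "constant")
})

test_that("background masking collapses exactly the qualifying pixels", {
  tr <- matrix(c(0.3, 0.99, 0.5, 0.98), 2)
  rr <- matrix(c(0.2, 0.01, 0.4, 0.30), 2)
  maps <- pli_maps(tr, matrix(0, 2, 2), rr)
  out <- mask_background_for_histograms(maps, t_back = 0.9, r_thres = 0.1)
  # only (0.99, 0.01) qualifies: R <= r_thres and T > t_back
  expect_equal(out$transmittance[2, 1], max(tr))
  expect_equal(out$retardation[2, 1], min(rr))
  expect_equal(out$transmittance[-2], tr[-2])
  expect_equal(out$retardation[-2], rr[-2])
  # no pixel qualifies -> unchanged
  out2 <- mask_background_for_histograms(maps, t_back = 1, r_thres = 0)
  expect_equal(out2$transmittance, tr)
  expect_equal(out2$retardation, rr)
})

test_that("find_reference_region returns the planted high-R blob", {
  r <- matrix(0.1, 200, 500)  # 100,000 pixels
  blob <- cbind(rep(50:54, 2), rep(100:101, each = 5))  # 10 px, 0.01%
  r[blob] <- 0.9
  reg <- find_reference_region(r)
  expect_equal(sum(reg), 10L)
  expect_true(all(reg[blob]))
})

test_that("between two blobs the higher-mean one is selected", {
  r <- matrix(0.1, 200, 500)
  r[20:24, 50:51] <- 0.8
  r[150:154, 300:301] <- 0.95
  reg <- find_reference_region(r)
  expect_equal(sum(reg), 10L)
  expect_true(all(reg[150:154, 300:301]))
})

test_that("the reference region is connected under 8-connectivity", {
  ph <- phantom_512()
  reg <- find_reference_region(ph$maps$retardation)
  lab <- pliincline:::.label_components_cpp(reg, 8L)
  expect_equal(max(lab), 1L)
  frac <- sum(reg) / length(reg)
  expect_gte(frac, 0.9e-4)
  expect_lte(frac, 1.1e-4)
  # the region sits inside the densest in-plane fibre patch: retardation
  # there is the image maximum
  expect_gt(min(ph$maps$retardation[reg]),
            quantile(ph$maps$retardation, 0.999))
})

test_that("union-find labelling matches component structure", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE        # diagonal: one component at 8-conn
  m[5, 5:6] <- TRUE                        # separate component
  lab8 <- pliincline:::.label_components_cpp(m, 8L)
  expect_equal(max(lab8), 2L)
  expect_equal(lab8[1, 1], lab8[2, 2])
  lab4 <- pliincline:::.label_components_cpp(m, 4L)
  expect_equal(max(lab4), 3L)  # diagonal splits at 4-connectivity
})

test_that("classification predicates partition the (R, T) plane", {
  thr <- pli_thresholds(r_thres = 0.3, t_thres = 0.4, t_back = 0.8,
                        t_ref = 0.2)
  g <- expand.grid(r = seq(0, 1, length.out = 21),
                   tr = seq(0, 1, length.out = 21))
  maps <- pli_maps(matrix(g$tr, 21), matrix(0, 21, 21), matrix(g$r, 21))
  lab <- classify_regions(maps, thr)
  hm <- g$r > 0.3 | g$tr < 0.4
  bg <- !hm & g$tr > 0.8
  lm <- !hm & !bg
  expect_equal(as.vector(lab == PLI_HM), hm)
  expect_equal(as.vector(lab == PLI_BG), bg)
  expect_equal(as.vector(lab == PLI_LM), lm)
  # boundary pixels follow the strict/non-strict inequalities
  one <- classify_regions(pli_maps(matrix(0.85, 1, 1), matrix(0, 1, 1),
                                   matrix(0.3, 1, 1)), thr)
  expect_equal(one[1, 1], PLI_BG)
  one <- classify_regions(pli_maps(matrix(0.85, 1, 1), matrix(0, 1, 1),
                                   matrix(0.31, 1, 1)), thr)
  expect_equal(one[1, 1], PLI_HM)
})

test_that("histogram thresholds are invariant under pixel permutation", {
  ph <- generate_phantom(phantom_spec(shape = c(128L, 128L), seed = 2))
  tn <- as.vector(normalise_transmittance(ph$maps$transmittance))
  rv <- as.vector(ph$maps$retardation)
  set.seed(1)
  perm <- sample.int(length(tn))
  expect_identical(refine_threshold(rv, "behind_retardation_peak"),
                   refine_threshold(rv[perm], "behind_retardation_peak"))
  expect_identical(refine_threshold(tn, "before_transmittance_peak"),
                   refine_threshold(tn[perm], "before_transmittance_peak"))
})

test_that("estimated thresholds separate the phantom tissue modes", {
  ph <- phantom_512()
  thr <- estimate_thresholds(maps_512())
  hm <- ph$truth$labels == PLI_HM
  lm <- ph$truth$labels == PLI_LM & ph$truth$myelin_fraction > 0
  # retardation threshold between the LM and HM retardation modes
  expect_gt(thr$r_thres, median(ph$maps$retardation[lm]))
  expect_lt(thr$r_thres, median(ph$maps$retardation[hm]))
  # mid transmittance threshold between the HM and LM transmittance modes
  t_norm <- maps_512()$transmittance
  expect_gt(thr$t_thres, median(t_norm[hm]))
  expect_lt(thr$t_thres, median(t_norm[lm]))
  expect_gt(thr$t_back, max(t_norm[lm]) - 0.02)
  expect_lte(thr$t_thres, thr$t_back)
  expect_lte(thr$t_ref, thr$t_back)
})

test_that("classification matches phantom ground truth outside transitions", {
  ph <- phantom_512()
  thr <- estimate_thresholds(maps_512())
  lab <- classify_regions(maps_512(), thr)
  ok <- ph$truth$labels != PLI_TRANSITION
  expect_gte(mean((lab == ph$truth$labels)[ok]), 0.99)
})
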