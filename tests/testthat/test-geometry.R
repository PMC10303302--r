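test_that("resampling interpolates areas linearly and preserves endpoints", {
  # constant tube
  prof <- tube_profile(3, 2, n = 5)
  rs <- resample_profile(prof, 0.5)
  expect_equal(rs$lumen_area_mm2, rep(pi * 1.5^2, nrow(rs)))
  expect_equal(range(rs$s_mm), c(0, 2))

  # linear ramp midpoint
  ramp <- vessel_profile(c(0, 10), c(2, 4))
  rs <- resample_profile(ramp, 1)
  expect_equal(rs$lumen_area_mm2[rs$s_mm == 5], 3.0)

  # random piecewise-linear profile vs a pointwise interpolation oracle
  set.seed(42)
  s <- sort(c(0, runif(8, 0, 20), 20))
  a <- runif(10, 2, 9)
  prof <- vessel_profile(s, a)
  rs <- resample_profile(prof, 0.37)
  oracle <- function(x) {
    i <- findInterval(x, prof$s_mm, rightmost.closed = TRUE)
    w <- (x - prof$s_mm[i]) / (prof$s_mm[i + 1] - prof$s_mm[i])
    prof$lumen_area_mm2[i] * (1 - w) + prof$lumen_area_mm2[i + 1] * w
  }
  inner <- rs$s_mm < 20
  expect_equal(rs$lumen_area_mm2[inner],
               vapply(rs$s_mm[inner], oracle, numeric(1)),
               tolerance = 1e-12)
})

test_that("profile validation rejects bad geometry", {
  expect_error(vessel_profile(c(0, 5, 3), c(1, 1, 1)), "non-decreasing")
  expect_error(vessel_profile(c(0, 5), c(1, -1)), "positive")
  expect_error(vessel_profile(0, 1), "at least 2")
  expect_error(vessel_profile(c(0, 5), c(4, 4), eem_area_mm2 = c(3, 5)), ">= lumen")
  expect_error(resample_profile(tube_profile(), step_mm = -1), "positive")
})

test_that("reference line fit recovers generating lines", {
  # constant diameter
  ref <- fit_reference(tube_profile(3, 30))
  expect_equal(ref$slope_mm_per_mm, 0, tolerance = 1e-12)
  expect_equal(ref$intercept_mm, 3, tolerance = 1e-12)

  # exact tapered line
  s <- seq(0, 40, by = 0.5)
  d <- 3.2 - 0.02 * s
  ref <- fit_reference(vessel_profile(s, pi * (d / 2)^2))
  expect_equal(ref$slope_mm_per_mm, -0.02, tolerance = 1e-10)
  expect_equal(ref$intercept_mm, 3.2, tolerance = 1e-10)

  # taper plus a narrowing, lesion excluded: generating line recovered
  ves <- make_vessel(length_mm = 40, proximal_diameter_mm = 3.2,
                     taper_mm_per_mm = -0.02,
                     stenoses = list(list(center_mm = 20, length_mm = 10,
                                          ds_pct = 60, shape = "gaussian")))
  ref <- fit_reference(ves$profile, lesion_exclusion = c(15, 25))
  expect_equal(ref$slope_mm_per_mm, -0.02, tolerance = 1e-6)
  expect_equal(ref$intercept_mm, 3.2, tolerance = 1e-6)

  expect_error(fit_reference(tube_profile(3, 30), c(-1, 31)), "Fewer than 2")
})

test_that("reference fit error shrinks roughly as 1/sqrt(n) under noise", {
  err_at <- function(n, seed) {
    set.seed(seed)
    s <- seq(0, 30, length.out = n)
    d <- 3.1 - 0.015 * s + rnorm(n, sd = 0.05)
    ref <- fit_reference(vessel_profile(s, pi * (pmax(d, 0.5) / 2)^2))
    abs(ref$slope_mm_per_mm + 0.015)
  }
  e_small <- mean(vapply(1:30, function(k) err_at(40, k), numeric(1)))
  e_big <- mean(vapply(1:30, function(k) err_at(4000, k), numeric(1)))
  expect_lt(e_big, e_small / 5)  # sqrt(100) = 10 expected, allow slack
})

test_that("lesion delimitation follows the pointwise DS threshold", {
  ref <- fit_reference(tube_profile(3, 30))
  expect_null(detect_lesion(tube_profile(3, 30), ref))

  # single 50% cosine narrowing: interval matches generator DS% > 20 region
  ves <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
                     stenoses = list(list(center_mm = 15, length_mm = 10,
                                          ds_pct = 50)))
  ref <- fit_reference(ves$profile, c(10, 20))
  les <- detect_lesion(ves$profile, ref, 20)
  expect_equal(les[1], ves$truth$lesion_start_mm, tolerance = 0.11)
  expect_equal(les[2], ves$truth$lesion_end_mm, tolerance = 0.11)

  # two separated narrowings: only the deeper one is delimited
  ves2 <- make_vessel(length_mm = 50, proximal_diameter_mm = 3,
                      stenoses = list(list(center_mm = 12, length_mm = 8, ds_pct = 35),
                                      list(center_mm = 35, length_mm = 8, ds_pct = 65)))
  ref2 <- fit_reference(ves2$profile, c(5, 42))
  les2 <- detect_lesion(ves2$profile, ref2, 20)
  expect_true(les2[1] > 20 && les2[2] < 45)  # contains only the deeper lesion
  expect_true(les2[1] <= 35 && 35 <= les2[2])
})

test_that("stenosis metrics reproduce closed-form and brute-force values", {
  # uniform 3 mm tube: MLA = pi * 1.5^2, DS 0
  m <- stenosis_metrics(tube_profile(3, 30))
  expect_equal(m$mla_mm2, pi * 1.5^2, tolerance = 1e-10)
  expect_equal(m$ds_pct, 0, tolerance = 1e-10)

  # flat 3 mm reference with a 1.5 mm minimum: DS 50, AS 75
  ves <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
                     stenoses = list(list(center_mm = 15, length_mm = 10,
                                          ds_pct = 50)))
  ref <- fit_reference(ves$profile, c(10, 20))
  m <- stenosis_metrics(ves$profile, ref)
  expect_equal(m$mld_mm, 1.5, tolerance = 1e-6)
  expect_equal(m$ds_pct, 50, tolerance = 1e-4)
  expect_equal(m$as_pct, 75, tolerance = 1e-4)
  # AS% identity for circular cross-sections
  expect_equal(m$as_pct, 100 * (1 - (1 - m$ds_pct / 100)^2), tolerance = 1e-10)

  # tapered stenosed vessel vs dense-grid brute-force scan
  ves2 <- make_vessel(length_mm = 30, proximal_diameter_mm = 3.2,
                      taper_mm_per_mm = -0.01,
                      stenoses = list(list(center_mm = 14, length_mm = 12,
                                           ds_pct = 55)),
                      step_mm = 0.02)
  ref2 <- fit_reference(ves2$profile, c(8, 20))
  m2 <- stenosis_metrics(ves2$profile, ref2)
  brute_idx <- which.min(ves2$profile$lumen_area_mm2)
  expect_equal(m2$mla_mm2, ves2$profile$lumen_area_mm2[brute_idx])
  expect_equal(m2$mla_position_mm, ves2$profile$s_mm[brute_idx])
  d_ref <- reference_diameter(ref2, m2$mla_position_mm)
  expect_equal(m2$ds_pct, 100 * (1 - m2$mld_mm / d_ref))
  expect_equal(m2$mla_mm2, ves2$truth$mla_mm2, tolerance = 1e-3)
})

test_that("stenosis metrics are stable under grid refinement", {
  ves <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
                     stenoses = list(list(center_mm = 15, length_mm = 10,
                                          ds_pct = 55)), step_mm = 0.01)
  ref <- fit_reference(ves$profile, c(10, 20))
  m_coarse <- stenosis_metrics(resample_profile(ves$profile, 0.25), ref)
  m_fine <- stenosis_metrics(resample_profile(ves$profile, 0.05), ref)
  expect_lt(abs(m_coarse$mla_mm2 - m_fine$mla_mm2) / m_fine$mla_mm2, 0.005)
  expect_lt(abs(m_coarse$ds_pct - m_fine$ds_pct) / m_fine$ds_pct, 0.005)
})

test_that("plaque burden uses EEM at the MLA and bad references warn", {
  ves <- make_vessel(length_mm = 30, proximal_diameter_mm = 3,
                     stenoses = list(list(center_mm = 15, length_mm = 10,
                                          ds_pct = 50)),
                     eem_margin_pct = 15)
  ref <- fit_reference(ves$profile, c(10, 20))
  m <- stenosis_metrics(ves$profile, ref)
  i <- which.min(ves$profile$lumen_area_mm2)
  expect_equal(m$plaque_burden_pct,
               100 * (ves$profile$eem_area_mm2[i] - ves$profile$lumen_area_mm2[i]) /
                 ves$profile$eem_area_mm2[i])

  # reference line fitted on a much narrower segment sits below the lumen:
  # DS% is clamped at zero with a warning flagging the bad fit
  ref_low <- fit_reference(tube_profile(1.5, 20))
  expect_warning(m2 <- stenosis_metrics(tube_profile(3, 20), ref_low), "clamped")
  expect_equal(m2$ds_pct, 0)
})
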