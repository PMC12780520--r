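test_that("reference construction validates and sorts rows", {
  r <- growth_reference(c(0, 1, 2), 1, c(10, 11, 12), 0.1,
                        "weight_for_age", "male", "age_months")
  expect_s3_class(r, "growth_reference")
  expect_equal(nrow(r$table), 3L)
  expect_equal(r$table$M, c(10, 11, 12))

  expect_warning(
    r2 <- growth_reference(c(2, 0, 1), 1, c(12, 10, 11), 0.1,
                           "weight_for_age", "male", "age_months"),
    "not sorted")
  expect_equal(r2$table$t, c(0, 1, 2))
  expect_equal(r2$table$M, c(10, 11, 12))

  expect_error(growth_reference(c(0, 1), 1, c(0, 11), 0.1,
                                "weight_for_age", "male", "age_months"),
               "non-positive M at row")
  expect_error(growth_reference(c(0, 1), 1, c(10, 11), c(0.1, -1),
                                "weight_for_age", "male", "age_months"),
               "non-positive S at row")
  expect_error(growth_reference(0, 1, 10, 0.1,
                                "weight_for_age", "male", "age_months"),
               "at least 2 rows")
})

test_that("CSV round trip with day-to-month conversion and filename metadata", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "weight_for_age_female_age_days.csv")
  write.csv(data.frame(t = c(0, 30.4375, 60.875), L = 1,
                       M = c(3, 3.5, 4), S = 0.1),
            path, row.names = FALSE)
  r <- load_reference(path)
  expect_equal(r$indicator, "weight_for_age")
  expect_equal(r$sex, "female")
  expect_equal(r$axis_kind, "age_months")
  expect_equal(r$table$t, c(0, 1, 2))

  bad <- file.path(dir, "nodata.csv")
  write.csv(data.frame(t = 1:3, L = 1, M = 1:3), bad, row.names = FALSE)
  expect_error(load_reference(bad, "weight_for_age", "male", "age_months"),
               "missing column")
})

test_that("interpolation is exact at knots, linear between, no extrapolation", {
  r <- growth_reference(c(0, 1, 2), c(1, 0.5, 0), c(10, 11, 12),
                        c(0.1, 0.12, 0.14),
                        "weight_for_age", "male", "age_months")
  at_knots <- interpolate_lms(r, c(0, 1, 2))
  expect_equal(at_knots$L, c(1, 0.5, 0))
  expect_equal(at_knots$M, c(10, 11, 12))
  expect_equal(at_knots$S, c(0.1, 0.12, 0.14))
  mid <- interpolate_lms(r, 1.5)
  expect_equal(mid$M, 11.5)
  expect_equal(mid$L, 0.25)
  expect_error(interpolate_lms(r, -0.1), "outside reference range")
  expect_error(interpolate_lms(r, 2.001), "outside reference range")
})

test_that("LMS transform: median, linear case, and high-precision oracle", {
  expect_equal(lms_zscore(10, 1, 10, 0.1), 0)
  expect_equal(lms_zscore(12, 1, 10, 0.1), 2)
  # brute-force arithmetic: ((y/M)^L - 1) / (L*S)
  y <- 14.2; L <- -1.6; M <- 16.0; S <- 0.11
  expected <- ((y / M)^L - 1) / (L * S)
  expect_equal(lms_zscore(y, L, M, S), expected, tolerance = 1e-14)
  expect_lt(abs(expected - (-1.20)), 0.02)
  expect_error(lms_zscore(-1, 1, 10, 0.1), "requires y > 0")
})

test_that("LMS transform is continuous at L = 0 and monotone in y", {
  y <- 8.3; M <- 10; S <- 0.12
  expect_lt(abs(lms_zscore(y, 1e-9, M, S) - lms_zscore(y, 0, M, S)), 1e-6)
  ys <- seq(2, 30, by = 0.25)
  for (L in c(-1.5, 0, 0.7)) {
    z <- lms_zscore(ys, L, M, S)
    expect_true(all(diff(z) > 0))
  }
})

test_that("forward/inverse round trip to 1e-10 over randomized parameters", {
  set.seed(42)
  zgrid <- seq(-5.5, 5, by = 0.25)
  for (i in 1:25) {
    L <- runif(1, -2, 1)
    M <- runif(1, 2, 120)
    S <- runif(1, 0.05, 0.2)
    ok <- 1 + L * S * zgrid > 1e-6 | abs(L) < 1e-8
    z <- zgrid[ok]
    y <- invert_lms_zscore(z, L, M, S)
    expect_lt(max(abs(lms_zscore(y, L, M, S) - z)), 1e-10)
  }
  expect_equal(invert_lms_zscore(0, -1.2, 9.5, 0.11), 9.5)
  expect_equal(invert_lms_zscore(2, 1, 10, 0.1), 12)
  expect_error(invert_lms_zscore(-60, 1, 10, 0.1), "1 \\+ L\\*S\\*z")
})

test_that("restricted adjustment: identity inside [-3,3], continuous, linear beyond", {
  L <- 0.3; M <- 12; S <- 0.13
  z_in <- seq(-3, 3, by = 0.25)
  y_in <- invert_lms_zscore(z_in, L, M, S)
  expect_equal(restricted_adjust(z_in, y_in, L, M, S, "weight_for_age"), z_in)

  # continuity at +/-3
  for (s in c(-1, 1)) {
    z_eps <- s * (3 + 1e-9)
    y_eps <- invert_lms_zscore(z_eps, L, M, S)
    adj <- restricted_adjust(z_eps, y_eps, L, M, S, "weight_for_age")
    expect_lt(abs(adj - s * 3), 1e-6)
  }

  # independent inverse-transform oracle above +3
  z_hi <- 4.7
  y_hi <- invert_lms_zscore(z_hi, L, M, S)
  sd3 <- invert_lms_zscore(3, L, M, S)
  sd2 <- invert_lms_zscore(2, L, M, S)
  expect_equal(restricted_adjust(z_hi, y_hi, L, M, S, "weight_for_age"),
               3 + (y_hi - sd3) / (sd3 - sd2), tolerance = 1e-12)
  z_lo <- -4.1
  y_lo <- invert_lms_zscore(z_lo, L, M, S)
  sd3n <- invert_lms_zscore(-3, L, M, S)
  sd2n <- invert_lms_zscore(-2, L, M, S)
  expect_equal(restricted_adjust(z_lo, y_lo, L, M, S, "weight_for_age"),
               -3 + (y_lo - sd3n) / (sd2n - sd3n), tolerance = 1e-12)

  # height-based indicator passes through
  expect_equal(restricted_adjust(4.7, y_hi, L, M, S, "length_height_for_age"),
               4.7)
})

test_that("compute_indices: medians give zeros, missing inputs degrade gracefully", {
  refs <- generate_reference_fixture(1)
  # a child exactly at the median of every reference
  lhfa <- refs[["length_height_for_age.male.age_months"]]
  wfa <- refs[["weight_for_age.male.age_months"]]
  age <- 10
  med_h <- interpolate_lms(lhfa, age)$M
  med_w <- interpolate_lms(wfa, age)$M
  kid <- data.frame(age_months = age, sex = "male", weight_kg = med_w,
                    lenhei_cm = med_h, measured_recumbent = TRUE)
  z <- compute_indices(kid, refs)
  expect_equal(z$haz, 0, tolerance = 1e-9)
  expect_equal(z$waz, 0, tolerance = 1e-9)
  # at median height the weight-for-length median differs from the
  # weight-for-age median only by interpolation curvature
  expect_lt(abs(z$whz), 0.01)

  kid$weight_kg <- NA
  z2 <- compute_indices(kid, refs)
  expect_false(is.na(z2$haz))
  expect_true(is.na(z2$waz))
  expect_true(is.na(z2$whz))
  expect_false(z2$no_index)

  kid$lenhei_cm <- NA
  z3 <- compute_indices(kid, refs)
  expect_true(z3$no_index)
})

test_that("position correction: recumbent child over 24 months loses 0.7 cm", {
  refs <- generate_reference_fixture(1)
  kid <- data.frame(age_months = 30, sex = "female", weight_kg = 11,
                    lenhei_cm = 90, measured_recumbent = TRUE)
  z <- compute_indices(kid, refs)
  pre_corrected <- data.frame(age_months = 30, sex = "female", weight_kg = 11,
                              lenhei_cm = 90 - 0.7,
                              measured_recumbent = FALSE)
  z_ref <- compute_indices(pre_corrected, refs)
  expect_equal(z$haz, z_ref$haz)
  expect_equal(z$whz, z_ref$whz)
  expect_equal(z$waz, z_ref$waz)

  # unknown position assumes the age-appropriate convention: no correction
  kid$measured_recumbent <- NA
  z_unknown <- compute_indices(kid, refs)
  naive <- data.frame(age_months = 30, sex = "female", weight_kg = 11,
                      lenhei_cm = 90, measured_recumbent = FALSE)
  expect_equal(z_unknown$haz, compute_indices(naive, refs)$haz)

  # correction can be disabled
  z_off <- compute_indices(kid, refs, position_correction = FALSE)
  expect_equal(z_off$haz, compute_indices(naive, refs)$haz)
})
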