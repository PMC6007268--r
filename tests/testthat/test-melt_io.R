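test_that("read_melt_curve parses, sorts and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "20,0.50", "40,0.55", "60,0.60"), f)
  cv <- read_melt_curve(f, C_T = 1e-5)
  expect_s3_class(cv, "melting_curve")
  expect_equal(cv$temperatures, c(20, 40, 60))
  expect_equal(cv$absorbances, c(0.50, 0.55, 0.60))
  expect_equal(cv$C_T, 1e-5)

  # unsorted input comes back sorted ascending
  writeLines(c("temperature,absorbance", "60,0.60", "20,0.50", "40,0.55"), f)
  expect_equal(read_melt_curve(f, 1e-5)$temperatures, c(20, 40, 60))

  # NaN absorbance names the offending line
  writeLines(c("20,0.50", "40,NaN", "60,0.60"), f)
  expect_error(read_melt_curve(f, 1e-5), "line")

  writeLines(c("20,0.50", "20,0.55"), f)
  expect_error(read_melt_curve(f, 1e-5), "duplicated temperatures")

  expect_error(read_melt_curve("/nonexistent/file.csv", 1e-5), "not found")
  writeLines(c("20,0.50", "40,0.55"), f)
  expect_error(read_melt_curve(f, C_T = -1), "positive")
})

test_that("fit_baselines recovers exact lines and flags degenerate curves", {
  Tt <- seq(10, 90, by = 1)
  # first/last 10% lie exactly on known lines
  A <- ifelse(Tt <= 18, 0.001 * Tt + 0.300,
        ifelse(Tt >= 82, 0.002 * Tt + 0.500, 0.45))
  cv <- melting_curve(Tt, A, 1e-5)
  bl <- fit_baselines(cv)
  expect_equal(bl$m_l, 0.001, tolerance = 1e-10)
  expect_equal(bl$b_l, 0.300, tolerance = 1e-10)
  expect_equal(bl$m_u, 0.002, tolerance = 1e-10)
  expect_equal(bl$b_u, 0.500, tolerance = 1e-10)
  expect_false(bl$degenerate)
  expect_gte(bl$n_lower, 2)

  # constant curve: slopes 0, equal intercepts, degenerate
  flat <- melting_curve(Tt, rep(0.5, length(Tt)), 1e-5)
  blf <- fit_baselines(flat)
  expect_equal(blf$m_l, 0); expect_equal(blf$m_u, 0)
  expect_equal(blf$b_l, 0.5); expect_equal(blf$b_u, 0.5)
  expect_true(blf$degenerate)

  expect_error(fit_baselines(melting_curve(1:3, c(1, 2, 3), 1e-5)),
               "insufficient")
})

test_that("baseline recovery from noisy synthetic curves is unbiased", {
  spec <- synthetic_spec(duplexes = "GCACG", concentrations = 1e-4,
                         noise_sd = 0.001, seed = 42)
  mc <- generate_melt(duplex_sequence("GCACG"), spec$params, 1e-4, spec)
  bl <- fit_baselines(mc)
  # generating upper baseline; SE of a 16-point line fit with sd 0.001 is
  # ~0.001/sqrt(16) on the intercept scale near the window centre
  expect_lt(abs(bl$m_u - spec$baselines$m_u), 3 * 2e-4)
  expect_lt(abs(bl$b_u - spec$baselines$b_u), 3 * 2e-2)
})

test_that("to_fraction_paired implements the baseline transformation", {
  Tt <- seq(20, 80, by = 5)
  bl <- structure(list(m_l = 5e-4, b_l = 0.6, m_u = 1e-3, b_u = 0.7,
                       n_lower = 2L, n_upper = 2L, degenerate = FALSE),
                  class = "baseline_fit")
  lower <- bl$m_l * Tt + bl$b_l
  upper <- bl$m_u * Tt + bl$b_u
  expect_equal(to_fraction_paired(melting_curve(Tt, lower, 1e-5), bl)$fractions,
               rep(1, length(Tt)))
  expect_equal(to_fraction_paired(melting_curve(Tt, upper, 1e-5), bl)$fractions,
               rep(0, length(Tt)))
  expect_equal(
    to_fraction_paired(melting_curve(Tt, (upper + lower) / 2, 1e-5),
                       bl)$fractions,
    rep(0.5, length(Tt)))
  # degenerate baselines rejected
  bad <- bl; bad$b_u <- 0.5
  expect_error(to_fraction_paired(melting_curve(Tt, lower, 1e-5), bad),
               "degenerate")
})

test_that("fraction transform is invariant under affine absorbance rescaling", {
  set.seed(3)
  spec <- synthetic_spec(duplexes = "GCUCG", concentrations = 1e-4,
                         noise_sd = 0.002, seed = 3)
  mc <- generate_melt(duplex_sequence("GCUCG"), spec$params, 1e-4, spec)
  f1 <- to_fraction_paired(mc, fit_baselines(mc))$fractions
  a <- 2.5; b <- 0.3
  mc2 <- melting_curve(mc$temperatures, a * mc$absorbances + b, mc$C_T)
  f2 <- to_fraction_paired(mc2, fit_baselines(mc2))$fractions
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("noiseless round trip recovers model fractions", {
  # exact contract: with pure-baseline windows (X identically 1 / 0 in the
  # first/last 10%) the transform inverts the construction to rounding
  Tt <- seq(10, 90, by = 0.5)
  Xstar <- pmin(1, pmax(0, (65 - Tt) / 30))  # 1 below 35, 0 above 65
  m_u <- 1.2e-3; b_u <- 0.70; m_l <- 5e-4; b_l <- 0.60
  A <- (1 - Xstar) * (m_u * Tt + b_u) + Xstar * (m_l * Tt + b_l)
  mc <- melting_curve(Tt, A, 1e-5)
  fc <- to_fraction_paired(mc, fit_baselines(mc))
  expect_lt(max(abs(fc$fractions - Xstar)), 1e-9)

  # thermodynamic melts never reach X = 1/0 exactly (residual association
  # and fraying); a sharp GC-closed 7-mer at low strand concentration,
  # melted from 5 degC as stable duplexes are in practice, keeps the window
  # contamination below the 1e-3 recovery target
  spec <- synthetic_spec(duplexes = "GGCGGCC", concentrations = 1e-7,
                         noise_sd = 0, grid = c(5, 90, 0.5))
  dx <- duplex_sequence("GGCGGCC")
  mc2 <- generate_melt(dx, spec$params, 1e-7, spec)
  X_true <- fraction_paired(dx, spec$params,
                            spec$grid + rnamelt_constants$C_to_K, 1e-7)
  fc2 <- to_fraction_paired(mc2, fit_baselines(mc2))
  expect_lt(max(abs(fc2$fractions - X_true)), 1e-3)
})

test_that("interpolate_tm matches the stated arithmetic and edge cases", {
  expect_equal(interpolate_tm(fraction_curve(c(40, 42), c(0.6, 0.4), 1e-5)), 41)
  expect_equal(interpolate_tm(fraction_curve(c(35, 36), c(0.55, 0.35), 1e-5)),
               35.25)
  expect_equal(
    interpolate_tm(fraction_curve(c(36, 37.1, 38), c(0.7, 0.5, 0.3), 1e-5)),
    37.1)
  expect_error(
    interpolate_tm(fraction_curve(c(30, 40), c(0.9, 0.8), 1e-5)),
    "no transition")
  expect_warning(
    tm <- interpolate_tm(
      fraction_curve(c(30, 31, 32, 33), c(0.6, 0.45, 0.55, 0.4), 1e-5)),
    "first crossing")
  expect_equal(tm, 30 + (0.5 - 0.6) / (0.45 - 0.6), tolerance = 1e-12)
})

test_that("interpolated Tm agrees with dense-grid root bracketing", {
  spec <- synthetic_spec(duplexes = "UCAGACU", concentrations = 5e-5,
                         noise_sd = 0)
  dx <- duplex_sequence("UCAGACU")
  coarse <- predict_curve(dx, spec$params, 5e-5, seq(10, 90, by = 2))
  tm_coarse <- interpolate_tm(coarse)
  dense_T <- seq(10, 90, by = 0.01)
  dense <- predict_curve(dx, spec$params, 5e-5, dense_T)
  idx <- which(diff(sign(dense$fractions - 0.5)) != 0)[1]
  expect_lt(abs(tm_coarse - dense_T[idx]), 2)   # within one coarse grid step
  expect_lt(abs(interpolate_tm(dense) - dense_T[idx]), 0.01)
})

test_that("manifest reading validates and applies overrides", {
  dir <- withr::local_tempdir()
  writeLines(c("10,0.6", "50,0.65", "90,0.8"), file.path(dir, "m1.csv"))
  mf <- file.path(dir, "manifest.csv")
  writeLines(c("curve_id,duplex_id,path,C_T,lower_frac,upper_frac",
               "c1,d1,m1.csv,1e-5,0.2,"), mf)
  df <- read_manifest(mf)
  expect_equal(df$lower_frac, 0.2)
  expect_equal(df$upper_frac, 0.1)
  expect_true(file.exists(df$path))
  writeLines(c("curve_id,duplex_id,C_T", "c1,d1,1e-5"), mf)
  expect_error(read_manifest(mf), "missing column")
})
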