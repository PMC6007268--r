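# Fitting-layer tests run on reduced synthetic corpora (coarse 2 degC grid,
# 2-3 concentrations) so the whole suite stays within minutes; the
# full-scale recovery experiment lives in test-acceptance.R.

test_that("melt_dataset validates duplex/curve linkage", {
  fc <- fraction_curve(c(10, 20), c(0.9, 0.8), 1e-5, duplex_id = "GCACG")
  data <- melt_dataset(list("GCACG"), list(fc))
  expect_equal(data$n_points, 2)
  orphan <- fraction_curve(c(10, 20), c(0.9, 0.8), 1e-5, duplex_id = "nope")
  expect_error(melt_dataset(list("GCACG"), list(orphan)), "unknown duplex")
  expect_error(melt_dataset(list("GCACG", "GCUCG"), list(fc)),
               "without curves")
})

test_that("residuals are zero at truth and match hand arithmetic", {
  cor <- make_corpus(n_duplexes = 6, conc_factors = c(0.25, 4))
  r <- nn_residuals(cor$spec$params, cor$gen$data)
  expect_equal(max(abs(r)), 0)
  expect_length(r, cor$gen$data$n_points)

  # 3-point hand computation on one curve
  dx <- duplex_sequence("GCACG")
  p <- nn_literature()
  temps <- c(30, 40, 50)
  Xm <- fraction_paired(dx, p, temps + 273.15, 1e-5)
  obs <- c(0.9, 0.5, 0.2)
  data1 <- melt_dataset(
    list(dx), list(fraction_curve(temps, obs, 1e-5, duplex_id = "GCACG")))
  expect_equal(nn_residuals(p, data1), obs - Xm, tolerance = 1e-12)
})

test_that("fit at the truth is an immediate fixed point", {
  cor <- make_corpus(n_duplexes = 6, conc_factors = c(0.25, 4))
  fit <- fit_partition_model(cor$gen$data, cor$spec$params, max_iter = 5)
  expect_true(fit$converged)
  expect_lt(fit$residual_norm, 1e-6)
  expect_equal(fit$residual_norm,
               sqrt(sum(nn_residuals(fit$params, cor$gen$data)^2)),
               tolerance = 1e-8)
})

test_that("noiseless recovery from a perturbed start (reduced corpus)", {
  cor <- make_corpus(n_duplexes = 12)
  truth <- cor$spec$params
  set.seed(21)
  init <- truth
  init$dH <- truth$dH * (1 + runif(20, -0.1, 0.1))
  init$dS <- truth$dS * (1 + runif(20, -0.1, 0.1))
  fit <- fit_partition_model(cor$gen$data, init, max_iter = 60)
  helix <- c(stack_names(), "initiation", "terminal_AU")
  err <- abs(delta_g(fit$params, T37)[helix] - delta_g(truth, T37)[helix])
  expect_lt(max(err), 0.01)
})

test_that("multistart is deterministic under seed and reports spreads", {
  cor <- make_corpus(n_duplexes = 5, conc_factors = c(0.25, 4),
                     grid = c(15, 85, 4))
  rep1 <- multistart_fit(cor$gen$data, cor$spec$params, n_starts = 2,
                         seed = 5, max_iter = 25)
  rep2 <- multistart_fit(cor$gen$data, cor$spec$params, n_starts = 2,
                         seed = 5, max_iter = 25)
  expect_identical(rep1$residual_norms, rep2$residual_norms)
  expect_identical(rep1$helix_dG37_spread, rep2$helix_dG37_spread)
  expect_gte(rep1$residual_spread, 0)
  expect_error(multistart_fit(cor$gen$data, cor$spec$params, n_starts = 1),
               "n_starts")
})

test_that("two-state regression recovers a generating set exactly", {
  p <- nn_literature()
  # the full 34-duplex design is full rank (small subsets need not be)
  strands <- table1_duplexes()$top_strand
  sc <- vapply(strands, function(s) duplex_sequence(s)$self_complementary,
               logical(1))
  summaries <- do.call(rbind, lapply(strands, function(s) {
    cnt <- decompose_duplex(s)
    dH <- sum(cnt * p$dH[names(cnt)])
    dS <- sum(cnt * p$dS[names(cnt)])
    if (duplex_sequence(s)$self_complementary) {
      dS <- dS + rnamelt_constants$dS_sym
    }
    data.frame(duplex_id = s, top_strand = s, dH = dH, dH_err = 1,
               dS = dS, dS_err = 2, dG37 = dH - T37 * dS / 1000,
               dG37_err = 0.1, stringsAsFactors = FALSE)
  }))
  fit <- fit_two_state_nn(summaries)
  helix <- c(stack_names(), "initiation", "terminal_AU")
  expect_equal(fit$params$dH[helix], p$dH[helix], tolerance = 1e-8)
  expect_equal(fit$params$dS[helix], p$dS[helix], tolerance = 1e-8)
  # consistent system: residual ~ 0, so reported SEs collapse to ~0
  expect_lt(max(fit$se_dH), 1e-6)

  # design row matches decompose_duplex for the worked example
  cnt <- decompose_duplex("GGCUUCAA")
  expect_equal(unname(cnt[c("GG/CC", "GC/CG", "CU/GA", "AA/UU", "GA/CU",
                            "CA/GU", "initiation", "terminal_AU")]),
               c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L))
})

test_that("equal weights reduce the regression to ordinary least squares", {
  set.seed(31)
  strands <- table1_duplexes()$top_strand
  p <- nn_literature()
  summaries <- do.call(rbind, lapply(strands, function(s) {
    cnt <- decompose_duplex(s)
    dH <- sum(cnt * p$dH[names(cnt)]) + rnorm(1, 0, 2)
    dS <- sum(cnt * p$dS[names(cnt)]) + rnorm(1, 0, 5)
    data.frame(duplex_id = s, top_strand = s, dH = dH, dH_err = 3,
               dS = dS, dS_err = 3, dG37 = dH - T37 * dS / 1000,
               dG37_err = 3, stringsAsFactors = FALSE)
  }))
  fit <- fit_two_state_nn(summaries)
  feats <- c(stack_names(), "initiation", "terminal_AU")
  X <- t(vapply(summaries$top_strand,
                function(s) decompose_duplex(s)[feats],
                numeric(length(feats))))
  ols <- stats::lm.fit(X, summaries$dH)$coefficients
  expect_equal(unname(fit$params$dH[feats]), unname(ols), tolerance = 1e-8)
})

test_that("rank deficiency names the unidentifiable features", {
  # two duplexes cannot identify 12 features
  strands <- rep(c("GCACG", "GCUCG", "GACUCAG"), each = 5)
  summaries <- data.frame(
    duplex_id = paste0("d", seq_along(strands)), top_strand = strands,
    dH = -40, dH_err = 1, dS = -100, dS_err = 1, dG37 = -8, dG37_err = 1,
    stringsAsFactors = FALSE)
  expect_error(fit_two_state_nn(summaries), "unidentifiable")
})

test_that("two-state curve fit recovers generating thermodynamics", {
  p <- nn_literature()
  dx <- duplex_sequence("GACUCAG")
  cnt <- decompose_duplex(dx)
  dH_true <- sum(cnt * p$dH[names(cnt)])
  dS_true <- sum(cnt * p$dS[names(cnt)])
  spec <- synthetic_spec(duplexes = "GACUCAG", concentrations = 1e-4,
                         noise_sd = 0, mode = "two_state", params = p)
  mc <- generate_melt(dx, p, 1e-4, spec)
  fit <- fit_two_state_curve(mc)
  expect_equal(fit$dH, dH_true, tolerance = 1e-3)
  expect_equal(fit$dS, dS_true, tolerance = 1e-3)
  tm_closed <- dH_true / (dS_true / 1000 + R_GAS * log(1e-4 / 4)) - 273.15
  expect_equal(fit$Tm, tm_closed, tolerance = 0.01)

  flat <- melting_curve(seq(10, 90, 0.5),
                        rep(0.65, length(seq(10, 90, 0.5))), 1e-4)
  expect_error(fit_two_state_curve(flat), "no transition")
})

test_that("jackknife on duplicated duplexes gives zero spread", {
  # four copies of the same physical duplex under different ids
  strands <- c("GCACG", "GCACG", "GCACG", "GCACG")
  spec <- synthetic_spec(duplexes = strands, concentrations = c(1e-5, 1e-4),
                         grid = c(15, 85, 4), noise_sd = 0)
  # distinct ids for identical sequences
  dxs <- lapply(seq_along(strands), function(i) {
    duplex_sequence(strands[i], duplex_id = paste0("copy", i))
  })
  spec$duplexes <- dxs
  gen <- suppressWarnings(generate_dataset(spec, transform = FALSE))
  jk <- jackknife(gen$data, spec$params, max_iter = 10)
  expect_length(jk$fits, 4)
  expect_lt(max(jk$param_sd_dG37[c(stack_names(), "initiation",
                                   "terminal_AU")]), 1e-8)
  expect_true(all(jk$param_sd_dG37 >= 0))
  expect_error(jackknife(subset_dataset(gen$data, c("copy1", "copy2")),
                         spec$params), ">= 3 duplexes")
})

test_that("rmsd matches its definition and rejects grid mismatch", {
  a <- fraction_curve(1:5, c(0.9, 0.7, 0.5, 0.3, 0.1), 1e-5)
  expect_equal(rmsd(a, a), 0)
  b <- a; b$fractions <- a$fractions + 0.07
  expect_equal(rmsd(a, b), 0.07)
  h <- fraction_curve(1:3, c(0.5, 0.4, 0.3), 1e-5)
  g <- fraction_curve(1:3, c(0.6, 0.2, 0.3), 1e-5)
  expect_equal(rmsd(h, g), sqrt(mean(c(0.1, 0.2, 0)^2)))
  wrong <- fraction_curve(2:4, c(0.5, 0.4, 0.3), 1e-5)
  expect_error(rmsd(h, wrong), "grids do not match")
})

test_that("paired one-tailed t-test matches stats::t.test", {
  d <- c(0.12, 0.35, -0.04, 0.22, 0.18)
  mine <- paired_one_tailed_t(d)
  ref <- stats::t.test(d, alternative = "greater")
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # one-tailed p is half the two-tailed p when t > 0
  two <- stats::t.test(d)
  expect_equal(mine$p, two$p.value / 2, tolerance = 1e-12)
  # degenerate zero-variance case: undefined, not significant
  z <- paired_one_tailed_t(rep(0, 4))
  expect_true(is.na(z$t))
  expect_false(z$significant)
})

test_that("benchmark report structure and self-comparison", {
  cor <- make_corpus(n_duplexes = 4, conc_factors = 1,
                     grid = c(15, 85, 4))
  p <- cor$spec$params
  rep1 <- benchmark_report(cor$gen$data, list(truth = p, also_truth = p))
  expect_true(all(c("mean_rmsd_per_duplex", "mean_rmsd_per_melt",
                    "mean_abs_dTm_per_duplex", "mean_abs_dTm_per_melt")
                  %in% names(rep1$averages)))
  diffs <- rep1$per_duplex
  expect_equal(diffs$rmsd[diffs$set == "truth"],
               diffs$rmsd[diffs$set == "also_truth"])
  tt <- rep1$t_tests$also_truth$rmsd_per_duplex
  expect_false(isTRUE(tt$significant))

  # truth outperforms a perturbed set on data it generated
  set.seed(9)
  pert <- p
  pert$dH <- p$dH * (1 + runif(20, -0.07, 0.07))
  pert$dS <- p$dS * (1 + runif(20, -0.07, 0.07))
  rep2 <- benchmark_report(cor$gen$data, list(truth = p, perturbed = pert))
  av <- rep2$averages
  expect_lt(av$mean_rmsd_per_duplex[av$set == "truth"],
            av$mean_rmsd_per_duplex[av$set == "perturbed"])
})

test_that("two-state loop preset applies the documented penalty", {
  p <- two_state_loop_preset(nn_literature())
  expect_true(all(p$dH[paste0("loop_", 1:8)] == 10.0))
  expect_true(all(p$dS[paste0("loop_", 1:8)] == -1.0))
  # ~10 kcal/mol free-energy penalty in the melting range
  g <- delta_g(p, 330)
  expect_equal(unname(g["loop_4"]), 10 + 330 / 1000, tolerance = 1e-9)
})
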