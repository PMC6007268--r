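# Parameter estimation: ensemble-model non-linear least squares, the
# two-state baselines, jackknife resampling and benchmark statistics.

#' Assemble a melt dataset
#'
#' @param duplexes List of `duplex_sequence` objects (or top-strand strings).
#' @param curves List of `fraction_curve` objects whose `duplex_id`s all
#'   resolve to a duplex; every duplex must have at least one curve.
#' @return Object of class `melt_dataset`.
#' @export
melt_dataset <- function(duplexes, curves) {
  duplexes <- lapply(duplexes, function(d) {
    if (is.character(d)) duplex_sequence(d) else d
  })
  names(duplexes) <- vapply(duplexes, `[[`, character(1), "duplex_id")
  ids <- vapply(curves, `[[`, character(1), "duplex_id")
  unknown <- setdiff(ids, names(duplexes))
  if (length(unknown) > 0) {
    stop("curve(s) reference unknown duplex id(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  orphan <- setdiff(names(duplexes), ids)
  if (length(orphan) > 0) {
    stop("duplex(es) without curves: ", paste(orphan, collapse = ", "))
  }
  structure(
    list(duplexes = duplexes, curves = curves,
         n_points = sum(vapply(curves, function(cv) length(cv$temperatures),
                               integer(1)))),
    class = "melt_dataset"
  )
}

#' @export
print.melt_dataset <- function(x, ...) {
  cat(sprintf("<melt_dataset> %d duplexes, %d curves, %d points\n",
              length(x$duplexes), length(x$curves), x$n_points))
  invisible(x)
}

#' Subset a melt dataset by duplex
#'
#' @param data A `melt_dataset`.
#' @param keep Character vector of duplex ids to retain.
#' @return A `melt_dataset`.
#' @export
subset_dataset <- function(data, keep) {
  melt_dataset(data$duplexes[keep],
               Filter(function(cv) cv$duplex_id %in% keep, data$curves))
}

# -- parameter vector <-> nn_param_set ---------------------------------------
# Optimizer scaling: dH/10 and dS*T_ref/10000 put both families near
# magnitude 1 (T_ref = 310.15 K).
.H_SCALE <- 10
.S_SCALE <- 10000 / 310.15  # T_ref = 310.15 K

params_to_vector <- function(params) {
  c(params$dH / .H_SCALE, params$dS / .S_SCALE)
}

vector_to_params <- function(theta) {
  nf <- length(nn_feature_names())
  nn_param_set(
    stats::setNames(theta[seq_len(nf)] * .H_SCALE, nn_feature_names()),
    stats::setNames(theta[nf + seq_len(nf)] * .S_SCALE, nn_feature_names())
  )
}

#' Per-point residuals of the ensemble model
#'
#' residual = X_melt(T) - X_model(T); ordering is dataset curve order, then
#' increasing temperature within each curve.
#'
#' @param params An `nn_param_set`.
#' @param data A `melt_dataset` of fraction curves.
#' @return Numeric residual vector over all points.
#' @export
nn_residuals <- function(params, data) {
  by_duplex <- split(seq_along(data$curves),
                     vapply(data$curves, `[[`, character(1), "duplex_id"))
  out <- vector("list", length(data$curves))
  for (id in names(by_duplex)) {
    dx <- data$duplexes[[id]]
    idx <- by_duplex[[id]]
    temps <- unique(sort(unlist(lapply(data$curves[idx],
                                       `[[`, "temperatures"))))
    pg <- partition_grid(dx, params, temps + rnamelt_constants$C_to_K)
    L <- ncol(pg$QL)
    num <- rowSums(pg$QL * pg$QR)
    mean_pi <- ifelse(pg$sumQL > 0, num / pg$sumQL / L, 0)
    for (j in idx) {
      cv <- data$curves[[j]]
      pos <- match(cv$temperatures, temps)
      pbp <- prob_any_pair(pg$Q[pos], cv$C_T, dx$self_complementary)
      X <- pmin(pmax(pbp * mean_pi[pos], 0), 1)
      out[[j]] <- cv$fractions - X
    }
  }
  unlist(out)
}

# -- Levenberg-Marquardt with trust-region damping ---------------------------
# Residual-vector least squares: finite-difference Jacobian (forward, step
# `fd_step` on the scaled parameters), lambda adapted multiplicatively.
.lm_least_squares <- function(resid_fn, theta0, max_iter = 300,
                              ftol = 1e-10, xtol = 1e-10, atol = 1e-6,
                              fd_step = 1e-6) {
  theta <- theta0
  r <- resid_fn(theta)
  cost <- sum(r^2)
  lambda <- 1e-4
  nu <- 2
  converged <- FALSE
  iter <- 0L
  n_par <- length(theta)
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- matrix(0, length(r), n_par)
    for (p in seq_len(n_par)) {
      tp <- theta
      h <- fd_step * max(1, abs(tp[p]))
      tp[p] <- tp[p] + h
      J[, p] <- (resid_fn(tp) - r) / h
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    # Marquardt scaling with a relative floor: directions of near-zero
    # curvature (e.g. loop parameters on loop-free data) must still be
    # damped, or steps explode along them
    dH <- diag(H)
    dH <- pmax(dH, 1e-6 * max(dH, 1e-300), 1e-12)
    improved <- FALSE
    for (tries in 1:40) {
      step <- tryCatch(
        solve(H + lambda * diag(dH, n_par), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        step <- as.numeric(step)
        theta_new <- theta + step
        r_new <- tryCatch(resid_fn(theta_new), error = function(e) NULL)
        if (!is.null(r_new) && all(is.finite(r_new))) {
          cost_new <- sum(r_new^2)
          if (cost_new < cost) {
            # gain ratio: actual vs Jacobian-predicted reduction
            pred <- -sum(step * (2 * g + (H + lambda * diag(dH, n_par)) %*% step))
            rho <- if (pred > 0) (cost - cost_new) / pred else 1
            rel <- (sqrt(cost) - sqrt(cost_new)) / max(sqrt(cost), 1e-300)
            stepnorm <- sqrt(sum(step^2)) / max(1, sqrt(sum(theta^2)))
            theta <- theta_new; r <- r_new; cost <- cost_new
            lambda <- max(lambda * max(1 / 3, 1 - (2 * rho - 1)^3), 1e-14)
            nu <- 2
            improved <- TRUE
            if (rel < ftol || stepnorm < xtol || sqrt(cost) < atol) {
              converged <- TRUE
            }
            break
          }
        }
      }
      lambda <- lambda * nu
      nu <- min(nu * 2, 64)
      if (lambda > 1e14) break
    }
    if (!improved) {
      # no downhill step found: accept as a (local) minimum
      converged <- TRUE
    }
    if (converged) break
  }
  list(theta = theta, residuals = r, residual_norm = sqrt(cost),
       converged = converged, iterations = iter)
}

#' Fit nearest-neighbor parameters to melting curves with the ensemble model
#'
#' Minimizes the sum of squared differences between measured and modeled
#' fractions of maximal base pairs over all points of all curves, by
#' trust-region-damped Levenberg-Marquardt least squares on the 40 scaled
#' enthalpy/entropy parameters. Convergence: relative reduction of the
#' residual norm < 1e-10 or relative step norm < 1e-10.
#'
#' @param data A `melt_dataset`.
#' @param init Initial `nn_param_set` (all 40 parameters).
#' @param max_iter Iteration cap; exceeding it flags `converged = FALSE`
#'   (a diagnostic result, not an error).
#' @param ftol,xtol Convergence tolerances.
#' @param atol Absolute residual-norm floor: a fit whose residual norm drops
#'   below this is exact to numerical purposes (only reachable on noiseless
#'   data) and stops early.
#' @param presearch If TRUE (default), a 1-D scan over a global stability
#'   offset (applied to the initiation enthalpy, which enters every duplex
#'   exactly once) precedes the least-squares iteration. Strongly perturbed
#'   starting values can displace every predicted transition outside the
#'   measured temperature range, where finite-difference gradients are
#'   numerically dead; the scan recentres the ensemble cheaply (a few dozen
#'   residual evaluations) and is a no-op for well-placed starts.
#' @return Object of class `fit_result`: `params`, `residual_norm`,
#'   `per_curve_rmsd` (named), `converged`, `iterations`.
#' @export
fit_partition_model <- function(data, init, max_iter = 300,
                                ftol = 1e-10, xtol = 1e-10, atol = 1e-6,
                                presearch = TRUE) {
  resid_fn <- function(theta) nn_residuals(vector_to_params(theta), data)
  if (presearch) {
    cost_of <- function(p) sum(nn_residuals(p, data)^2)
    best_delta <- 0
    best_cost <- cost_of(init)
    for (delta in seq(-20, 20, by = 1)) {
      if (delta == 0) next
      cand <- init
      cand$dH["initiation"] <- init$dH[["initiation"]] + delta
      cc <- cost_of(cand)
      if (cc < best_cost) { best_cost <- cc; best_delta <- delta }
    }
    init$dH["initiation"] <- init$dH[["initiation"]] + best_delta
  }
  res <- .lm_least_squares(resid_fn, params_to_vector(init),
                           max_iter = max_iter, ftol = ftol, xtol = xtol,
                           atol = atol)
  params <- vector_to_params(res$theta)
  lens <- vapply(data$curves, function(cv) length(cv$temperatures), integer(1))
  grp <- rep(seq_along(lens), lens)
  rmsd_per <- sqrt(tapply(res$residuals^2, grp, mean))
  names(rmsd_per) <- vapply(data$curves, `[[`, character(1), "curve_id")
  structure(
    list(params = params, residual_norm = res$residual_norm,
         per_curve_rmsd = rmsd_per, converged = res$converged,
         iterations = res$iterations),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> residual norm %.6g over %d curves (%sconverged, %d iterations)\n",
              x$residual_norm, length(x$per_curve_rmsd),
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Multistart convergence protocol
#'
#' Runs `n_starts` fits from initial parameter sets obtained by perturbing
#' every parameter of `base_init` with an independent uniform variate of up
#' to `perturb_frac` (default 20%) of its value, and reports the spread of
#' the residual norm and of the helix-feature (stack, initiation, terminal
#' AU) dG37 across starts. Disordered-loop parameters typically vary widely
#' while the residual norm and helix dG37 do not, because short duplexes
#' carry little loop-informative signal.
#'
#' @param data A `melt_dataset`.
#' @param base_init Base initial `nn_param_set`.
#' @param n_starts Number of starts (>= 2), default 100.
#' @param perturb_frac Maximal relative perturbation, default 0.20.
#' @param seed Master seed; per-start substreams are derived
#'   deterministically.
#' @param ... Passed to [fit_partition_model()].
#' @return Object of class `multistart_report`: `fits` (list of
#'   `fit_result`), `residual_norms`, `residual_spread`,
#'   `helix_dG37_spread` (max over helix features of max-min dG37),
#'   `loop_dG37_spread`, `seed`.
#' @export
multistart_fit <- function(data, base_init, n_starts = 100,
                           perturb_frac = 0.20, seed = 1, ...) {
  if (n_starts < 2) stop("n_starts must be >= 2")
  base_theta <- c(base_init$dH, base_init$dS)
  fits <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    set.seed((seed * 1000003L + k) %% .Machine$integer.max)
    u <- stats::runif(length(base_theta), -perturb_frac, perturb_frac)
    pert <- base_theta * (1 + u)
    nf <- length(nn_feature_names())
    init_k <- nn_param_set(
      stats::setNames(pert[seq_len(nf)], nn_feature_names()),
      stats::setNames(pert[nf + seq_len(nf)], nn_feature_names())
    )
    fits[[k]] <- fit_partition_model(data, init_k, ...)
  }
  norms <- vapply(fits, `[[`, numeric(1), "residual_norm")
  helix <- c(stack_names(), "initiation", "terminal_AU")
  g37 <- sapply(fits, function(f) delta_g(f$params, rnamelt_constants$T37))
  spread <- apply(g37, 1, function(v) diff(range(v)))
  structure(
    list(fits = fits, residual_norms = norms,
         residual_spread = diff(range(norms)),
         helix_dG37_spread = max(spread[helix]),
         loop_dG37_spread = max(spread[paste0("loop_", 1:8)]),
         seed = seed),
    class = "multistart_report"
  )
}

#' @export
print.multistart_report <- function(x, ...) {
  cat(sprintf("<multistart_report> %d starts: residual norm %.6g-%.6g (spread %.2g); helix dG37 spread %.2g, loop dG37 spread %.2g kcal/mol\n",
              length(x$fits), min(x$residual_norms), max(x$residual_norms),
              x$residual_spread, x$helix_dG37_spread, x$loop_dG37_spread))
  invisible(x)
}

# -- two-state baselines ------------------------------------------------------

#' Error-weighted two-state nearest-neighbor regression
#'
#' The classical linear route: per-duplex whole-duplex dH, dS and dG37 from
#' two-state curve fits are written as sums of nearest-neighbor
#' contributions and solved by error-weighted linear least squares (SVD),
#' separately for each thermodynamic quantity. Self-complementary duplexes
#' contribute the fixed symmetry correction, which is subtracted from the
#' response (it is not a fitted parameter). Parameter uncertainties are the
#' square roots of the diagonal of the variance-covariance matrix.
#'
#' @param summaries A data.frame with columns `duplex_id`, `top_strand`,
#'   `dH`, `dH_err`, `dS`, `dS_err`, `dG37`, `dG37_err` (kcal/mol and
#'   cal/(mol K); errors are standard errors used as weights 1/err^2).
#' @return List with `params` (an `nn_param_set` whose loop features are 0),
#'   `se_dH`, `se_dS`, `se_dG37` (named standard errors), `dG37` (named
#'   fitted free energies at 37 degC) and `rank`.
#' @export
fit_two_state_nn <- function(summaries) {
  feats <- c(stack_names(), "initiation", "terminal_AU")
  X <- t(vapply(summaries$top_strand,
                function(s) decompose_duplex(s)[feats],
                numeric(length(feats))))
  colnames(X) <- feats
  sc <- vapply(summaries$top_strand,
               function(s) duplex_sequence(s)$self_complementary, logical(1))
  if (nrow(X) < length(feats)) {
    stop("need at least as many duplexes as features (",
         length(feats), "), got ", nrow(X))
  }
  sym_dS <- rnamelt_constants$dS_sym
  sym_dG37 <- -rnamelt_constants$T37 * sym_dS / 1000

  solve_wls <- function(y, err) {
    w <- 1 / err^2
    sw <- sqrt(w)
    Xw <- X * sw
    yw <- y * sw
    sv <- svd(Xw)
    tol <- max(dim(Xw)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    if (!all(pos)) {
      # features in the null space are unidentifiable: name them
      null_load <- abs(sv$v[, !pos, drop = FALSE])
      bad <- feats[apply(null_load, 1, max) > 1e-8]
      stop("rank-deficient two-state design; unidentifiable feature(s): ",
           paste(bad, collapse = ", "))
    }
    beta <- sv$v %*% ((crossprod(sv$u, yw)) / sv$d)
    dof <- nrow(Xw) - ncol(Xw)
    rss <- sum((yw - Xw %*% beta)^2)
    sigma2 <- if (dof > 0) rss / dof else 0
    covb <- sv$v %*% diag(1 / sv$d^2, length(sv$d)) %*% t(sv$v) * sigma2
    list(beta = stats::setNames(as.numeric(beta), feats),
         se = stats::setNames(sqrt(pmax(diag(covb), 0)), feats),
         rank = sum(pos))
  }

  fH <- solve_wls(summaries$dH, summaries$dH_err)
  fS <- solve_wls(summaries$dS - ifelse(sc, sym_dS, 0), summaries$dS_err)
  fG <- solve_wls(summaries$dG37 - ifelse(sc, sym_dG37, 0), summaries$dG37_err)

  zero <- stats::setNames(rep(0, 8), paste0("loop_", 1:8))
  params <- nn_param_set(c(fH$beta, zero), c(fS$beta, zero))
  list(params = params, se_dH = fH$se, se_dS = fS$se,
       se_dG37 = fG$se, dG37 = fG$beta, rank = fH$rank)
}

#' Two-state non-linear fit of a single melting curve
#'
#' Fits A(T) = (1 - f(T)) (m_u T + b_u) + f(T) (m_l T + b_l) where f is the
#' fraction of strands in duplex from the bimolecular two-state equilibrium
#' with K(T) = exp(-(dH - T dS/1000)/RT) at the curve's strand
#' concentration (self-complementarity changes the concentration algebra).
#' Baselines and dH, dS are fit jointly by least squares, initialized from
#' the 10% baseline windows and an interpolated Tm.
#'
#' @param curve A `melting_curve`.
#' @param self_complementary Logical, default FALSE.
#' @param dH_init Optional starting enthalpy, kcal/mol.
#' @return List with `dH` (kcal/mol), `dS` (cal/(mol K)), `Tm` (degC),
#'   `baselines`, `residual_norm`, `converged`.
#' @export
fit_two_state_curve <- function(curve, self_complementary = FALSE,
                                dH_init = -60) {
  bl <- fit_baselines(curve)
  if (bl$degenerate) stop("no transition: degenerate baselines")
  fc <- to_fraction_paired(curve, bl)
  tm0 <- tryCatch(interpolate_tm(fc),
                  error = function(e) stop("no transition: ", conditionMessage(e)))
  TmK <- tm0 + rnamelt_constants$C_to_K
  lnC <- if (self_complementary) log(curve$C_T) else log(curve$C_T / 4)
  dS0 <- 1000 * (dH_init / TmK - rnamelt_constants$R * lnC)

  Tt <- curve$temperatures
  TK <- Tt + rnamelt_constants$C_to_K
  model_A <- function(theta) {
    dH <- theta[1] * .H_SCALE
    dS <- theta[2] * .S_SCALE
    K <- exp(-(dH - TK * dS / 1000) / (rnamelt_constants$R * TK))
    f <- prob_any_pair(K + 1, curve$C_T, self_complementary)
    (1 - f) * (theta[3] * Tt + theta[4]) + f * (theta[5] * Tt + theta[6])
  }
  resid_fn <- function(theta) curve$absorbances - model_A(theta)
  theta0 <- c(dH_init / .H_SCALE, dS0 / .S_SCALE, bl$m_u, bl$b_u, bl$m_l, bl$b_l)
  res <- .lm_least_squares(resid_fn, theta0, max_iter = 200)
  dH <- res$theta[1] * .H_SCALE
  dS <- res$theta[2] * .S_SCALE
  Tm <- dH / (dS / 1000 + rnamelt_constants$R * lnC) - rnamelt_constants$C_to_K
  list(dH = dH, dS = dS, Tm = Tm,
       baselines = list(m_u = res$theta[3], b_u = res$theta[4],
                        m_l = res$theta[5], b_l = res$theta[6]),
       residual_norm = res$residual_norm, converged = res$converged)
}

# -- jackknife ----------------------------------------------------------------

#' Jackknife resampling over duplexes
#'
#' Refits the model once per duplex with that duplex left out, records the
#' held-out predictions for its curves, and reports per-parameter standard
#' deviations across resamples as the parameter uncertainty. Resamples that
#' fail to converge are flagged and excluded from the SD with a warning.
#'
#' @param data A `melt_dataset` with >= 3 duplexes.
#' @param init Initial `nn_param_set` (a full-data fit makes a good warm
#'   start).
#' @param ... Passed to [fit_partition_model()].
#' @return Object of class `jackknife_result`: `fits` (named by left-out
#'   duplex), `heldout_rmsd` (mean RMSD of the left-out duplex's curves
#'   under the resample fit), `param_sd_dH`, `param_sd_dS`,
#'   `param_sd_dG37`, `mean_dG37`, `n_converged`.
#' @export
jackknife <- function(data, init, ...) {
  ids <- names(data$duplexes)
  if (length(ids) < 3) stop("jackknife needs >= 3 duplexes")
  fits <- vector("list", length(ids))
  names(fits) <- ids
  heldout <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    train <- subset_dataset(data, setdiff(ids, id))
    fits[[id]] <- fit_partition_model(train, init, ...)
    test <- subset_dataset(data, id)
    r <- nn_residuals(fits[[id]]$params, test)
    heldout[id] <- sqrt(mean(r^2))
  }
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(conv)) {
    warning("non-converged jackknife resample(s) excluded from SD: ",
            paste(ids[!conv], collapse = ", "))
  }
  use <- fits[conv]
  Hs <- sapply(use, function(f) f$params$dH)
  Ss <- sapply(use, function(f) f$params$dS)
  Gs <- sapply(use, function(f) delta_g(f$params, rnamelt_constants$T37))
  structure(
    list(fits = fits, heldout_rmsd = heldout,
         param_sd_dH = apply(Hs, 1, stats::sd),
         param_sd_dS = apply(Ss, 1, stats::sd),
         param_sd_dG37 = apply(Gs, 1, stats::sd),
         mean_dG37 = rowMeans(Gs),
         n_converged = sum(conv)),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> %d resamples (%d converged); max stack dG37 SD %.3g kcal/mol\n",
              length(x$fits), x$n_converged,
              max(x$param_sd_dG37[stack_names()])))
  invisible(x)
}

# -- benchmarking -------------------------------------------------------------

#' RMSD between an observed and a predicted fraction curve
#'
#' @param observed,predicted `fraction_curve`/`model_curve` objects on the
#'   same temperature grid.
#' @return sqrt(mean squared pointwise difference).
#' @export
rmsd <- function(observed, predicted) {
  if (length(observed$temperatures) != length(predicted$temperatures) ||
      any(abs(observed$temperatures - predicted$temperatures) > 1e-9)) {
    stop("temperature grids do not match")
  }
  sqrt(mean((observed$fractions - predicted$fractions)^2))
}

#' One-tailed paired t-test on accuracy differences
#'
#' Tests whether the mean of the paired differences is greater than zero
#' (alternative: positive improvement), at type I error rate 0.05. With zero
#' variance of the differences the test is undefined and reported as not
#' significant.
#'
#' @param differences Numeric vector (n >= 2) of per-duplex or per-melt
#'   paired accuracy differences (baseline error minus candidate error, so
#'   positive means the candidate is better).
#' @return List with `t`, `df`, `p`, `significant` (at 0.05), `mean_diff`.
#' @export
paired_one_tailed_t <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("need at least 2 paired differences")
  s <- stats::sd(differences)
  m <- mean(differences)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                significant = FALSE, mean_diff = m))
  }
  t <- m / (s / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  list(t = t, df = n - 1L, p = p, significant = is.finite(p) && p < 0.05,
       mean_diff = m)
}

#' Benchmark parameter sets against a melt dataset
#'
#' For every duplex and every named parameter set, computes the RMSD between
#' each observed fraction curve and the ensemble-model prediction at the
#' same temperatures and concentration, and the absolute difference between
#' interpolated experimental Tm and model-predicted Tm. Two-state parameter
#' sets should be passed through [two_state_loop_preset()] first (or set
#' `two_state_preset` to their names). Reports per-duplex means, per-melt
#' values, averages per duplex and per melt, and one-tailed paired t-tests
#' of every set against the first (reference) set, per duplex by default.
#'
#' @param data A `melt_dataset`.
#' @param param_sets Named list of `nn_param_set` objects; the first is the
#'   reference for t-tests.
#' @param two_state_preset Character vector of names in `param_sets` to which
#'   the loop preset (dH = 10 kcal/mol, dS = -1 e.u.) is applied.
#' @param tm_window Search window for [predict_tm()].
#' @return Object of class `benchmark_report`: `per_duplex` (data.frame of
#'   mean RMSD and mean |dTm| per duplex x set), `per_melt`, `averages`
#'   (per-duplex and per-melt averages per set), `t_tests` (vs the reference
#'   set, on per-duplex RMSD and |dTm|; plus per-melt variants).
#' @export
benchmark_report <- function(data, param_sets, two_state_preset = character(),
                             tm_window = c(0, 110)) {
  stopifnot(length(param_sets) >= 1, !is.null(names(param_sets)))
  for (nm in two_state_preset) {
    param_sets[[nm]] <- two_state_loop_preset(param_sets[[nm]])
  }
  sets <- names(param_sets)
  rows <- list()
  for (cv in data$curves) {
    dx <- data$duplexes[[cv$duplex_id]]
    tm_obs <- tryCatch(interpolate_tm(cv), error = function(e) NA_real_)
    for (nm in sets) {
      pc <- predict_curve(dx, param_sets[[nm]], cv$C_T, cv$temperatures)
      tm_mod <- tryCatch(
        predict_tm(dx, param_sets[[nm]], cv$C_T, window = tm_window),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        duplex_id = cv$duplex_id, curve_id = cv$curve_id, set = nm,
        rmsd = rmsd(cv, pc), abs_dTm = abs(tm_obs - tm_mod),
        stringsAsFactors = FALSE)
    }
  }
  per_melt <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(rmsd, abs_dTm) ~ duplex_id + set,
                          data = per_melt, FUN = mean, na.action = stats::na.pass,
                          na.rm = TRUE)
  averages <- do.call(rbind, lapply(sets, function(nm) {
    pd <- agg[agg$set == nm, ]
    pm <- per_melt[per_melt$set == nm, ]
    data.frame(set = nm,
               mean_rmsd_per_duplex = mean(pd$rmsd, na.rm = TRUE),
               mean_rmsd_per_melt = mean(pm$rmsd, na.rm = TRUE),
               mean_abs_dTm_per_duplex = mean(pd$abs_dTm, na.rm = TRUE),
               mean_abs_dTm_per_melt = mean(pm$abs_dTm, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  ref <- sets[1]
  t_tests <- list()
  wide <- function(df, col) {
    out <- stats::reshape(df[, c("duplex_id", "set", col)],
                          idvar = "duplex_id", timevar = "set",
                          direction = "wide")
    stats::setNames(out[, -1, drop = FALSE], sub(paste0(col, "\\."), "",
                                                 names(out)[-1]))
  }
  rm_wide <- wide(agg, "rmsd")
  tm_wide <- wide(agg, "abs_dTm")
  for (nm in setdiff(sets, ref)) {
    t_tests[[nm]] <- list(
      rmsd_per_duplex = paired_one_tailed_t(rm_wide[[ref]] - rm_wide[[nm]]),
      abs_dTm_per_duplex = paired_one_tailed_t(
        stats::na.omit(tm_wide[[ref]] - tm_wide[[nm]]))
    )
  }
  structure(
    list(per_duplex = agg, per_melt = per_melt, averages = averages,
         t_tests = t_tests, reference = ref),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> averages:\n")
  print(x$averages, row.names = FALSE, digits = 4)
  for (nm in names(x$t_tests)) {
    tt <- x$t_tests[[nm]]$rmsd_per_duplex
    cat(sprintf("  %s vs %s (RMSD, per duplex): mean diff %.4g, p = %.3g%s\n",
                x$reference, nm, tt$mean_diff, tt$p,
                if (isTRUE(tt$significant)) " *" else ""))
  }
  invisible(x)
}
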