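# Seeded synthetic optical melting experiments: ensemble (or two-state)
# transition between linear baselines, additive absorbance noise, multiple
# strand concentrations per duplex.

#' Default generating parameter set for synthetic experiments
#'
#' The literature helix parameters extended with mildly destabilizing
#' disordered-loop terms (dH = 0, dS = -(8 + n) e.u. for per-side length n,
#' i.e. dG37 from ~2.8 to ~5.0 kcal/mol), the magnitude expected for
#' unstructured symmetric internal loops.
#'
#' @return An `nn_param_set`.
#' @export
nn_synthetic_truth <- function() {
  p <- nn_literature()
  p$dS[paste0("loop_", 1:8)] <- -(8 + 1:8)
  p$dH[paste0("loop_", 1:8)] <- 0
  p
}

#' Specification of a synthetic melting experiment set
#'
#' @param duplexes Character vector of top strands, or list of
#'   `duplex_sequence`s. Defaults to the 34-duplex reference manifest.
#' @param concentrations Total strand concentrations, mol/L, reused for every
#'   duplex; or NULL (default) for the experimentalist's design: per duplex,
#'   the concentration at which the two-state transition midpoint sits at
#'   `target_tm` is computed from the generating parameters, and
#'   `conc_factors` spread melts around it (clamped to 1e-7..5e-3 M). Weak
#'   short duplexes are thus melted at high concentration and stable ones at
#'   low concentration, keeping every transition inside the grid.
#' @param conc_factors Multiplicative spread of per-duplex concentrations
#'   (default 8 melts over a ~180-fold range).
#' @param target_tm Target transition midpoint for the auto-concentration
#'   rule, degC (default 45).
#' @param grid Temperature grid, degC: `c(start, stop, step)`, default
#'   c(10, 90, 0.5) (161 points, matching typical 100-160 point melts).
#' @param baselines Named list `m_u`, `b_u`, `m_l`, `b_l` (AU/degC, AU). The
#'   defaults slope upward (absorbance rises on melting) with the upper
#'   everywhere above the lower, leaving pure-baseline 10% windows for
#'   transitions in the 30-70 degC range.
#' @param noise_sd Additive absorbance noise SD in AU, default 0.002
#'   (instrument-scale noise on a ~0.1 AU hyperchromic change).
#' @param params Generating `nn_param_set`, default [nn_synthetic_truth()].
#' @param mode "ensemble" (partition-function transition) or "two_state".
#' @param seed Master seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duplexes = NULL,
                           concentrations = NULL,
                           conc_factors = 2^seq(-3.5, 3.5, by = 1),
                           target_tm = 45,
                           grid = c(10, 90, 0.5),
                           baselines = list(m_u = 1.2e-3, b_u = 0.70,
                                            m_l = 5e-4, b_l = 0.60),
                           noise_sd = 0.002,
                           params = nn_synthetic_truth(),
                           mode = c("ensemble", "two_state"),
                           seed = 1) {
  mode <- match.arg(mode)
  if (is.null(duplexes)) duplexes <- table1_duplexes()$top_strand
  duplexes <- lapply(duplexes, function(d) {
    if (is.character(d)) duplex_sequence(d) else d
  })
  if (grid[3] <= 0) stop("grid step must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(concentrations) && any(concentrations <= 0)) {
    stop("concentrations must be positive")
  }
  Tg <- seq(grid[1], grid[2], by = grid[3])
  up <- baselines$m_u * Tg + baselines$b_u
  lo <- baselines$m_l * Tg + baselines$b_l
  if (any(up <= lo)) {
    stop("invalid spec: baselines cross within the temperature grid")
  }
  structure(
    list(duplexes = duplexes, concentrations = concentrations,
         conc_factors = conc_factors, target_tm = target_tm,
         grid = Tg, baselines = baselines, noise_sd = noise_sd,
         params = params, mode = mode, seed = seed),
    class = "synthetic_spec"
  )
}

# Concentrations for one duplex under a spec: explicit list, or the
# auto rule C* such that the two-state midpoint sits at target_tm
# (K(T*) C*/4 = 1 for heteroduplexes, K(T*) C* = 1 for self-complementary).
.spec_concentrations <- function(spec, seq) {
  if (!is.null(spec$concentrations)) return(spec$concentrations)
  TK <- spec$target_tm + rnamelt_constants$C_to_K
  cnt <- decompose_duplex(seq)
  dH <- sum(cnt * spec$params$dH[names(cnt)])
  dS <- sum(cnt * spec$params$dS[names(cnt)])
  if (seq$self_complementary) dS <- dS + rnamelt_constants$dS_sym
  K <- exp(-(dH - TK * dS / 1000) / (rnamelt_constants$R * TK))
  base <- if (seq$self_complementary) 1 / K else 4 / K
  pmin(pmax(base * spec$conc_factors, 1e-7), 5e-3)
}

# Two-state restricted fraction: only the fully paired structure competes
# with the denatured state.
.two_state_fraction <- function(seq, params, T_kelvin, C_T) {
  counts <- decompose_duplex(seq)
  dH <- sum(counts * params$dH[names(counts)])
  dS <- sum(counts * params$dS[names(counts)])
  if (seq$self_complementary) dS <- dS + rnamelt_constants$dS_sym
  K <- exp(-(dH - T_kelvin * dS / 1000) / (rnamelt_constants$R * T_kelvin))
  prob_any_pair(K + 1, C_T, seq$self_complementary)
}

#' Generate one synthetic melting curve
#'
#' A(T) = (1 - X(T)) (m_u T + b_u) + X(T) (m_l T + b_l) + noise, with X from
#' the ensemble model (or the two-state restriction). Deterministic given
#' the seed.
#'
#' @param seq A `duplex_sequence` or top strand.
#' @param params Generating `nn_param_set`.
#' @param C_T Total strand concentration, mol/L.
#' @param spec A `synthetic_spec` (grid, baselines, noise, mode).
#' @param seed Seed for this curve's noise (default: spec$seed).
#' @param curve_id Identifier.
#' @return A `melting_curve`.
#' @export
generate_melt <- function(seq, params, C_T, spec, seed = spec$seed,
                          curve_id = NULL) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  if (is.null(curve_id)) curve_id <- sprintf("%s_%.3g", seq$duplex_id, C_T)
  Tg <- spec$grid
  TK <- Tg + rnamelt_constants$C_to_K
  X <- if (spec$mode == "two_state") {
    .two_state_fraction(seq, params, TK, C_T)
  } else {
    fraction_paired(seq, params, TK, C_T)
  }
  bl <- spec$baselines
  A <- (1 - X) * (bl$m_u * Tg + bl$b_u) + X * (bl$m_l * Tg + bl$b_l)
  if (spec$noise_sd > 0) {
    set.seed(seed %% .Machine$integer.max)
    A <- A + stats::rnorm(length(A), sd = spec$noise_sd)
  }
  melting_curve(Tg, A, C_T, curve_id = curve_id, duplex_id = seq$duplex_id)
}

#' Generate a full synthetic melt dataset
#'
#' One curve per duplex x concentration. Curves are returned already
#' transformed to fraction curves via the standard baseline-fit pipeline
#' (and, optionally, as raw absorbance curves). The generating truth is
#' attached for recovery scoring. Warns if some Watson-Crick stack is not
#' represented in any duplex (recovery tests need full coverage).
#'
#' @param spec A `synthetic_spec`.
#' @param transform How to obtain fraction curves from the generated
#'   absorbances: `"fit"` (default) runs the full `fit_baselines` +
#'   `to_fraction_paired` pipeline; `"exact"` applies the fraction
#'   transformation with the generating (true) baselines, isolating
#'   absorbance noise from baseline-estimation error; `"none"` stores the
#'   exact model fractions (noise-free regardless of noise_sd). `TRUE`/
#'   `FALSE` are accepted as aliases for `"fit"`/`"none"`.
#' @return List with `data` (a `melt_dataset` of fraction curves), `raw`
#'   (list of `melting_curve`s), `truth` (the generating `nn_param_set`),
#'   `coverage` (feature counts across duplexes).
#' @export
generate_dataset <- function(spec, transform = c("fit", "exact", "none")) {
  if (is.logical(transform)) transform <- if (transform) "fit" else "none"
  transform <- match.arg(transform)
  coverage <- Reduce(`+`, lapply(spec$duplexes, decompose_duplex))
  absent <- names(coverage)[coverage == 0 & names(coverage) %in% stack_names()]
  if (length(absent) > 0) {
    warning("stack feature(s) not covered by any duplex: ",
            paste(absent, collapse = ", "))
  }
  bl <- spec$baselines
  true_baselines <- structure(
    list(m_l = bl$m_l, b_l = bl$b_l, m_u = bl$m_u, b_u = bl$b_u,
         n_lower = NA_integer_, n_upper = NA_integer_, degenerate = FALSE),
    class = "baseline_fit")
  raw <- list()
  curves <- list()
  k <- 0L
  for (di in seq_along(spec$duplexes)) {
    dx <- spec$duplexes[[di]]
    concs <- .spec_concentrations(spec, dx)
    for (ci in seq_along(concs)) {
      k <- k + 1L
      C_T <- concs[ci]
      cid <- sprintf("%s_c%02d", dx$duplex_id, ci)
      mc <- generate_melt(dx, spec$params, C_T, spec,
                          seed = (spec$seed * 7919L + k) %% .Machine$integer.max,
                          curve_id = cid)
      raw[[k]] <- mc
      curves[[k]] <- switch(transform,
        fit = to_fraction_paired(mc, fit_baselines(mc)),
        exact = to_fraction_paired(mc, true_baselines),
        none = {
          TK <- spec$grid + rnamelt_constants$C_to_K
          X <- if (spec$mode == "two_state") {
            .two_state_fraction(dx, spec$params, TK, C_T)
          } else {
            fraction_paired(dx, spec$params, TK, C_T)
          }
          fraction_curve(spec$grid, X, C_T, curve_id = cid,
                         duplex_id = dx$duplex_id)
        })
    }
  }
  list(data = melt_dataset(spec$duplexes, curves), raw = raw,
       truth = spec$params, coverage = coverage)
}

#' Write a synthetic dataset as melt CSVs plus a manifest
#'
#' @param gen Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV.
#' @export
write_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(gen$raw, function(mc) {
    f <- paste0(mc$curve_id, ".csv")
    write_melt_curve(mc, file.path(dir, f))
    data.frame(curve_id = mc$curve_id, duplex_id = mc$duplex_id,
               path = f, C_T = mc$C_T, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  seqs <- data.frame(
    duplex_id = vapply(gen$data$duplexes, `[[`, character(1), "duplex_id"),
    top_strand = vapply(gen$data$duplexes, `[[`, character(1), "top_strand"),
    stringsAsFactors = FALSE)
  manifest$top_strand <- seqs$top_strand[match(manifest$duplex_id,
                                               seqs$duplex_id)]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a melt dataset from a manifest
#'
#' Reads every melt CSV listed in the manifest, fits baselines (honouring
#' per-curve window overrides) and transforms to fraction curves.
#'
#' @param manifest_path Manifest CSV (see [read_manifest()]); must carry a
#'   `top_strand` column or be accompanied by `duplexes`.
#' @param duplexes Optional named character vector duplex_id -> top strand.
#' @return A `melt_dataset`.
#' @export
load_dataset <- function(manifest_path, duplexes = NULL) {
  mf <- read_manifest(manifest_path)
  if (is.null(duplexes)) {
    if (!"top_strand" %in% names(mf)) {
      stop("manifest has no top_strand column and no duplexes supplied")
    }
    duplexes <- mf$top_strand[!duplicated(mf$duplex_id)]
    names(duplexes) <- mf$duplex_id[!duplicated(mf$duplex_id)]
  }
  dxs <- lapply(names(duplexes), function(id) {
    duplex_sequence(duplexes[[id]], duplex_id = id)
  })
  curves <- lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    if (!file.exists(row$path)) {
      stop("manifest row ", i, " (curve '", row$curve_id,
           "'): melt file not found: ", row$path)
    }
    mc <- read_melt_curve(row$path, C_T = row$C_T, curve_id = row$curve_id,
                          duplex_id = row$duplex_id)
    to_fraction_paired(mc, fit_baselines(mc, row$lower_frac, row$upper_frac))
  })
  melt_dataset(dxs, curves)
}
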