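# Reading optical melting curves, baseline correction, fraction-paired
# transformation and experimental Tm interpolation.

#' Construct a melting curve
#'
#' @param temperatures Numeric, degC, strictly increasing after sorting.
#' @param absorbances Numeric, AU, same length, finite.
#' @param C_T Total strand concentration, mol/L (> 0).
#' @param curve_id,duplex_id Identifiers.
#' @return Object of class `melting_curve`; points sorted by temperature.
#' @export
melting_curve <- function(temperatures, absorbances, C_T,
                          curve_id = "curve", duplex_id = "duplex") {
  if (length(temperatures) != length(absorbances)) {
    stop("temperatures and absorbances must have equal length")
  }
  if (!all(is.finite(temperatures)) || !all(is.finite(absorbances))) {
    bad <- which(!is.finite(temperatures) | !is.finite(absorbances))
    stop("non-finite temperature/absorbance at point(s): ",
         paste(bad, collapse = ", "))
  }
  ord <- order(temperatures)
  temperatures <- temperatures[ord]
  absorbances <- absorbances[ord]
  if (anyDuplicated(temperatures)) {
    dup <- which(duplicated(temperatures))
    stop("duplicated temperatures at sorted point(s): ",
         paste(dup, collapse = ", "))
  }
  if (!is.numeric(C_T) || length(C_T) != 1 || !is.finite(C_T) || C_T <= 0) {
    stop("C_T must be a single positive strand concentration in mol/L")
  }
  structure(
    list(curve_id = curve_id, duplex_id = duplex_id,
         temperatures = temperatures, absorbances = absorbances, C_T = C_T),
    class = "melting_curve"
  )
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %s (%s): %d points, %.4g-%.4g degC, C_T = %.3g M\n",
              x$curve_id, x$duplex_id, length(x$temperatures),
              min(x$temperatures), max(x$temperatures), x$C_T))
  invisible(x)
}

#' Read a melting curve from a two-column CSV
#'
#' Expects comma-separated temperature (degC) and absorbance (AU) columns;
#' '#' comments and an optional single non-numeric header line are allowed.
#'
#' @param path File path.
#' @param C_T Total strand concentration, mol/L.
#' @param curve_id,duplex_id Identifiers (default from file name).
#' @return A `melting_curve`, sorted by temperature.
#' @export
read_melt_curve <- function(path, C_T, curve_id = NULL, duplex_id = "duplex") {
  if (!file.exists(path)) stop("melt file not found: ", path)
  if (is.null(curve_id)) curve_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no data rows in ", path)
  parse_row <- function(s) suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
  first <- parse_row(lines[1])
  if (all(is.na(first))) {  # header line
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (length(lines) == 0) stop("no numeric rows in ", path)
  vals <- lapply(lines, parse_row)
  ncols <- vapply(vals, length, integer(1))
  bad <- which(ncols < 2 | vapply(vals, function(v) anyNA(v[1:2]), logical(1)))
  if (length(bad) > 0) {
    stop("non-numeric or malformed row(s) in ", path, " at line(s): ",
         paste(lineno[bad], collapse = ", "))
  }
  Tc <- vapply(vals, `[`, numeric(1), 1)
  A <- vapply(vals, `[`, numeric(1), 2)
  melting_curve(Tc, A, C_T, curve_id = curve_id, duplex_id = duplex_id)
}

#' Write a melting curve (or model curve) to CSV
#'
#' @param curve A `melting_curve`, `fraction_curve` or `model_curve`.
#' @param path Output path.
#' @export
write_melt_curve <- function(curve, path) {
  y <- if (!is.null(curve$absorbances)) {
    cbind(temperature_C = curve$temperatures, absorbance_AU = curve$absorbances)
  } else {
    cbind(temperature_C = curve$temperatures, fraction = curve$fractions)
  }
  utils::write.csv(as.data.frame(y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit linear upper and lower baselines
#'
#' Least-squares lines through the first `lower_frac` (low-temperature,
#' double-helix side -> lower baseline) and last `upper_frac` (high-
#' temperature, random-coil side -> upper baseline) of the points. Window
#' fractions default to 10% each and may be adjusted per curve when the
#' automatic windows do not cover purely linear regions.
#'
#' @param curve A `melting_curve`.
#' @param lower_frac,upper_frac Fractions of the point count (0 < f < 1).
#' @return Object of class `baseline_fit` with slopes/intercepts
#'   (`m_l`, `b_l`, `m_u`, `b_u`, AU/degC and AU), window sizes `n_lower`,
#'   `n_upper`, and `degenerate` (TRUE when the upper baseline does not lie
#'   strictly above the lower across the curve's temperature span).
#' @export
fit_baselines <- function(curve, lower_frac = 0.10, upper_frac = 0.10) {
  n <- length(curve$temperatures)
  n_lower <- max(2L, floor(lower_frac * n))
  n_upper <- max(2L, floor(upper_frac * n))
  if (n < 4L || n_lower + n_upper > n) {
    stop("insufficient points for baseline fitting: n = ", n)
  }
  fit_line <- function(idx, which) {
    Tt <- curve$temperatures[idx]
    A <- curve$absorbances[idx]
    if (length(idx) < 2) stop("fewer than 2 points in ", which, " window")
    if (diff(range(Tt)) <= 0) {
      stop("zero temperature spread in ", which, " baseline window")
    }
    cf <- stats::lm.fit(cbind(1, Tt), A)$coefficients
    c(slope = unname(cf[2]), intercept = unname(cf[1]))
  }
  lo <- fit_line(seq_len(n_lower), "lower")
  up <- fit_line(seq(n - n_upper + 1L, n), "upper")
  span <- range(curve$temperatures)
  sep <- (up["slope"] * span + up["intercept"]) -
         (lo["slope"] * span + lo["intercept"])
  sep[abs(sep) < 1e-12] <- 0  # identical baselines up to rounding
  structure(
    list(m_l = unname(lo["slope"]), b_l = unname(lo["intercept"]),
         m_u = unname(up["slope"]), b_u = unname(up["intercept"]),
         n_lower = n_lower, n_upper = n_upper,
         degenerate = any(sep <= 0)),
    class = "baseline_fit"
  )
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> lower: A = %.4g T + %.4g (n=%d); upper: A = %.4g T + %.4g (n=%d)%s\n",
              x$m_l, x$b_l, x$n_lower, x$m_u, x$b_u, x$n_upper,
              if (x$degenerate) "  [DEGENERATE]" else ""))
  invisible(x)
}

#' Construct a fraction-paired curve
#'
#' @param temperatures degC.
#' @param fractions Fraction of maximal base pairs (may slightly exceed
#'   \[0,1\] due to noise; not clamped).
#' @param C_T Total strand concentration, mol/L.
#' @param curve_id,duplex_id Identifiers.
#' @return Object of class `fraction_curve`.
#' @export
fraction_curve <- function(temperatures, fractions, C_T,
                           curve_id = "curve", duplex_id = "duplex") {
  if (length(temperatures) != length(fractions)) {
    stop("temperatures and fractions must have equal length")
  }
  if (!all(is.finite(fractions))) stop("non-finite fractions")
  structure(
    list(curve_id = curve_id, duplex_id = duplex_id,
         temperatures = temperatures, fractions = fractions, C_T = C_T),
    class = "fraction_curve"
  )
}

#' @export
print.fraction_curve <- function(x, ...) {
  cat(sprintf("<fraction_curve> %s (%s): %d points, C_T = %.3g M\n",
              x$curve_id, x$duplex_id, length(x$temperatures), x$C_T))
  invisible(x)
}

#' Transform absorbance to fraction of maximal base pairs
#'
#' X(T) = ((m_u T + b_u) - A(T)) / ((m_u T + b_u) - (m_l T + b_l)).
#' Values are not clamped to \[0,1\]: noise excursions carry information for
#' the least-squares fit.
#'
#' @param curve A `melting_curve`.
#' @param baselines A `baseline_fit` (non-degenerate over the curve).
#' @return A `fraction_curve`.
#' @export
to_fraction_paired <- function(curve, baselines) {
  Tt <- curve$temperatures
  upper <- baselines$m_u * Tt + baselines$b_u
  lower <- baselines$m_l * Tt + baselines$b_l
  den <- upper - lower
  if (any(den <= 0)) {
    stop("degenerate baselines: upper does not exceed lower at every point")
  }
  fraction_curve(Tt, (upper - curve$absorbances) / den, curve$C_T,
                 curve_id = curve$curve_id, duplex_id = curve$duplex_id)
}

#' Experimental melting temperature by linear interpolation
#'
#' Tm is the temperature where the fraction of maximal pairs crosses 0.5,
#' interpolated linearly between the bracketing pair of points. If the curve
#' crosses 0.5 more than once (noise), the first crossing scanning by
#' increasing temperature is used, with a warning.
#'
#' @param curve A `fraction_curve`.
#' @return Tm in degC.
#' @export
interpolate_tm <- function(curve) {
  Tt <- curve$temperatures
  X <- curve$fractions
  hit <- which(X == 0.5)
  s <- X - 0.5
  cross <- which(s[-length(s)] * s[-1] < 0)
  if (length(hit) == 0 && length(cross) == 0) {
    stop("no transition: curve does not cross fraction 0.5")
  }
  n_cross <- length(cross) + length(hit)
  if (n_cross > 1) {
    warning("curve '", curve$curve_id, "' crosses 0.5 ", n_cross,
            " times; using the first crossing by increasing temperature")
  }
  first_hit <- if (length(hit) > 0) hit[1] else Inf
  first_cross <- if (length(cross) > 0) cross[1] else Inf
  if (first_hit <= first_cross) return(Tt[first_hit])
  i <- cross[1]
  Tt[i] + (Tt[i + 1] - Tt[i]) * (0.5 - X[i]) / (X[i + 1] - X[i])
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `curve_id`, `duplex_id`, `path`
#' (melt-curve file, relative to the manifest's directory unless absolute),
#' `C_T` (mol/L), and optional `lower_frac`, `upper_frac` baseline-window
#' overrides. A companion column `top_strand` may map each `duplex_id` to its
#' sequence; alternatively supply `duplexes`.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with normalized columns (absolute `path`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        strip.white = TRUE)
  need <- c("curve_id", "duplex_id", "path", "C_T")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"lower_frac" %in% names(df)) df$lower_frac <- 0.10
  if (!"upper_frac" %in% names(df)) df$upper_frac <- 0.10
  df$lower_frac[is.na(df$lower_frac)] <- 0.10
  df$upper_frac[is.na(df$upper_frac)] <- 0.10
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  df
}
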