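# No-slip duplex partition function, per-pair probabilities, bimolecular
# pairing probability and model melting curves.
#
# The ensemble contains every subset of the L possible pairs (a base can only
# pair with its complement -- strands do not slip) whose internal gaps are at
# most 8, i.e. disordered internal loops of up to 8x8 nucleotides. The
# partition function Q sums Boltzmann factors exp(-dG/RT) over all states,
# with the fully denatured state carrying weight exactly 1.
#
# Left/right partial sums are computed by recursion. Internally A_i is the
# weight of everything 5' of pair i with i's right side unresolved, and B_i
# the mirror image from the 3' end (no initiation). With s_i the Boltzmann
# factor of the helix-end term at pair i (terminal AU or 1):
#   A_i = init*sym*s_i + A_{i-1}*stack(i-1,i) + sum_k A_k*s_k*loop_g*s_i
#   B_i = s_i          + B_{i+1}*stack(i,i+1) + sum_m B_m*s_m*loop_g*s_i
# The exported partials are Q_L,i = A_i*s_i (3' tail frayed) and
# Q_R,i = B_i/s_i, so that both identities hold exactly:
#   sum_i Q_L,i = Q - 1          (decomposition by rightmost pair)
#   Q_L,i * Q_R,i = total weight of structures containing pair i,
#                   with initiation counted exactly once (Eq for P_i).

# Per-duplex geometry reused across temperatures/parameter sets.
.duplex_layout <- function(seq) {
  chars <- strsplit(seq$top_strand, "")[[1]]
  L <- seq$length
  list(
    L = L,
    au = chars %in% c("A", "U"),
    stacks = stack_label(paste0(chars[-L], chars[-1])),  # stack between i,i+1
    sym = seq$self_complementary
  )
}

# Partition function on a vector of temperatures (kelvin). Returns Q (vector
# length nT), QL and QR (nT x L matrices) and sumQL.
partition_grid <- function(seq, params, T_kelvin) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  lay <- .duplex_layout(seq)
  L <- lay$L
  nT <- length(T_kelvin)
  RT <- rnamelt_constants$R * T_kelvin

  # per-feature dG(T): 20 x nT
  gH <- params$dH; gS <- params$dS
  dg <- outer(gH, rep(1, nT)) - outer(gS / 1000, T_kelvin)
  w <- exp(-dg / rep(RT, each = nrow(dg)))  # Boltzmann factor per feature
  rownames(w) <- names(gH)

  stackW <- t(w[lay$stacks, , drop = FALSE])          # nT x (L-1)
  loopW <- t(w[paste0("loop_", 1:8), , drop = FALSE])  # nT x 8
  endW <- exp(-(gH[["terminal_AU"]] - T_kelvin * gS[["terminal_AU"]] / 1000) / RT)
  s <- matrix(1, nT, L)
  s[, lay$au] <- endW                                   # s_i per pair
  initW <- t(w["initiation", , drop = FALSE])[, 1]
  if (lay$sym) {
    initW <- initW * exp(rnamelt_constants$dS_sym / 1000 / rnamelt_constants$R)
  }

  A <- matrix(0, nT, L)
  for (i in seq_len(L)) {
    acc <- initW * s[, i]
    if (i >= 2) acc <- acc + A[, i - 1] * stackW[, i - 1]
    if (i >= 3) {
      for (k in max(1L, i - 9L):(i - 2L)) {
        g <- i - k - 1L
        if (g <= 8L) acc <- acc + A[, k] * s[, k] * loopW[, g] * s[, i]
      }
    }
    A[, i] <- acc
  }
  B <- matrix(0, nT, L)
  for (i in L:1) {
    acc <- s[, i]
    if (i <= L - 1) acc <- acc + B[, i + 1] * stackW[, i]
    if (i <= L - 2) {
      for (m in (i + 2L):min(L, i + 9L)) {
        g <- m - i - 1L
        if (g <= 8L) acc <- acc + B[, m] * s[, m] * loopW[, g] * s[, i]
      }
    }
    B[, i] <- acc
  }
  QL <- A * s
  QR <- B / s
  sumQL <- rowSums(QL)
  Q <- 1 + sumQL
  if (!all(is.finite(Q))) {
    stop("non-finite partition function (Boltzmann overflow); ",
         "rescale energies or restrict the temperature range")
  }
  list(Q = Q, QL = QL, QR = QR, sumQL = sumQL, T_kelvin = T_kelvin)
}

#' Partition function of a duplex at one temperature
#'
#' Sums Boltzmann factors over all no-slip pairing states (internal loops up
#' to 8x8), including the unpaired state at weight 1, via left/right
#' recursions from the 5' and 3' ends.
#'
#' @param seq A `duplex_sequence` (or top-strand string).
#' @param params An `nn_param_set`.
#' @param T_kelvin Absolute temperature, K (scalar).
#' @return Object of class `partition_result`: `Q` (>= 1), `QL`, `QR`
#'   (vectors over positions 1..L), `sumQL` (= Q - 1), `T_kelvin`. The
#'   partials satisfy `QL[i] * QR[i]` = total weight of structures containing
#'   pair i, with initiation counted once.
#' @export
compute_partition <- function(seq, params, T_kelvin) {
  stopifnot(length(T_kelvin) == 1)
  pg <- partition_grid(seq, params, T_kelvin)
  structure(
    list(Q = pg$Q[1], QL = pg$QL[1, ], QR = pg$QR[1, ],
         sumQL = pg$sumQL[1], T_kelvin = T_kelvin),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> T = %.2f K, Q = %.6g (L = %d)\n",
              x$T_kelvin, x$Q, length(x$QL)))
  invisible(x)
}

#' Per-pair probabilities conditional on at least one pair
#'
#' P_i = QL_i QR_i / (Q - 1): the probability that position i is paired to
#' its complement, given that the duplex has formed (>= 1 pair).
#'
#' @param result A `partition_result`.
#' @return Numeric vector over positions 1..L, each in \[0, 1\].
#' @export
pair_probabilities <- function(result) {
  if (result$sumQL <= 0 || result$Q <= 1) {
    stop("Q is numerically 1: conditional pair probabilities undefined ",
         "(no pairing possible at this temperature)")
  }
  result$QL * result$QR / result$sumQL
}

#' Probability that a duplex has at least one base pair
#'
#' Bimolecular mass balance at total strand concentration C_T with ensemble
#' association constant K = Q - 1. Non-self-complementary (A + B, equal
#' strand concentrations C_T/2):
#'   P = (1 + K C_T - sqrt(1 + 2 K C_T)) / (K C_T)
#' Self-complementary (2A):
#'   P = (1 + 4 K C_T - sqrt(1 + 8 K C_T)) / (4 K C_T)
#' Evaluated in the algebraically identical conjugate forms
#'   P = x / (1 + x + sqrt(1 + 2x))     and
#'   P = 4x / (1 + 4x + sqrt(1 + 8x)),
#' which are free of catastrophic cancellation for all x = K C_T >= 0 and
#' carry the series limits P -> x/2 (resp. 2x) as x -> 0 exactly.
#'
#' @param Q Partition function value(s) (>= 1); vectorized.
#' @param C_T Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @return Probability in \[0, 1\] (vectorized over Q).
#' @export
prob_any_pair <- function(Q, C_T, self_complementary = FALSE) {
  if (any(Q < 1)) stop("Q must be >= 1")
  if (C_T <= 0) stop("C_T must be positive")
  x <- (Q - 1) * C_T
  p <- if (self_complementary) {
    4 * x / (1 + 4 * x + sqrt(1 + 8 * x))
  } else {
    x / (1 + x + sqrt(1 + 2 * x))
  }
  pmin(pmax(p, 0), 1)
}

#' Model fraction of maximal base pairs
#'
#' X(T) = P_bp * sum_i P_i / L: the probability that the duplex has formed
#' at all (concentration-dependent) times the mean conditional pairing
#' probability over all L positions.
#'
#' @param seq A `duplex_sequence`.
#' @param params An `nn_param_set`.
#' @param T_kelvin Absolute temperature(s), K.
#' @param C_T Total strand concentration, mol/L.
#' @return Fraction(s) in \[0, 1\], one per temperature.
#' @export
fraction_paired <- function(seq, params, T_kelvin, C_T) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  pg <- partition_grid(seq, params, T_kelvin)
  pbp <- prob_any_pair(pg$Q, C_T, seq$self_complementary)
  # mean conditional pair probability; 0/0 -> no pairing at all -> X = 0
  num <- rowSums(pg$QL * pg$QR)
  mean_pi <- ifelse(pg$sumQL > 0, num / pg$sumQL / length(pg$QL[1, ]), 0)
  pmin(pmax(pbp * mean_pi, 0), 1)
}

#' Predict a model melting curve
#'
#' @param seq A `duplex_sequence`.
#' @param params An `nn_param_set`.
#' @param C_T Total strand concentration, mol/L.
#' @param temperatures Grid in degC (non-empty).
#' @return Object of class `model_curve` (`temperatures` degC, `fractions`).
#' @export
predict_curve <- function(seq, params, C_T, temperatures) {
  if (length(temperatures) == 0) stop("empty temperature grid")
  if (is.character(seq)) seq <- duplex_sequence(seq)
  X <- fraction_paired(seq, params, temperatures + rnamelt_constants$C_to_K, C_T)
  structure(
    list(curve_id = paste0(seq$duplex_id, "_model"), duplex_id = seq$duplex_id,
         temperatures = temperatures, fractions = X, C_T = C_T),
    class = c("model_curve", "fraction_curve")
  )
}

#' Predicted melting temperature
#'
#' The temperature at which the model fraction of maximal pairs equals 0.5,
#' found by bisection (robust to flat tails) to 0.001 degC.
#'
#' @param seq A `duplex_sequence`.
#' @param params An `nn_param_set`.
#' @param C_T Total strand concentration, mol/L.
#' @param window Search window in degC, default c(0, 110).
#' @return Tm in degC.
#' @export
predict_tm <- function(seq, params, C_T, window = c(0, 110)) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  f <- function(Tc) {
    fraction_paired(seq, params, Tc + rnamelt_constants$C_to_K, C_T) - 0.5
  }
  lo <- window[1]; hi <- window[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    stop("no transition: model fraction does not cross 0.5 in [",
         lo, ", ", hi, "] degC")
  }
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}
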