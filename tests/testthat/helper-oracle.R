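# Shared fixtures and independent oracles for the partition recursion.

R_GAS <- rnamelt_constants$R
T37 <- rnamelt_constants$T37

# Random parameter set in a physically plausible range (no overflow at L<=10)
random_params <- function() {
  nn_param_set(
    stats::setNames(stats::runif(20, -15, 5), nn_feature_names()),
    stats::setNames(stats::runif(20, -40, 10), nn_feature_names())
  )
}

# Enumeration oracle: Q, sum-of-QL identity and per-pair probabilities by
# brute force over all valid pairing states, via the state-feature matrix.
oracle_partition <- function(seq, params, T_kelvin) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  sfm <- rnamelt:::state_feature_matrix(seq)
  g <- delta_g(params, T_kelvin)
  e <- as.numeric(sfm$counts %*% g)
  if (sfm$sym) e <- e - T_kelvin * rnamelt_constants$dS_sym / 1000
  w <- exp(-e / (R_GAS * T_kelvin))
  sw <- sum(w)   # Q - 1 held unrounded: 1 + sw - 1 would lose precision
  Pi <- vapply(seq_len(seq$length), function(i) {
    has_i <- vapply(sfm$states, function(st) i %in% st, logical(1))
    sum(w[has_i]) / sw
  }, numeric(1))
  list(Q = 1 + sw, Qm1 = sw, Pi = Pi)
}

# Bimolecular mass-balance oracles for prob_any_pair, solved numerically
# (root of the equilibrium condition in the paired fraction P, independent
# of the closed-form algebra being checked).
# Non-self-complementary A + B <-> AB, C_A = C_B = C_T/2, K = Q - 1:
# duplex D = P C_T / 2, monomer A = B = (1 - P) C_T / 2, K = D / (A B).
oracle_prob_pair_nsc <- function(K, C_T) {
  f <- function(P) K * (1 - P)^2 * C_T / 2 - P
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# Self-complementary 2A <-> A2: D = P C_T / 2, M = (1 - P) C_T, K = D / M^2.
oracle_prob_pair_sc <- function(K, C_T) {
  f <- function(P) 2 * K * (1 - P)^2 * C_T - P
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# Small synthetic corpus used by several fitting tests: subset of the
# reference duplexes covering all 10 stacks, coarse grid for speed.
small_corpus_strands <- function(n = 12) {
  strands <- table1_duplexes()$top_strand
  # greedily pick duplexes until all stacks are covered, then fill up to n
  need <- stack_names()
  pick <- character(0)
  for (s in strands) {
    cnt <- decompose_duplex(s)
    if (any(cnt[intersect(names(cnt), need)] > 0)) {
      pick <- c(pick, s)
      need <- setdiff(need, names(cnt)[cnt > 0])
    }
    if (length(need) == 0) break
  }
  extra <- setdiff(strands, pick)
  c(pick, extra)[seq_len(max(n, length(pick)))]
}

make_corpus <- function(n_duplexes = 12, conc_factors = 2^c(-2, 0, 2),
                        grid = c(10, 90, 2), noise_sd = 0, seed = 1,
                        transform = "none") {
  spec <- synthetic_spec(
    duplexes = small_corpus_strands(n_duplexes),
    conc_factors = conc_factors, grid = grid,
    noise_sd = noise_sd, seed = seed)
  list(spec = spec, gen = generate_dataset(spec, transform = transform))
}
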