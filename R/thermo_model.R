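# Sequence and nearest-neighbor parameter data model.

#' Physical constants used throughout the package
#'
#' @format A list with elements:
#' \describe{
#'   \item{R}{Gas constant, kcal/(mol K): 1.98717e-3.}
#'   \item{T37}{310.15 K (37 degC), the reference temperature for dG37.}
#'   \item{dS_sym}{Symmetry entropy correction -R ln 2 = -1.377 cal/(mol K),
#'     applied once per paired structure of a self-complementary duplex.}
#'   \item{C_to_K}{273.15, Celsius-to-kelvin offset.}
#' }
#' @export
rnamelt_constants <- list(
  R = 1.98717e-3,
  T37 = 310.15,
  dS_sym = -1.377,
  C_to_K = 273.15
)

.RNA_BASES <- c("A", "C", "G", "U")
.RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Canonical Watson-Crick stack names
#'
#' The ten distinguishable nearest-neighbor stacks of Watson-Crick pairs,
#' written top-dinucleotide/bottom-dinucleotide (both 5'->3').
#' @export
stack_names <- function() {
  c("AA/UU", "AU/UA", "UA/AU", "CU/GA", "CA/GU",
    "GU/CA", "GA/CU", "CG/GC", "GG/CC", "GC/CG")
}

# Total map from a top-strand dinucleotide to its canonical stack name.
# Complementary dinucleotides (read off the opposite strand) collapse to the
# same stack, e.g. AA and UU are the same physical stack AA/UU.
.STACK_MAP <- c(
  AA = "AA/UU", UU = "AA/UU",
  AU = "AU/UA",
  UA = "UA/AU",
  CU = "CU/GA", AG = "CU/GA",
  CA = "CA/GU", UG = "CA/GU",
  GU = "GU/CA", AC = "GU/CA",
  GA = "GA/CU", UC = "GA/CU",
  CG = "CG/GC",
  GG = "GG/CC", CC = "GG/CC",
  GC = "GC/CG"
)

#' Map a top-strand dinucleotide to its canonical stack name
#'
#' @param dinucleotide Character vector of two-letter strings over A,C,G,U,
#'   read 5'->3' on the top strand.
#' @return Character vector of canonical stack names (see [stack_names()]).
#' @examples
#' stack_label(c("AA", "UU", "UC"))
#' @export
stack_label <- function(dinucleotide) {
  lab <- .STACK_MAP[dinucleotide]
  if (anyNA(lab)) {
    stop("not a Watson-Crick dinucleotide: ",
         paste(unique(dinucleotide[is.na(lab)]), collapse = ", "))
  }
  unname(lab)
}

#' All nearest-neighbor feature names
#'
#' The 20 features of the model: 10 Watson-Crick stacks, intermolecular
#' initiation, the terminal AU penalty, and disordered internal loops of
#' per-side length 1..8 (total loop size 2..16 nucleotides).
#' @return Character vector of length 20.
#' @export
nn_feature_names <- function() {
  c(stack_names(), "initiation", "terminal_AU", paste0("loop_", 1:8))
}

.revcomp <- function(chars) rev(unname(.RNA_COMPLEMENT[chars]))

#' Construct a duplex sequence
#'
#' A duplex is specified by its top strand 5'->3'; the bottom strand is the
#' full reverse complement (no-slip, fully complementary model). The
#' self-complementarity flag is derived: a strand that equals its own reverse
#' complement dimerizes with itself.
#'
#' @param top_strand RNA string 5'->3' over A, C, G, U.
#' @param duplex_id Identifier; defaults to the top strand itself.
#' @return An object of class `duplex_sequence` with fields `duplex_id`,
#'   `top_strand`, `bottom_strand`, `length` (number of base pairs) and
#'   `self_complementary`.
#' @examples
#' dx <- duplex_sequence("GGCUUCAA")
#' dx$length
#' duplex_sequence("UGAUCA")$self_complementary
#' @export
duplex_sequence <- function(top_strand, duplex_id = top_strand) {
  top_strand <- toupper(gsub("\\s", "", top_strand))
  chars <- strsplit(top_strand, "")[[1]]
  bad <- setdiff(chars, .RNA_BASES)
  if (length(bad) > 0) {
    stop("invalid RNA characters in top strand '", top_strand, "': ",
         paste(unique(bad), collapse = ", "))
  }
  L <- length(chars)
  if (L < 2) stop("duplex must have at least 2 base pairs, got ", L)
  rc <- .revcomp(chars)
  structure(
    list(
      duplex_id = duplex_id,
      top_strand = top_strand,
      bottom_strand = paste(rc, collapse = ""),
      length = L,
      self_complementary = all(chars == rc)
    ),
    class = "duplex_sequence"
  )
}

#' @export
print.duplex_sequence <- function(x, ...) {
  cat(sprintf("<duplex_sequence> %s  5'-%s-3' / 3'-%s-5'  (%d bp%s)\n",
              x$duplex_id, x$top_strand, rev_string(x$bottom_strand),
              x$length,
              if (x$self_complementary) ", self-complementary" else ""))
  invisible(x)
}

rev_string <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

#' Construct a nearest-neighbor parameter set
#'
#' Holds per-feature enthalpy (kcal/mol) and entropy (cal/(mol K), "e.u.")
#' changes for the 20 model features -- the 40 free parameters of the fit.
#' The gas constant and the self-complementary symmetry correction are fixed
#' constants, not parameters.
#'
#' @param dH Named numeric of enthalpies, kcal/mol; names must be exactly
#'   [nn_feature_names()].
#' @param dS Named numeric of entropies, cal/(mol K); same names.
#' @return An object of class `nn_param_set`.
#' @export
nn_param_set <- function(dH, dS) {
  feats <- nn_feature_names()
  if (!setequal(names(dH), feats) || !setequal(names(dS), feats)) {
    stop("dH and dS must be named with exactly the 20 NN features")
  }
  dH <- dH[feats]; dS <- dS[feats]
  if (!all(is.finite(dH)) || !all(is.finite(dS))) {
    stop("non-finite NN parameter values")
  }
  structure(list(dH = dH, dS = dS), class = "nn_param_set")
}

#' @export
print.nn_param_set <- function(x, ...) {
  df <- data.frame(
    feature = nn_feature_names(),
    dH_kcal_mol = unname(x$dH),
    dS_cal_mol_K = unname(x$dS),
    dG37_kcal_mol = unname(delta_g(x, rnamelt_constants$T37))
  )
  cat("<nn_param_set> (40 free parameters)\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Free energy change of every feature at a temperature
#'
#' dG(T) = dH - T dS / 1000, bridging kcal/mol enthalpies with cal/(mol K)
#' entropies.
#'
#' @param params An `nn_param_set`.
#' @param T_kelvin Absolute temperature, K (scalar).
#' @return Named numeric of feature free energies, kcal/mol.
#' @export
delta_g <- function(params, T_kelvin) {
  params$dH - T_kelvin * params$dS / 1000
}

#' Free energy change of one feature
#'
#' @param params An `nn_param_set`.
#' @param feature Feature name (one of [nn_feature_names()]).
#' @param T_kelvin Absolute temperature, K.
#' @return dG in kcal/mol.
#' @export
feature_delta_g <- function(params, feature, T_kelvin) {
  if (!feature %in% nn_feature_names()) {
    stop("unknown NN feature: ", feature)
  }
  unname(params$dH[feature] - T_kelvin * params$dS[feature] / 1000)
}

#' Decompose a duplex into nearest-neighbor feature counts
#'
#' Counts each adjacent top-strand dinucleotide as one canonical stack,
#' one initiation event per duplex, and one terminal AU penalty for each
#' duplex-terminal closing pair that is A-U or U-A. Self-complementary
#' duplexes are counted once (the decomposition is a property of the duplex,
#' not of the strands).
#'
#' @param seq A `duplex_sequence` (or a top-strand string).
#' @return Named integer vector over stacks + initiation + terminal_AU
#'   (loop features never occur in a fully paired duplex and are omitted).
#' @examples
#' decompose_duplex(duplex_sequence("AAAA"))
#' @export
decompose_duplex <- function(seq) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  chars <- strsplit(seq$top_strand, "")[[1]]
  L <- seq$length
  counts <- stats::setNames(integer(12), c(stack_names(), "initiation", "terminal_AU"))
  labs <- stack_label(paste0(chars[-L], chars[-1]))
  tab <- table(labs)
  counts[names(tab)] <- as.integer(tab)
  counts["initiation"] <- 1L
  counts["terminal_AU"] <- sum(chars[c(1L, L)] %in% c("A", "U"))
  counts
}

# -- pairing states -----------------------------------------------------------

.MAX_LOOP <- 8L  # largest allowed disordered internal loop, per side

#' Validate a pairing state
#'
#' A pairing state is the subset of positions 1..L paired to their complement
#' (no-slip). Valid states have every internal gap between consecutive paired
#' positions of length at most 8 (larger disordered loops are outside the
#' model).
#'
#' @param paired Integer vector of paired positions (may be empty).
#' @param L Duplex length.
#' @return TRUE/FALSE.
#' @export
is_valid_state <- function(paired, L) {
  paired <- sort(unique(as.integer(paired)))
  if (length(paired) == 0) return(TRUE)
  if (paired[1] < 1L || paired[length(paired)] > L) return(FALSE)
  if (length(paired) == 1) return(TRUE)
  all(diff(paired) - 1L <= .MAX_LOOP)
}

#' Enumerate all valid pairing states of a duplex
#'
#' Brute-force enumeration used as the independent oracle for the recursive
#' partition function. Includes the empty (fully denatured) state.
#'
#' @param seq A `duplex_sequence` with at most 16 base pairs.
#' @return List of integer vectors of paired positions.
#' @export
enumerate_states <- function(seq) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  L <- seq$length
  if (L > 16) stop("enumeration limited to L <= 16, got L = ", L)
  states <- vector("list", 2^L)
  n <- 0L
  for (mask in 0:(2^L - 1)) {
    paired <- which(bitwAnd(mask, bitwShiftL(1L, 0:(L - 1))) != 0L)
    if (is_valid_state(paired, L)) {
      n <- n + 1L
      states[[n]] <- paired
    }
  }
  states[seq_len(n)]
}

#' Free energy of one pairing state
#'
#' The energy of a secondary structure is the sum of: initiation (once),
#' one stack term per adjacent pair of paired positions, one disordered-loop
#' term per maximal internal gap (indexed by per-side length g = gap size),
#' one terminal AU term per helix-terminal A-U/U-A pair (each side of a pair
#' whose neighbour on that side is unpaired or off the end of the duplex),
#' and, for self-complementary duplexes, the fixed symmetry correction
#' -T dS_sym / 1000. Frayed single-stranded ends contribute nothing.
#'
#' @param seq A `duplex_sequence`.
#' @param state Integer vector of paired positions (non-empty).
#' @param params An `nn_param_set`.
#' @param T_kelvin Absolute temperature, K.
#' @return dG of the structure, kcal/mol.
#' @export
structure_energy <- function(seq, state, params, T_kelvin) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  state <- sort(unique(as.integer(state)))
  if (length(state) == 0) {
    stop("empty state: the unpaired reference state has dG = 0 by convention")
  }
  if (!is_valid_state(state, seq$length)) {
    stop("invalid pairing state for duplex ", seq$duplex_id)
  }
  g <- delta_g(params, T_kelvin)
  chars <- strsplit(seq$top_strand, "")[[1]]
  au <- chars %in% c("A", "U")

  e <- g[["initiation"]]
  if (length(state) > 1) {
    gaps <- diff(state) - 1L
    stacked <- gaps == 0L
    if (any(stacked)) {
      i <- state[-length(state)][stacked]
      e <- e + sum(g[stack_label(paste0(chars[i], chars[i + 1L]))])
    }
    if (any(!stacked)) {
      e <- e + sum(g[paste0("loop_", gaps[!stacked])])
    }
  }
  # per-side helix-end terms: left side of i is an end if i-1 is unpaired or
  # off the duplex; symmetric on the right
  paired <- logical(seq$length)
  paired[state] <- TRUE
  for (i in state) {
    if (au[i]) {
      if (i == 1L || !paired[i - 1L]) e <- e + g[["terminal_AU"]]
      if (i == seq$length || !paired[i + 1L]) e <- e + g[["terminal_AU"]]
    }
  }
  if (seq$self_complementary) {
    e <- e - T_kelvin * rnamelt_constants$dS_sym / 1000
  }
  unname(e)
}

# Feature-count matrix over all valid states of a duplex: one row per
# non-empty state, columns = 20 features + "sym" (0/1). Lets the enumeration
# oracle evaluate many parameter sets cheaply:
# energies = counts %*% dG(T) + sym * dG_sym(T).
state_feature_matrix <- function(seq) {
  if (is.character(seq)) seq <- duplex_sequence(seq)
  states <- Filter(function(s) length(s) > 0, enumerate_states(seq))
  feats <- nn_feature_names()
  chars <- strsplit(seq$top_strand, "")[[1]]
  au <- chars %in% c("A", "U")
  L <- seq$length
  M <- matrix(0L, nrow = length(states), ncol = length(feats),
              dimnames = list(NULL, feats))
  for (k in seq_along(states)) {
    st <- states[[k]]
    M[k, "initiation"] <- 1L
    if (length(st) > 1) {
      gaps <- diff(st) - 1L
      stacked <- gaps == 0L
      if (any(stacked)) {
        i <- st[-length(st)][stacked]
        for (lab in stack_label(paste0(chars[i], chars[i + 1L]))) {
          M[k, lab] <- M[k, lab] + 1L
        }
      }
      for (gp in gaps[!stacked]) {
        M[k, paste0("loop_", gp)] <- M[k, paste0("loop_", gp)] + 1L
      }
    }
    paired <- logical(L); paired[st] <- TRUE
    nau <- 0L
    for (i in st) {
      if (au[i]) {
        if (i == 1L || !paired[i - 1L]) nau <- nau + 1L
        if (i == L || !paired[i + 1L]) nau <- nau + 1L
      }
    }
    M[k, "terminal_AU"] <- nau
  }
  list(states = states, counts = M, sym = seq$self_complementary)
}

# -- parameter tables ---------------------------------------------------------

#' Read a nearest-neighbor parameter table
#'
#' Comma- or tab-separated with columns `feature`, `dH_kcal_mol`,
#' `dS_cal_mol_K`; feature names must be exactly the vocabulary of
#' [nn_feature_names()] (loop rows may be omitted, defaulting to 0).
#'
#' @param path File path.
#' @param fill_loops If TRUE (default), absent loop features are filled with
#'   zeros; other absent features are an error.
#' @return An `nn_param_set`.
#' @export
read_nn_params <- function(path, fill_loops = TRUE) {
  sep <- if (grepl("\t", readLines(path, n = 1)[1])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("feature", "dH_kcal_mol", "dS_cal_mol_K")
  if (!all(need %in% names(df))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  feats <- nn_feature_names()
  unknown <- setdiff(df$feature, feats)
  if (length(unknown) > 0) {
    stop("unknown NN features in ", path, ": ", paste(unknown, collapse = ", "))
  }
  dH <- stats::setNames(rep(NA_real_, length(feats)), feats)
  dS <- dH
  dH[df$feature] <- df$dH_kcal_mol
  dS[df$feature] <- df$dS_cal_mol_K
  missing <- feats[is.na(dH)]
  if (fill_loops) {
    loops <- grep("^loop_", missing, value = TRUE)
    dH[loops] <- 0; dS[loops] <- 0
    missing <- setdiff(missing, loops)
  }
  if (length(missing) > 0) {
    stop("missing NN features in ", path, ": ", paste(missing, collapse = ", "))
  }
  nn_param_set(dH, dS)
}

#' Write a nearest-neighbor parameter table
#'
#' @param params An `nn_param_set`.
#' @param path Output file path (CSV).
#' @export
write_nn_params <- function(params, path) {
  df <- data.frame(feature = nn_feature_names(),
                   dH_kcal_mol = unname(params$dH),
                   dS_cal_mol_K = unname(params$dS))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Literature two-state nearest-neighbor parameters
#'
#' The standard published Watson-Crick helix parameter set derived by
#' two-state analysis of 90 duplexes (1 M NaCl): dH (kcal/mol) and dS
#' (cal/(mol K)) for the 10 stacks, initiation and the terminal AU penalty.
#' Loop features are filled with the given penalty (default 0; benchmarking
#' against ensemble models conventionally uses dH = 10 kcal/mol,
#' dS = -1 e.u. to suppress loop formation, see [two_state_loop_preset()]).
#'
#' @param loop_dH,loop_dS Values assigned to the 8 disordered-loop features.
#' @return An `nn_param_set`.
#' @export
nn_literature <- function(loop_dH = 0, loop_dS = 0) {
  p <- read_nn_params(system.file("extdata", "nn_literature.csv",
                                  package = "rnamelt", mustWork = TRUE))
  p$dH[paste0("loop_", 1:8)] <- loop_dH
  p$dS[paste0("loop_", 1:8)] <- loop_dS
  p
}

#' Apply the two-state loop preset to a parameter set
#'
#' Two-state-derived parameter sets have no disordered-loop terms; when used
#' inside the ensemble model their loop features are set to dH = 10.0
#' kcal/mol, dS = -1.0 cal/(mol K), a ~10 kcal/mol free-energy penalty in the
#' experimental temperature range that effectively forbids loop formation.
#'
#' @param params An `nn_param_set`.
#' @return The parameter set with loop features overwritten.
#' @export
two_state_loop_preset <- function(params) {
  params$dH[paste0("loop_", 1:8)] <- 10.0
  params$dS[paste0("loop_", 1:8)] <- -1.0
  params
}

#' The 34-duplex reference manifest
#'
#' The duplex top strands of the curated 34-duplex optical melting corpus
#' (5-10 bp, 1 M NaCl), with per-duplex melt counts and the source
#' annotation of strand complementarity. `self_complementary` is derived
#' from the sequence; `annotated_non_self_comp` preserves the source's
#' slash annotation (the palindromic strand UUAUCGAUAA is annotated
#' non-self-complementary in the source despite being its own reverse
#' complement).
#'
#' @return A data.frame with columns `duplex_id`, `top_strand`, `n_melts`,
#'   `self_complementary`, `annotated_non_self_comp`, `reference`.
#' @export
table1_duplexes <- function() {
  df <- utils::read.csv(system.file("extdata", "duplexes_34.csv",
                                    package = "rnamelt", mustWork = TRUE),
                        stringsAsFactors = FALSE, comment.char = "#")
  df$self_complementary <- vapply(df$top_strand, function(s) {
    duplex_sequence(s)$self_complementary
  }, logical(1), USE.NAMES = FALSE)
  df
}
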