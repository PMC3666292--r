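#' Conformational propensities from labelled chains
#'
#' For residue type i and structure class j in (H, E, C), the propensity is
#' S\[i, j\] = a_ij / a_i, where a_i is the pooled count of residue i over all
#' chains and a_ij the count of residue i observed in class j. Residue types
#' never observed (a_i = 0) receive a flagged uniform row (1/3, 1/3, 1/3);
#' non-standard residue codes are skipped.
#'
#' @param chains character vector of sequences (or `data.frame` from
#'   [read_fasta()]).
#' @param states character vector of 3-state structure strings, aligned 1:1
#'   with `chains`.
#' @return A `conformation_table`: list with `S` (20 x 3 propensity matrix),
#'   integer counts `a_i` and `a_ij`, and a logical `flagged` vector marking
#'   unobserved residues.
#' @examples
#' ct <- conformation_parameters("AAA", "HHC")
#' ct$S["A", ]   # 2/3, 0, 1/3
#' @export
conformation_parameters <- function(chains, states) {
  if (is.data.frame(chains)) chains <- chains$sequence
  if (is.data.frame(states)) states <- states$states
  if (!length(chains)) stop("no chains supplied", call. = FALSE)
  stopifnot(length(chains) == length(states))

  a_ij <- matrix(0L, 20L, 3L, dimnames = list(AA_ALPHABET, THREE_STATES))
  for (k in seq_along(chains)) {
    if (nchar(chains[k]) != nchar(states[k])) {
      stop("chain ", k, " has ", nchar(chains[k]),
           " residues but its structure string has ", nchar(states[k]),
           call. = FALSE)
    }
    res <- split_chars(chains[k])
    ss <- check_three_state(states[k], paste0("structure string ", k))
    keep <- res %in% AA_ALPHABET
    tab <- table(factor(res[keep], levels = AA_ALPHABET),
                 factor(ss[keep], levels = THREE_STATES))
    a_ij <- a_ij + as.integer(tab)
  }
  a_i <- rowSums(a_ij)
  flagged <- a_i == 0
  S <- a_ij / ifelse(a_i == 0, 1, a_i)
  S[flagged, ] <- 1 / 3
  structure(list(S = S, a_i = a_i, a_ij = a_ij, flagged = flagged),
            class = "conformation_table")
}

#' @export
print.conformation_table <- function(x, digits = 3, ...) {
  cat("Conformational propensities (S[i,j] = a_ij / a_i)\n")
  print(round(x$S, digits))
  if (any(x$flagged)) {
    cat("unobserved residues (uniform rows):",
        paste(names(x$flagged)[x$flagged], collapse = " "), "\n")
  }
  invisible(x)
}

# Scalar block for one residue: (S_H, S_E, S_C, charge, hydropathy, mass),
# each scaled to [0,1] over its fixed table range. Unknown residues get
# uniform propensities and mid-range physicochemistry.
scalar_features <- function(residue, ct, pt) {
  if (residue %in% AA_ALPHABET) {
    s <- ct$S[residue, ]
    ph <- c(pt$net_charge[[residue]], pt$hydropathy[[residue]],
            pt$side_chain_mass[[residue]])
  } else {
    s <- rep(1 / 3, 3)
    ph <- c(0, 0, mean(MASS_RANGE))
  }
  c(s,
    (ph[1] + 1) / 2,
    (ph[2] - HYDROPATHY_RANGE[1]) / diff(HYDROPATHY_RANGE),
    (ph[3] - MASS_RANGE[1]) / diff(MASS_RANGE))
}

#' Encode a chain into sliding-window feature vectors
#'
#' For each residue i the feature vector concatenates the 20 normalized PSSM
#' values of the `ws` window positions centred at i (window positions outside
#' the chain contribute an all-zero — or, optionally, half-value — block)
#' followed by six scalars for the central residue: its three conformational
#' propensities, net charge mapped (-1, 0, +1) to (0, 0.5, 1), hydropathy
#' min-max scaled over \[-4.5, 4.5\] and side-chain mass scaled over
#' \[1.0079, 130.1689\]. The dimension is therefore 20 * ws + 6 (e.g. 266
#' for ws = 13, 146 for ws = 7).
#'
#' @param chain sequence string.
#' @param profile normalized `pssm_profile` aligned to `chain`.
#' @param ct `conformation_table` (from the training data).
#' @param ws odd window size, 7-19.
#' @param pt physicochemical tables; see [physico_tables()].
#' @param pad `"zero"` (default) or `"half"` value for out-of-chain window
#'   positions.
#' @return Numeric matrix, one row per residue, 20 * ws + 6 columns, all
#'   entries in \[0, 1\].
#' @export
encode_windows <- function(chain, profile, ct, ws = 13L,
                           pt = physico_tables(), pad = c("zero", "half")) {
  pad <- match.arg(pad)
  stopifnot(inherits(profile, "pssm_profile"),
            inherits(ct, "conformation_table"),
            ws %% 2 == 1, ws >= 7, ws <= 19)
  if (!isTRUE(profile$normalized)) {
    stop("profile must be normalized before encoding; see normalize_profile()",
         call. = FALSE)
  }
  res <- split_chars(chain)
  L <- length(res)
  if (nrow(profile$scores) != L) {
    stop("profile has ", nrow(profile$scores), " rows but chain has ", L,
         " residues", call. = FALSE)
  }
  half <- (ws - 1L) %/% 2L
  fill <- if (pad == "zero") 0 else 0.5
  # padded (L + 2*half) x 20 score matrix; window rows are then contiguous
  padded <- matrix(fill, L + 2L * half, 20L)
  padded[half + seq_len(L), ] <- profile$scores
  X <- matrix(0, L, 20L * ws + 6L)
  for (n in seq_len(ws)) {
    X[, (n - 1L) * 20L + 1:20] <- padded[(n - 1L) + seq_len(L), , drop = FALSE]
  }
  for (i in seq_len(L)) {
    X[i, 20L * ws + 1:6] <- scalar_features(res[i], ct, pt)
  }
  colnames(X) <- c(paste0("p", rep(seq_len(ws) - half - 1L, each = 20L),
                          "_", rep(AA_ALPHABET, ws)),
                   "sH", "sE", "sC", "charge", "hydropathy", "mass")
  X
}
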