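#' @keywords internal
"_PACKAGE"

# Canonical internal residue order (alphabetical one-letter codes).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# Column order used by PSI-BLAST ASCII matrices; parse_pssm() permutes
# incoming columns from this order into AA_ALPHABET order.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Non-standard codes tolerated in input sequences under the default policy.
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O")

EIGHT_STATES <- c("H", "G", "I", "E", "B", "T", "S", "-")
THREE_STATES <- c("H", "E", "C")

# Numeric labels used when exporting training problems (H, E, C).
SS_LABEL_MAP <- c(H = -1, E = 1, C = 2)

#' Physicochemical lookup tables
#'
#' Per-residue net charge (-1/0/+1), Kyte-Doolittle hydropathy and side-chain
#' mass (Da) for the 20 standard amino acids, as used to build the six
#' central-residue scalar features.
#'
#' @return A list with named numeric vectors `net_charge`, `hydropathy` and
#'   `side_chain_mass`, each covering all 20 one-letter codes.
#' @examples
#' physico_tables()$net_charge[["R"]]   # +1
#' physico_tables()$hydropathy[["I"]]   # 4.5
#' @export
physico_tables <- function() {
  list(
    net_charge = c(
      A = 0, R = 1, N = 0, D = -1, C = 0, E = -1, Q = 0, G = 0, H = 1, I = 0,
      L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
    )[AA_ALPHABET],
    hydropathy = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
    )[AA_ALPHABET],
    side_chain_mass = c(
      A = 15.0347, R = 100.1431, N = 58.0597, D = 59.0445, C = 47.0947,
      E = 73.0713, Q = 72.0865, G = 1.0079, H = 81.0969, I = 57.1151,
      L = 57.1151, K = 72.1297, M = 75.1483, F = 91.1323, P = 41.0725,
      S = 31.0341, T = 45.0609, W = 130.1689, Y = 107.1317, V = 43.0883
    )[AA_ALPHABET]
  )
}

# Fixed scaling ranges for the scalar features: the min/max of the tables
# themselves, so train and test use the identical transform.
HYDROPATHY_RANGE <- c(-4.5, 4.5)
MASS_RANGE <- c(1.0079, 130.1689)

#' Look up the physicochemical features of one residue
#'
#' @param residue single one-letter amino-acid code.
#' @param tables result of [physico_tables()].
#' @param policy `"unknown"` (default) returns charge 0, hydropathy 0 and the
#'   mid-range mass for non-standard codes (B, Z, X, U, O); `"strict"` errors.
#' @return Named numeric vector `c(charge, hydropathy, mass)`.
#' @export
lookup_physico <- function(residue, tables = physico_tables(),
                           policy = c("unknown", "strict")) {
  policy <- match.arg(policy)
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  if (residue %in% AA_ALPHABET) {
    return(c(charge = unname(tables$net_charge[residue]),
             hydropathy = unname(tables$hydropathy[residue]),
             mass = unname(tables$side_chain_mass[residue])))
  }
  if (policy == "strict" || !(residue %in% AA_NONSTANDARD)) {
    stop("unknown residue code '", residue, "'", call. = FALSE)
  }
  c(charge = 0, hydropathy = 0, mass = mean(MASS_RANGE))
}

#' Reference conformational propensities
#'
#' The 20x3 table of conformational propensities S[i, j] = a_ij / a_i
#' (fraction of residue i observed in helix/sheet/coil) computed over the
#' CB513 benchmark, shipped as a plain-text fixture for comparison with
#' tables recomputed by [conformation_parameters()].
#'
#' @return A `conformation_table` object (propensity matrix without counts).
#' @export
reference_conformation <- function() {
  path <- system.file("extdata", "conformation_cb513.tsv", package = "sspipe",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  S <- as.matrix(tab[, c("H", "E", "C")])
  rownames(S) <- tab$aa
  S <- S[AA_ALPHABET, , drop = FALSE]
  structure(list(S = S, a_i = NULL, a_ij = NULL,
                 flagged = stats::setNames(rep(FALSE, 20L), AA_ALPHABET)),
            class = "conformation_table")
}
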