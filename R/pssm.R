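#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-Q`-style ASCII matrix layout: header lines, a line of 20 (or
#' 40) residue column letters, then one row per residue holding the position,
#' the residue letter and 20 integer log-odds scores (any further columns —
#' weighted percentages, information content — are ignored). Columns are
#' permuted from the file's order into the package's canonical alphabetical
#' residue order.
#'
#' @param path PSSM file.
#' @param chain optional sequence string; residue letters in the file are
#'   checked against it position by position.
#' @return A `pssm_profile`: list with `residues` (character vector) and
#'   `scores` (L x 20 numeric matrix, columns named by residue), plus a
#'   `normalized` flag (`FALSE` for raw log-odds).
#' @export
parse_pssm <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  # Header = first line whose tokens are all single residue letters (>= 20).
  is_header <- vapply(toks, function(t) {
    length(t) >= 20L && all(nchar(t) == 1L) && all(t[1:20] %in% AA_ALPHABET)
  }, logical(1))
  if (!any(is_header)) stop("no PSSM column header found in '", path, "'",
                            call. = FALSE)
  h <- which(is_header)[1]
  col_order <- toks[[h]][1:20]

  rows <- list()
  residues <- character(0)
  for (k in seq(h + 1L, length.out = max(0L, length(lines) - h))) {
    t <- toks[[k]]
    if (length(t) == 0L) next
    if (!grepl("^[0-9]+$", t[1])) break   # footer (Lambda/K lines etc.)
    vals <- suppressWarnings(as.numeric(t[3:22]))
    if (length(t) < 22L || anyNA(vals)) {
      stop("PSSM row at line ", k, " does not hold 20 log-odds values",
           call. = FALSE)
    }
    residues <- c(residues, toupper(t[2]))
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("PSSM file '", path, "' holds no residue rows",
                          call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, AA_ALPHABET, drop = FALSE]

  if (!is.null(chain)) {
    ch <- split_chars(chain)
    if (length(ch) != length(residues)) {
      stop("PSSM has ", length(residues), " rows but chain has ", length(ch),
           " residues", call. = FALSE)
    }
    bad <- which(ch != residues)
    if (length(bad)) {
      stop("PSSM residue mismatch at position ", bad[1], ": file has '",
           residues[bad[1]], "', chain has '", ch[bad[1]], "'", call. = FALSE)
    }
  }
  new_pssm(residues, scores, normalized = FALSE)
}

new_pssm <- function(residues, scores, normalized) {
  structure(list(residues = residues, scores = scores,
                 normalized = normalized),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile:", length(x$residues), "residues x 20 columns",
      if (x$normalized) "(normalized)" else "(raw log-odds)", "\n")
  invisible(x)
}

#' Write a profile in the PSI-BLAST ASCII layout
#'
#' Emits the same layout [parse_pssm()] reads, so profiles round-trip; used
#' for fixtures and for persisting synthetic profiles.
#'
#' @param p a `pssm_profile` holding raw (integer) scores.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm_profile"))
  scores <- p$scores[, PSIBLAST_ORDER, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("   ", paste(sprintf("%3s", PSIBLAST_ORDER),
                                   collapse = " "))), con)
  for (i in seq_along(p$residues)) {
    writeLines(paste0(sprintf("%5d %s ", i, p$residues[i]),
                      paste(sprintf("%3d", round(scores[i, ])),
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Normalize a PSSM profile to the unit interval
#'
#' Feature vectors fed to the classifier are scaled to \[0, 1\]. Two
#' conventions are offered: `minmax` (default) maps linearly from fixed
#' bounds `(lo, hi)` and clips, so the transform is identical at train and
#' prediction time without any dataset statistics; `logistic` applies
#' 1 / (1 + exp(-x)).
#'
#' @param p a raw `pssm_profile`.
#' @param method `"minmax"` or `"logistic"`.
#' @param lo,hi min-max bounds (defaults -10, 10).
#' @return A normalized `pssm_profile` with all scores in \[0, 1\].
#' @export
normalize_profile <- function(p, method = c("minmax", "logistic"),
                              lo = -10, hi = 10) {
  method <- match.arg(method)
  stopifnot(inherits(p, "pssm_profile"), lo < hi)
  x <- p$scores
  y <- if (method == "minmax") {
    pmin(pmax((x - lo) / (hi - lo), 0), 1)
  } else {
    1 / (1 + exp(-x))
  }
  out <- new_pssm(p$residues, y, normalized = TRUE)
  out$norm_spec <- list(method = method, lo = lo, hi = hi)
  out
}

#' Synthesize a PSSM-like profile for a chain
#'
#' Test stand-in for PSI-BLAST output. Every entry is an integer log-odds
#' score: background scores are drawn from a discretized normal centred at
#' -2 and clipped to \[-9, 4\]; with probability `signal` a row's true-residue
#' column is instead drawn from an elevated distribution on \[5, 10\]
#' (5 + Binomial(5, 0.4)), so at `signal = 1` the true column is strictly
#' maximal in every row, and at `signal = 0` rows carry no information about
#' the residue.
#'
#' @param chain sequence string.
#' @param signal real in \[0, 1\]: probability that a row's true residue is
#'   elevated.
#' @param seed integer; output is deterministic given the seed.
#' @return A raw `pssm_profile` aligned to `chain`.
#' @export
synthesize_pssm <- function(chain, signal = 0.8, seed = 1L) {
  stopifnot(is.character(chain), length(chain) == 1L,
            signal >= 0, signal <= 1)
  ch <- split_chars(chain)
  L <- length(ch)
  with_seed(seed, {
    scores <- matrix(pmin(pmax(round(stats::rnorm(L * 20, -2, 2)), -9), 4),
                     nrow = L, ncol = 20)
    colnames(scores) <- AA_ALPHABET
    elevated <- stats::runif(L) < signal
    hi <- 5L + stats::rbinom(L, 5, 0.4)
    for (i in which(elevated)) {
      j <- match(ch[i], AA_ALPHABET)
      if (!is.na(j)) scores[i, j] <- hi[i]
    }
    new_pssm(ch, scores, normalized = FALSE)
  })
}
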