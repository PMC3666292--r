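# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate a 3-state string; returns its character vector.
check_three_state <- function(s, what = "structure string") {
  stopifnot(is.character(s), length(s) == 1L)
  ch <- split_chars(s)
  bad <- which(!(ch %in% THREE_STATES))
  if (length(bad)) {
    stop(what, " contains invalid character '", ch[bad[1]],
         "' at position ", bad[1], " (expected H/E/C)", call. = FALSE)
  }
  ch
}

check_same_length <- function(truth, pred) {
  if (nchar(truth) != nchar(pred)) {
    stop("length mismatch: truth has ", nchar(truth), " residues, prediction has ",
         nchar(pred), call. = FALSE)
  }
}
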