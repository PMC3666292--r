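# Independent brute-force SOV oracle. Works on 1-based inclusive position
# sets and literal set intersections, unlike the implementation's run-length
# segment arithmetic, so the two routes share no code.

oracle_segments <- function(s) {
  ch <- strsplit(s, "")[[1]]
  segs <- list()
  i <- 1L
  while (i <= length(ch)) {
    j <- i
    while (j < length(ch) && ch[j + 1L] == ch[i]) j <- j + 1L
    segs[[length(segs) + 1L]] <- list(state = ch[i], pos = i:j)
    i <- j + 1L
  }
  segs
}

# Per-class numerator and normalization sums for one truth/pred pair.
oracle_sov_sums <- function(truth, pred, variant) {
  obs <- oracle_segments(truth)
  prd <- oracle_segments(pred)
  num <- 0
  nrm <- 0
  for (cl in c("H", "E", "C")) {
    o <- Filter(function(x) x$state == cl, obs)
    p <- Filter(function(x) x$state == cl, prd)
    if (variant == "sov94") nrm <- nrm + sum(vapply(o, function(x) length(x$pos), 1))
    for (s1 in o) {
      overlapped <- FALSE
      for (s2 in p) {
        both <- intersect(s1$pos, s2$pos)
        if (!length(both)) next
        overlapped <- TRUE
        minov <- length(both)
        maxov <- length(union(s1$pos, s2$pos))   # segments: union is the extent
        len1 <- length(s1$pos)
        len2 <- length(s2$pos)
        delta <- if (variant == "sov99") {
          min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
        } else {
          min(maxov - minov, minov)
        }
        num <- num + (minov + delta) / maxov * len1
        if (variant == "sov99") nrm <- nrm + len1
      }
      if (variant == "sov99" && !overlapped) nrm <- nrm + length(s1$pos)
    }
  }
  list(num = num, nrm = nrm)
}

oracle_sov <- function(truth, pred, variant = "sov99") {
  num <- 0
  nrm <- 0
  for (k in seq_along(truth)) {
    s <- oracle_sov_sums(truth[k], pred[k], variant)
    num <- num + s$num
    nrm <- nrm + s$nrm
  }
  if (nrm == 0) return(NA_real_)
  min(100, 100 * num / nrm)
}

# Random 3-state string of length L (no run-length constraints).
rand_ss3 <- function(L) paste(sample(c("H", "E", "C"), L, TRUE), collapse = "")

# Random 8-state string of length L.
rand_ss8 <- function(L) {
  paste(sample(c("H", "G", "I", "E", "B", "T", "S", "-"), L, TRUE),
        collapse = "")
}

# Tiny labelled dataset for classifier tests: class is a deterministic
# function of the PSSM row (three disjoint high columns), hence separable.
separable_dataset <- function(n_chains = 12, len = 40, seed = 1) {
  spec <- sim_spec(n_chains = n_chains, len_range = c(len, len), seed = seed)
  d <- simulate_dataset(spec)
  hi_col <- c(H = 1L, E = 2L, C = 3L)
  for (k in seq_along(d$id)) {
    cls <- strsplit(d$states[k], "")[[1]]
    sc <- matrix(-9, length(cls), 20)
    colnames(sc) <- colnames(d$profiles[[k]]$scores)
    for (i in seq_along(cls)) sc[i, hi_col[[cls[i]]]] <- 10
    d$profiles[[k]]$scores <- sc
  }
  d
}
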