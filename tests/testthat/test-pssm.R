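write_pssm_fixture <- function(rows, residues) {
  f <- withr::local_tempfile(fileext = ".pssm", .local_envir = parent.frame())
  order20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  lines <- c("", "Last position-specific scoring matrix computed",
             paste("  ", paste(order20, collapse = "  ")))
  for (i in seq_along(residues)) {
    lines <- c(lines, paste(i, residues[i], paste(rows[[i]], collapse = " ")))
  }
  writeLines(lines, f)
  f
}

test_that("parse_pssm reads a well-formed file and checks the chain", {
  rows <- list(1:20, 21:40, rep(-3L, 20))
  f <- write_pssm_fixture(rows, c("M", "F", "K"))
  p <- parse_pssm(f, chain = "MFK")
  expect_equal(dim(p$scores), c(3L, 20L))
  expect_equal(p$residues, c("M", "F", "K"))
  # column permutation: file order starts A R N D...; canonical is A C D E...
  expect_equal(unname(p$scores[1, c("A", "R", "N", "D")]), c(1, 2, 3, 4))
  expect_error(parse_pssm(f, chain = "MFA"), "position 3")
})

test_that("parse_pssm rejects truncated and malformed rows", {
  rows <- list(1:20, 1:12)          # second row truncated
  f <- write_pssm_fixture(rows, c("M", "F"))
  expect_error(parse_pssm(f), "line 5")
  expect_error(parse_pssm(tempfile()), "not found")
})

test_that("profiles round-trip through the package's own writer", {
  p <- synthesize_pssm("MFKVYGYDSNIHK", signal = 0.7, seed = 99)
  f <- withr::local_tempfile()
  write_pssm(p, f)
  p2 <- parse_pssm(f, chain = "MFKVYGYDSNIHK")
  expect_equal(p2$scores, p$scores)
  expect_equal(p2$residues, p$residues)
})

test_that("normalization maps into [0,1] under both conventions", {
  p <- synthesize_pssm("MFK", 1, 1)
  p$scores[1, 1:3] <- c(-10, 0, 10)
  p$scores[2, 1] <- 15                       # outside the bounds
  n <- normalize_profile(p)                  # minmax (-10, 10)
  expect_equal(unname(n$scores[1, 1:3]), c(0, 0.5, 1))
  expect_equal(unname(n$scores[2, 1]), 1)    # clipped
  l <- normalize_profile(p, "logistic")
  expect_equal(unname(l$scores[1, 2]), 0.5)  # sigmoid at zero

  set.seed(3)
  for (rep in 1:20) {
    p$scores[] <- rnorm(length(p$scores), 0, 50)
    for (m in c("minmax", "logistic")) {
      out <- normalize_profile(p, m)$scores
      expect_true(all(out >= 0 & out <= 1))
    }
  }
})

test_that("synthetic profiles are deterministic and respect the signal", {
  a <- synthesize_pssm("MFKVYGYDSN", 0.8, 7)
  b <- synthesize_pssm("MFKVYGYDSN", 0.8, 7)
  expect_identical(a, b)
  expect_false(identical(a, synthesize_pssm("MFKVYGYDSN", 0.8, 8)))

  # signal 1: the true residue's column is strictly maximal in every row
  chain <- paste(rep("ACDEFGHIKLMNPQRSTWYV", 5), collapse = "")
  p <- synthesize_pssm(chain, 1, 5)
  ch <- strsplit(chain, "")[[1]]
  for (i in seq_along(ch)) {
    j <- match(ch[i], colnames(p$scores))
    expect_true(all(p$scores[i, -j] < p$scores[i, j]))
  }
})

test_that("at signal 0 profile scores are independent of the residue", {
  chain <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTWYV", "")[[1]],
                        1000, TRUE), collapse = "")
  p <- synthesize_pssm(chain, 0, 123)
  ch <- strsplit(chain, "")[[1]]
  true_col <- vapply(seq_along(ch),
                     function(i) p$scores[i, ch[i]], numeric(1))
  set.seed(1)
  other <- vapply(seq_along(ch), function(i) {
    p$scores[i, sample(setdiff(colnames(p$scores), ch[i]), 1)]
  }, numeric(1))
  lev <- sort(unique(c(true_col, other)))
  tab <- rbind(table(factor(true_col, lev)), table(factor(other, lev)))
  pv <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(pv, 0.01)   # fails to reject independence
})
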