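test_that("q3 counts matching residues, pooled over chains", {
  expect_equal(q3("HHHCCC", "HHHCCC"), 100)
  expect_equal(q3("HHHCCC", "HHHCCE"), 100 * 5 / 6)
  # a 30-residue chain with 23 matches scores 76.67
  truth <- paste(rep("H", 30), collapse = "")
  pred <- paste(c(rep("H", 23), rep("C", 7)), collapse = "")
  expect_equal(q3(truth, pred), 100 * 23 / 30)
  expect_equal(round(q3(truth, pred), 1), 76.7)
  # pooling: 5/6 and 3/3 -> 8/9
  expect_equal(q3(c("HHHCCC", "EEE"), c("HHHCCE", "EEE")), 100 * 8 / 9)
  expect_error(q3("HH", "H"), "length mismatch")
  expect_error(q3("HX", "HH"), "position 2")
})

test_that("precision and recall come from the pooled confusion matrix", {
  pr <- precision_recall("HHEE", "HHHH")
  expect_equal(unname(pr$precision["H"]), 50)
  expect_equal(unname(pr$recall["H"]), 100)
  expect_equal(unname(pr$recall["E"]), 0)
  expect_true(is.na(pr$precision["E"]))        # nothing predicted E
  expect_true(is.na(pr$precision["C"]))
  expect_equal(sum(pr$confusion), 4L)
  expect_equal(unname(rowSums(pr$confusion)), c(2L, 2L, 0L))

  perfect <- precision_recall("HECHEC", "HECHEC")
  expect_equal(unname(perfect$precision), rep(100, 3))
  expect_equal(unname(perfect$recall), rep(100, 3))
})

test_that("swapping truth and prediction transposes the confusion matrix", {
  set.seed(5)
  for (rep in 1:25) {
    a <- rand_ss3(sample(5:50, 1))
    b <- rand_ss3(nchar(a))
    pa <- precision_recall(a, b)
    pb <- precision_recall(b, a)
    expect_equal(pa$confusion, t(pb$confusion), ignore_attr = TRUE)
    expect_equal(pa$precision, pb$recall)
    expect_equal(pa$recall, pb$precision)
    expect_equal(q3(a, b), q3(b, a))
  }
})

test_that("segmentize produces maximal runs that reconstruct the string", {
  seg <- segmentize("HHHEEC")
  expect_equal(seg$state, c("H", "E", "C"))
  expect_equal(seg$start, c(0L, 3L, 5L))
  expect_equal(seg$end, c(3L, 5L, 6L))
  expect_equal(segmentize("H"), data.frame(state = "H", start = 0L, end = 1L))
  expect_equal(nrow(segmentize("")), 0L)
  set.seed(2)
  for (rep in 1:20) {
    s <- rand_ss3(sample(1:60, 1))
    seg <- segmentize(s)
    rebuilt <- paste(unlist(Map(function(st, a, b) rep(st, b - a),
                                seg$state, seg$start, seg$end)),
                     collapse = "")
    expect_equal(rebuilt, s)
    expect_true(all(seg$end > seg$start))
    expect_true(all(head(seg$state, -1) != tail(seg$state, -1)))  # maximal
  }
})

test_that("sov is 100 on perfect agreement for both variants", {
  set.seed(7)
  for (rep in 1:50) {
    s <- rand_ss3(sample(1:50, 1))
    expect_equal(sov(s, s, "sov99"), 100)
    expect_equal(sov(s, s, "sov94"), 100)
  }
})

test_that("sov matches the brute-force oracle on random pairs", {
  set.seed(13)
  for (rep in 1:200) {
    a <- rand_ss3(sample(2:40, 1))
    b <- rand_ss3(nchar(a))
    expect_equal(sov(a, b, "sov99"), oracle_sov(a, b, "sov99"),
                 tolerance = 1e-12)
    expect_equal(sov(a, b, "sov94"), oracle_sov(a, b, "sov94"),
                 tolerance = 1e-12)
  }
  expect_error(sov("HH", "H"), "length mismatch")
})

test_that("sov pools segment sums across chains before normalizing", {
  a1 <- "HHHHCCEE"; b1 <- "HHCCCCEE"
  a2 <- "CCCHHH";   b2 <- "CCHHHH"
  expect_equal(sov(c(a1, a2), c(b1, b2), "sov99"),
               oracle_sov(c(a1, a2), c(b1, b2), "sov99"))
  # pooling is not the mean of per-chain scores in general
  pooled <- sov(c(a1, a2), c(b1, b2), "sov94")
  expect_equal(pooled, oracle_sov(c(a1, a2), c(b1, b2), "sov94"))
})

test_that("sov99 penalizes a split helix more than q3 does", {
  truth <- "CHHHHHHHHC"
  contiguous <- "CHHHHHHCCC"   # 6 helix residues right, one block
  split <- "CHHHCHHHCC"        # 6 helix residues right, two blocks
  expect_equal(q3(truth, contiguous), q3(truth, split))  # same residue accuracy
  expect_lt(sov(truth, split, "sov99"), sov(truth, contiguous, "sov99"))
})

test_that("ss_evaluate assembles a consistent report", {
  set.seed(31)
  truth <- replicate(5, rand_ss3(sample(10:30, 1)))
  pred <- corrupt_prediction(truth, 0.25, seed = 8)
  rep_ <- ss_evaluate(truth, pred)
  expect_s3_class(rep_, "sov_report")
  expect_equal(rep_$q3, q3(truth, pred))
  expect_equal(rep_$sov94, sov(truth, pred, "sov94"))
  expect_equal(rep_$sov99, sov(truth, pred, "sov99"))
  expect_equal(rep_$q3, 100 * sum(diag(rep_$confusion)) / sum(rep_$confusion))
  expect_equal(sum(rep_$confusion), sum(nchar(truth)))
  expect_output(print(rep_), "Q3")
})
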