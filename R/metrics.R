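#' Three-state per-residue accuracy (Q3)
#'
#' Percentage of residues whose predicted class equals the observed class,
#' pooled over all supplied chains.
#'
#' @param truth,pred character vectors of aligned 3-state strings.
#' @return Percentage in \[0, 100\].
#' @export
q3 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  match_n <- 0L
  total <- 0L
  for (k in seq_along(truth)) {
    check_same_length(truth[k], pred[k])
    t <- check_three_state(truth[k], "observed string")
    p <- check_three_state(pred[k], "predicted string")
    match_n <- match_n + sum(t == p)
    total <- total + length(t)
  }
  if (total == 0L) stop("empty input", call. = FALSE)
  100 * match_n / total
}

#' Confusion matrix with per-class precision and recall
#'
#' Counts are pooled over chains into a 3x3 matrix (rows = observed class,
#' columns = predicted class). Precision(i) = 100 * correctly predicted i /
#' total predicted i; Recall(i) = 100 * correctly predicted i / total
#' observed i. An undefined ratio (zero denominator) is reported as `NA`,
#' never as 0.
#'
#' @inheritParams q3
#' @return List with `confusion` (3x3 integer matrix), and named `precision`
#'   and `recall` percentage vectors over H, E, C.
#' @export
precision_recall <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  conf <- matrix(0L, 3L, 3L, dimnames = list(observed = THREE_STATES,
                                             predicted = THREE_STATES))
  for (k in seq_along(truth)) {
    check_same_length(truth[k], pred[k])
    t <- factor(check_three_state(truth[k]), levels = THREE_STATES)
    p <- factor(check_three_state(pred[k]), levels = THREE_STATES)
    conf <- conf + as.integer(table(t, p))
  }
  diagc <- diag(conf)
  col_s <- colSums(conf)
  row_s <- rowSums(conf)
  list(confusion = conf,
       precision = ifelse(col_s > 0, 100 * diagc / col_s, NA_real_),
       recall = ifelse(row_s > 0, 100 * diagc / row_s, NA_real_))
}

#' Decompose a structure string into maximal segments
#'
#' @param states 3-state string.
#' @return `data.frame` with columns `state`, `start`, `end` (0-based,
#'   half-open); concatenating the runs reconstructs the input.
#' @export
segmentize <- function(states) {
  if (nchar(states) == 0L) {
    return(data.frame(state = character(0), start = integer(0),
                      end = integer(0)))
  }
  ch <- check_three_state(states)
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = end - r$lengths, end = end)
}

# Per-class numerator and normalization sums for one chain.
sov_chain_sums <- function(truth, pred, variant) {
  obs <- segmentize(truth)
  prd <- segmentize(pred)
  num <- stats::setNames(numeric(3), THREE_STATES)
  nrm <- stats::setNames(numeric(3), THREE_STATES)
  for (cl in THREE_STATES) {
    o <- obs[obs$state == cl, , drop = FALSE]
    p <- prd[prd$state == cl, , drop = FALSE]
    if (variant == "sov94") nrm[cl] <- sum(o$end - o$start)
    if (!nrow(o)) next
    for (i in seq_len(nrow(o))) {
      len1 <- o$end[i] - o$start[i]
      paired <- FALSE
      for (j in seq_len(nrow(p))) {
        minov <- min(o$end[i], p$end[j]) - max(o$start[i], p$start[j])
        if (minov <= 0) next
        paired <- TRUE
        len2 <- p$end[j] - p$start[j]
        maxov <- max(o$end[i], p$end[j]) - min(o$start[i], p$start[j])
        delta <- if (variant == "sov99") {
          max(0L, min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L))
        } else {
          min(maxov - minov, minov)
        }
        num[cl] <- num[cl] + (minov + delta) / maxov * len1
        if (variant == "sov99") nrm[cl] <- nrm[cl] + len1
      }
      if (variant == "sov99" && !paired) nrm[cl] <- nrm[cl] + len1
    }
  }
  list(num = num, nrm = nrm)
}

#' Segment overlap score (SOV)
#'
#' Segment-based agreement between observed and predicted structure. For
#' every class i and every overlapping pair of an observed segment s1 and a
#' predicted segment s2 of class i, the pair contributes
#' `(minov + delta) / maxov * len(s1)`, where `minov` is the length of the
#' actual overlap and `maxov` the length of the total extent of the pair.
#' The two published conventions differ in the allowance delta and the
#' normalization N:
#' \describe{
#'   \item{sov99}{delta = min(maxov - minov, minov, floor(len(s1)/2),
#'     floor(len(s2)/2)); N sums len(s1) over every counted pair plus every
#'     observed segment with no overlapping partner.}
#'   \item{sov94}{delta = min(maxov - minov, minov); N is the total number
#'     of observed residues, each observed segment counted once. Because an
#'     observed segment overlapping several predicted segments contributes
#'     several numerator terms, this convention can nominally exceed 100;
#'     the returned score is capped at 100.}
#' }
#' Sums are pooled across chains (and classes) before the final division.
#'
#' @inheritParams q3
#' @param variant `"sov99"` (default) or `"sov94"`.
#' @return Percentage in \[0, 100\]; `NA` if no observed segments exist.
#' @export
sov <- function(truth, pred, variant = c("sov99", "sov94")) {
  variant <- match.arg(variant)
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  num <- 0
  nrm <- 0
  for (k in seq_along(truth)) {
    check_same_length(truth[k], pred[k])
    s <- sov_chain_sums(truth[k], pred[k], variant)
    num <- num + sum(s$num)
    nrm <- nrm + sum(s$nrm)
  }
  if (nrm == 0) return(NA_real_)
  min(100, 100 * num / nrm)
}

#' Evaluate a set of predictions
#'
#' Computes Q3, SOV94, SOV99, the pooled confusion matrix and per-class
#' precision/recall in one report.
#'
#' @inheritParams q3
#' @return An `sov_report` object.
#' @export
ss_evaluate <- function(truth, pred) {
  pr <- precision_recall(truth, pred)
  structure(list(q3 = q3(truth, pred),
                 sov94 = sov(truth, pred, "sov94"),
                 sov99 = sov(truth, pred, "sov99"),
                 confusion = pr$confusion,
                 precision = pr$precision,
                 recall = pr$recall,
                 n_residues = sum(pr$confusion),
                 n_chains = length(truth)),
            class = "sov_report")
}

#' @export
print.sov_report <- function(x, digits = 2, ...) {
  cat(sprintf("Secondary-structure evaluation (%d chains, %d residues)\n",
              x$n_chains, x$n_residues))
  cat(sprintf("  Q3    = %.*f\n  SOV94 = %.*f\n  SOV99 = %.*f\n",
              digits, x$q3, digits, x$sov94, digits, x$sov99))
  m <- cbind(x$confusion, `Recall (%)` = round(x$recall, digits))
  print(m)
  cat("Precision (%):",
      paste(sprintf("%s=%.*f", THREE_STATES, digits, x$precision),
            collapse = "  "), "\n")
  invisible(x)
}

#' Scores before and after filtering
#'
#' Convenience wrapper reporting how the consensus-length filter changed Q3
#' and SOV99 for a prediction against the observed structure.
#'
#' @param before,after predicted strings before and after [apply_filter()].
#' @param truth observed strings.
#' @return Named numeric vector `q3_before`, `q3_after`, `sov99_before`,
#'   `sov99_after`.
#' @export
filter_report <- function(before, after, truth) {
  c(q3_before = q3(truth, before), q3_after = q3(truth, after),
    sov99_before = sov(truth, before, "sov99"),
    sov99_after = sov(truth, after, "sov99"))
}
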