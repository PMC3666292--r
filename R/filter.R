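#' Consensus-length refinement of a predicted structure string
#'
#' A single residue cannot fold into a helix or sheet on its own: a helix
#' needs at least three contiguous residues and a sheet at least two. The
#' filter scans every position i of the prediction and applies two rules:
#' \describe{
#'   \item{Case H}{if `str[i]` is H and both `str[i-1]` and `str[i+1]` are H,
#'     the position is kept; otherwise it is replaced by the majority label
#'     over the segment `(i-3, ..., i+3)`.}
#'   \item{Case E}{if `str[i]` is E and `str[i-1]` or `str[i+1]` is E, the
#'     position is kept; otherwise it is replaced by the segment majority.}
#' }
#' Positions labelled C are never examined. The examined segment is clipped
#' to the sequence; a neighbour outside the sequence counts as "not H" /
#' "not E", so terminal H/E positions are always majority-checked. A tie in
#' the segment majority keeps the original label.
#'
#' In the default `"frozen"` mode every rule reads the original prediction
#' and all replacements are written to a fresh copy, so the result is
#' independent of scan order and replacements never cascade within the pass.
#' The `"sequential"` mode updates in place left to right, letting earlier
#' replacements influence later decisions; it is provided for comparison.
#' One pass only, in either mode.
#'
#' @param pred 3-state string or character vector of strings.
#' @param extension half-width of the examined segment (default 3, the
#'   7-position segment).
#' @param mode `"frozen"` (default) or `"sequential"`.
#' @return Refined string(s), same length(s) as the input.
#' @examples
#' apply_filter("CCCHCCC")   # "CCCCCCC" — isolated helix residue removed
#' apply_filter("CEECC")     # unchanged: each E has an E neighbour
#' @export
apply_filter <- function(pred, extension = 3L, mode = c("frozen", "sequential")) {
  mode <- match.arg(mode)
  stopifnot(extension >= 1L)
  H <- 1L; E <- 2L   # integer codes: H=1, E=2, C=3
  vapply(pred, function(s) {
    ch <- check_three_state(s, "predicted string")
    orig <- match(ch, THREE_STATES)
    L <- length(orig)
    out <- orig
    cur <- orig   # what rules read: frozen original, or the evolving copy
    for (i in seq_len(L)) {
      src <- if (mode == "frozen") orig else cur
      lab <- src[i]
      if (lab == H) {
        if (i > 1L && i < L && src[i - 1L] == H && src[i + 1L] == H) next
      } else if (lab == E) {
        if ((i > 1L && src[i - 1L] == E) || (i < L && src[i + 1L] == E)) next
      } else {
        next   # C positions are never examined
      }
      cnt <- tabulate(src[max(1L, i - extension):min(L, i + extension)], 3L)
      top <- which(cnt == max(cnt))
      if (length(top) == 1L) {
        out[i] <- top
      }                      # majority tie: keep the original label
      if (mode == "sequential") cur <- out
    }
    paste(THREE_STATES[out], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
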