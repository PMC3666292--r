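#' Read protein chains from a FASTA file
#'
#' Each record becomes one row; sequences are uppercased. By default the
#' non-standard codes B, Z, X, U and O are tolerated (downstream features
#' treat them as "unknown"); any other character is an error.
#'
#' @param path FASTA file.
#' @param policy `"unknown"` tolerates B/Z/X/U/O, `"strict"` rejects them.
#' @return `data.frame` with character columns `id` and `sequence`, in file
#'   order.
#' @export
read_fasta <- function(path, policy = c("unknown", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records",
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  allowed <- c(AA_ALPHABET, if (policy == "unknown") AA_NONSTANDARD)
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L) {
      stop("FASTA record '", ids[k], "' has an empty sequence", call. = FALSE)
    }
    ch <- split_chars(seqs[k])
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      stop("FASTA record '", ids[k], "' has invalid residue '", ch[bad[1]],
           "' at position ", bad[1], call. = FALSE)
    }
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein chains to a FASTA file
#'
#' @param chains `data.frame` with columns `id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  stopifnot(is.data.frame(chains), all(c("id", "sequence") %in% names(chains)))
  set <- Biostrings::BStringSet(chains$sequence)
  names(set) <- chains$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read structure strings from plain text
#'
#' One chain per line, `"<id> <string>"`; blank lines ignored. The companion
#' of [read_fasta()] for 8- or 3-state secondary-structure annotations.
#'
#' @param path text file.
#' @return `data.frame` with columns `id` and `states`.
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("structure file '", path, "' is empty", call. = FALSE)
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  states <- trimws(sub("^\\S+\\s+", "", lines))
  if (any(!nzchar(states)) || length(parts) != length(lines)) {
    stop("malformed structure line: '", lines[which(!nzchar(states))[1]], "'",
         call. = FALSE)
  }
  data.frame(id = parts, states = states, stringsAsFactors = FALSE)
}

#' Write structure strings as plain text
#'
#' @param ss `data.frame` with columns `id` and `states`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ss <- function(ss, path) {
  stopifnot(is.data.frame(ss), all(c("id", "states") %in% names(ss)))
  writeLines(paste(ss$id, ss$states), path)
  invisible(path)
}

#' DSSP 8-state to 3-state reduction schemes
#'
#' Five conventions exist for collapsing the eight DSSP states
#' (H, G, I, E, B, T, S, -) to helix/sheet/coil:
#' \describe{
#'   \item{1}{H, G, I to H; E to E; the rest to C (the default, used by PHD).}
#'   \item{2}{H, G to H; E, B to E; the rest to C.}
#'   \item{3}{H, G to H; E to E; the rest to C.}
#'   \item{4}{H to H; E, B to E; the rest to C.}
#'   \item{5}{H to H; E to E; the rest to C.}
#' }
#' A blank is accepted as a synonym of `-`.
#'
#' @param scheme integer 1-5.
#' @return Named character vector mapping each 8-state code to H/E/C.
#' @export
reduction_scheme <- function(scheme = 1L) {
  stopifnot(length(scheme) == 1L, scheme %in% 1:5)
  # 'C' is accepted in input (strings in the wild are often partially
  # reduced); it can only mean coil, under every scheme.
  map <- stats::setNames(rep("C", length(EIGHT_STATES) + 1L),
                         c(EIGHT_STATES, "C"))
  helix <- switch(scheme, c("H", "G", "I"), c("H", "G"), c("H", "G"), "H", "H")
  sheet <- switch(scheme, "E", c("E", "B"), "E", c("E", "B"), "E")
  map[helix] <- "H"
  map[sheet] <- "E"
  map
}

#' Reduce an 8-state structure string to 3 states
#'
#' @param states 8-state string (character vector is mapped element-wise).
#' @param scheme reduction scheme 1-5; see [reduction_scheme()].
#' @return String(s) over H/E/C of the same length(s).
#' @examples
#' reduce_structure("HGIEBTS-")          # "HHHECCCC"
#' reduce_structure("EB", scheme = 4)    # "EE"
#' @export
reduce_structure <- function(states, scheme = 1L) {
  map <- reduction_scheme(scheme)
  vapply(states, function(s) {
    ch <- split_chars(s)
    ch[ch == " "] <- "-"
    bad <- which(!(ch %in% names(map)))
    if (length(bad)) {
      stop("invalid 8-state character '", ch[bad[1]], "' at position ",
           bad[1], call. = FALSE)
    }
    paste(map[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
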