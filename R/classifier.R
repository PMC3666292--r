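#' Bundle chains, structures and profiles into a dataset
#'
#' @param chains `data.frame` from [read_fasta()] (columns `id`, `sequence`)
#'   or a character vector of sequences.
#' @param states optional character vector of 3-state strings (required for
#'   training and evaluation), aligned 1:1 with `chains`.
#' @param profiles list of raw `pssm_profile` objects aligned 1:1 with
#'   `chains`.
#' @return An `ss_data` object.
#' @export
ss_dataset <- function(chains, states = NULL, profiles) {
  if (is.data.frame(chains)) {
    ids <- chains$id
    seqs <- chains$sequence
  } else {
    seqs <- chains
    ids <- if (!is.null(names(chains))) names(chains)
           else sprintf("chain%03d", seq_along(chains))
  }
  stopifnot(length(profiles) == length(seqs))
  if (!is.null(states)) {
    if (is.data.frame(states)) states <- states$states
    stopifnot(length(states) == length(seqs))
    for (k in seq_along(seqs)) {
      if (nchar(states[k]) != nchar(seqs[k])) {
        stop("chain '", ids[k], "': structure string length ",
             nchar(states[k]), " != sequence length ", nchar(seqs[k]),
             call. = FALSE)
      }
    }
  }
  for (k in seq_along(profiles)) {
    stopifnot(inherits(profiles[[k]], "pssm_profile"))
    if (nrow(profiles[[k]]$scores) != nchar(seqs[k])) {
      stop("chain '", ids[k], "': PSSM has ", nrow(profiles[[k]]$scores),
           " rows but sequence has ", nchar(seqs[k]), " residues",
           call. = FALSE)
    }
  }
  structure(list(id = ids, sequence = seqs, states = states,
                 profiles = profiles),
            class = "ss_data")
}

#' @export
print.ss_data <- function(x, ...) {
  cat("ss_data:", length(x$id), "chains,",
      sum(nchar(x$sequence)), "residues,",
      if (is.null(x$states)) "unlabelled" else "labelled", "\n")
  invisible(x)
}

#' @export
`[.ss_data` <- function(x, i) {
  ss_dataset(data.frame(id = x$id[i], sequence = x$sequence[i],
                        stringsAsFactors = FALSE),
             states = if (is.null(x$states)) NULL else x$states[i],
             profiles = x$profiles[i])
}

# Normalize + window-encode every chain of a dataset against one
# conformation table; returns pooled design matrix, labels, chain index.
encode_dataset <- function(data, ct, ws, norm, pt = physico_tables(),
                           pad = "zero") {
  Xs <- vector("list", length(data$id))
  for (k in seq_along(data$id)) {
    p <- data$profiles[[k]]
    if (!isTRUE(p$normalized)) {
      p <- normalize_profile(p, norm$method, norm$lo, norm$hi)
    }
    Xs[[k]] <- encode_windows(data$sequence[k], p, ct, ws, pt, pad)
  }
  X <- do.call(rbind, Xs)
  y <- NULL
  if (!is.null(data$states)) {
    y <- factor(unlist(lapply(data$states, split_chars)),
                levels = THREE_STATES)
  }
  list(X = X, y = y,
       chain = rep(seq_along(data$id), nchar(data$sequence)))
}

OVO_PAIRS <- list(c("H", "E"), c("E", "C"), c("C", "H"))

#' Fit the one-vs-one secondary-structure SVM
#'
#' Trains the three-class predictor: for each pair of classes (H/E, E/C,
#' C/H) a binary radial-basis-function support vector machine is fitted on
#' the window-encoded features of the residues belonging to those classes;
#' prediction combines the three votes by max-wins. The conformation table
#' is computed from the training chains only, and every preprocessing
#' artifact (normalization bounds, conformation table, window size, feature
#' layout) is stored in the fitted object, so `predict` on a fresh
#' FASTA + PSSM input is self-contained (and `saveRDS`/`readRDS` gives a
#' single-file model bundle).
#'
#' @param data an `ss_data` with `states` present.
#' @param ws odd sliding-window size in 7-19 (default 13, the size found
#'   optimal by grid search on CB513).
#' @param cost,gamma RBF-SVM parameters (defaults 2 and 2^-4, the CB513
#'   optimum).
#' @param normalization list with `method` ("minmax" or "logistic") and,
#'   for minmax, bounds `lo`, `hi`.
#' @param pad PSSM padding for out-of-chain window positions.
#' @param seed integer seed (training is deterministic given the data; the
#'   seed is applied for reproducibility of any stochastic SVM internals).
#' @return An object of class `ss_fit`.
#' @export
ss_fit <- function(data, ws = 13L, cost = 2, gamma = 2^-4,
                   normalization = list(method = "minmax", lo = -10, hi = 10),
                   pad = "zero", seed = 1L) {
  stopifnot(inherits(data, "ss_data"))
  if (is.null(data$states)) stop("training data must carry structure strings",
                                 call. = FALSE)
  ct <- conformation_parameters(data$sequence, data$states)
  enc <- encode_dataset(data, ct, ws, normalization, pad = pad)
  missing <- THREE_STATES[!(THREE_STATES %in% enc$y)]
  if (length(missing)) {
    stop("training labels lack class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  freq <- table(enc$y)
  models <- with_seed(seed, lapply(OVO_PAIRS, function(pr) {
    idx <- enc$y %in% pr
    e1071::svm(enc$X[idx, , drop = FALSE], factor(enc$y[idx], levels = pr),
               kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE, cachesize = 200)
  }))
  structure(list(models = models, pairs = OVO_PAIRS, ws = as.integer(ws),
                 cost = cost, gamma = gamma, normalization = normalization,
                 pad = pad, conformation = ct,
                 class_freq = freq, label_map = SS_LABEL_MAP,
                 n_features = ncol(enc$X), n_residues = nrow(enc$X),
                 n_chains = length(data$id), seed = seed),
            class = "ss_fit")
}

# Max-wins voting over the three binary decisions, with deterministic ties:
# highest training-class frequency first, then the fixed order C > H > E.
max_wins_vote <- function(votes, class_freq) {
  tally <- stats::setNames(numeric(3), THREE_STATES)
  for (v in votes) tally[v] <- tally[v] + 1
  top <- names(tally)[tally == max(tally)]
  if (length(top) > 1L) {
    f <- class_freq[top]
    top <- top[f == max(f)]
    if (length(top) > 1L) top <- intersect(c("C", "H", "E"), top)[1]
  }
  top[1]
}

#' Predict secondary structure
#'
#' @param object fitted `ss_fit` model.
#' @param newdata an `ss_data` (structure strings are ignored if present), or
#'   an already-encoded feature matrix with `20 * ws + 6` columns.
#' @param filter apply the consensus-length filter ([apply_filter()]) to the
#'   predicted strings (only when `newdata` is an `ss_data`).
#' @param ... unused.
#' @return For `ss_data` input, a character vector of predicted 3-state
#'   strings (one per chain); for matrix input, a factor of per-residue
#'   labels.
#' @export
predict.ss_fit <- function(object, newdata, filter = FALSE, ...) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != object$n_features) {
      stop("feature matrix has ", ncol(newdata), " columns; model expects ",
           object$n_features, call. = FALSE)
    }
    if (nrow(newdata) == 0L) return(factor(character(0), levels = THREE_STATES))
    return(factor(vote_matrix(object, newdata), levels = THREE_STATES))
  }
  stopifnot(inherits(newdata, "ss_data"))
  enc <- encode_dataset(newdata, object$conformation, object$ws,
                        object$normalization, pad = object$pad)
  lab <- vote_matrix(object, enc$X)
  out <- vapply(seq_along(newdata$id), function(k) {
    paste(lab[enc$chain == k], collapse = "")
  }, character(1))
  if (filter) out <- apply_filter(out)
  out
}

vote_matrix <- function(object, X) {
  votes <- lapply(object$models, function(m) {
    as.character(stats::predict(m, X))
  })
  vapply(seq_len(nrow(X)), function(i) {
    max_wins_vote(lapply(votes, `[[`, i), object$class_freq)
  }, character(1))
}

#' @export
print.ss_fit <- function(x, ...) {
  cat("One-vs-one RBF-SVM secondary-structure model\n")
  cat(sprintf("  %d binary classifiers (H/E, E/C, C/H); C = %g, gamma = %g\n",
              length(x$models), x$cost, x$gamma))
  cat(sprintf("  window size %d -> %d features per residue\n",
              x$ws, x$n_features))
  cat(sprintf("  trained on %d chains (%d residues)\n",
              x$n_chains, x$n_residues))
  invisible(x)
}

#' @export
summary.ss_fit <- function(object, ...) {
  out <- list(fit = object,
              support_vectors = vapply(object$models,
                                       function(m) length(m$index),
                                       integer(1)),
              class_freq = object$class_freq)
  class(out) <- "summary.ss_fit"
  out
}

#' @export
print.summary.ss_fit <- function(x, ...) {
  print(x$fit)
  cat("  support vectors per binary problem:",
      paste(x$support_vectors, collapse = ", "), "\n")
  cat("  training class frequencies:\n")
  print(x$class_freq)
  invisible(x)
}

#' Chain-level cross-validation folds
#'
#' Chains (not residues) are shuffled with the seed and dealt round-robin
#' into folds, so windows of one chain never straddle the train/test split.
#'
#' @param n_chains number of chains.
#' @param folds number of folds (default 3).
#' @param seed integer seed.
#' @return Integer vector of fold labels (1..folds), one per chain.
#' @export
make_folds <- function(n_chains, folds = 3L, seed = 1L) {
  stopifnot(folds >= 2L, n_chains >= folds)
  ord <- with_seed(seed, sample.int(n_chains))
  f <- integer(n_chains)
  f[ord] <- rep_len(seq_len(folds), n_chains)
  f
}

#' Grid search over window size and SVM parameters
#'
#' Exhaustively evaluates every (window size, cost, gamma) combination by
#' chain-level k-fold cross-validation, scoring each by residue-level Q3
#' pooled over the test folds. The default grid is the 6 x 6 set
#' C in 2^0..2^5, gamma in 2^-6..2^-1 for each window size in 7..19.
#' Conformation tables are recomputed from each fold's training chains so no
#' test label leaks into the features. Ties in accuracy are broken toward
#' the smallest window size, then the smallest cost, then the smallest
#' gamma.
#'
#' @param data labelled `ss_data`.
#' @param ws_set odd window sizes to try.
#' @param cost_set,gamma_set SVM parameter grids.
#' @param folds number of CV folds (default 3).
#' @param normalization,pad as in [ss_fit()].
#' @param seed integer seed (controls fold assignment).
#' @param verbose print progress.
#' @return An `ss_grid` object: `table` (one row per combination, with
#'   column `accuracy`) and `best` (the selected row).
#' @export
ss_grid_search <- function(data, ws_set = seq(7L, 19L, 2L),
                           cost_set = 2^(0:5), gamma_set = 2^(-6:-1),
                           folds = 3L,
                           normalization = list(method = "minmax",
                                                lo = -10, hi = 10),
                           pad = "zero", seed = 1L, verbose = FALSE) {
  stopifnot(inherits(data, "ss_data"), !is.null(data$states))
  fold_of <- make_folds(length(data$id), folds, seed)
  grid <- expand.grid(gamma = gamma_set, cost = cost_set, ws = ws_set,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("ws", "cost", "gamma")]
  grid$accuracy <- NA_real_

  for (ws in ws_set) {
    correct <- stats::setNames(rep(0, nrow(grid)), NULL)
    total <- 0
    for (f in seq_len(folds)) {
      tr <- data[fold_of != f]
      te <- data[fold_of == f]
      ct <- conformation_parameters(tr$sequence, tr$states)
      enc_tr <- encode_dataset(tr, ct, ws, normalization, pad = pad)
      enc_te <- encode_dataset(te, ct, ws, normalization, pad = pad)
      freq <- table(enc_tr$y)
      total <- total + length(enc_te$y)
      for (g in which(grid$ws == ws)) {
        models <- with_seed(seed, lapply(OVO_PAIRS, function(pr) {
          idx <- enc_tr$y %in% pr
          e1071::svm(enc_tr$X[idx, , drop = FALSE],
                     factor(enc_tr$y[idx], levels = pr),
                     kernel = "radial", cost = grid$cost[g],
                     gamma = grid$gamma[g], scale = FALSE, cachesize = 200)
        }))
        fit <- list(models = models, class_freq = freq)
        lab <- vote_matrix(fit, enc_te$X)
        correct[g] <- correct[g] + sum(lab == as.character(enc_te$y))
        if (verbose) {
          message(sprintf("ws=%d C=%g gamma=%g fold=%d", ws, grid$cost[g],
                          grid$gamma[g], f))
        }
      }
    }
    sel <- grid$ws == ws
    grid$accuracy[sel] <- 100 * correct[sel] / total
  }
  ord <- order(-grid$accuracy, grid$ws, grid$cost, grid$gamma)
  structure(list(table = grid, best = grid[ord[1], ], folds = folds,
                 seed = seed),
            class = "ss_grid")
}

#' @export
print.ss_grid <- function(x, ...) {
  cat(sprintf("Grid search over %d combinations (%d-fold chain CV)\n",
              nrow(x$table), x$folds))
  b <- x$best
  cat(sprintf("  best: ws = %d, C = %g, gamma = %g, Q3 = %.4f\n",
              b$ws, b$cost, b$gamma, b$accuracy))
  invisible(x)
}

#' @export
plot.ss_grid <- function(x, ...) {
  tab <- x$table
  best_per_ws <- vapply(split(tab$accuracy, tab$ws), max, numeric(1))
  ws <- as.integer(names(best_per_ws))
  plot(ws, best_per_ws, type = "b", xlab = "window size",
       ylab = "best CV Q3 (%)",
       main = "Cross-validated accuracy by window size", ...)
  invisible(x)
}
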