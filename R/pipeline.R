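#' Write a feature matrix in sparse SVM-trainer format
#'
#' One line per residue: numeric label (H -> -1, E -> +1, C -> +2) followed
#' by 1-based `index:value` pairs for the non-zero features — the layout
#' accepted by libsvm-style command-line trainers.
#'
#' @param X feature matrix from [encode_windows()].
#' @param y factor or character vector of H/E/C labels (one per row).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(X, y, path) {
  stopifnot(nrow(X) == length(y))
  lab <- SS_LABEL_MAP[as.character(y)]
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    paste(lab[i], paste(sprintf("%d:%.6g", nz, X[i, nz]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full prediction pipeline
#'
#' Wires the three stages together: feature extraction (PSSM normalization,
#' conformation parameters and window encoding), one-vs-one SVM training and
#' prediction, and consensus-length filtering, followed by evaluation when
#' the test set carries true structures. Re-running with the same inputs and
#' seed reproduces identical outputs.
#'
#' @param train labelled `ss_data` used for fitting.
#' @param test `ss_data` to predict (evaluated if labelled).
#' @param ws,cost,gamma,normalization,seed passed to [ss_fit()].
#' @param out_dir optional directory; when given, the model
#'   (`model.rds`), raw and filtered predictions (`pred_raw.ss3`,
#'   `pred_filtered.ss3`) and the evaluation report (`report.txt`) are
#'   written there.
#' @return List with the fitted `model`, `pred_raw` and `pred_filtered`
#'   string vectors, and `report_raw` / `report_filtered` (`sov_report`s, or
#'   `NULL` for unlabelled test data).
#' @export
run_pipeline <- function(train, test, ws = 13L, cost = 2, gamma = 2^-4,
                         normalization = list(method = "minmax",
                                              lo = -10, hi = 10),
                         seed = 1L, out_dir = NULL) {
  model <- ss_fit(train, ws = ws, cost = cost, gamma = gamma,
                  normalization = normalization, seed = seed)
  pred_raw <- predict(model, test)
  pred_filtered <- apply_filter(pred_raw)
  report_raw <- report_filtered <- NULL
  if (!is.null(test$states)) {
    report_raw <- ss_evaluate(test$states, pred_raw)
    report_filtered <- ss_evaluate(test$states, pred_filtered)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model, file.path(out_dir, "model.rds"))
    write_ss(data.frame(id = test$id, states = pred_raw),
             file.path(out_dir, "pred_raw.ss3"))
    write_ss(data.frame(id = test$id, states = pred_filtered),
             file.path(out_dir, "pred_filtered.ss3"))
    if (!is.null(report_filtered)) {
      con <- file(file.path(out_dir, "report.txt"), "w")
      sink(con)
      cat("== raw predictions ==\n")
      print(report_raw)
      cat("\n== filtered predictions ==\n")
      print(report_filtered)
      sink()
      close(con)
    }
  }
  list(model = model, pred_raw = pred_raw, pred_filtered = pred_filtered,
       report_raw = report_raw, report_filtered = report_filtered)
}
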