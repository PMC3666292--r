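#' Specification for the synthetic benchmark generator
#'
#' The generator emulates the three statistical properties the pipeline
#' relies on: (a) segmental structure strings obeying the physical minimum
#' run lengths (helix >= 3, sheet >= 2, coil >= 1) with
#' geometric-with-floor run lengths; (b) residue composition conditioned on
#' the structure class, by Bayes inversion of a conformational-propensity
#' table under a uniform residue prior (optionally sharpened); and (c)
#' PSSM-like integer log-odds profiles correlated with the true residue via
#' [synthesize_pssm()].
#'
#' @param n_chains number of chains.
#' @param len_range `c(min, max)` chain lengths, sampled uniformly.
#' @param mean_run named vector of mean run lengths for H, E, C; runs are
#'   `min + Geometric` with these means.
#' @param min_run hard minimum run lengths (helix 3, sheet 2, coil 1).
#' @param propensity a `conformation_table` whose columns are inverted into
#'   class-conditional emission probabilities (default the packaged CB513
#'   reference table).
#' @param sharpness exponent applied to the propensity columns before
#'   normalization; values above 1 make compositions more class-specific.
#'   The default (3) places end-to-end synthetic Q3 in a discriminative
#'   65-90 band rather than saturating it.
#' @param signal PSSM signal strength in \[0, 1\] (see [synthesize_pssm()]).
#' @param seed integer seed; all output is deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_chains = 200L, len_range = c(40L, 100L),
                     mean_run = c(H = 9, E = 5, C = 6),
                     min_run = c(H = 3L, E = 2L, C = 1L),
                     propensity = reference_conformation(),
                     sharpness = 3, signal = 0.8, seed = 1L) {
  stopifnot(n_chains >= 1L, length(len_range) == 2L,
            len_range[1] >= 1L, len_range[1] <= len_range[2],
            all(THREE_STATES %in% names(mean_run)),
            all(mean_run[THREE_STATES] >= min_run[THREE_STATES]),
            signal >= 0, signal <= 1, sharpness > 0)
  if (len_range[2] < min_run[["H"]]) {
    stop("infeasible spec: maximum chain length ", len_range[2],
         " is below the minimum helix run of ", min_run[["H"]],
         call. = FALSE)
  }
  emission <- apply(propensity$S[AA_ALPHABET, THREE_STATES], 2,
                    function(col) {
                      w <- col^sharpness
                      w / sum(w)
                    })
  structure(list(n_chains = as.integer(n_chains),
                 len_range = as.integer(len_range),
                 mean_run = mean_run[THREE_STATES],
                 min_run = min_run[THREE_STATES],
                 emission = emission, sharpness = sharpness,
                 signal = signal, seed = as.integer(seed)),
            class = "sim_spec")
}

# One segmental structure string of length L: alternating classes with
# geometric-with-floor run lengths; a tail too short for the drawn class's
# minimum run is filled with coil.
sim_structure <- function(L, mean_run, min_run, trans_to_coil = 0.85,
                          helix_vs_sheet = 0.62) {
  init <- sample(THREE_STATES, 1L, prob = c(0.35, 0.21, 0.44))
  out <- character(0)
  cur <- init
  while (length(out) < L) {
    mn <- min_run[[cur]]
    p <- 1 / (mean_run[[cur]] - mn + 1)
    run <- mn + stats::rgeom(1L, p)
    remaining <- L - length(out)
    if (run >= remaining) {
      run <- remaining
      if (run < mn) cur <- "C"
    }
    out <- c(out, rep(cur, run))
    cur <- if (cur == "C") {
      if (stats::runif(1) < helix_vs_sheet) "H" else "E"
    } else {
      if (stats::runif(1) < trans_to_coil) "C"
      else setdiff(c("H", "E"), cur)
    }
  }
  paste(out, collapse = "")
}

#' Generate a synthetic labelled dataset
#'
#' @param spec a [sim_spec()].
#' @return An `ss_data` with sequences, true 3-state structure strings and
#'   raw synthetic PSSM profiles; byte-identical across runs with the same
#'   spec.
#' @export
simulate_dataset <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    lens <- sample(seq(spec$len_range[1], spec$len_range[2]),
                   spec$n_chains, replace = TRUE)
    states <- vapply(lens, sim_structure, character(1),
                     mean_run = spec$mean_run, min_run = spec$min_run)
    seqs <- vapply(states, function(s) {
      cls <- split_chars(s)
      paste(vapply(cls, function(cl) {
        sample(AA_ALPHABET, 1L, prob = spec$emission[, cl])
      }, character(1)), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    pssm_seeds <- sample.int(.Machine$integer.max, spec$n_chains)
    profiles <- lapply(seq_len(spec$n_chains), function(k) {
      synthesize_pssm(seqs[k], spec$signal, pssm_seeds[k])
    })
    ss_dataset(data.frame(id = sprintf("sim%04d", seq_len(spec$n_chains)),
                          sequence = seqs, stringsAsFactors = FALSE),
               states = unname(states), profiles = profiles)
  })
}

#' Corrupt a structure string with independent label noise
#'
#' Each position is flipped, independently with probability `error_rate`, to
#' one of the two other classes chosen uniformly. Used to exercise the
#' filter and the metrics without a trained model.
#'
#' @param truth 3-state string or vector of strings.
#' @param error_rate flip probability in \[0, 1\].
#' @param seed integer seed.
#' @return Corrupted string(s), deterministic given the seed.
#' @export
corrupt_prediction <- function(truth, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    vapply(truth, function(s) {
      ch <- check_three_state(s)
      flip <- stats::runif(length(ch)) < error_rate
      if (any(flip)) {
        ch[flip] <- vapply(ch[flip], function(cl) {
          sample(setdiff(THREE_STATES, cl), 1L)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}
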