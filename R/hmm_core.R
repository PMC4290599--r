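#' Construct a hidden Markov model over the DNA alphabet
#'
#' Builds a first-order HMM with silent `begin` and `end` states and emitting
#' states over `{A,C,G,T}`. The transition matrix both parameterizes and fixes
#' the topology: entries that are exactly zero are *structural* zeros, and
#' training ([baum_welch()]) never makes them positive.
#'
#' @param trans Square numeric matrix of transition probabilities with row and
#'   column names. The first state must be the silent `begin` state (no
#'   incoming transitions), the last the silent `end` state (no outgoing
#'   transitions). Every other row must sum to 1.
#' @param emis Numeric matrix (states x 4, columns `A,C,G,T`) of emission
#'   probabilities; the `begin`/`end` rows must be all zero, every emitting
#'   row must sum to 1. Zero entries are structural (e.g. a clamped G state).
#' @param labels Optional character vector, one per state, giving the
#'   structural role of each state (e.g. `"run1"`, `"loop2"`); `NA` for
#'   `begin`/`end`. Used by [annotate_g4()].
#' @param model_id Optional integer tag (1-4) recording which G4 topology the
#'   model instantiates.
#' @return An object of class `g4hmm`.
#' @seealso [build_model()] for the four G4 topologies, [hmm_viterbi()],
#'   [hmm_forward()], [baum_welch()].
#' @export
hmm <- function(trans, emis, labels = NULL, model_id = NULL) {
  model <- structure(
    list(states = rownames(trans), trans = trans, emis = emis,
         labels = labels, model_id = model_id),
    class = "g4hmm")
  validate_hmm(model)
  model
}

#' Validate the structural invariants of an HMM
#'
#' Checks stochasticity (rows of the transition matrix and emitting rows of
#' the emission matrix sum to 1 within `tol`), the silent begin/end contract
#' (begin has no incoming transitions and emits nothing; end has no outgoing
#' transitions and emits nothing), and shape consistency.
#'
#' @param model A `g4hmm` object.
#' @param tol Numeric tolerance on row sums.
#' @return `model`, invisibly; errors if an invariant is violated.
#' @export
validate_hmm <- function(model, tol = 1e-9) {
  trans <- model$trans
  emis <- model$emis
  m <- nrow(trans)
  if (is.null(m) || m != ncol(trans) || m < 3)
    stop("transition matrix must be square with >= 3 states")
  if (!identical(rownames(trans), colnames(trans)))
    stop("transition matrix row/column names must agree")
  if (nrow(emis) != m || ncol(emis) != 4)
    stop("emission matrix must be states x 4")
  if (!identical(colnames(emis), DNA_BASES))
    stop("emission columns must be A, C, G, T")
  if (any(trans < 0) || any(emis < 0))
    stop("negative probabilities")
  rs <- rowSums(trans)
  if (any(abs(rs[-m] - 1) > tol))
    stop("outgoing transition probabilities must sum to 1 for every non-end state")
  if (rs[m] != 0)
    stop("end state must have no outgoing transitions")
  if (any(trans[, 1] != 0))
    stop("begin state must have no incoming transitions")
  if (any(emis[c(1, m), ] != 0))
    stop("begin/end states are silent and must emit nothing")
  es <- rowSums(emis)[-c(1, m)]
  if (any(abs(es - 1) > tol))
    stop("emission probabilities must sum to 1 for every emitting state")
  if (!is.null(model$labels) && length(model$labels) != m)
    stop("labels must have one entry per state")
  invisible(model)
}

#' @export
print.g4hmm <- function(x, ...) {
  m <- nrow(x$trans)
  cat(sprintf("<g4hmm> %d states (%d emitting)%s, %d allowed transitions\n",
              m, m - 2,
              if (!is.null(x$model_id)) sprintf(", G4 model %d", x$model_id) else "",
              sum(x$trans > 0)))
  invisible(x)
}

# Encode a DNA string as integers 1..4; errors on anything outside ACGT.
# Input is uppercased first (soft-masked lowercase accepted).
encode_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("sequence contains bases outside {A,C,G,T}: %s",
                 paste(bad, collapse = ", ")))
  }
  idx
}

log_mat <- function(p) {
  out <- log(p)
  out[p == 0] <- -Inf
  out
}

#' Viterbi decoding: the most probable state path
#'
#' Computes the maximum-probability path of emitting states for `seq` by
#' dynamic programming in log space (O(m^2 n) for m states and n bases). Ties
#' are broken deterministically toward the lowest state index.
#'
#' @param model A `g4hmm` object.
#' @param seq A single DNA string over `{A,C,G,T}` (case-insensitive).
#' @return An object of class `g4hmm_path`: list with `states` (character
#'   path, one emitting state per base), `state_idx`, `log_prob` (joint log
#'   probability of path and sequence) and `no_path`. When the topology admits
#'   no path for `seq` this is not an error: `no_path` is `TRUE`,
#'   `log_prob` is `-Inf` and the path is empty.
#' @export
hmm_viterbi <- function(model, seq) {
  obs <- encode_dna(seq)
  res <- hmm_viterbi_cpp(log_mat(model$trans), log_mat(model$emis), obs)
  if (length(res$path) == 0L)
    return(structure(list(states = character(0), state_idx = integer(0),
                          log_prob = -Inf, no_path = TRUE),
                     class = "g4hmm_path"))
  structure(list(states = model$states[res$path], state_idx = res$path,
                 log_prob = res$logprob, no_path = FALSE),
            class = "g4hmm_path")
}

#' @export
print.g4hmm_path <- function(x, ...) {
  if (x$no_path) cat("<g4hmm_path> no admissible path (log-prob -Inf)\n")
  else cat(sprintf("<g4hmm_path> %d states, log-prob %.4f\n",
                   length(x$states), x$log_prob))
  invisible(x)
}

#' Forward algorithm: full sequence log-likelihood
#'
#' Log of the total probability of `seq` summed over all admissible state
#' paths, `log P(x | theta)`, computed in log space with log-sum-exp.
#' Returns `-Inf` when no path exists; always at least the Viterbi path
#' log-probability.
#'
#' @inheritParams hmm_viterbi
#' @return A single numeric log-likelihood.
#' @export
hmm_forward <- function(model, seq) {
  obs <- encode_dna(seq)
  hmm_forward_cpp(log_mat(model$trans), log_mat(model$emis), obs)$loglik
}

#' Backward algorithm: full sequence log-likelihood by backward recursion
#'
#' Same quantity as [hmm_forward()] computed from the opposite end of the
#' sequence; agrees with the forward value to numerical precision and is used
#' together with it in Baum-Welch expected counts.
#'
#' @inheritParams hmm_viterbi
#' @return A single numeric log-likelihood.
#' @export
hmm_backward <- function(model, seq) {
  obs <- encode_dna(seq)
  hmm_backward_cpp(log_mat(model$trans), log_mat(model$emis), obs)$loglik
}

#' Baum-Welch training
#'
#' Expectation-maximization re-estimation of transition and emission
#' probabilities from unlabeled sequences. Expected counts are accumulated
#' with the forward-backward algorithm; the M-step adds `pseudocount` to every
#' *allowed* (structurally nonzero) entry before normalizing, so the topology
#' is preserved exactly: transitions and emissions that start at zero stay
#' zero. Iteration stops when the improvement in total log-likelihood drops
#' below `tol`, or after `max_iter` iterations.
#'
#' @param model A `g4hmm` object holding the initial parameters.
#' @param seqs Character vector of training sequences.
#' @param tol Convergence threshold on the total log-likelihood (default
#'   `1e-4`).
#' @param max_iter Iteration cap (default 500).
#' @param pseudocount Dirichlet-style pseudocount added to allowed expected
#'   counts (default `1e-3`). With a positive pseudocount the data
#'   log-likelihood is monotone non-decreasing up to a perturbation of the
#'   order of the pseudocount.
#' @param on_no_path What to do with training sequences that admit no path
#'   under the topology: `"exclude"` (default; they are dropped with a warning
#'   naming them) or `"error"`.
#' @return The trained `g4hmm`, with attributes `loglik_trace` (total
#'   log-likelihood at the start of each iteration), `n_iter`, `converged`,
#'   and `excluded` (names/indices of dropped sequences).
#' @export
baum_welch <- function(model, seqs, tol = 1e-4, max_iter = 500L,
                       pseudocount = 1e-3,
                       on_no_path = c("exclude", "error")) {
  on_no_path <- match.arg(on_no_path)
  if (length(seqs) == 0L) stop("empty training set")
  obs_list <- lapply(seqs, encode_dna)
  ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))

  allowedA <- model$trans > 0
  allowedE <- model$emis > 0
  logA <- log_mat(model$trans)
  logE <- log_mat(model$emis)

  # structural admissibility does not depend on parameter values, only on the
  # zero pattern, so one likelihood pass at the initial parameters finds all
  # no-path sequences
  ll0 <- vapply(obs_list, function(o) hmm_forward_cpp(logA, logE, o)$loglik,
                numeric(1))
  bad <- !is.finite(ll0)
  excluded <- ids[bad]
  if (any(bad)) {
    msg <- sprintf("%d training sequence(s) admit no path under the topology: %s",
                   sum(bad), paste(excluded, collapse = ", "))
    if (on_no_path == "error") stop(msg)
    warning(msg)
    obs_list <- obs_list[!bad]
    if (length(obs_list) == 0L) stop("no trainable sequences remain")
  }

  m <- nrow(model$trans)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- matrix(0, m, m)
    E <- matrix(0, m, 4)
    total_ll <- 0
    for (o in obs_list) {
      cnt <- hmm_expected_counts_cpp(logA, logE, o)
      A <- A + cnt$trans
      E <- E + cnt$emis
      total_ll <- total_ll + cnt$loglik
    }
    trace <- c(trace, total_ll)
    if (it > 1L && (total_ll - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    A <- A + pseudocount * allowedA
    E <- E + pseudocount * allowedE
    rsA <- rowSums(A)
    keep <- rsA > 0
    A[keep, ] <- A[keep, , drop = FALSE] / rsA[keep]
    A[m, ] <- 0
    rsE <- rowSums(E)
    keepE <- rsE > 0
    E[keepE, ] <- E[keepE, , drop = FALSE] / rsE[keepE]
    logA <- log_mat(A)
    logE <- log_mat(E)
  }
  out <- model
  out$trans <- exp(logA)
  out$trans[!allowedA] <- 0
  out$emis <- exp(logE)
  out$emis[!allowedE] <- 0
  dimnames(out$trans) <- dimnames(model$trans)
  dimnames(out$emis) <- dimnames(model$emis)
  # renormalize away exp/log round-trip error
  rs <- rowSums(out$trans)
  out$trans[rs > 0, ] <- out$trans[rs > 0, , drop = FALSE] / rs[rs > 0]
  rs <- rowSums(out$emis)
  out$emis[rs > 0, ] <- out$emis[rs > 0, , drop = FALSE] / rs[rs > 0]
  validate_hmm(out)
  attr(out, "loglik_trace") <- trace
  attr(out, "n_iter") <- length(trace)
  attr(out, "converged") <- converged
  attr(out, "excluded") <- excluded
  out
}

#' Sample sequences from an HMM
#'
#' Draws sequences (and their generating state paths) by walking the model
#' from `begin` to `end`. Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param model A `g4hmm` object.
#' @param n Number of sequences to draw.
#' @param max_len Guard against non-terminating walks (error if exceeded).
#' @return A list of `n` elements, each a list with `seq` (DNA string) and
#'   `path` (character vector of generating emitting states).
#' @export
hmm_simulate <- function(model, n = 1L, max_len = 100000L) {
  m <- nrow(model$trans)
  if (all(model$trans[1, ] == 0)) stop("begin state has no outgoing transitions")
  replicate(n, simplify = FALSE, {
    cur <- 1L
    bases <- character(0)
    path <- integer(0)
    repeat {
      cur <- sample.int(m, 1L, prob = model$trans[cur, ])
      if (cur == m) break
      bases <- c(bases, sample(DNA_BASES, 1L, prob = model$emis[cur, ]))
      path <- c(path, cur)
      if (length(bases) > max_len)
        stop("sampled walk exceeded max_len; check self-loop probabilities")
    }
    list(seq = paste(bases, collapse = ""), path = model$states[path])
  })
}

#' Write an HMM to a JSON file
#'
#' Serializes states, labels, the allowed transition edges with their
#' probabilities, and per-state emission tables. Numbers are written at full
#' double precision so [read_hmm()] round-trips the model exactly.
#'
#' @param model A `g4hmm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(model, path) {
  idx <- which(model$trans > 0, arr.ind = TRUE)
  edges <- data.frame(from = model$states[idx[, 1]],
                      to = model$states[idx[, 2]],
                      prob = model$trans[idx])
  emis <- lapply(seq_along(model$states), function(i)
    as.list(setNames(model$emis[i, ], DNA_BASES)))
  names(emis) <- model$states
  obj <- list(format = "g4hmm-1", states = model$states,
              labels = model$labels, model_id = model$model_id,
              edges = edges, emissions = emis)
  # I(17) = 17 significant digits: IEEE doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an HMM written by [write_hmm()]
#'
#' @param path Path to a JSON model file.
#' @return A `g4hmm` object.
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- obj$states
  m <- length(states)
  trans <- matrix(0, m, m, dimnames = list(states, states))
  trans[cbind(match(obj$edges$from, states), match(obj$edges$to, states))] <-
    obj$edges$prob
  emis <- matrix(0, m, 4, dimnames = list(states, DNA_BASES))
  for (s in states) emis[s, ] <- unlist(obj$emissions[[s]])[DNA_BASES]
  labels <- obj$labels
  if (!is.null(labels)) labels <- as.character(labels)
  hmm(trans, emis, labels = labels, model_id = obj$model_id)
}
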