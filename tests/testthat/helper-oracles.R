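# Independent oracles used across the suite. These deliberately avoid the
# package's DP / regex / counting code paths: enumeration, recursive
# backtracking and substring counting only.

BASES <- c("A", "C", "G", "T")

# Brute-force enumeration of all admissible state paths of `model` for `seq`.
# Returns the number of paths, total log-probability (forward oracle), the
# best log-probability (Viterbi oracle), the best path (first in state-index
# lexicographic order), and whether the maximum is unique (1e-9).
enum_paths <- function(model, seq) {
  obs <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  m <- nrow(model$trans)
  logps <- numeric(0)
  paths <- list()
  rec <- function(prefix, cur, logp, i) {
    if (i > length(obs)) {
      a <- model$trans[cur, m]
      if (a > 0) {
        logps[[length(logps) + 1L]] <<- logp + log(a)
        paths[[length(paths) + 1L]] <<- prefix
      }
      return(invisible())
    }
    for (k in 2:(m - 1)) {
      a <- model$trans[cur, k]
      e <- model$emis[k, obs[i]]
      if (a > 0 && e > 0)
        rec(c(prefix, k), k, logp + log(a) + log(e), i + 1L)
    }
  }
  rec(integer(0), 1L, 0, 1L)
  if (length(logps) == 0L)
    return(list(n_paths = 0L, total = -Inf, best = -Inf,
                best_path = integer(0), unique_max = FALSE))
  mx <- max(logps)
  list(n_paths = length(logps),
       total = mx + log(sum(exp(logps - mx))),
       best = mx,
       best_path = paths[[which.max(logps)]],
       unique_max = sum(logps > mx - 1e-9) == 1L)
}

# joint log-probability of a (sequence, generating path) pair
path_joint_logp <- function(model, seq, path_states) {
  idx <- match(path_states, model$states)
  obs <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  m <- nrow(model$trans)
  sum(log(model$trans[cbind(c(1L, idx[-length(idx)]), idx)])) +
    sum(log(model$emis[cbind(idx, obs)])) +
    log(model$trans[idx[length(idx)], m])
}

# Random valid toy HMM: guaranteed begin -> chain -> end backbone plus random
# extra edges, Dirichlet-ish probabilities, strictly positive emissions.
random_toy_hmm <- function(n_emit, edge_prob = 0.25) {
  states <- c("begin", paste0("S", seq_len(n_emit)), "end")
  m <- n_emit + 2L
  allowed <- matrix(FALSE, m, m)
  allowed[1, 2] <- TRUE
  for (i in 2:(m - 1)) allowed[i, min(i + 1L, m)] <- TRUE
  for (i in 2:(m - 1)) for (j in 2:m)
    if (runif(1) < edge_prob) allowed[i, j] <- TRUE
  if (runif(1) < 0.3 && m > 3) allowed[1, sample(3:(m - 1), 1)] <- TRUE
  allowed[, 1] <- FALSE
  allowed[m, ] <- FALSE
  trans <- matrix(0, m, m, dimnames = list(states, states))
  for (i in 1:(m - 1)) {
    idx <- which(allowed[i, ])
    p <- rgamma(length(idx), 1)
    trans[i, idx] <- p / sum(p)
  }
  emis <- matrix(0, m, 4, dimnames = list(states, BASES))
  for (i in 2:(m - 1)) {
    p <- rgamma(4, 1)
    emis[i, ] <- p / sum(p)
  }
  hmm(trans, emis)
}

random_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

# Recursive backtracking matcher reproducing greedy-quantifier regex
# semantics for the 7-component G4 pattern; independent of PCRE.
oracle_match_at <- function(chars, i, run_min, run_max, loop_min, loop_max) {
  n <- length(chars)
  rec <- function(pos, comp) {
    if (comp > 7L) return(pos)
    if (comp %% 2L == 1L) {            # G-run component
      g <- 0L
      while (pos + g <= n && chars[pos + g] == "G" && g < run_max) g <- g + 1L
      if (g < run_min) return(NA_integer_)
      for (k in seq(g, run_min)) {     # greedy: longest first
        r <- rec(pos + k, comp + 1L)
        if (!is.na(r)) return(r)
      }
      return(NA_integer_)
    }
    avail <- 0L                        # loop component
    while (pos + avail <= n && chars[pos + avail] %in% BASES &&
           avail < loop_max) avail <- avail + 1L
    if (avail < loop_min) return(NA_integer_)
    for (k in seq(avail, loop_min)) {
      r <- rec(pos + k, comp + 1L)
      if (!is.na(r)) return(r)
    }
    NA_integer_
  }
  rec(i, 1L)
}

# Leftmost-first non-overlapping scan built on the backtracking matcher:
# the O(n^2) oracle for scan_g4(). Returns a matrix of 0-based [start, end).
oracle_scan <- function(seq, run_min = 3L, run_max = 5L,
                        loop_min = 1L, loop_max = 7L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  res <- NULL
  i <- 1L
  while (i <= n) {
    if (chars[i] != "G") {
      i <- i + 1L
      next
    }
    e <- oracle_match_at(chars, i, run_min, run_max, loop_min, loop_max)
    if (!is.na(e)) {
      res <- rbind(res, c(i - 1L, e - 1L))
      i <- e
    } else i <- i + 1L
  }
  if (is.null(res)) matrix(integer(0), 0, 2) else res
}

# Overlapping k-mer multiset as a sorted character vector (independent of
# count_kmers).
kmer_multiset <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  sort(vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L), ""))
}

# All distinct sequences sharing seq's overlapping trinucleotide multiset
# (exhaustive DFS over the order-2 transition multigraph).
enum_shuffles <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  verts <- paste0(chars[-n], chars[-1])
  from <- verts[-(n - 1L)]
  to <- verts[-1L]
  res <- character(0)
  rec <- function(cur, fr, tg, acc) {
    if (!length(fr)) {
      res[[length(res) + 1L]] <<- paste(acc, collapse = "")
      return(invisible())
    }
    idx <- which(fr == cur)
    for (j in unique(tg[idx])) {
      jj <- idx[tg[idx] == j][1L]
      rec(j, fr[-jj], tg[-jj], c(acc, substr(j, 2L, 2L)))
    }
  }
  rec(verts[1L], from, to, c(chars[1L], chars[2L]))
  unique(res)
}

# The frozen model-2 parameterization used for the parameter-recovery study:
# clamped G emissions, G-free loops, no empty loops, self-loop probabilities
# 0.8 -- every free transition is strongly identified at 200 sequences.
recovery_truth_model2 <- function() {
  truth <- build_model(2, clamp_g = TRUE)
  set_row <- function(m, row, targets, probs) {
    m$trans[row, ] <- 0
    m$trans[row, targets] <- probs
    m
  }
  for (k in 1:4) {
    last <- sprintf("run%d.G4", k)
    if (k < 4) {
      loop <- sprintf("loop%d.N1", k)
      nxt <- sprintf("run%d.G1", k + 1)
      truth <- set_row(truth, last, c(last, loop), c(0.80, 0.20))
      truth <- set_row(truth, loop, c(loop, nxt), c(0.80, 0.20))
    } else {
      truth <- set_row(truth, last, c(last, "end"), c(0.80, 0.20))
    }
  }
  for (s in truth$states)
    if (grepl("\\.N", s)) truth$emis[s, ] <- c(0.40, 0.25, 0.00, 0.35)
  validate_hmm(truth)
  truth
}
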