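test_that("single-emitting-state model has closed-form Viterbi and forward", {
  states <- c("begin", "S", "end")
  trans <- matrix(0, 3, 3, dimnames = list(states, states))
  trans["begin", "S"] <- 1
  trans["S", "S"] <- 0.6
  trans["S", "end"] <- 0.4
  emis <- matrix(0, 3, 4, dimnames = list(states, c("A", "C", "G", "T")))
  emis["S", ] <- c(0.1, 0.2, 0.3, 0.4)
  m <- hmm(trans, emis)

  seq <- "GGT"
  expected <- log(1) + 2 * log(0.6) + log(0.4) +
    log(0.3) + log(0.3) + log(0.4)
  v <- hmm_viterbi(m, seq)
  expect_false(v$no_path)
  expect_equal(v$states, c("S", "S", "S"))
  expect_equal(v$log_prob, expected, tolerance = 1e-12)
  # a single admissible path: forward and backward equal Viterbi exactly
  expect_equal(hmm_forward(m, seq), expected, tolerance = 1e-12)
  expect_equal(hmm_backward(m, seq), expected, tolerance = 1e-12)
})

test_that("forward, backward and Viterbi agree with brute-force enumeration", {
  set.seed(101)
  n_nopath <- 0L
  for (rep in 1:40) {
    m <- random_toy_hmm(sample(2:8, 1))
    seq <- random_dna(sample(1:8, 1))
    oracle <- enum_paths(m, seq)
    fw <- hmm_forward(m, seq)
    bw <- hmm_backward(m, seq)
    v <- hmm_viterbi(m, seq)
    if (oracle$n_paths == 0L) {
      n_nopath <- n_nopath + 1L
      expect_identical(fw, -Inf)
      expect_identical(bw, -Inf)
      expect_true(v$no_path)
      next
    }
    expect_equal(fw, oracle$total, tolerance = 1e-9)
    expect_equal(bw, oracle$total, tolerance = 1e-9)
    expect_equal(v$log_prob, oracle$best, tolerance = 1e-9)
    expect_gte(fw, v$log_prob - 1e-12)
    if (oracle$unique_max)
      expect_equal(v$state_idx, oracle$best_path)
    if (oracle$n_paths == 1L)
      expect_equal(fw, v$log_prob, tolerance = 1e-12)
  }
  # the draw should have exercised both admissible and no-path inputs
  expect_gt(n_nopath, 0L)
  expect_lt(n_nopath, 40L)
})

test_that("bases outside ACGT are an error, no-path is a flagged result", {
  m1 <- build_model(1)
  expect_error(hmm_viterbi(m1, "GGANGG"), "outside")
  expect_error(hmm_forward(m1, "GGAXGG"), "outside")
  expect_error(hmm_forward(m1, ""), "non-empty")
  # lowercase is accepted (uppercased on input)
  expect_equal(hmm_forward(m1, "ggaggaggagg"), hmm_forward(m1, "GGAGGAGGAGG"))

  # too few Gs to traverse four runs: flagged, not an error
  m2 <- build_model(2)
  v <- hmm_viterbi(m2, "GGGAGGGAGGGAGGG")  # all runs shorter than 4
  expect_true(v$no_path)
  expect_identical(v$log_prob, -Inf)
  expect_identical(hmm_forward(m2, "GGGAGGGAGGGAGGG"), -Inf)
})

test_that("total probability over all fixed-length emissions is at most 1", {
  set.seed(7)
  m <- random_toy_hmm(3)
  n <- 4
  all_seqs <- apply(expand.grid(rep(list(BASES), n)), 1, paste, collapse = "")
  p <- sum(exp(vapply(all_seqs, function(s) hmm_forward(m, s), numeric(1))))
  expect_lte(p, 1 + 1e-12)
  expect_gt(p, 0)
})

test_that("one EM iteration equals hand-computed expected-count re-estimation", {
  states <- c("begin", "S1", "S2", "end")
  trans <- matrix(0, 4, 4, dimnames = list(states, states))
  trans["begin", "S1"] <- 1
  trans["S1", c("S1", "S2")] <- c(0.5, 0.5)
  trans["S2", c("S2", "end")] <- c(0.4, 0.6)
  emis <- matrix(0, 4, 4, dimnames = list(states, c("A", "C", "G", "T")))
  emis["S1", ] <- c(0.7, 0.1, 0.1, 0.1)
  emis["S2", ] <- c(0.1, 0.1, 0.7, 0.1)
  m <- hmm(trans, emis)
  seq <- "AGG"
  pc <- 1e-3

  # expected counts by path enumeration: weight each path by its posterior
  oracle <- enum_paths(m, seq)
  obs <- match(strsplit(seq, "")[[1]], BASES)
  expA <- matrix(0, 4, 4)
  expE <- matrix(0, 4, 4)
  total <- exp(oracle$total)
  rec <- function(prefix, cur, p, i) {
    if (i > length(obs)) {
      a <- m$trans[cur, 4]
      if (a > 0) {
        w <- p * a / total
        full <- c(1L, prefix, 4L)
        for (j in seq_len(length(full) - 1L))
          expA[full[j], full[j + 1L]] <<- expA[full[j], full[j + 1L]] + w
        for (j in seq_along(prefix))
          expE[prefix[j], obs[j]] <<- expE[prefix[j], obs[j]] + w
      }
      return(invisible())
    }
    for (k in 2:3) {
      a <- m$trans[cur, k]
      e <- m$emis[k, obs[i]]
      if (a > 0 && e > 0) rec(c(prefix, k), k, p * a * e, i + 1L)
    }
  }
  rec(integer(0), 1L, 1, 1L)
  handA <- expA + pc * (m$trans > 0)
  handA <- handA / pmax(rowSums(handA), .Machine$double.xmin)
  handA[4, ] <- 0
  handE <- expE + pc * (m$emis > 0)
  handE[2:3, ] <- handE[2:3, ] / rowSums(handE[2:3, ])

  fit <- baum_welch(m, seq, max_iter = 1L, pseudocount = pc)
  expect_equal(unname(fit$trans), unname(handA), tolerance = 1e-9)
  expect_equal(unname(fit$emis[2:3, ]), unname(handE[2:3, ]), tolerance = 1e-9)
})

test_that("training on deterministically emitted data recovers empirical frequencies", {
  # chain with no transition choices: only emissions are free
  states <- c("begin", "P1", "P2", "end")
  trans <- matrix(0, 4, 4, dimnames = list(states, states))
  trans["begin", "P1"] <- 1
  trans["P1", "P2"] <- 1
  trans["P2", "end"] <- 1
  emis <- matrix(0, 4, 4, dimnames = list(states, c("A", "C", "G", "T")))
  emis["P1", ] <- 0.25
  emis["P2", ] <- 0.25
  m <- hmm(trans, emis)

  seqs <- c("AC", "AG", "AC", "TC", "AC", "AG")
  fit <- baum_welch(m, seqs)
  expect_equal(unname(fit$trans), unname(trans), tolerance = 1e-9)
  expect_equal(fit$emis["P1", "A"], 5 / 6, tolerance = 0.01)
  expect_equal(fit$emis["P1", "T"], 1 / 6, tolerance = 0.01)
  expect_equal(fit$emis["P2", "C"], 4 / 6, tolerance = 0.01)
  expect_equal(fit$emis["P2", "G"], 2 / 6, tolerance = 0.01)
})

test_that("Baum-Welch log-likelihood never decreases and zeros stay zero", {
  set.seed(21)
  for (rep in 1:5) {
    set <- make_g4_set(g4_spec(n = 12, seed = 300 + rep))
    m <- build_model(sample(c(1L, 3L), 1))
    fit <- suppressWarnings(baum_welch(m, set$seqs, max_iter = 30))
    trace <- attr(fit, "loglik_trace")
    expect_gte(min(diff(trace)), -1e-8)
    expect_true(all(fit$trans[m$trans == 0] == 0))
    expect_true(all(fit$emis[m$emis == 0] == 0))
  }
  expect_error(baum_welch(build_model(1), character(0)), "empty")
})

test_that("no-path training sequences are excluded with a warning, or fatal on request", {
  seqs <- c(good = "GGGGAGGGGAGGGGAGGGG", bad = "GGGAGGGAGGGAGGG")
  m2 <- build_model(2)
  expect_warning(fit <- baum_welch(m2, seqs, max_iter = 3), "bad")
  expect_identical(attr(fit, "excluded"), "bad")
  expect_error(baum_welch(m2, seqs, on_no_path = "error"), "bad")
})

test_that("sampling is reproducible, finite under the model, and matches emissions", {
  m <- build_model(2)
  set.seed(42)
  a <- hmm_simulate(m, 5)
  set.seed(42)
  b <- hmm_simulate(m, 5)
  expect_identical(a, b)
  for (x in a) {
    expect_true(is.finite(hmm_forward(m, x$seq)))
    expect_identical(nchar(x$seq), length(x$path))
  }

  # law of large numbers: pooled base frequencies of a single-state sampler
  # approach its emission distribution
  states <- c("begin", "S", "end")
  trans <- matrix(0, 3, 3, dimnames = list(states, states))
  trans["begin", "S"] <- 1
  trans["S", c("S", "end")] <- c(0.995, 0.005)
  emis <- matrix(0, 3, 4, dimnames = list(states, c("A", "C", "G", "T")))
  emis["S", ] <- c(0.4, 0.3, 0.2, 0.1)
  iid <- hmm(trans, emis)
  set.seed(8)
  draws <- hmm_simulate(iid, 500)
  pooled <- table(factor(unlist(strsplit(vapply(draws, `[[`, "", "seq"), "")),
                         levels = c("A", "C", "G", "T")))
  freq <- as.numeric(pooled) / sum(pooled)
  expect_equal(freq, c(0.4, 0.3, 0.2, 0.1), tolerance = 0.02)
})

test_that("model serialization round-trips exactly", {
  set.seed(5)
  set <- make_g4_set(g4_spec(n = 10, seed = 77))
  m <- suppressWarnings(baum_welch(build_model(3), set$seqs, max_iter = 5))
  for (a in c("loglik_trace", "n_iter", "converged", "excluded"))
    attr(m, a) <- NULL
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_identical(m2$states, m$states)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$model_id, m$model_id)
  expect_equal(m2$trans, m$trans, tolerance = 0)
  expect_equal(m2$emis, m$emis, tolerance = 0)
})

test_that("dynamic programs scale like O(m^2 n): doubling n at most ~doubles time", {
  m <- build_model(4)
  set.seed(3)
  mk <- function(n) paste(rep("GGGGA", n / 5), collapse = "")
  t1 <- median(vapply(1:5, function(i)
    system.time(hmm_forward(m, mk(2000)))[["elapsed"]], numeric(1)))
  t2 <- median(vapply(1:5, function(i)
    system.time(hmm_forward(m, mk(4000)))[["elapsed"]], numeric(1)))
  # generous bound: linear growth in n with ample timing slack
  expect_lt(t2, max(t1, 0.005) * 4.5)
})

test_that("invalid model structures are rejected", {
  states <- c("begin", "S", "end")
  trans <- matrix(0, 3, 3, dimnames = list(states, states))
  trans["begin", "S"] <- 1
  trans["S", c("S", "end")] <- c(0.7, 0.4)  # row sums to 1.1
  emis <- matrix(0, 3, 4, dimnames = list(states, c("A", "C", "G", "T")))
  emis["S", ] <- 0.25
  expect_error(hmm(trans, emis), "sum to 1")
  trans["S", c("S", "end")] <- c(0.6, 0.4)
  trans["end", "S"] <- 0.5  # end must not leave
  expect_error(hmm(trans, emis), "end state")
})
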