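test_that("the four topologies have the documented state counts and structure", {
  counts <- list(
    `1` = c(g = 8L, loop = 3L),
    `2` = c(g = 16L, loop = 3L),
    `3` = c(g = 8L, loop = 10L),
    `4` = c(g = 16L, loop = 10L))
  for (id in 1:4) {
    m <- build_model(id)
    g_states <- grep("\\.G", m$states)
    loop_states <- grep("\\.N", m$states)
    expect_identical(length(g_states), counts[[as.character(id)]][["g"]])
    expect_identical(length(loop_states), counts[[as.character(id)]][["loop"]])
    # silent begin/end bracket the emitting states
    expect_identical(m$states[1], "begin")
    expect_identical(m$states[length(m$states)], "end")
    expect_true(all(m$emis[c(1, nrow(m$emis)), ] == 0))
    # exactly 4 run blocks and 3 loop blocks, alternating
    expect_identical(sort(unique(m$labels[g_states])), paste0("run", 1:4))
    expect_identical(sort(unique(m$labels[loop_states])), paste0("loop", 1:3))
    validate_hmm(m)
  }
  expect_error(build_model(5), "unknown")
  expect_error(build_model(0), "unknown")
})

test_that("minimum emittable length is the graph shortest path: 8/16/8/16", {
  expect_identical(min_emittable_length(build_model(1)), 8L)
  expect_identical(min_emittable_length(build_model(2)), 16L)
  expect_identical(min_emittable_length(build_model(3)), 8L)
  expect_identical(min_emittable_length(build_model(4)), 16L)
  # the hybrid can never emit shorter than its G-run donor
  expect_gte(min_emittable_length(build_model(4)),
             min_emittable_length(build_model(2)))
  # sampled emissions respect the bound
  set.seed(30)
  for (id in 1:4) {
    m <- build_model(id)
    lens <- nchar(vapply(hmm_simulate(m, 25), `[[`, "", "seq"))
    expect_true(all(lens >= min_emittable_length(m)))
  }
})

test_that("rigid runs fix run length at the block size", {
  m <- build_model(1, rigid_runs = TRUE)
  set.seed(31)
  for (x in hmm_simulate(m, 20)) {
    lab <- m$labels[match(x$path, m$states)]
    expect_true(all(table(lab)[paste0("run", 1:4)] == 2L))
  }
  # sequences built from exact 2-G runs decode as before
  expect_false(hmm_viterbi(m, "GGAGGAGGAGG")$no_path)
})

test_that("Viterbi annotation of GGAGGAGGAGG under model 1 matches enumeration", {
  m <- build_model(1)
  seq <- "GGAGGAGGAGG"
  oracle <- enum_paths(m, seq)
  ann <- annotate_g4(m, seq)
  expect_false(ann$no_path)
  expect_equal(ann$log_prob, oracle$best, tolerance = 1e-9)
  expect_true(oracle$unique_max)
  expect_identical(ann$labels, m$labels[oracle$best_path])
  # runs sit on the G pairs (0-based intervals), loops on the As
  expect_identical(ann$regions$name,
                   c("run1", "loop1", "run2", "loop2", "run3", "loop3", "run4"))
  expect_equal(ann$regions$start, c(0, 2, 3, 5, 6, 8, 9),
               ignore_attr = TRUE)
  expect_equal(ann$regions$end, c(2, 3, 5, 6, 8, 9, 11),
               ignore_attr = TRUE)
})

test_that("model 2 decodes four 4-G runs with single-base loops", {
  m <- build_model(2)
  seq <- "GGGGAGGGGAGGGGAGGGG"
  oracle <- enum_paths(m, seq)
  ann <- annotate_g4(m, seq)
  expect_equal(ann$log_prob, oracle$best, tolerance = 1e-9)
  runs <- ann$regions[startsWith(ann$regions$name, "run"), ]
  loops <- ann$regions[startsWith(ann$regions$name, "loop"), ]
  expect_identical(nrow(runs), 4L)
  expect_true(all(runs$end - runs$start == 4))
  expect_true(all(loops$end - loops$start == 1))
  # run labels cover only G bases
  chars <- strsplit(seq, "")[[1]]
  expect_true(all(chars[which(in_run(ann))] == "G"))
})

test_that("annotations always contain exactly four ordered run regions when they exist", {
  set.seed(32)
  set <- make_g4_set(g4_spec(n = 15, loop_lengths = 1:7, seed = 33))
  m <- build_model(1)
  for (s in set$seqs) {
    ann <- annotate_g4(m, s)
    expect_false(ann$no_path)
    runs <- ann$regions$name[startsWith(ann$regions$name, "run")]
    expect_identical(runs, paste0("run", 1:4))
    # region order alternates run1 loop1 ... run4 (loops may be absent)
    expect_identical(ann$regions$name[1], "run1")
    expect_identical(ann$regions$name[nrow(ann$regions)], "run4")
    # model 1 run regions are at least 2 bases
    reg <- ann$regions
    expect_true(all((reg$end - reg$start)[startsWith(reg$name, "run")] >= 2))
  }
})

test_that("G4-form sequences are admissible iff runs reach the model's block size", {
  set.seed(34)
  ok <- make_g4_set(g4_spec(n = 10, run_lengths = 4:5, seed = 35))
  for (s in ok$seqs) {
    expect_true(is.finite(hmm_forward(build_model(2), s)))
    expect_true(is.finite(hmm_forward(build_model(4), s)))
  }
  # all four longest runs below 4: models 2 and 4 assign zero probability
  expect_identical(hmm_forward(build_model(4), "GGGAGGGAGGGAGGG"), -Inf)
  annot <- annotate_g4(build_model(2), "GGGAGGGAGGGAGGG")
  expect_true(annot$no_path)
  expect_identical(nrow(annot$regions), 0L)
})

test_that("annotation recovers the generating segmentation when the sampled path is the unique optimum", {
  m <- build_model(1)
  set.seed(36)
  checked <- 0L
  for (attempt in 1:400) {
    x <- hmm_simulate(m, 1)[[1]]
    if (nchar(x$seq) > 13L) next
    oracle <- enum_paths(m, x$seq)
    gen_lp <- path_joint_logp(m, x$seq, x$path)
    v <- hmm_viterbi(m, x$seq)
    expect_gte(v$log_prob, gen_lp - 1e-9)
    if (oracle$unique_max && abs(gen_lp - oracle$best) < 1e-9) {
      ann <- annotate_g4(m, x$seq)
      expect_identical(ann$labels, m$labels[match(x$path, m$states)])
      checked <- checked + 1L
    }
    if (checked >= 15L) break
  }
  expect_gte(checked, 10L)
})

test_that("clamped G states emit only G and survive training", {
  m <- build_model(2, clamp_g = TRUE)
  g_rows <- grep("\\.G", m$states)
  expect_true(all(m$emis[g_rows, "G"] == 1))
  set.seed(37)
  set <- make_g4_set(g4_spec(n = 10, run_lengths = 4:5, seed = 38))
  fit <- suppressWarnings(baum_welch(m, set$seqs, max_iter = 10))
  expect_true(all(fit$emis[g_rows, "G"] == 1))
  expect_true(all(fit$emis[g_rows, c("A", "C", "T")] == 0))
})

test_that("annotation output formats are consistent with the regions", {
  m <- build_model(1)
  ann <- annotate_g4(m, "GGAGGAGGAGG")
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, "toy", bed_path = bed, tsv_path = tsv)
  b <- read.delim(bed, header = FALSE)
  expect_identical(nrow(b), nrow(ann$regions))
  expect_identical(b$V4, ann$regions$name)
  p <- read.delim(tsv)
  expect_identical(nrow(p), nchar(ann$seq))
  expect_identical(p$label, ann$labels)
})
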