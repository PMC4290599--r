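#' Specification for synthetic G4-form sequences
#'
#' Describes a generator of sequences of the canonical G4 form
#' `G+N*G+N*G+N*G+`: four G-runs joined by three loops, with run and loop
#' lengths drawn from the given supports. Defaults emulate the broad class of
#' experimentally plausible G4 motifs: run lengths 2-5 and loop lengths 0-7
#' (uniform weights), loops depleted in G (weight 0.1) so that the generating
#' run/loop segmentation is unambiguous. `hard = TRUE` raises loop G content
#' to 0.25, deliberately stressing the run/loop boundary ambiguity that
#' arises when consecutive Gs stretch across a boundary.
#'
#' @param n Number of sequences.
#' @param run_lengths,run_weights Support and weights of the per-run length
#'   distribution (defaults 2:5, uniform).
#' @param loop_lengths,loop_weights Support and weights of the per-loop
#'   length distribution (defaults 0:7, uniform).
#' @param loop_base_probs Base composition of loops (named, A/C/G/T). The
#'   first and last base of each non-empty loop is drawn from the non-G part
#'   of this distribution so runs never bleed into loops.
#' @param flank Length of non-G4 flanking sequence on each side (default 0:
#'   training-style exact G4 forms have no flanks).
#' @param hard If `TRUE`, loop G weight is raised to 0.25.
#' @param seed Optional integer seed stored in the spec.
#' @return An object of class `g4_spec`.
#' @export
g4_spec <- function(n = 100L, run_lengths = 2:5, run_weights = NULL,
                    loop_lengths = 0:7, loop_weights = NULL,
                    loop_base_probs = c(A = 0.3, C = 0.3, G = 0.1, T = 0.3),
                    flank = 0L, hard = FALSE, seed = NULL) {
  if (any(run_lengths < 1L)) stop("run lengths must be >= 1")
  if (any(loop_lengths < 0L)) stop("loop lengths must be >= 0")
  if (hard) loop_base_probs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  loop_base_probs <- loop_base_probs[DNA_BASES] / sum(loop_base_probs)
  structure(list(n = as.integer(n),
                 run_lengths = run_lengths,
                 run_weights = run_weights %||% rep(1, length(run_lengths)),
                 loop_lengths = loop_lengths,
                 loop_weights = loop_weights %||% rep(1, length(loop_lengths)),
                 loop_base_probs = loop_base_probs,
                 flank = as.integer(flank), seed = seed),
            class = "g4_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one loop of given length, first/last base never G
sample_loop <- function(len, probs) {
  if (len == 0L) return(character(0))
  nong <- probs
  nong["G"] <- 0
  nong <- nong / sum(nong)
  if (len <= 2L) return(sample(DNA_BASES, len, replace = TRUE, prob = nong))
  c(sample(DNA_BASES, 1L, prob = nong),
    sample(DNA_BASES, len - 2L, replace = TRUE, prob = probs),
    sample(DNA_BASES, 1L, prob = nong))
}

#' Generate synthetic G4 sequences with exact structural truth
#'
#' Draws `spec$n` sequences of the form `G+N*G+N*G+N*G+` together with their
#' generating per-base run/loop segmentation, for use as ground truth in
#' prediction-metric and training tests. Reproducible under `spec$seed`.
#'
#' @param spec A [g4_spec()].
#' @return A list with `seqs` (named character vector, ids `g4_0001`...),
#'   `labels` (list of per-base character vectors, `run1`..`loop3`),
#'   `in_run` (list of logical vectors), and `meta` (data frame of drawn run
#'   and loop lengths).
#' @export
make_g4_set <- function(spec) {
  stopifnot(inherits(spec, "g4_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  seqs <- character(spec$n)
  labels <- vector("list", spec$n)
  meta <- matrix(0L, spec$n, 7,
                 dimnames = list(NULL, c("r1", "l1", "r2", "l2", "r3", "l3", "r4")))
  nong <- spec$loop_base_probs
  nong["G"] <- 0
  nong <- nong / sum(nong)
  for (i in seq_len(spec$n)) {
    runs <- spec$run_lengths[sample.int(length(spec$run_lengths), 4L,
                                        replace = TRUE, prob = spec$run_weights)]
    loops <- spec$loop_lengths[sample.int(length(spec$loop_lengths), 3L,
                                          replace = TRUE, prob = spec$loop_weights)]
    parts <- list()
    labs <- list()
    for (k in 1:4) {
      parts <- c(parts, list(rep("G", runs[k])))
      labs <- c(labs, list(rep(sprintf("run%d", k), runs[k])))
      if (k < 4L) {
        parts <- c(parts, list(sample_loop(loops[k], spec$loop_base_probs)))
        labs <- c(labs, list(rep(sprintf("loop%d", k), loops[k])))
      }
    }
    if (spec$flank > 0L) {
      # flank bases never G next to the motif so run lengths stay exact
      fl <- function() {
        f <- sample(DNA_BASES, spec$flank, replace = TRUE, prob = spec$loop_base_probs)
        f[spec$flank] <- sample(DNA_BASES, 1L, prob = nong)
        f
      }
      left <- fl()
      right <- rev(fl())
      parts <- c(list(left), parts, list(right))
      labs <- c(list(rep("flank", spec$flank)), labs,
                list(rep("flank", spec$flank)))
    }
    seqs[i] <- paste(unlist(parts), collapse = "")
    labels[[i]] <- unlist(labs)
    meta[i, ] <- c(runs[1], loops[1], runs[2], loops[2], runs[3], loops[3], runs[4])
  }
  names(seqs) <- sprintf("g4_%04d", seq_len(spec$n))
  list(seqs = seqs, labels = labels,
       in_run = lapply(labels, startsWith, prefix = "run"),
       meta = as.data.frame(meta))
}

#' Generate a synthetic genome with planted G4 motifs
#'
#' Builds a random background sequence guaranteed to contain no G4 match at
#' the given scan bounds (every background G-run is capped below `run_min`),
#' then plants `n_motifs` synthetic motifs at well-separated positions with
#' non-G bases flanking each insertion. Planted motifs use G-free loops by
#' default so each one yields exactly one scanner match at its exact
#' coordinates, giving a BED truth set with guaranteed recall.
#'
#' @param length Genome length in bases.
#' @param n_motifs Number of motifs to plant (0 allowed).
#' @param motif_spec A [g4_spec()] for the planted motifs; the default draws
#'   runs 3-5 and loops 1-7 with G-free loops, matching the default scan
#'   bounds.
#' @param gc GC content of the background (default 0.4).
#' @param run_min Scan run minimum the background must not reach.
#' @param seed Optional integer seed.
#' @return A list with `seq` (one DNA string), `truth` (BED-like data frame
#'   `start`, `end`, `motif`, 0-based half-open) and `motif_spec`.
#' @export
make_genome <- function(length = 100000L, n_motifs = 25L,
                        motif_spec = g4_spec(n = n_motifs,
                                             run_lengths = 3:5,
                                             loop_lengths = 1:7,
                                             loop_base_probs = c(A = 1, C = 1,
                                                                 G = 0, T = 1)),
                        gc = 0.4, run_min = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(DNA_BASES, length, replace = TRUE, prob = probs)
  # cap every G-run below run_min so the background cannot match
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  for (j in which(r$values & r$lengths >= run_min)) {
    run_start <- ends[j] - r$lengths[j] + 1L
    brk <- run_start + seq(run_min - 1L, r$lengths[j] - 1L, by = run_min)
    chars[brk] <- sample(c("A", "C", "T"), base::length(brk), replace = TRUE)
  }
  truth <- data.frame(start = integer(0), end = integer(0), motif = character(0))
  if (n_motifs > 0L) {
    motif_spec$n <- as.integer(n_motifs)
    motifs <- make_g4_set(motif_spec)$seqs
    widths <- nchar(motifs)
    slot <- length %/% n_motifs
    if (slot < max(widths) + 4L) stop("genome too short for the planted motifs")
    starts <- integer(n_motifs)
    for (i in seq_len(n_motifs)) {
      off <- sample.int(slot - widths[i] - 3L, 1L) + 1L  # leave flank room
      starts[i] <- (i - 1L) * slot + off
      idx <- starts[i]:(starts[i] + widths[i] - 1L)
      chars[idx] <- strsplit(motifs[[i]], "", fixed = TRUE)[[1]]
      chars[starts[i] - 1L] <- "T"            # non-G boundaries: no run fusion
      chars[starts[i] + widths[i]] <- "T"
    }
    truth <- data.frame(start = starts - 1L, end = starts - 1L + widths,
                        motif = unname(motifs))
  }
  list(seq = paste(chars, collapse = ""), truth = truth,
       motif_spec = motif_spec)
}

#' The 50-gene putative-G4 table
#'
#' The published table of 50 validated human pre-mRNA genes with their
#' putative non-overlapping G4 counts (from a regex-based pre-mRNA G4
#' database) and gene lengths in nucleotides, shipped as a plain-text
#' fixture. The counts sum to 12,930.
#'
#' @return A data frame with columns `gene`, `count`, `length` (50 rows).
#' @examples
#' tab <- table2_fixture()
#' sum(tab$count)  # 12930
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "grsdb2_gene_table.tsv", package = "g4hmm",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
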