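#' Regular-expression pattern for a putative G4 motif
#'
#' Builds the PCRE pattern `G{run}loop G{run}loop G{run}loop G{run}` for the
#' given run/loop length bounds. Quantifiers are greedy by default, so G-runs
#' absorb as many consecutive Gs as the bounds allow before loops take the
#' surplus (consecutive Gs can legitimately stretch over a run/loop border;
#' this fixes the ambiguity deterministically). `Inf` maxima give open-ended
#' quantifiers, e.g. the generic form `G+N*G+N*G+N*G+`.
#'
#' @param run_min,run_max G-run length bounds (defaults 3 and 5).
#' @param loop_min,loop_max Loop length bounds (defaults 1 and 7).
#' @param allow_n If `TRUE`, `N` bases may appear inside loops (never in
#'   runs); default `FALSE`.
#' @param greedy_runs If `FALSE`, run quantifiers are lazy so loops absorb
#'   surplus Gs instead.
#' @return A single regex string.
#' @export
g4_pattern <- function(run_min = 3L, run_max = 5L, loop_min = 1L, loop_max = 7L,
                       allow_n = FALSE, greedy_runs = TRUE) {
  if (run_min < 1L || loop_min < 0L) stop("run_min >= 1 and loop_min >= 0 required")
  if (run_max < run_min || loop_max < loop_min) stop("length bounds inverted")
  quant <- function(lo, hi) {
    if (is.infinite(hi)) sprintf("{%d,}", lo) else sprintf("{%d,%d}", lo, hi)
  }
  run <- paste0("G", quant(run_min, run_max), if (!greedy_runs) "?")
  cls <- if (allow_n) "[ACGTN]" else "[ACGT]"
  loop <- paste0(cls, quant(loop_min, loop_max))
  paste0(run, loop, run, loop, run, loop, run)
}

#' Scan sequences for non-overlapping putative G4 motifs
#'
#' Regular-expression prefilter: finds leftmost non-overlapping matches of
#' the G4 pattern (four G-runs joined by three loops) in each sequence.
#' Matching resumes immediately after each match end, so reported motifs are
#' pairwise non-overlapping. The default bounds (runs 3-5, loops 1-7) are the
#' convention of most pattern-matching G4 screens; `preset = "stegle"` gives
#' the fully generic form (runs >= 1, loops >= 0).
#'
#' Sequences are uppercased before matching (soft-masked lowercase is
#' treated as sequence). `N` never matches a G-run and is only allowed in
#' loops when `allow_n = TRUE`.
#'
#' With `strands = "both"` the reverse complement is also scanned (picking up
#' C-rich motifs on the forward strand); minus-strand matches are reported in
#' forward coordinates with `strand = "-"` and `match` giving the G-rich text
#' as read on the minus strand.
#'
#' @param seqs Named character vector of DNA sequences (a single unnamed
#'   string is given the id `"seq1"`).
#' @inheritParams g4_pattern
#' @param strands `"+"` (default) or `"both"`.
#' @param preset `NULL` or `"stegle"`.
#' @return A data frame of class `g4_motifs`: `seqid`, `start`, `end`
#'   (0-based half-open), `width`, `strand`, `match`.
#' @examples
#' scan_g4("GGGAGGGTGGGAGGG")  # one motif spanning [0, 15)
#' @export
scan_g4 <- function(seqs, run_min = 3L, run_max = 5L, loop_min = 1L,
                    loop_max = 7L, allow_n = FALSE, greedy_runs = TRUE,
                    strands = c("+", "both"), preset = NULL) {
  strands <- match.arg(strands)
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      strand = character(0), match = character(0))
  if (length(seqs) == 0L) {
    class(empty) <- c("g4_motifs", "data.frame")
    return(empty)
  }
  if (!is.null(preset)) {
    if (preset != "stegle") stop("unknown preset: ", preset)
    run_min <- 1L; run_max <- Inf; loop_min <- 0L; loop_max <- Inf
  }
  if (is.null(names(seqs)))
    names(seqs) <- if (length(seqs) == 1L) "seq1" else paste0("seq", seq_along(seqs))
  pat <- g4_pattern(run_min, run_max, loop_min, loop_max, allow_n, greedy_runs)

  scan_one <- function(seq, id, strand) {
    seq <- toupper(seq)
    hits <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (hits[1] == -1L)
      return(data.frame(seqid = character(0), start = integer(0),
                        end = integer(0), width = integer(0),
                        strand = character(0), match = character(0)))
    st <- as.integer(hits)
    w <- attr(hits, "match.length")
    txt <- substring(seq, st, st + w - 1L)
    if (strand == "-") {
      len <- nchar(seq)
      # scanned coordinates are on the reverse complement; map back
      fwd_start <- len - (st + w - 1L)
      data.frame(seqid = id, start = fwd_start, end = fwd_start + w,
                 width = w, strand = "-", match = txt)
    } else {
      data.frame(seqid = id, start = st - 1L, end = st - 1L + w,
                 width = w, strand = "+", match = txt)
    }
  }

  out <- lapply(names(seqs), function(id) {
    fwd <- scan_one(seqs[[id]], id, "+")
    if (strands == "both") {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(seqs[[id]]))))
      rbind(fwd, scan_one(rc, id, "-"))
    } else fwd
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("g4_motifs", "data.frame")
  out
}

#' Scan a FASTA file for putative G4 motifs
#'
#' Streaming wrapper over [scan_g4()]: reads a (multi-)FASTA file and returns
#' the motifs plus per-record and total counts.
#'
#' @param path Path to a FASTA file.
#' @param ... Passed to [scan_g4()].
#' @return A list with `motifs` (the [scan_g4()] data frame) and `counts`
#'   (data frame `seqid`, `n_motifs`, plus a `total` attribute).
#' @export
scan_fasta <- function(path, ...) {
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) {
    motifs <- scan_g4(character(0), ...)
    counts <- data.frame(seqid = character(0), n_motifs = integer(0))
  } else {
    motifs <- scan_g4(seqs, ...)
    counts <- data.frame(seqid = names(seqs),
                         n_motifs = as.integer(table(factor(motifs$seqid,
                                                            levels = names(seqs)))))
  }
  attr(counts, "total") <- nrow(motifs)
  list(motifs = motifs, counts = counts)
}
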