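#' Read a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of sequences; ids are the first
#'   whitespace-delimited token of each header. Duplicate ids are an error;
#'   an empty file returns an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA: no records in ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write motifs or regions as BED6
#'
#' Coordinates are 0-based half-open throughout the package, which is
#' exactly the BED convention: intervals are written as-is.
#'
#' @param x Data frame with columns `seqid`, `start`, `end`, and optionally
#'   `name`, `score`, `strand` (defaults: running index, 0, `+`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$seqid,
                    start = x$start,
                    end = x$end,
                    name = x$name %||% sprintf("G4_%d", seq_len(nrow(x))),
                    score = x$score %||% 0,
                    strand = x$strand %||% "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Two-stage G4 screen: regex prefilter, then HMM Z-score reduction
#'
#' Stage 1 scans the genome for non-overlapping putative G4 motifs with the
#' regular-expression prefilter; stage 2 scores every stage-1 motif with a
#' trained G4 HMM (log-odds against `bg`), standardizes the scores into
#' Z-scores over *all* stage-1 motifs genome-wide (one collection, not
#' per-chromosome), and partitions them by the lower-tailed and upper-tailed
#' 5% points of the standard normal. Motifs the topology cannot emit get
#' log-odds `-Inf`, are excluded from the Z mean/SD, and are always cut.
#'
#' @param genome Named character vector of sequences, or a path to a FASTA
#'   file.
#' @param model A trained `g4hmm`.
#' @param bg A `g4_background`.
#' @param run_min,run_max,loop_min,loop_max Scan bounds (defaults 3-5, 1-7).
#' @param alpha Tail probability per cutoff (default 0.05).
#' @param sd_type Standard deviation convention for [zscores()].
#' @return A list with `motifs` (scan table plus `L`, `Z`,
#'   `retained_lower`, `retained_upper`) and `summary` (data frame with rows
#'   `RE`, `RE+HMM lower`, `RE+HMM upper`: motif counts and percent
#'   reduction relative to stage 1).
#' @export
pipeline_re_then_hmm <- function(genome, model, bg, run_min = 3L, run_max = 5L,
                                 loop_min = 1L, loop_max = 7L, alpha = 0.05,
                                 sd_type = "sample") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome)))
    genome <- read_fasta(genome)
  motifs <- scan_g4(genome, run_min = run_min, run_max = run_max,
                    loop_min = loop_min, loop_max = loop_max)
  n_re <- nrow(motifs)
  if (n_re == 0L) {
    summary <- data.frame(stage = c("RE", "RE+HMM lower", "RE+HMM upper"),
                          n_motifs = c(0L, 0L, 0L),
                          pct_reduction = c(NA, NA, NA))
    return(list(motifs = motifs, summary = summary))
  }
  motifs$L <- vapply(motifs$match, function(s) log_odds(model, bg, s),
                     numeric(1), USE.NAMES = FALSE)
  motifs$Z <- suppressWarnings(zscores(motifs$L, sd_type = sd_type))
  lower <- screen_zscores(motifs$Z, mode = "lower", alpha = alpha)
  upper <- screen_zscores(motifs$Z, mode = "upper", alpha = alpha)
  motifs$retained_lower <- lower$retained
  motifs$retained_upper <- upper$retained
  summary <- data.frame(
    stage = c("RE", "RE+HMM lower", "RE+HMM upper"),
    n_motifs = c(n_re, sum(lower$retained), sum(upper$retained)),
    pct_reduction = c(NA,
                      100 * (1 - sum(lower$retained) / n_re),
                      100 * (1 - sum(upper$retained) / n_re)))
  list(motifs = motifs, summary = summary)
}
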