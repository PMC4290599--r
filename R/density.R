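#' G4 density of a gene
#'
#' `D(X) = G(X) / |X|`: the number of putative G4 sequences in gene X divided
#' by the gene length in nucleotides. Vectorized.
#'
#' @param count Putative-G4 count `G(X)` (>= 0).
#' @param length Gene length `|X|` in nucleotides (> 0).
#' @return Numeric density.
#' @examples
#' g4_density(69, 5371)  # HTF9C
#' @export
g4_density <- function(count, length) {
  if (any(length <= 0)) stop("gene length must be positive")
  if (any(count < 0)) stop("G4 count must be non-negative")
  count / length
}

#' Cross-gene Z-scores of G4 density
#'
#' Computes `D(X)` for every gene in the table and standardizes it across all
#' genes in the set: `Z(D) = (D - mean(D)) / s`. The default `s` is the
#' sample (n-1) standard deviation, the convention that reproduces the
#' published per-gene reference Z-scores to three decimals (the population
#' convention does not; see the methods vignette).
#'
#' @param records Data frame with columns `gene`, `count`, `length`.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return `records` with columns `density` and `z` added, ordered as given.
#' @export
density_zscores <- function(records, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!all(c("gene", "count", "length") %in% names(records)))
    stop("records must have columns gene, count, length")
  if (nrow(records) < 2L) stop("need at least 2 genes")
  d <- g4_density(records$count, records$length)
  s <- sd(d)
  if (sd_type == "population") s <- s * sqrt((nrow(records) - 1) / nrow(records))
  if (!is.finite(s) || s == 0)
    stop("zero variance across genes: densities are all equal, cannot standardize")
  records$density <- d
  records$z <- (d - mean(d)) / s
  records
}

#' Genes with significantly many G4 sequences
#'
#' Subset of genes whose density Z-score reaches `z_threshold`, ordered by
#' decreasing Z. The default threshold is the upper-tail 5% point of the
#' standard normal (`qnorm(0.95)`, +1.645), the symmetric analog of the
#' lower-tail screening cutoff.
#'
#' @param records Data frame from [density_zscores()] (must carry `z`).
#' @param z_threshold Minimum Z-score (default `qnorm(0.95)`).
#' @return The significant subset of `records`, ordered by `z` descending.
#' @export
significant_genes <- function(records, z_threshold = qnorm(0.95)) {
  if (is.null(records$z)) stop("records carry no z column; run density_zscores() first")
  out <- records[records$z >= z_threshold, , drop = FALSE]
  out[order(out$z, decreasing = TRUE), , drop = FALSE]
}
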