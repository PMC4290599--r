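#' Fit an i.i.d. background model from training sequences
#'
#' Estimates base frequencies `q_b` for `b` in `{A,C,G,T}` by pooled counting
#' over all training sequences, with a pseudocount of 1 per base so every
#' frequency is strictly positive.
#'
#' @param seqs Character vector of DNA sequences.
#' @param pseudocount Count added to each base (default 1).
#' @return A named numeric vector of class `g4_background` summing to 1.
#' @export
fit_background <- function(seqs, pseudocount = 1) {
  if (length(seqs) == 0L) stop("empty training set")
  counts <- table(factor(unlist(lapply(seqs, function(s)
    DNA_BASES[encode_dna(s)])), levels = DNA_BASES))
  q <- (as.numeric(counts) + pseudocount) / (sum(counts) + 4 * pseudocount)
  structure(setNames(q, DNA_BASES), class = "g4_background")
}

#' Log-odds score of a sequence against the background
#'
#' `L(x) = log P(x | theta) - sum_i log q_{x_i}`: the forward log-likelihood
#' under the HMM minus the log-probability of the same bases under the i.i.d.
#' background (a likelihood ratio, so the strong length dependence of the raw
#' log-likelihood largely cancels).
#'
#' @param model A `g4hmm` object.
#' @param bg A `g4_background` from [fit_background()].
#' @param seq A DNA string.
#' @return The log-odds score; `-Inf` when the topology admits no path for
#'   `seq` (an explicit flag value, not an error).
#' @export
log_odds <- function(model, bg, seq) {
  fw <- hmm_forward(model, seq)
  if (!is.finite(fw)) return(-Inf)
  fw - sum(log(bg[encode_dna(seq)]))
}

#' Standardize scores to Z-scores over a collection
#'
#' `Z_x = (L(x) - Lbar) / s` where the mean and standard deviation are taken
#' over exactly the supplied collection (e.g. all validation sequences, or
#' all putative motifs of a dataset) -- never over training data. The default
#' standard deviation is the sample (n-1) convention, which reproduces the
#' published per-gene density Z-scores exactly (see the methods vignette);
#' the population (n) convention is available for comparison.
#'
#' Non-finite scores (`-Inf` from unscorable sequences) are excluded from the
#' mean and standard deviation and are returned as `-Inf` Z-scores with a
#' warning.
#'
#' @param scores Numeric vector of log-odds scores (length >= 2 finite).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Numeric vector of Z-scores, same length and names as `scores`.
#' @export
zscores <- function(scores, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  fin <- is.finite(scores)
  if (sum(fin) < 2L)
    stop("need at least 2 finite scores to standardize")
  if (!all(fin))
    warning(sprintf("%d non-finite score(s) excluded from mean/SD and kept as -Inf",
                    sum(!fin)))
  x <- scores[fin]
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0)
    stop("zero variance: the score collection is degenerate, cannot standardize")
  out <- (scores - mean(x)) / s
  out[!fin] <- -Inf
  out
}

#' Screen Z-scores by standard-normal quantile cutoffs
#'
#' Partitions a collection of Z-scores into *reduced* (cut) and *retained*
#' sequences. The default cutoffs are the exact lower/upper 5% points of the
#' standard normal, `qnorm(alpha)` and `qnorm(1 - alpha)` (displayed rounded,
#' -1.645 / +1.645). Modes:
#' \describe{
#'   \item{`lower`}{cut `Z < cutoff_low` (removes the unlikely left tail).}
#'   \item{`upper`}{retain only `Z > cutoff_high` (keeps the significantly
#'     high-scoring candidates; everything else is cut).}
#'   \item{`two-sided`}{cut both tails, retaining the central mass.}
#' }
#' `-Inf` Z-scores are always reduced.
#'
#' @param z Numeric vector of Z-scores (`-Inf` allowed).
#' @param mode One of `"lower"`, `"upper"`, `"two-sided"`.
#' @param alpha Tail probability per cutoff (default 0.05).
#' @param cutoff_low,cutoff_high Override the quantile cutoffs directly.
#' @return A list with logical vectors `retained` and `reduced`, the cutoffs,
#'   `n_reduced` and `reduction_pct` (percentage of the collection cut).
#' @export
screen_zscores <- function(z, mode = c("lower", "upper", "two-sided"),
                           alpha = 0.05,
                           cutoff_low = qnorm(alpha),
                           cutoff_high = qnorm(1 - alpha)) {
  mode <- match.arg(mode)
  if (any(is.na(z))) stop("Z-scores must not be NA")
  reduced <- switch(mode,
    "lower" = z < cutoff_low,
    "upper" = z <= cutoff_high,
    "two-sided" = z < cutoff_low | z > cutoff_high)
  list(retained = !reduced, reduced = reduced,
       cutoff_low = cutoff_low, cutoff_high = cutoff_high, mode = mode,
       n_reduced = sum(reduced),
       reduction_pct = 100 * mean(reduced))
}

#' Score a collection of sequences and screen it
#'
#' Convenience wrapper producing the standard report: per-sequence forward
#' log-likelihood, log-odds `L`, collection Z-score and screening verdict.
#'
#' @param model A trained `g4hmm`.
#' @param bg A `g4_background`.
#' @param seqs Named character vector of sequences (the Z-score collection).
#' @param mode Screening mode, see [screen_zscores()].
#' @param alpha Tail probability per cutoff.
#' @param sd_type Standard deviation convention for [zscores()].
#' @return A data frame with columns `id`, `logP`, `L`, `Z`, `verdict`
#'   (`"retained"`/`"reduced"`).
#' @export
score_collection <- function(model, bg, seqs, mode = "lower", alpha = 0.05,
                             sd_type = "sample") {
  ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
  logP <- vapply(seqs, function(s) hmm_forward(model, s), numeric(1),
                 USE.NAMES = FALSE)
  L <- vapply(seqs, function(s) log_odds(model, bg, s), numeric(1),
              USE.NAMES = FALSE)
  Z <- suppressWarnings(zscores(L, sd_type = sd_type))
  scr <- screen_zscores(Z, mode = mode, alpha = alpha)
  data.frame(id = ids, logP = logP, L = L, Z = Z,
             verdict = ifelse(scr$retained, "retained", "reduced"))
}
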