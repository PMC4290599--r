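#' Sensitivity, PPV and F-measure from per-base counts
#'
#' `SEN = TP/(TP+FN)`, `PPV = TP/(TP+FP)`, `F = 2*SEN*PPV/(SEN+PPV)`.
#' Undefined ratios (zero denominators) are reported as `NaN` together with
#' an `undefined` flag, never silently as 0.
#'
#' @param tp,fp,fn Per-base counts pooled over a dataset: `tp` correctly
#'   predicted Gs in G-runs, `fp` predicted run Gs that are not in true runs,
#'   `fn` true run Gs that were not predicted.
#' @return An object of class `grun_metrics`: list with `TP`, `FP`, `FN`,
#'   `SEN`, `PPV`, `F`, `undefined`.
#' @examples
#' metrics_from_counts(1196, 3, 0)  # SEN 1.000, PPV 0.998, F 0.999
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  sen <- if (tp + fn > 0) tp / (tp + fn) else NaN
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  f <- if (is.finite(sen) && is.finite(ppv) && sen + ppv > 0)
    2 * sen * ppv / (sen + ppv) else NaN
  structure(list(TP = tp, FP = fp, FN = fn, SEN = sen, PPV = ppv, F = f,
                 undefined = !is.finite(sen) || !is.finite(ppv) || !is.finite(f)),
            class = "grun_metrics")
}

#' @export
print.grun_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  SEN %.3f  PPV %.3f  F %.3f%s\n",
              x$TP, x$FP, x$FN, x$SEN, x$PPV, x$F,
              if (x$undefined) "  [undefined ratios flagged]" else ""))
  invisible(x)
}

#' Per-base G-run prediction metrics over a dataset
#'
#' Tallies, pooled over all sequences (micro-average), how well predicted
#' G-run labels recover the true ones. Only G bases are counted, following
#' the definition of TP/FP/FN as (mis)predicted *Gs*: a G is a TP when both
#' truth and prediction place it in a G-run, an FP when only the prediction
#' does, an FN when only the truth does.
#'
#' @param seqs Character vector of sequences.
#' @param truth,pred Lists of logical per-base in-G-run vectors, aligned with
#'   `seqs` (see [in_run()] to derive one from an annotation). A prediction
#'   for an unannotatable sequence should be all-`FALSE`.
#' @return A `grun_metrics` object.
#' @export
grun_metrics <- function(seqs, truth, pred) {
  if (length(seqs) != length(truth) || length(seqs) != length(pred))
    stop("seqs, truth and pred must have equal length")
  tp <- fp <- fn <- 0L
  for (i in seq_along(seqs)) {
    g <- strsplit(toupper(seqs[[i]]), "", fixed = TRUE)[[1]] == "G"
    tr <- truth[[i]]
    pr <- pred[[i]]
    if (length(tr) != length(g) || length(pr) != length(g))
      stop(sprintf("label length mismatch for sequence %d", i))
    tp <- tp + sum(g & tr & pr)
    fp <- fp + sum(g & !tr & pr)
    fn <- fn + sum(g & tr & !pr)
  }
  metrics_from_counts(tp, fp, fn)
}

#' k-fold cross-validated G-run prediction
#'
#' Splits sequences into `k` folds (sequence-level, never splitting one
#' sequence), trains the chosen G4 topology by Baum-Welch on k-1 folds,
#' Viterbi-annotates the held-out fold, and pools the per-base counts.
#' Fold assignment is deterministic under `seed`.
#'
#' @param seqs Character vector of sequences.
#' @param truth List of logical per-base in-G-run vectors (ground truth).
#' @param model_id G4 topology to evaluate (1-4).
#' @param k Number of folds (default 10; `k = length(seqs)` gives
#'   leave-one-out).
#' @param seed Optional integer seed for the fold split.
#' @param ... Passed to [baum_welch()].
#' @return A list with `folds` (data frame of per-fold counts and metrics)
#'   and `pooled` (a `grun_metrics` over all folds).
#' @export
cross_validate <- function(seqs, truth, model_id = 1L, k = 10L, seed = NULL,
                           ...) {
  n <- length(seqs)
  if (n < k) stop("need at least k sequences")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  rows <- vector("list", k)
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    model <- build_model(model_id)
    trained <- suppressWarnings(baum_welch(model, seqs[train], ...))
    pred <- lapply(seqs[test], function(s) in_run(annotate_g4(trained, s)))
    mt <- grun_metrics(seqs[test], truth[test], pred)
    tot <- tot + c(tp = mt$TP, fp = mt$FP, fn = mt$FN)
    rows[[f]] <- data.frame(fold = f, TP = mt$TP, FP = mt$FP, FN = mt$FN,
                            SEN = mt$SEN, PPV = mt$PPV, F = mt$F)
  }
  list(folds = do.call(rbind, rows),
       pooled = metrics_from_counts(tot[["tp"]], tot[["fp"]], tot[["fn"]]))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped into a single step),
#' trapezoidal area. Higher scores must indicate the positive class; `-Inf`
#' scores are valid (they rank below everything and tie with each other).
#'
#' @param labels Logical (or 0/1) vector: `TRUE` for positives.
#' @param scores Numeric scores, same length.
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  if (any(is.na(labels)) || any(is.na(scores))) stop("NA in labels or scores")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))             # ties share a group
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  tpr <- cumsum(tp) / n_pos
  fpr <- cumsum(fp) / n_neg
  thr <- s[!duplicated(s)]
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}
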