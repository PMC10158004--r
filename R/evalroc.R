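#' Empirical ROC curve and AUC
#'
#' The curve runs over all distinct score thresholds (predict positive
#' when `score >= threshold`), a step function from (0,0) to (1,1).  The
#' AUC is the Mann-Whitney probability that a random positive outscores a
#' random negative, ties credited one half — identical to the trapezoidal
#' area under the empirical curve.
#'
#' @param scores numeric marker levels, one per sample.
#' @param labels class labels.
#' @param positive_class label treated as positive.
#' @param ci compute a seeded bootstrap percentile CI for the AUC.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `fpr` (1 - specificity), `auc`, `n_pos`, `n_neg`,
#'   `positive_class`, and optionally `auc_ci`.
#' @export
roc_curve_auc <- function(scores, labels, positive_class, ci = FALSE,
                          n_boot = 2000, seed = 0) {
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- auc_rank(scores, pos)
  out <- list(thresholds = thr,
              sensitivity = c(0, sens), fpr = c(0, fpr),
              auc = auc, n_pos = n_pos, n_neg = n_neg,
              positive_class = positive_class)
  if (ci) {
    boots <- with_seed(seed, replicate(n_boot, {
      i <- sample(seq_along(scores), replace = TRUE)
      if (length(unique(pos[i])) < 2) NA_real_ else auc_rank(scores[i], pos[i])
    }))
    out$auc_ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(out, class = "roc_curve")
}

# AUC via the rank/U formula with half credit for ties.
auc_rank <- function(scores, pos) {
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.3f (%d positive '%s', %d negative)\n",
              x$auc, x$n_pos, x$positive_class, x$n_neg))
  if (!is.null(x$auc_ci))
    cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f]\n", x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(c(x$fpr, 1), c(x$sensitivity, 1), type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' Scans every distinct threshold of the curve and returns the one
#' maximizing Youden's `J = sensitivity + specificity - 1`; ties are
#' broken toward higher specificity.
#'
#' @param curve a [roc_curve_auc()] object.
#' @param scores,labels the data the curve was built from (needed for the
#'   confusion counts at the chosen threshold).
#' @return A list with `threshold`, `J` and `metrics`
#'   (a [confusion_metrics()] object).
#' @export
youden_threshold <- function(curve, scores, labels) {
  stopifnot(inherits(curve, "roc_curve"))
  thr <- curve$thresholds
  sens <- curve$sensitivity[-1]          # drop the (0,0) anchor
  spec <- 1 - curve$fpr[-1]
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[order(-spec[best], -thr[best])][1]
  predicted <- ifelse(scores >= thr[best], curve$positive_class, "other")
  lab <- ifelse(labels == curve$positive_class, curve$positive_class, "other")
  m <- confusion_metrics(predicted, lab, positive = curve$positive_class)
  list(threshold = thr[best], J = unname(J[best]), metrics = m)
}

#' Confusion-matrix performance metrics
#'
#' Exact 2x2 counts and the derived panel: accuracy, precision,
#' sensitivity, specificity, F1 and Youden's J.  F1 is reported as 0 with
#' `f1_undefined = TRUE` when `TP + FP = 0` or `TP + FN = 0`.
#'
#' @param predicted,labels equal-length vectors of class labels.
#' @param positive label treated as positive.
#' @return A list of class `confusion_metrics`.
#' @export
confusion_metrics <- function(predicted, labels, positive = 1) {
  if (length(predicted) != length(labels))
    stop("`predicted` and `labels` must have equal length")
  pp <- predicted == positive; lp <- labels == positive
  TP <- sum(pp & lp); FP <- sum(pp & !lp)
  FN <- sum(!pp & lp); TN <- sum(!pp & !lp)
  accuracy <- (TP + TN) / length(labels)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  sensitivity <- if (TP + FN > 0) TP / (TP + FN) else 0
  specificity <- if (TN + FP > 0) TN / (TN + FP) else 0
  f1_undefined <- (TP + FP == 0) || (TP + FN == 0)
  f1 <- if (f1_undefined || precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = accuracy, precision = precision,
                 sensitivity = sensitivity, specificity = specificity,
                 F1 = f1, f1_undefined = f1_undefined,
                 J = sensitivity + specificity - 1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy=%.3f precision=%.3f sensitivity=%.3f specificity=%.3f F1=%.3f J=%.3f\n",
              x$accuracy, x$precision, x$sensitivity, x$specificity, x$F1, x$J))
  invisible(x)
}

#' Validate candidate biomarkers on an independent cohort
#'
#' Evaluates each candidate as a single-marker classifier on a held-out
#' marker-by-sample table: for each pairwise contrast, the ROC/AUC of the
#' marker level and the confusion panel at the Youden threshold.
#'
#' @param candidates a `biomarker_table` (or character vector of ids).
#' @param genes,metabolites held-out [omics_table()]s containing the
#'   marker levels.
#' @param contrasts list of `c(positive_group, negative_group)` pairs;
#'   default the three pairwise contrasts Cold/NC, Hot/NC, Cold/Hot.
#' @return A data.frame of class `validation_table` with one row per
#'   marker x contrast: `auc`, `p` (Mann-Whitney), `threshold` and the
#'   confusion panel.
#' @export
validate_biomarkers <- function(candidates, genes, metabolites,
                                contrasts = list(c("Cold", "NC"), c("Hot", "NC"),
                                                 c("Cold", "Hot"))) {
  ids <- if (is.data.frame(candidates)) candidates$entity_id else candidates
  rows <- list()
  for (id in ids) {
    tab <- if (id %in% feature_ids(genes)) genes
           else if (id %in% feature_ids(metabolites)) metabolites
           else next
    grp <- group_of(tab)
    for (ct in contrasts) {
      keep <- grp %in% ct
      scores <- tab$values[id, keep]
      labels <- grp[keep]
      # orient the marker so that higher scores indicate the positive class
      flip <- mean(scores[labels == ct[1]]) < mean(scores[labels == ct[2]])
      sc <- if (flip) -scores else scores
      curve <- roc_curve_auc(sc, labels, positive_class = ct[1])
      yt <- youden_threshold(curve, sc, labels)
      mw <- mann_whitney_test(scores[labels == ct[1]], scores[labels == ct[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        marker = id, contrast = paste(ct, collapse = "_vs_"),
        auc = curve$auc, p = mw$p, threshold = yt$threshold,
        accuracy = yt$metrics$accuracy, precision = yt$metrics$precision,
        sensitivity = yt$metrics$sensitivity, specificity = yt$metrics$specificity,
        F1 = yt$metrics$F1, J = yt$metrics$J,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  class(out) <- c("validation_table", "data.frame")
  out
}
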