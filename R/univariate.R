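#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test.  The statistic `U` counts pairs
#' `(x_i, y_j)` with `x_i > y_j`, ties credited one half.  The p-value is
#' the exact permutation probability when the pooled size is at most 12
#' and no ties are present, and the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return A list with `U`, `p` and `degenerate` (`TRUE` when the pooled
#'   values are all identical, in which case `p = 1`).
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1.0, degenerate = TRUE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(wt$p.value, 1), degenerate = FALSE)
}

#' Fold change on linear-scale group means
#'
#' `fc = (mean(x) + pseudocount) / (mean(y) + pseudocount)`, oriented
#' case (x) over control (y).
#'
#' @param x,y non-negative numeric vectors (linear-scale abundances).
#' @param pseudocount added to both means (default 0).
#' @return A list with `fc` and `log2fc`.
#' @export
log2_fold_change <- function(x, y, pseudocount = 0) {
  if (!length(x) || !length(y)) stop("groups must be non-empty")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  den <- mean(y) + pseudocount
  if (den == 0) stop("control mean plus pseudocount is zero")
  fc <- (mean(x) + pseudocount) / den
  list(fc = fc, log2fc = log2(fc))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`; `NaN` is an error.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues)) stop("p-values contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential features with the composite cutoff rule
#'
#' Per feature: Mann-Whitney p between the two contrast groups, BH
#' adjustment across features, fold change of linear-scale group means,
#' and the composite call `up` iff `q < q_max` and `fc > fc_up` (and
#' `vip > vip_min` when a VIP vector is supplied); `down` symmetrically
#' with `fc < fc_down`; otherwise `ns`.  When `vip` is absent the rule
#' degrades to fold change plus q only.
#'
#' @param table an [omics_table()].
#' @param contrast character pair `c(case_group, control_group)`,
#'   e.g. `c("Cold", "NC")`.
#' @param vip optional named numeric vector of VIP scores per feature.
#' @param cfg an [sf_config()].
#' @param log_base base on which `table$values` is logged (default 2);
#'   abundances are de-logged before computing fold change.  Use `NULL`
#'   for tables already on the linear scale.
#' @param pseudocount passed to [log2_fold_change()].
#' @return A data.frame of class `differential_table` with columns
#'   `feature_id`, `fc`, `log2fc`, `U`, `p`, `q`, `vip`, `status`.
#' @export
call_differential_features <- function(table, contrast, vip = NULL, cfg = sf_config(),
                                       log_base = 2, pseudocount = 0) {
  stopifnot(inherits(table, "omics_table"), length(contrast) == 2)
  grp <- table$sample_meta$group
  for (g in contrast) {
    if (sum(grp == g) < 2)
      stop("contrast group '", g, "' absent or has fewer than 2 samples")
  }
  vals <- table$values
  lin <- if (is.null(log_base)) vals else log_base^vals
  a <- grp == contrast[1]; b <- grp == contrast[2]
  p <- U <- fc <- l2fc <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    mw <- mann_whitney_test(vals[i, a], vals[i, b])
    U[i] <- mw$U; p[i] <- mw$p
    f <- log2_fold_change(lin[i, a], lin[i, b], pseudocount)
    fc[i] <- f$fc; l2fc[i] <- f$log2fc
  }
  q <- bh_adjust(p)
  vv <- rep(NA_real_, nrow(vals))
  if (!is.null(vip)) {
    if (is.null(names(vip))) stop("`vip` must be named by feature id")
    vv <- unname(vip[rownames(vals)])
  }
  vip_ok <- if (is.null(vip)) rep(TRUE, nrow(vals)) else !is.na(vv) & vv > cfg$vip_min
  status <- rep("ns", nrow(vals))
  status[q < cfg$q_max & fc > cfg$fc_up & vip_ok] <- "up"
  status[q < cfg$q_max & fc < cfg$fc_down & vip_ok] <- "down"
  message(sprintf("%s vs %s: %d up, %d down of %d features",
                  contrast[1], contrast[2], sum(status == "up"),
                  sum(status == "down"), nrow(vals)))
  out <- data.frame(feature_id = rownames(vals), fc = fc, log2fc = l2fc,
                    U = U, p = p, q = q, vip = vv, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

#' Ids of features called differential
#'
#' @param records a `differential_table`.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of feature ids with the requested status.
#' @export
differential_ids <- function(records, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") records$status != "ns" else records$status == direction
  records$feature_id[keep]
}

#' Welch's t-test utility
#'
#' Companion to the rank test for users who prefer a parametric screen;
#' not used by the headline differential calls.
#'
#' @param x,y numeric vectors.
#' @return A list with `t` and `p` (two-sided).
#' @export
welch_test <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
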