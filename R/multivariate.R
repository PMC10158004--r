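#' Principal component analysis of an omics table
#'
#' Samples are observations, features variables; columns are centered and
#' optionally unit-variance scaled before eigen-decomposition.
#'
#' @param table an [omics_table()] or a samples-by-features numeric matrix.
#' @param n_components number of components to return.
#' @param scale. unit-variance scale the features (default `FALSE`).
#' @return A list with `scores` (samples x components) and `explained`
#'   (fractions of total variance, non-increasing, summing to <= 1).
#' @export
pca_transform <- function(table, n_components = 2, scale. = FALSE) {
  X <- as_sample_matrix(table)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  if (n_components > min(n - 1, p))
    stop("n_components exceeds min(n - 1, p) = ", min(n - 1, p))
  if (scale.) {
    sds <- apply(X, 2, stats::sd)
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)])
}

as_sample_matrix <- function(table) {
  if (inherits(table, "omics_table")) t(table$values)
  else if (is.matrix(table)) table
  else stop("expected an omics_table or a samples-by-features matrix")
}

binary_y <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("exactly two classes are required")
  y <- as.numeric(as.character(labels) == lv[2])
  if (min(table(labels)) < 2) stop("each class needs at least 2 samples")
  attr(y, "levels") <- lv
  y
}

#' Fit a two-class PLS-DA model by NIPALS
#'
#' PLS1 regression of the centered class indicator on column-centered
#' (optionally autoscaled) X, with X-deflation per component.  An optional
#' single orthogonal-signal-correction step removes one y-orthogonal
#' component before fitting, approximating OPLS-DA.
#'
#' @param table an [omics_table()] or samples-by-features matrix.
#' @param labels two-class factor/character vector, one per sample.
#' @param A number of components; must not exceed `min(n - 1, p)`.
#' @param scale autoscale features to unit variance (default `FALSE`;
#'   recommended for metabolite tables).
#' @param orthogonal remove one orthogonal component first (default `FALSE`).
#' @return An object of class `plsda` holding weights `W` (p x A, unit
#'   columns), scores `T` (n x A, mutually orthogonal), x-loadings `P`,
#'   y-loadings `q`, centering/scaling vectors and the regression
#'   coefficients `B` on the original feature scale.
#' @export
fit_plsda <- function(table, labels, A = 2, scale = FALSE, orthogonal = FALSE) {
  X0 <- as_sample_matrix(table)
  y <- binary_y(labels)
  n <- nrow(X0); p <- ncol(X0)
  if (length(y) != n) stop("labels length must match sample count")
  if (A < 1 || A > min(n - 1, p))
    stop("A must lie in [1, min(n - 1, p) = ", min(n - 1, p), "]")
  x_center <- colMeans(X0)
  x_scale <- if (scale) apply(X0, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) x_scale[x_scale == 0] <- 1
  X <- sweep(sweep(X0, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  yc <- y - y_center

  if (orthogonal) {
    w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
    t1 <- drop(X %*% w)
    pl <- drop(crossprod(X, t1)) / sum(t1^2)
    w_o <- pl - drop(crossprod(w, pl)) * w
    if (sqrt(sum(w_o^2)) > 1e-12) {
      w_o <- w_o / sqrt(sum(w_o^2))
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
    }
  }

  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A); qv <- numeric(A)
  Xa <- X
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("degenerate X: weight vector has zero norm at component ", a,
           " (X carries no covariance with the class)")
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    P[, a] <- drop(crossprod(Xa, t_a)) / tt
    qv[a] <- sum(yc * t_a) / tt
    W[, a] <- w
    Tm[, a] <- t_a
    Xa <- Xa - tcrossprod(t_a, P[, a])
  }
  R <- W %*% solve(crossprod(P, W))   # weights w.r.t. original X
  B <- drop(R %*% qv)
  structure(list(A = A, W = W, T = Tm, P = P, q = qv, B = B,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, levels = attr(y, "levels"),
                 n = n, p = p, scaled = scale, orthogonal = orthogonal,
                 feature_ids = colnames(X0)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d component(s), %d sample(s), %d feature(s)%s\n",
              x$A, x$n, x$p,
              if (x$orthogonal) " (one orthogonal component removed)" else ""))
  cat("  classes: ", paste(x$levels, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object a `plsda` fit.
#' @param newdata samples-by-features matrix or [omics_table()]; defaults
#'   to refitting values are not stored, so `newdata` is required.
#' @param type `"response"` for the continuous class score in `[0,1]`-ish
#'   range, `"class"` for thresholded labels.
#' @param ... unused.
#' @return Numeric scores or a character vector of class labels.
#' @export
predict.plsda <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- as_sample_matrix(newdata)
  X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  yhat <- drop(X %*% object$B) + object$y_center
  if (type == "response") yhat
  else object$levels[(yhat >= 0.5) + 1L]
}

#' @export
coef.plsda <- function(object, ...) {
  stats::setNames(object$B, object$feature_ids)
}

#' Variable importance in the projection (VIP)
#'
#' Wold's formulation:
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` with
#' `SSY_a = q_a^2 * t_a' t_a` (weight vectors are unit norm).  The mean
#' squared VIP equals 1, i.e. `sum_j VIP_j^2 = p`.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$q^2 * colSums(model$T^2)
  if (sum(ssy) <= 0) stop("explained class variance is zero; VIP undefined")
  vip <- sqrt(model$p * drop(model$W^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$feature_ids)
}

#' Cross-validated selection of the number of PLS-DA components
#'
#' k-fold stratified cross-validation of `Q^2(A) = 1 - PRESS(A)/TSS`
#' over held-out samples.  `A*` is the smallest A whose `Q^2` is within
#' 0.01 of the maximum.
#'
#' @param table an [omics_table()] or samples-by-features matrix.
#' @param labels two-class labels.
#' @param A_max largest component count examined.
#' @param k number of folds (default 10); folds are stratified by class
#'   and deterministic under `seed`.
#' @param seed integer seed for fold assignment.
#' @param scale,orthogonal passed to [fit_plsda()].
#' @return A list with `A_star`, `Q2` (one value per A) and `folds`.
#' @export
cross_validate_components <- function(table, labels, A_max = 3, k = 10, seed = 0,
                                      scale = FALSE, orthogonal = FALSE) {
  X <- as_sample_matrix(table)
  y <- binary_y(labels)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  k <- min(k, min(table(labels)))   # keep folds stratifiable
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  A_max <- min(A_max, n - ceiling(n / k) - 1, ncol(X))
  A_max <- max(A_max, 1)
  press <- numeric(A_max); tss <- 0
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2) next
    fit <- fit_plsda(X[tr, , drop = FALSE], labels[tr], A = A_max,
                     scale = scale, orthogonal = orthogonal)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, fit$x_center), 2, fit$x_scale, "/")
    tss <- tss + sum((y[te] - fit$y_center)^2)
    # prediction truncated to the first A components
    for (A in seq_len(A_max)) {
      RA <- fit$W[, 1:A, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:A, drop = FALSE], fit$W[, 1:A, drop = FALSE]))
      yhat <- drop(Xte %*% RA %*% fit$q[1:A]) + fit$y_center
      press[A] <- press[A] + sum((y[te] - yhat)^2)
    }
  }
  Q2 <- 1 - press / tss
  if (all(Q2 <= 0)) {
    warning("all Q^2 <= 0: model uninformative; A* set to 1")
    A_star <- 1L
  } else {
    A_star <- min(which(Q2 >= max(Q2) - 0.01))
  }
  list(A_star = A_star, Q2 = Q2, folds = folds)
}
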