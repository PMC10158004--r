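#' Construct an omics abundance table
#'
#' An `omics_table` couples a feature-by-sample abundance matrix (log2
#' intensities or peak areas, unit-free) with per-sample metadata.  It is
#' the substrate of every statistical stage in the pipeline.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param sample_meta data.frame with columns `sample_id`, `group`
#'   (one of `"NC"`, `"Cold"`, `"Hot"`) and `tissue`.
#' @param feature_kind `"gene"` or `"metabolite"`.
#' @return An object of class `omics_table`: a list with elements
#'   `values`, `sample_meta`, `feature_kind`.
#' @export
omics_table <- function(values, sample_meta, feature_kind = c("gene", "metabolite")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as row names and sample ids as column names")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries; impute or remove them first")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "tissue")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  bad_group <- setdiff(unique(sample_meta$group), c("NC", "Cold", "Hot"))
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(
    list(values = values, sample_meta = sample_meta, feature_kind = feature_kind),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf(
    "omics_table: %d %s feature(s) x %d sample(s)\n",
    nrow(x$values), x$feature_kind, ncol(x$values)
  ))
  tab <- table(x$sample_meta$group)
  cat("  groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset the samples of an omics table
#'
#' @param x an `omics_table`.
#' @param samples character vector of sample ids (or logical mask).
#' @return An `omics_table` restricted to the given samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "omics_table"))
  if (is.logical(samples)) samples <- colnames(x$values)[samples]
  omics_table(x$values[, samples, drop = FALSE],
              x$sample_meta[x$sample_meta$sample_id %in% samples, , drop = FALSE],
              x$feature_kind)
}

group_of <- function(x) {
  stats::setNames(x$sample_meta$group, x$sample_meta$sample_id)
}

#' Half-minimum imputation of missing abundances
#'
#' Replaces `NA` cells by half of the per-feature minimum observed value,
#' the usual treatment for below-detection-limit gaps in MS peak tables.
#' Features that are entirely missing raise an error.
#'
#' @param values numeric matrix with possible `NA`s.
#' @return The matrix with `NA`s imputed.
#' @export
impute_half_min <- function(values) {
  stopifnot(is.matrix(values))
  for (i in seq_len(nrow(values))) {
    nas <- is.na(values[i, ])
    if (!any(nas)) next
    if (all(nas)) stop("feature ", rownames(values)[i], " has no observed values")
    values[i, nas] <- min(values[i, !nas]) / 2
  }
  values
}
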