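#' Read a feature-by-sample abundance table with its metadata
#'
#' The abundance file is delimited text with a header row of sample ids and
#' feature ids in the first column; the metadata file maps every sample id
#' to its `group` and `tissue`.
#'
#' @param path abundance table (TSV/CSV, extension decides the delimiter).
#' @param meta_path sample metadata table with columns
#'   `sample_id`, `group`, `tissue`.
#' @param feature_kind `"gene"` or `"metabolite"`.
#' @param impute if `TRUE`, `NA` cells are filled by [impute_half_min()];
#'   otherwise missing cells are a hard error.
#' @return An [omics_table()].
#' @export
read_feature_table <- function(path, meta_path, feature_kind = c("gene", "metabolite"),
                               impute = FALSE) {
  feature_kind <- match.arg(feature_kind)
  raw <- utils::read.table(path, header = TRUE, sep = delim_of(path),
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = list(ids, colnames(cells))))
  bad <- which(is.na(vals) & !(is.na(cells) | cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' (value '%s')",
                 ids[bad[1, 1]], colnames(cells)[bad[1, 2]], cells[bad[1, , drop = FALSE]]))
  if (anyNA(vals)) {
    if (impute) vals <- impute_half_min(vals)
    else {
      na1 <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing cell at feature '%s', sample '%s'; rerun with impute = TRUE",
                   ids[na1[1]], colnames(vals)[na1[2]]))
    }
  }
  meta <- utils::read.table(meta_path, header = TRUE, sep = delim_of(meta_path),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  omics_table(vals, meta, feature_kind)
}

#' Write an omics table (and its metadata) to TSV
#'
#' Exact inverse of [read_feature_table()] on valid data.
#'
#' @param x an `omics_table`.
#' @param path output abundance TSV.
#' @param meta_path output metadata TSV (skipped if `NULL`).
#' @export
write_feature_table <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "omics_table"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

delim_of <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a GMT gene-set collection
#'
#' Standard GMT: tab-separated lines `set_id<TAB>description<TAB>member...`.
#' Members are treated as a set (duplicates within a line collapse) but
#' their order is preserved.
#'
#' @param path GMT file.
#' @param kind `"symptom"` or `"pathway"`.
#' @return A `gene_set_collection`: named list of
#'   `list(description =, members =)` with attribute `kind`.
#' @export
read_gmt <- function(path, kind = c("symptom", "pathway")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 columns")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line ", i, " (set '", f[1], "') has no members")
    ids[i] <- f[1]
    sets[[i]] <- list(description = f[2], members = members)
  }
  if (anyDuplicated(ids))
    stop("duplicate set id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene_set_collection(stats::setNames(sets, ids), kind)
}

#' Construct a gene-set collection
#'
#' @param sets named list of `list(description =, members =)`.
#' @param kind `"symptom"` or `"pathway"`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, kind = c("symptom", "pathway")) {
  kind <- match.arg(kind)
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a non-empty uniquely named list")
  for (id in names(sets)) {
    m <- sets[[id]]$members
    if (!length(m) || !all(nzchar(m))) stop("set '", id, "' has empty member(s)")
    sets[[id]]$members <- unique(m)
  }
  structure(sets, kind = kind, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1))
  cat(sprintf("gene_set_collection (%s): %d set(s), sizes %d-%d\n",
              attr(x, "kind"), length(x), min(sizes), max(sizes)))
  invisible(x)
}

set_members <- function(collection, id) collection[[id]]$members

#' Write a gene-set collection to GMT
#'
#' @param x a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x), function(id) {
    paste(c(id, x[[id]]$description, x[[id]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction edge list
#'
#' Accepts two-column TSV (optionally with a numeric confidence column on
#' the STRING 0-1000 combined-score scale) or three-column SIF
#' (`node relation node`).  Self-loops are dropped; duplicate undirected
#' pairs collapse to one edge keeping the maximum confidence; edges under
#' `conf_min` are removed when a confidence column exists.
#'
#' @param path edge file.
#' @param conf_min minimum confidence retained (default 400,
#'   "medium confidence" on the STRING scale).
#' @return An `edge_table` data.frame with columns
#'   `node_a`, `node_b`, `confidence` (NA when absent in the input).
#' @export
read_edge_list <- function(path, conf_min = 400) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  first <- strsplit(lines[1], "[\t ]+")[[1]]
  if (length(first) >= 2L &&
      tolower(first[1]) %in% c("node_a", "source", "protein1", "from"))
    lines <- lines[-1]
  n <- length(lines)
  a <- b <- character(n); conf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2L) stop("malformed edge line ", i)
    if (length(f) == 2L) {
      a[i] <- f[1]; b[i] <- f[2]
    } else {
      cf <- suppressWarnings(as.numeric(f[3]))
      if (is.na(cf)) {           # SIF: node relation node
        a[i] <- f[1]; b[i] <- f[3]
      } else {
        a[i] <- f[1]; b[i] <- f[2]; conf[i] <- cf
      }
    }
  }
  edge_table(data.frame(node_a = a, node_b = b, confidence = conf,
                        stringsAsFactors = FALSE),
             conf_min = conf_min)
}

#' Construct a validated undirected edge table
#'
#' @param edges data.frame with columns `node_a`, `node_b` and optionally
#'   `confidence`; extra columns (e.g. `relation`) are kept.
#' @param conf_min drop edges with confidence below this (applied only
#'   where confidence is present).
#' @return An `edge_table` data.frame.
#' @export
edge_table <- function(edges, conf_min = 0) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("node_a", "node_b") %in% names(edges)))
  if (!"confidence" %in% names(edges))
    edges$confidence <- rep(NA_real_, nrow(edges))
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]        # self-loops
  if (conf_min > 0) {
    drop <- !is.na(edges$confidence) & edges$confidence < conf_min
    edges <- edges[!drop, , drop = FALSE]
  }
  key <- ifelse(edges$node_a < edges$node_b,
                paste(edges$node_a, edges$node_b, sep = "\r"),
                paste(edges$node_b, edges$node_a, sep = "\r"))
  # keep max confidence per undirected pair (NA sorts last)
  o <- order(key, -xtfrm(ifelse(is.na(edges$confidence), -Inf, edges$confidence)))
  edges <- edges[o, , drop = FALSE]
  edges <- edges[!duplicated(key[o]), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("edge_table", "data.frame")
  edges
}

#' Write an edge table to TSV
#' @param x an `edge_table`.
#' @param path output file.
#' @export
write_edge_list <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
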