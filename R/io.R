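#' Expression dataset container
#'
#' Holds a genes-by-samples matrix of log2-scale expression values together
#' with a per-sample class label. Gene and sample identifiers are the matrix
#' dimnames; both must be unique, and all values finite. Duplicate gene rows
#' are an input error: probe-to-gene collapsing is a preprocessing concern
#' and must happen before data enter the package.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param labels character vector of class labels, either named by sample ID
#'   or in column order of `values`.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix) and `labels` (named by sample ID).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
#' expression_dataset(m, c(s1 = "d", s2 = "d", s3 = "c", s4 = "c"))
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    .input_error("values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    .input_error("values must have gene rownames and sample colnames")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    .input_error(paste0("duplicate gene IDs: ", paste(dup, collapse = ", ")))
  if (anyDuplicated(sid))
    .input_error("duplicate sample IDs")
  if (!all(is.finite(values)))
    .input_error("expression values must all be finite")
  labels <- as.character(labels)
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values))
      .input_error("unnamed labels must match the number of samples")
    names(labels) <- sid
  }
  missing <- setdiff(sid, names(labels))
  if (length(missing))
    .input_error(paste0("samples missing from labels: ",
                        paste(missing, collapse = ", ")))
  labels <- labels[sid]
  structure(list(values = values, labels = labels),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset an ExpressionDataset
#'
#' `x[i, j]` keeps genes `i` and samples `j`; labels follow the samples.
#' @param x an `ExpressionDataset`.
#' @param i,j gene / sample indices (any form accepted by matrix indexing).
#' @export
`[.ExpressionDataset` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  expression_dataset(v, x$labels[colnames(v)])
}

#' Gene set collection restricted to a gene universe
#'
#' Stores named gene sets after intersection with the analysis universe
#' (the genes of the attached dataset). Sets that become empty after the
#' intersection are retained but flagged unusable. The size of the analysed
#' set is the size after intersection.
#'
#' @param sets named list of character vectors of gene IDs.
#' @param universe character vector: the dataset's gene IDs.
#' @return object of class `GeneSetCollection` with elements `sets`
#'   (intersected, duplicate-free), `universe`, `original_sizes`, and
#'   `usable` (logical per set).
#' @export
gene_set_collection <- function(sets, universe) {
  if (anyDuplicated(names(sets)) || is.null(names(sets)))
    .input_error("gene set names must be present and unique")
  universe <- as.character(universe)
  original <- vapply(sets, function(s) length(unique(s)), 0L)
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    s[s %in% universe]
  })
  structure(list(sets = sets, universe = universe,
                 original_sizes = original,
                 usable = lengths(sets) > 0L),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets over %d genes (%d usable)\n",
              length(x$sets), length(x$universe), sum(x$usable)))
  invisible(x)
}

#' Sizes of the analysed gene sets
#'
#' @param gsc a `GeneSetCollection`.
#' @return named integer vector of post-intersection set sizes.
#' @export
set_sizes <- function(gsc) lengths(gsc$sets)

#' Undirected gene-interaction edge list
#'
#' Canonicalises an edge table: undirected ((a,b) == (b,a)), self-edges
#' dropped, duplicates collapsed keeping the maximum score. Scores must lie
#' in (0, 1]; binary interactions carry score 1.
#'
#' @param gene_a,gene_b character vectors of endpoint gene IDs.
#' @param score numeric vector of confidence scores in (0, 1].
#' @return object of class `EdgeList`: a data.frame with columns
#'   `gene_a`, `gene_b`, `score`, with `gene_a < gene_b` per row.
#' @export
edge_list <- function(gene_a, gene_b, score = rep(1, length(gene_a))) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  score <- as.numeric(score)
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(score))
  if (any(score <= 0))
    .input_error("edge scores must be positive")
  if (any(score > 1))
    .input_error("edge scores must lie in (0, 1] after rescaling")
  self <- gene_a == gene_b
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s); self-connection is added via a_ii = 1",
                    sum(self)))
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]; score <- score[!self]
  }
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  df <- data.frame(gene_a = a, gene_b = b, score = score,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    mx <- tapply(df$score, key, max)
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    df$score <- as.numeric(mx[paste(df$gene_a, df$gene_b, sep = "\r")])
    df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("EdgeList", "data.frame")
  df
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression table with its sample labels
#'
#' The expression file is delimited text (tab or comma, auto-detected) with
#' gene IDs in the first column and sample IDs in the header. The label file
#' is a 2-column table (sample_id, class); an optional header row is
#' recognised and skipped. Labels are attached by sample-ID join, not by
#' position.
#'
#' @param path expression table path.
#' @param label_path label table path.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, label_path) {
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  gid <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gid
  lab <- utils::read.table(label_path, header = FALSE, sep = .detect_sep(label_path),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(lab) < 2L) .input_error("label file must have 2 columns")
  if (tolower(lab[1L, 1L]) %in% c("sample_id", "sample"))
    lab <- lab[-1L, , drop = FALSE]
  labels <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing))
    .input_error(paste0("samples missing from labels: ",
                        paste(missing, collapse = ", ")))
  expression_dataset(m, labels[colnames(m)])
}

#' Write an ExpressionDataset to delimited text
#'
#' @param ds an `ExpressionDataset`.
#' @param path output expression TSV path (gene_id column first).
#' @param label_path output label TSV path (sample_id, class).
#' @export
write_expression <- function(ds, path, label_path) {
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ds$labels), class = unname(ds$labels)),
    label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member genes. Sets are restricted to the
#' supplied gene universe; sets empty after intersection are kept but
#' flagged unusable.
#'
#' @param path GMT file path.
#' @param universe gene IDs of the attached dataset.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .input_error(sprintf("malformed GMT line %d: fewer than 3 tab fields", i))
    nm <- f[[1L]]
    if (nm %in% names(sets))
      .input_error(sprintf("duplicate gene set name '%s' (line %d)", nm, i))
    sets[[nm]] <- f[-(1:2)]
  }
  gene_set_collection(sets, universe)
}

#' Write a GeneSetCollection as GMT
#'
#' Writes the analysed (universe-intersected) membership.
#' @param gsc a `GeneSetCollection`.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(gsc, path, description = "na") {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, description, gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(gsc)
}

#' Read a gene-interaction edge list
#'
#' Binary mode expects 2 delimited columns (gene_a, gene_b); scored mode
#' expects a third confidence column. Confidence values above 1 are assumed
#' to be on the STRING 0-1000 scale and are divided by 1000; values already
#' in (0, 1] pass through. Self-edges are dropped with a warning; the output
#' is symmetric and deduplicated (maximum score kept).
#'
#' @param path edge-list path (tab or comma delimited, no header).
#' @param mode `"binary"` or `"scored"`.
#' @return an [edge_list()].
#' @export
read_edge_list <- function(path, mode = c("binary", "scored")) {
  mode <- match.arg(mode)
  tab <- utils::read.table(path, header = FALSE, sep = .detect_sep(path),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (mode == "binary") {
    if (ncol(tab) < 2L) .input_error("binary edge list needs 2 columns")
    score <- rep(1, nrow(tab))
  } else {
    if (ncol(tab) < 3L) .input_error("scored edge list needs 3 columns")
    score <- as.numeric(tab[[3L]])
    if (any(is.na(score)) || any(score <= 0))
      .input_error("edge scores must be positive numbers")
    if (any(score > 1)) score <- score / 1000
    if (any(score > 1))
      .input_error("edge scores exceed 1000; unrecognised score scale")
  }
  edge_list(tab[[1L]], tab[[2L]], score)
}

#' Write an EdgeList to TSV
#' @param edges an `EdgeList`.
#' @param path output path.
#' @param scores write the score column (set `FALSE` for binary export).
#' @export
write_edge_list <- function(edges, path, scores = TRUE) {
  df <- as.data.frame(edges)
  if (!scores) df <- df[, c("gene_a", "gene_b"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(edges)
}
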