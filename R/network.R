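#' Per-gene connectivity weights from an interaction network
#'
#' Builds the row sums of the symmetric gene-gene adjacency matrix with unit
#' self-loops: `w_i = 1 + sum of a_ij over the other analysed genes`, where
#' `a_ij` is 1 for a binary interaction or the confidence score in scored
#' mode. The self-loop `a_ii = 1` guarantees isolated genes get weight 1
#' rather than 0. Only edges with both endpoints inside the analysis
#' universe contribute; connectivity is meant to describe the genes under
#' consideration.
#'
#' An optional monotone transform can be applied afterwards, because raw hub
#' degrees enter the gene-set score squared and can dominate it:
#' `log2p1` uses `log2(1 + w)`, `rank` uses the (average-tie) rank of `w`.
#' The default `identity` keeps the literal row-sum definition.
#'
#' @param edges an [edge_list()].
#' @param universe character vector of analysed gene IDs (non-empty).
#' @param transform `"identity"` (default), `"log2p1"`, or `"rank"`.
#' @return object of class `ConnectivityWeights`: list with `gene_ids`,
#'   `weights` (named numeric), `raw_degree` (named numeric edge-score sums
#'   without the self-loop), and `transform`.
#' @export
#' @examples
#' e <- edge_list(c("A", "A"), c("B", "C"), c(0.9, 0.5))
#' build_weights(e, c("A", "B", "C", "D"))$weights
build_weights <- function(edges, universe,
                          transform = c("identity", "log2p1", "rank")) {
  transform <- match.arg(transform)
  universe <- as.character(universe)
  if (!length(universe)) .input_error("universe must be non-empty")
  if (anyDuplicated(universe)) .input_error("universe has duplicate gene IDs")
  deg <- stats::setNames(numeric(length(universe)), universe)
  keep <- edges$gene_a %in% universe & edges$gene_b %in% universe
  if (any(keep)) {
    a <- edges$gene_a[keep]; b <- edges$gene_b[keep]; s <- edges$score[keep]
    for (tab in list(tapply(s, a, sum), tapply(s, b, sum)))
      deg[names(tab)] <- deg[names(tab)] + as.numeric(tab)
  }
  w <- 1 + deg
  w <- switch(transform,
              identity = w,
              log2p1 = log2(1 + w),
              rank = rank(w, ties.method = "average"))
  structure(list(gene_ids = universe,
                 weights = stats::setNames(as.numeric(w), universe),
                 raw_degree = deg, transform = transform),
            class = "ConnectivityWeights")
}

#' @export
print.ConnectivityWeights <- function(x, ...) {
  cat(sprintf("ConnectivityWeights: %d genes, transform=%s, weight range [%g, %g]\n",
              length(x$gene_ids), x$transform,
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Export connectivity weights as TSV
#' @param w a `ConnectivityWeights`.
#' @param path output path; columns gene_id, raw_degree, weight.
#' @export
write_weights <- function(w, path) {
  utils::write.table(
    data.frame(gene_id = w$gene_ids,
               raw_degree = unname(w$raw_degree[w$gene_ids]),
               weight = unname(w$weights[w$gene_ids])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(w)
}

# weight lookup for a gene subset; NULL weights mean the unweighted analysis
.weights_for <- function(weights, genes) {
  if (is.null(weights)) return(stats::setNames(rep(1, length(genes)), genes))
  missing <- setdiff(genes, names(weights$weights))
  if (length(missing))
    .input_error(paste0("genes absent from connectivity weights: ",
                        paste(utils::head(missing, 5L), collapse = ", ")))
  weights$weights[genes]
}

#' Correlation between gene-set membership and connectivity
#'
#' Diagnostic for whether network connectivity carries information beyond
#' simple pathway membership: the Spearman rank correlation between the
#' number of gene sets each gene belongs to and its connectivity weight
#' (with binary identity weights, 1 + the number of connected genes).
#' A modest positive value indicates the two are related but far from
#' redundant, motivating the weighted analysis.
#'
#' @param gsc a `GeneSetCollection`.
#' @param w a `ConnectivityWeights` over the same gene universe.
#' @return the Spearman correlation, or `NA` (with a warning) when either
#'   vector is constant and the correlation is undefined.
#' @export
membership_connectivity_correlation <- function(gsc, w) {
  genes <- gsc$universe
  if (!setequal(genes, w$gene_ids))
    .input_error("gene set collection and weights must share a gene universe")
  counts <- stats::setNames(numeric(length(genes)), genes)
  for (s in gsc$sets) counts[s] <- counts[s] + 1
  ww <- w$weights[genes]
  if (stats::sd(counts) == 0 || stats::sd(ww) == 0) {
    warning("constant membership counts or weights: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(counts, ww, method = "spearman")
}
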