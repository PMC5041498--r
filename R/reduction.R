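#' Reduce a significant gene set to its core subset
#'
#' Within a gene set the genes are ranked by decreasing magnitude of the
#' (weighted) SAM statistic, ties broken lexicographically by gene ID. The
#' set is then gradually partitioned into the reduced subset `R_k` (first k
#' ranked genes) and the residual subset holding the rest. At each step the
#' residual subset's permutation p-value is computed; the iteration stops
#' the first time that p-value exceeds the threshold `c_k`, and the core is
#' `R_k` at that point. Intuition: genes are admitted to the core, most
#' significant first, until what remains no longer carries detectable
#' signal. If the residual stays significant through the last step the core
#' is the entire set; a singleton set is its own core without any residual
#' test (the residual would be empty).
#'
#' Fresh permutations are drawn at every step from a seed derived
#' deterministically from `(seed, set_name, k)`, so the trace is exactly
#' reproducible and the per-step p-value sequence does not depend on `c_k`
#' (which makes the core size monotone in `c_k`).
#'
#' @param ds an `ExpressionDataset`.
#' @param members gene IDs of the set (must all be in `stats`).
#' @param stats the `SamStatistics` of the observed labelling, carrying the
#'   weighting, `s0`, and the class labels used throughout the reduction.
#' @param c_k stopping threshold in `[0, 1]`; larger values admit more genes.
#' @param B permutations per residual test.
#' @param seed master seed for the per-step permutation streams.
#' @param set_name name used in the trace and in seed derivation.
#' @return object of class `ReductionTrace`: list with `set_name`,
#'   `ranked_genes`, `residual_pvalues` (one per executed step),
#'   `stop_k`, `core` (the first `stop_k` ranked genes), and `c_k`.
#' @export
reduce_gene_set <- function(ds, members, stats, c_k = 0.05, B = 1000L,
                            seed = 1L, set_name = "geneset") {
  if (c_k < 0 || c_k > 1) .input_error("c_k must be in [0, 1]")
  unknown <- setdiff(members, stats$gene_ids)
  if (length(unknown))
    .input_error(paste0("genes not in statistics: ",
                        paste(utils::head(unknown, 5L), collapse = ", ")))
  de <- stats$d_effective[members]
  ranked <- members[order(-abs(de), members, method = "radix")]
  m <- length(ranked)
  if (m == 1L) {
    return(structure(list(set_name = set_name, ranked_genes = ranked,
                          residual_pvalues = numeric(0), stop_k = 1L,
                          core = ranked, c_k = c_k),
                     class = "ReductionTrace"))
  }
  weights <- if (stats$weighted)
    structure(list(gene_ids = names(stats$w),
                   weights = stats$w, raw_degree = stats$w - 1,
                   transform = "identity"),
              class = "ConnectivityWeights")
  pvals <- numeric(0)
  stop_k <- m
  for (k in seq_len(m - 1L)) {
    residual <- ranked[(k + 1L):m]
    pk <- permutation_pvalue(ds, stats$case_label, stats$control_label,
                             members = residual, weights = weights, B = B,
                             seed = derive_seed(seed, set_name, k),
                             s0 = stats$s0)$p_value
    pvals <- c(pvals, pk)
    if (pk > c_k) { stop_k <- k; break }
  }
  structure(list(set_name = set_name, ranked_genes = ranked,
                 residual_pvalues = pvals, stop_k = as.integer(stop_k),
                 core = ranked[seq_len(stop_k)], c_k = c_k),
            class = "ReductionTrace")
}

#' @export
print.ReductionTrace <- function(x, ...) {
  cat(sprintf("ReductionTrace '%s': %d/%d genes in core (c_k=%g)\n",
              x$set_name, x$stop_k, length(x$ranked_genes), x$c_k))
  invisible(x)
}

#' Export a reduction trace as TSV
#' @param trace a `ReductionTrace`.
#' @param stats the `SamStatistics` the trace was built from.
#' @param path output path; columns rank, gene, d, d_effective, residual_p.
#' @export
write_trace <- function(trace, stats, path) {
  m <- length(trace$ranked_genes)
  rp <- rep(NA_real_, m)
  rp[seq_along(trace$residual_pvalues)] <- trace$residual_pvalues
  utils::write.table(
    data.frame(rank = seq_len(m), gene = trace$ranked_genes,
               d = unname(stats$d[trace$ranked_genes]),
               d_effective = unname(stats$d_effective[trace$ranked_genes]),
               residual_p = rp),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(trace)
}

#' Stage-1 gene-set screening by permutation test
#'
#' Computes the (weighted) permutation p-value for every usable gene set in
#' the collection and returns the sets significant at level `alpha`,
#' together with the full p-value table. Each set gets its own permutation
#' stream derived from `(seed, "stage1", set name)`; `s0` is estimated once
#' from the observed labelling over the whole gene universe and shared.
#'
#' @inheritParams permutation_pvalue
#' @param gsc a `GeneSetCollection` over the dataset's genes.
#' @param alpha significance level on the raw permutation p-value.
#' @return list with `selected` (character vector of significant set names)
#'   and `table` (data.frame: set, size, p_value, selected).
#' @export
select_significant_sets <- function(ds, gsc, weights = NULL, alpha = 0.05,
                                    B = 1000L, seed = 1L,
                                    case_label = NULL, control_label = NULL,
                                    s0 = "auto") {
  if (alpha <= 0 || alpha > 1) .input_error("alpha must be in (0, 1]")
  cls <- .infer_classes(ds$labels, case_label, control_label)
  if (identical(s0, "auto")) {
    case_idx <- which(ds$labels == cls[["case"]])
    s0 <- estimate_s0(.pooled_sd(ds$values, case_idx))
  }
  nms <- names(gsc$sets)[gsc$usable]
  pv <- vapply(nms, function(nm) {
    permutation_pvalue(ds, cls[["case"]], cls[["control"]],
                       members = gsc$sets[[nm]], weights = weights, B = B,
                       seed = derive_seed(seed, "stage1", nm),
                       s0 = s0)$p_value
  }, 0)
  tab <- data.frame(set = nms, size = unname(lengths(gsc$sets)[nms]),
                    p_value = unname(pv), selected = unname(pv <= alpha),
                    stringsAsFactors = FALSE)
  list(selected = tab$set[tab$selected], table = tab, s0 = s0)
}
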