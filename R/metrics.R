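#' Prediction table: per-sample class confidences
#'
#' Container for a prediction run: sample IDs, optionally the true class,
#' and a samples-by-classes matrix of confidences with every row summing
#' to 1.
#'
#' @param sample_ids character vector.
#' @param truth optional true class per sample (required by the metrics that
#'   compare against truth).
#' @param probs numeric matrix, samples x classes, named columns, entries in
#'   `[0, 1]`, rows summing to 1 (within numerical tolerance).
#' @return object of class `PredictionTable`.
#' @export
prediction_table <- function(sample_ids, truth = NULL, probs) {
  sample_ids <- as.character(sample_ids)
  if (!is.matrix(probs) || is.null(colnames(probs)))
    .input_error("probs must be a matrix with class colnames")
  if (nrow(probs) != length(sample_ids))
    .input_error("probs rows must match sample_ids")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    .input_error("confidences must lie in [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    .input_error("confidence rows must sum to 1")
  if (!is.null(truth)) {
    truth <- as.character(truth)
    if (length(truth) != length(sample_ids))
      .input_error("truth must match sample_ids")
    unknown <- setdiff(truth, colnames(probs))
    if (length(unknown))
      .input_error(paste0("true classes absent from probability columns: ",
                          paste(unique(unknown), collapse = ", ")))
  }
  structure(list(sample_ids = sample_ids, truth = truth,
                 probs = probs),
            class = "PredictionTable")
}

#' @export
print.PredictionTable <- function(x, ...) {
  cat(sprintf("PredictionTable: %d samples, %d classes (%s)\n",
              length(x$sample_ids), ncol(x$probs),
              paste(colnames(x$probs), collapse = ", ")))
  invisible(x)
}

.require_truth <- function(pt) {
  if (is.null(pt$truth))
    .input_error("this metric needs the true classes in the prediction table")
}

#' Misclassification rate
#'
#' Two-class predictions are classified by the confidence cutoff: a sample
#' goes to the first (case) class when its confidence for that class is at
#' least `cutoff` (a confidence of exactly 0.5 therefore classifies to the
#' case class). With more than two classes the argmax rule is used, ties
#' resolved toward the earlier column. The error rate is the fraction of
#' misclassified samples, `(FP + FN) / n` in the two-class case.
#'
#' @param pt a [prediction_table()] with truth.
#' @param cutoff two-class confidence cutoff, default 0.5.
#' @return a number in `[0, 1]`.
#' @export
error_rate <- function(pt, cutoff = 0.5) {
  .require_truth(pt)
  K <- ncol(pt$probs)
  pred <- if (K == 2L) {
    ifelse(pt$probs[, 1L] >= cutoff, colnames(pt$probs)[1L],
           colnames(pt$probs)[2L])
  } else {
    colnames(pt$probs)[apply(pt$probs, 1L, which.max)]
  }
  mean(pred != pt$truth)
}

#' Generalized Brier score
#'
#' `GBS = (1/2n) * sum_i sum_k (Y_ik - p_ik)^2` where `Y_ik` indicates the
#' true class. 0 for perfect confident predictions; the factor `1/(2n)`
#' scales it into `[0, 1]`.
#'
#' @inheritParams error_rate
#' @return a number in `[0, 1]`; smaller is better.
#' @export
gbs <- function(pt) {
  .require_truth(pt)
  Y <- outer(pt$truth, colnames(pt$probs), `==`) * 1
  sum((Y - pt$probs)^2) / (2 * nrow(pt$probs))
}

#' Belief confusion metric
#'
#' `BCM = 1 - (1/K) * sum_k (1 - v_k / N_k)` where `v_k` is the total
#' confidence assigned to class k by its true members and `N_k` their
#' count: the average confidence that a sample belongs to its own class.
#' 1 for perfect confident predictions.
#'
#' @inheritParams error_rate
#' @return a number in `[0, 1]`; larger is better.
#' @export
bcm <- function(pt) {
  .require_truth(pt)
  classes <- colnames(pt$probs)
  terms <- vapply(classes, function(k) {
    members <- pt$truth == k
    if (!any(members))
      .input_error(sprintf("class '%s' has no true members; BCM undefined", k))
    1 - sum(pt$probs[members, k]) / sum(members)
  }, 0)
  1 - mean(terms)
}

# average precision for one class: rank all samples by confidence for that
# class (descending, ties broken by sample ID), then average the precision
# at each true member's rank
.average_precision <- function(conf, positive, ids) {
  ord <- order(-conf, ids, method = "radix")
  pos <- positive[ord]
  hits <- cumsum(pos)
  sum((hits / seq_along(pos))[pos]) / sum(pos)
}

#' Macro-averaged area under the precision-recall curve
#'
#' For every class the samples are ranked by their confidence for that
#' class (descending; ties broken deterministically by sample ID) and the
#' class AUPR is computed by step-wise average precision, i.e. the mean of
#' precision = TP/(TP+FP) at the rank of each true member. The reported
#' value is the unweighted mean over classes. It captures how well samples
#' known to belong to a class are ranked above the rest.
#'
#' @inheritParams error_rate
#' @return a number in `(0, 1]`; larger is better.
#' @export
aupr <- function(pt) {
  .require_truth(pt)
  classes <- colnames(pt$probs)
  mean(vapply(classes, function(k) {
    positive <- pt$truth == k
    if (!any(positive))
      .input_error(sprintf("class '%s' has no true members; AUPR undefined", k))
    .average_precision(pt$probs[, k], positive, pt$sample_ids)
  }, 0))
}

#' Selection-stability index: mean pairwise Jaccard
#'
#' Given the gene (or gene-set) lists produced by k runs of an algorithm —
#' typically the k folds of a cross-validation — the stability index is the
#' mean over all k(k-1)/2 pairs of the Jaccard similarity
#' `|intersection| / |union|`. Two conventions close edge cases the
#' definition leaves open: a pair of empty lists counts 1 (two runs that
#' agree on selecting nothing), a pair with exactly one empty list counts 0.
#'
#' @param lists a list of k >= 2 character vectors.
#' @return a number in `[0, 1]`; larger means more stable selection.
#' @export
#' @examples
#' rand_index(list(c("A", "B", "C"), c("B", "C", "D")))  # 0.5
rand_index <- function(lists) {
  k <- length(lists)
  if (k < 2L) .input_error("rand_index needs at least 2 lists")
  lists <- lapply(lists, unique)
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- lists[[i]]; b <- lists[[j]]
      total <- total + if (!length(a) && !length(b)) 1
      else if (!length(a) || !length(b)) 0
      else length(intersect(a, b)) / length(union(a, b))
    }
  }
  2 * total / (k * (k - 1))
}

#' All predictive metrics in one report
#'
#' @inheritParams error_rate
#' @param gene_lists,geneset_lists optional lists of per-run selections for
#'   the stability indices.
#' @return object of class `MetricsReport`: list with `error_rate`, `gbs`,
#'   `bcm`, `aupr`, and (when lists are given) `rand_gene`, `rand_geneset`.
#' @export
metrics_report <- function(pt, gene_lists = NULL, geneset_lists = NULL) {
  out <- list(error_rate = error_rate(pt), gbs = gbs(pt), bcm = bcm(pt),
              aupr = aupr(pt))
  if (!is.null(gene_lists)) out$rand_gene <- rand_index(gene_lists)
  if (!is.null(geneset_lists)) out$rand_geneset <- rand_index(geneset_lists)
  structure(out, class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: error %.3f, GBS %.3f, BCM %.3f, AUPR %.3f\n",
              x$error_rate, x$gbs, x$bcm, x$aupr))
  if (!is.null(x$rand_gene))
    cat(sprintf("  stability: Rand(gene) %.3f", x$rand_gene),
        if (!is.null(x$rand_geneset))
          sprintf(", Rand(set) %.3f", x$rand_geneset), "\n", sep = "")
  invisible(x)
}
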