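#' Exchangeability constant s0 for the SAM statistic
#'
#' The SAM statistic divides the group-mean difference by `s(i) + s0`, where
#' `s0` is a small positive constant that damps the statistic for genes with
#' near-zero variance. Here `s0` is the median of the positive per-gene
#' pooled standard deviations; if every entry is zero (a degenerate matrix)
#' a fixed small constant `1e-6` is returned. The full percentile search of
#' the original SAM procedure is deliberately not used: the median is the
#' standard simplification and keeps the permutation null directly
#' comparable across label shuffles, since `s0` is computed once from the
#' observed labelling and then held fixed.
#'
#' @param s numeric vector of per-gene pooled standard deviations.
#' @return a single positive number.
#' @export
#' @examples
#' estimate_s0(c(0.1, 0.4, 0.2, 0.9))  # 0.3
estimate_s0 <- function(s) {
  if (!length(s)) .input_error("empty standard deviation vector")
  if (any(s < 0)) .input_error("standard deviations must be nonnegative")
  pos <- s[s > 0]
  if (!length(pos)) return(1e-6)
  stats::median(pos)
}

# core two-group moments for a genes x samples matrix and a 0/1 case
# indicator matrix (n x B): returns the B-column matrix of SAM d statistics.
# Vectorised over permutations via two matrix products.
.sam_d_matrix <- function(X, case_ind, s0, w = NULL) {
  n <- ncol(X)
  nd <- sum(case_ind[, 1L])
  nc <- n - nd
  S1 <- X %*% case_ind            # per-gene case sums, genes x B
  Q1 <- (X * X) %*% case_ind
  tot <- rowSums(X); qtot <- rowSums(X * X)
  S0 <- tot - S1; Q0 <- qtot - Q1 # column-wise recycling over genes
  Md <- S1 / nd; Mc <- S0 / nc
  ss <- pmax((Q1 - nd * Md^2) + (Q0 - nc * Mc^2), 0)
  s <- sqrt((1 / nd + 1 / nc) * ss / (nd + nc - 2))
  d <- (Md - Mc) / (s + s0)
  if (!is.null(w)) d <- d * w     # recycled down columns (per gene)
  d
}

.case_indicator <- function(n, case_idx) {
  ci <- matrix(0, n, 1L)
  ci[case_idx, 1L] <- 1
  ci
}

# pooled sd for every gene under the observed labelling
.pooled_sd <- function(X, case_idx) {
  n <- ncol(X)
  ci <- .case_indicator(n, case_idx)
  nd <- length(case_idx); nc <- n - nd
  S1 <- X %*% ci; Q1 <- (X * X) %*% ci
  Md <- S1 / nd; Mc <- (rowSums(X) - S1) / nc
  ss <- pmax((Q1 - nd * Md^2) + ((rowSums(X * X) - Q1) - nc * Mc^2), 0)
  as.numeric(sqrt((1 / nd + 1 / nc) * ss / (nd + nc - 2)))
}

#' Per-gene SAM statistics, optionally connectivity-weighted
#'
#' Computes for every gene the moderated mean-difference statistic
#' `d_i = (mean_case(i) - mean_control(i)) / (s(i) + s0)`, where `s(i)` is
#' the two-group pooled standard deviation
#' `sqrt((1/n_d + 1/n_c) * (SS_case + SS_control) / (n_d + n_c - 2))`.
#' With connectivity weights the effective statistic becomes `w_i * d_i`,
#' which is what the weighted gene-set score and the weighted gene ranking
#' use; without weights `d_effective` equals `d` exactly.
#'
#' @param ds an `ExpressionDataset`.
#' @param case_label,control_label the two class labels (default: inferred
#'   as the lexicographically first / second distinct label).
#' @param s0 `"auto"` (median pooled sd over all genes of `ds`) or a fixed
#'   positive number.
#' @param weights optional `ConnectivityWeights` covering the dataset genes.
#' @return object of class `SamStatistics`: list with `gene_ids`, `d`, `s`,
#'   `s0`, `weighted`, `w`, `d_effective`, `case_label`, `control_label`.
#' @export
sam_statistics <- function(ds, case_label = NULL, control_label = NULL,
                           s0 = "auto", weights = NULL) {
  cls <- .infer_classes(ds$labels, case_label, control_label)
  case_idx <- which(ds$labels == cls[["case"]])
  ctrl_idx <- which(ds$labels == cls[["control"]])
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L)
    .degenerate_error("each class needs at least 2 samples for the pooled sd")
  X <- ds$values
  s <- .pooled_sd(X, case_idx)
  if (identical(s0, "auto")) s0 <- estimate_s0(s)
  if (!is.numeric(s0) || s0 <= 0) .input_error("s0 must be positive")
  keep <- c(case_idx, ctrl_idx)   # ignore samples of other classes, if any
  d <- as.numeric(.sam_d_matrix(X[, keep, drop = FALSE],
                                .case_indicator(length(keep),
                                                seq_along(case_idx)),
                                s0))
  w <- .weights_for(weights, rownames(X))
  structure(list(gene_ids = rownames(X),
                 d = stats::setNames(d, rownames(X)),
                 s = stats::setNames(s, rownames(X)),
                 s0 = s0,
                 weighted = !is.null(weights),
                 w = w,
                 d_effective = stats::setNames(as.numeric(w) * d, rownames(X)),
                 case_label = cls[["case"]], control_label = cls[["control"]]),
            class = "SamStatistics")
}

#' Gene-set score: sum of squared (weighted) SAM statistics
#'
#' `score(j) = sum over member genes of d_effective_i^2`, which is the plain
#' sum of squared SAM statistics for the unweighted analysis and
#' `sum (w_i d_i)^2` for the weighted one.
#'
#' @param stats a `SamStatistics`.
#' @param members non-empty character vector of member gene IDs.
#' @return a single nonnegative number.
#' @export
samgs_score <- function(stats, members) {
  if (!length(members)) .input_error("empty gene set")
  unknown <- setdiff(members, stats$gene_ids)
  if (length(unknown))
    .input_error(paste0("genes not in statistics: ",
                        paste(utils::head(unknown, 5L), collapse = ", ")))
  sum(stats$d_effective[members]^2)
}

#' Permutation p-value for a gene set score
#'
#' Tests a gene set by shuffling the phenotype labels: the observed
#' (weighted) sum-of-squares score is compared with its null distribution
#' over `B` uniformly drawn label permutations that preserve the class
#' sizes. The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so `p >= 1/(B+1)` always.
#' `s0` is computed once from the observed labelling over all genes of `ds`
#' and held fixed across permutations.
#'
#' With `exhaustive = TRUE` all distinct assignments of `n_d` case positions
#' are enumerated instead (only sensible for very small samples); `B` is
#' then the number of enumerated assignments.
#'
#' @inheritParams sam_statistics
#' @param members gene IDs of the tested set.
#' @param B number of permutations (ignored when `exhaustive`).
#' @param seed integer seed; required, the permutation stream is fully
#'   reproducible from it.
#' @param exhaustive enumerate all label assignments instead of sampling.
#' @return object of class `PermutationResult`: list with `observed_score`,
#'   `null_scores`, `p_value`, `B`, `seed`.
#' @export
permutation_pvalue <- function(ds, case_label = NULL, control_label = NULL,
                               members, weights = NULL, B = 1000L,
                               seed = 1L, s0 = "auto", exhaustive = FALSE) {
  cls <- .infer_classes(ds$labels, case_label, control_label)
  case_idx <- which(ds$labels == cls[["case"]])
  ctrl_idx <- which(ds$labels == cls[["control"]])
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L)
    .degenerate_error("each class needs at least 2 samples")
  if (!exhaustive && B < 1L) .input_error("B must be >= 1")
  # keep samples in their original dataset order so the analysis (and its
  # permutation stream) is canonical under exchange of the class roles
  keep <- sort(c(case_idx, ctrl_idx))
  X <- ds$values[, keep, drop = FALSE]
  if (identical(s0, "auto"))
    s0 <- estimate_s0(.pooled_sd(ds$values, case_idx))
  unknown <- setdiff(members, rownames(X))
  if (length(unknown))
    .input_error(paste0("genes not in dataset: ",
                        paste(utils::head(unknown, 5L), collapse = ", ")))
  w <- .weights_for(weights, members)
  Xm <- X[members, , drop = FALSE]
  n <- ncol(X); nd <- length(case_idx)
  # the sum-of-squares score is invariant to complementing the indicator
  # (d merely flips sign), so the permutation group is canonicalised to the
  # smaller class: exchanging case/control roles then yields the exact same
  # observed score, null draws, and p-value
  a <- min(nd, n - nd)
  small_label <- if (nd <= n - nd) cls[["case"]] else cls[["control"]]
  obs_pos <- which(ds$labels[keep] == small_label)
  obs <- sum(.sam_d_matrix(Xm, .case_indicator(n, obs_pos), s0, w)^2)
  if (exhaustive) {
    combos <- utils::combn(n, a)
    ind <- matrix(0, n, ncol(combos))
    ind[cbind(as.vector(combos),
              rep(seq_len(ncol(combos)), each = a))] <- 1
    B <- ncol(combos)
  } else {
    set.seed(seed)
    ind <- matrix(0, n, B)
    for (b in seq_len(B)) ind[sample.int(n, a), b] <- 1
  }
  null_scores <- colSums(.sam_d_matrix(Xm, ind, s0, w)^2)
  # a permutation that is mathematically tied with the observed score (for
  # instance the observed labelling or its complement) must count as an
  # exceedance even if floating point puts it an ulp below
  tol <- 1e-8 * (1 + abs(obs))
  p <- (1 + sum(null_scores >= obs - tol)) / (B + 1)
  structure(list(observed_score = obs, null_scores = as.numeric(null_scores),
                 p_value = p, B = as.integer(B), seed = as.integer(seed)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: observed=%.4g, B=%d, p=%.4g\n",
              x$observed_score, x$B, x$p_value))
  invisible(x)
}
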