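#' End-to-end (weighted) SAMGSR gene selection
#'
#' Runs the two stages on a 2-class dataset: (1) screen the gene-set
#' collection by permutation test at level `alpha`; (2) reduce every
#' significant set to its core subset with threshold `c_k`. The selected
#' genes are the deduplicated union of the cores. Passing connectivity
#' weights switches every SAM/score computation to its weighted counterpart
#' (the weighted algorithm); with `weights = NULL` the original algorithm
#' runs. The result is fully deterministic given `seed`.
#'
#' @inheritParams select_significant_sets
#' @param c_k reduction stopping threshold.
#' @return object of class `SelectionResult`: list with `selected_sets`
#'   (stage-1 table), `traces` (named list of `ReductionTrace`), `genes`
#'   (union of cores, in first-appearance order), `c_k`, `alpha`,
#'   `weighted`, `stats` (the observed `SamStatistics`), and `empty` flag.
#' @export
run_selection <- function(ds, gsc, weights = NULL, c_k = 0.05, alpha = 0.05,
                          B = 1000L, seed = 1L,
                          case_label = NULL, control_label = NULL) {
  cls <- .infer_classes(ds$labels, case_label, control_label)
  stats <- sam_statistics(ds, cls[["case"]], cls[["control"]],
                          s0 = "auto", weights = weights)
  stage1 <- select_significant_sets(ds, gsc, weights = weights,
                                    alpha = alpha, B = B, seed = seed,
                                    case_label = cls[["case"]],
                                    control_label = cls[["control"]],
                                    s0 = stats$s0)
  traces <- list()
  for (nm in stage1$selected) {
    traces[[nm]] <- reduce_gene_set(ds, gsc$sets[[nm]], stats, c_k = c_k,
                                    B = B, seed = seed, set_name = nm)
  }
  genes <- unique(unlist(lapply(traces, `[[`, "core"), use.names = FALSE))
  if (is.null(genes)) genes <- character(0)
  structure(list(selected_sets = stage1$table, traces = traces,
                 genes = genes, c_k = c_k, alpha = alpha,
                 weighted = !is.null(weights), stats = stats,
                 empty = length(genes) == 0L),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult (%s): %d significant set(s), %d core gene(s), c_k=%g\n",
              if (x$weighted) "weighted" else "unweighted",
              length(x$traces), length(x$genes), x$c_k))
  if (length(x$genes))
    cat("  genes:", paste(utils::head(x$genes, 10L), collapse = ", "),
        if (length(x$genes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Fit a calibrated two-class classifier on selected genes
#'
#' The selection stages only pick genes; the classifier is fitted
#' separately on the selected features. The default is a linear
#' support-vector machine with Platt sigmoid calibration of the decision
#' margin into class probabilities (`e1071::svm`, `probability = TRUE`);
#' `method = "logistic"` fits a plain logistic regression instead. Both
#' produce probabilities that sum to 1 over the two classes and are
#' monotone in the linear decision margin; fitting is deterministic given
#' `seed`.
#'
#' @param ds training `ExpressionDataset`.
#' @param genes non-empty character vector of feature genes.
#' @param case_label,control_label the two class labels.
#' @param method `"svm"` (default) or `"logistic"`.
#' @param seed integer seed (the SVM's internal calibration cross-validation
#'   consumes randomness).
#' @return object of class `samgsr_classifier` with elements `genes`,
#'   `method`, `model`, `case_label`, `control_label`, `coefficients`
#'   (linear decision weights) and `intercept`.
#' @export
fit_classifier <- function(ds, genes, case_label = NULL,
                           control_label = NULL,
                           method = c("svm", "logistic"), seed = 1L) {
  method <- match.arg(method)
  if (!length(genes))
    .degenerate_error("empty gene selection: no features to fit a classifier on")
  cls <- .infer_classes(ds$labels, case_label, control_label)
  keep <- ds$labels %in% cls
  x <- t(ds$values[genes, keep, drop = FALSE])
  y <- factor(ds$labels[keep], levels = c(cls[["case"]], cls[["control"]]))
  if (nlevels(droplevels(y)) < 2L)
    .degenerate_error("both classes must be present to fit a classifier")
  set.seed(seed)
  if (method == "svm") {
    model <- e1071::svm(x, y, kernel = "linear", probability = TRUE,
                        scale = FALSE)
    coefs <- drop(t(model$coefs) %*% model$SV)
    intercept <- -model$rho
  } else {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- as.integer(y == cls[["case"]])
    model <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    cf <- stats::coef(model)
    coefs <- cf[-1L]; intercept <- cf[1L]
  }
  structure(list(genes = genes, method = method, model = model,
                 case_label = cls[["case"]], control_label = cls[["control"]],
                 coefficients = coefs, intercept = intercept,
                 seed = as.integer(seed)),
            class = "samgsr_classifier")
}

#' Predict calibrated class probabilities
#'
#' @param object a `samgsr_classifier`.
#' @param newdata an `ExpressionDataset` (or genes-by-samples matrix)
#'   containing the classifier's genes.
#' @param ... unused.
#' @return a [prediction_table()] with the case class as first column; the
#'   truth column is filled from the dataset labels when available.
#' @export
predict.samgsr_classifier <- function(object, newdata, ...) {
  truth <- NULL
  if (inherits(newdata, "ExpressionDataset")) {
    truth <- newdata$labels
    newdata <- newdata$values
  }
  x <- t(newdata[object$genes, , drop = FALSE])
  if (object$method == "svm") {
    pr <- attr(stats::predict(object$model, x, probability = TRUE),
               "probabilities")
    p_case <- pr[, object$case_label]
  } else {
    eta <- drop(x %*% object$coefficients) + object$intercept
    p_case <- stats::plogis(eta)
  }
  p <- cbind(p_case, 1 - p_case)
  colnames(p) <- c(object$case_label, object$control_label)
  prediction_table(rownames(x), truth = truth[rownames(x)], probs = p)
}

# constant-probability predictions from training class frequencies; used
# when a CV fold ends with an empty selection
.majority_prediction <- function(train_labels, test_ds, case_label,
                                 control_label) {
  p_case <- mean(train_labels == case_label)
  n <- ncol(test_ds$values)
  p <- cbind(rep(p_case, n), rep(1 - p_case, n))
  colnames(p) <- c(case_label, control_label)
  prediction_table(colnames(test_ds$values), truth = test_ds$labels,
                   probs = p)
}

#' Cross-validated tuning of the reduction threshold c_k
#'
#' `c_k` controls the sparseness of the final model; its value is chosen by
#' k-fold cross-validation. The training samples are divided into
#' class-stratified folds; for every candidate `c_k` the full selection
#' pipeline plus classifier is fitted on k-1 folds and the misclassification
#' rate (0.5 cutoff) measured on the held-out fold. The chosen `c_k`
#' minimises the mean fold error; ties go to the smaller value (the sparser
#' model). A fold whose selection comes up empty predicts the training
#' majority class rather than aborting. Per-fold gene and set lists at the
#' chosen `c_k` are kept so selection stability can be scored with
#' [rand_index()].
#'
#' @inheritParams run_selection
#' @param grid candidate `c_k` values in `[0, 1]`.
#' @param folds number of folds (each class must have at least `folds`
#'   samples).
#' @param classifier `"svm"` or `"logistic"`, passed to [fit_classifier()].
#' @return object of class `CvResult`: list with `grid` (sorted),
#'   `fold_errors` (grid x folds matrix), `mean_error`, `best_ck`,
#'   `per_fold_gene_lists`, `per_fold_set_lists`, `rand_gene`,
#'   `rand_geneset`, `folds`.
#' @export
tune_ck <- function(ds, gsc, weights = NULL,
                    grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5),
                    folds = 10L, alpha = 0.05, B = 1000L, seed = 1L,
                    case_label = NULL, control_label = NULL,
                    classifier = c("svm", "logistic")) {
  classifier <- match.arg(classifier)
  if (!length(grid) || any(grid < 0 | grid > 1))
    .input_error("grid must be non-empty with values in [0, 1]")
  if (folds < 2L) .input_error("folds must be >= 2")
  grid <- sort(unique(grid))
  cls <- .infer_classes(ds$labels, case_label, control_label)
  n <- ncol(ds$values)
  fold_id <- integer(n)
  set.seed(derive_seed(seed, "folds"))
  for (lab in cls) {
    idx <- sample(which(ds$labels == lab))
    if (length(idx) < folds)
      .degenerate_error(sprintf(
        "class '%s' has %d samples, fewer than %d folds; use fewer folds",
        lab, length(idx), folds))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_errors <- matrix(NA_real_, length(grid), folds,
                        dimnames = list(format(grid), NULL))
  gene_lists <- rep(list(vector("list", folds)), length(grid))
  set_lists <- rep(list(vector("list", folds)), length(grid))
  for (f in seq_len(folds)) {
    tr <- ds[, fold_id != f]
    te <- ds[, fold_id == f]
    for (gi in seq_along(grid)) {
      sel <- run_selection(tr, gsc, weights = weights, c_k = grid[gi],
                           alpha = alpha, B = B,
                           seed = derive_seed(seed, "cv", f),
                           case_label = cls[["case"]],
                           control_label = cls[["control"]])
      gene_lists[[gi]][[f]] <- sel$genes
      set_lists[[gi]][[f]] <- sel$selected_sets$set[sel$selected_sets$selected]
      pt <- if (sel$empty) {
        .majority_prediction(tr$labels, te, cls[["case"]], cls[["control"]])
      } else {
        clf <- fit_classifier(tr, sel$genes, cls[["case"]], cls[["control"]],
                              method = classifier,
                              seed = derive_seed(seed, "clf", f, gi))
        predict(clf, te)
      }
      fold_errors[gi, f] <- error_rate(pt)
    }
  }
  mean_error <- rowMeans(fold_errors)
  best_i <- which.min(mean_error)  # grid sorted ascending: ties -> smaller c_k
  structure(list(grid = grid, fold_errors = fold_errors,
                 mean_error = unname(mean_error), best_ck = grid[best_i],
                 per_fold_gene_lists = gene_lists[[best_i]],
                 per_fold_set_lists = set_lists[[best_i]],
                 rand_gene = rand_index(gene_lists[[best_i]]),
                 rand_geneset = rand_index(set_lists[[best_i]]),
                 folds = as.integer(folds)),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult: best c_k = %g (mean CV error %.3f over %d folds)\n",
              x$best_ck, min(x$mean_error), x$folds))
  cat(sprintf("  gene-level Rand %.3f, set-level Rand %.3f\n",
              x$rand_gene, x$rand_geneset))
  invisible(x)
}

#' Compose binary task probabilities into multi-class probabilities
#'
#' When the K classes factor into independent binary tasks (for example
#' histology subtype x clinical stage), the composite class probability is
#' the product of the per-task probabilities:
#' `P(AC-I) = P(AC) * P(stage I)` and so on. Each task table must contain
#' every sample; if each task's probabilities sum to 1 over its two levels,
#' the composite probabilities sum to 1 over the crossed classes.
#'
#' @param task_probs named list of per-task probability matrices (samples in
#'   rows with rownames, task levels in columns) or [prediction_table()]s.
#' @param class_map named list: composite class name -> character vector
#'   giving one level per task, in `task_probs` order.
#' @param truth optional composite true class per sample.
#' @return a [prediction_table()] over the composite classes.
#' @export
#' @examples
#' subtype <- matrix(c(0.6, 0.4), 1, 2, dimnames = list("s1", c("AC", "SCC")))
#' stage <- matrix(c(0.7, 0.3), 1, 2, dimnames = list("s1", c("I", "II")))
#' compose_multiclass(list(sub = subtype, st = stage),
#'                    list("AC-I" = c("AC", "I"), "AC-II" = c("AC", "II"),
#'                         "SCC-I" = c("SCC", "I"), "SCC-II" = c("SCC", "II")))
compose_multiclass <- function(task_probs, class_map, truth = NULL) {
  mats <- lapply(task_probs, function(tp) {
    if (inherits(tp, "PredictionTable")) {
      m <- tp$probs; rownames(m) <- tp$sample_ids; m
    } else tp
  })
  ids <- rownames(mats[[1L]])
  for (m in mats) {
    if (is.null(rownames(m)))
      .input_error("task probability tables need sample rownames")
    missing <- setdiff(ids, rownames(m))
    if (length(missing) || nrow(m) != length(ids))
      .input_error(paste0("samples missing from a task table: ",
                          paste(utils::head(c(missing, setdiff(rownames(m), ids)), 5L),
                                collapse = ", ")))
  }
  out <- sapply(names(class_map), function(cc) {
    lv <- class_map[[cc]]
    p <- rep(1, length(ids))
    for (t in seq_along(mats)) p <- p * mats[[t]][ids, lv[t]]
    p
  })
  out <- matrix(out, nrow = length(ids),
                dimnames = list(ids, names(class_map)))
  prediction_table(ids, truth = truth, probs = out)
}
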