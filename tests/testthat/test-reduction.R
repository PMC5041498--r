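test_that("reduction boundaries: c_k = 0 keeps one gene, c_k = 1 keeps all, singletons pass through", {
  ds <- make_dataset(n_genes = 6, n_case = 10, n_ctrl = 10,
                     shift_genes = c("g01", "g02"), seed = 6)
  st <- sam_statistics(ds, "case", "control")
  members <- rownames(ds$values)

  tr0 <- reduce_gene_set(ds, members, st, c_k = 0, B = 30, seed = 3)
  expect_equal(tr0$stop_k, 1L)
  expect_equal(tr0$core, tr0$ranked_genes[1])

  tr1 <- reduce_gene_set(ds, members, st, c_k = 1, B = 30, seed = 3)
  expect_equal(tr1$stop_k, length(members))
  expect_equal(tr1$core, tr1$ranked_genes)
  expect_length(tr1$residual_pvalues, length(members) - 1L)

  ts <- reduce_gene_set(ds, "g03", st, c_k = 0.05, B = 30, seed = 3)
  expect_equal(ts$core, "g03")
  expect_length(ts$residual_pvalues, 0L)

  # trace internal consistency
  tr <- reduce_gene_set(ds, members, st, c_k = 0.05, B = 30, seed = 3)
  expect_equal(tr$core, tr$ranked_genes[seq_len(tr$stop_k)])
  expect_true(all(tr$residual_pvalues >= 1 / 31 & tr$residual_pvalues <= 1))
  if (tr$stop_k < length(members)) {
    expect_gt(tr$residual_pvalues[tr$stop_k], 0.05)
    if (tr$stop_k > 1L)
      expect_true(all(tr$residual_pvalues[seq_len(tr$stop_k - 1L)] <= 0.05))
  }
})

test_that("the stopping index matches a brute-force all-k oracle on a planted set", {
  ds <- make_dataset(n_genes = 10, n_case = 30, n_ctrl = 30,
                     shift_genes = c("g01", "g02"), shift = 2, seed = 12)
  st <- sam_statistics(ds, "case", "control")
  members <- rownames(ds$values)
  tr <- reduce_gene_set(ds, members, st, c_k = 0.05, B = 200, seed = 7,
                        set_name = "planted")

  # oracle: rank independently, evaluate every residual subset on its own
  ranked <- members[order(-abs(st$d_effective[members]), members,
                          method = "radix")]
  pvals <- vapply(seq_len(length(ranked) - 1L), function(k) {
    permutation_pvalue(ds, "case", "control",
                       ranked[(k + 1L):length(ranked)],
                       B = 200, seed = derive_seed(7, "planted", k),
                       s0 = st$s0)$p_value
  }, 0)
  oracle_stop <- if (any(pvals > 0.05)) which(pvals > 0.05)[1L] else length(ranked)

  expect_equal(tr$ranked_genes, ranked)
  expect_equal(tr$stop_k, oracle_stop)
  expect_equal(tr$residual_pvalues, pvals[seq_along(tr$residual_pvalues)])
  # the two planted genes carry the signal and head the ranking
  expect_equal(tr$stop_k, 2L)
  expect_setequal(tr$core, c("g01", "g02"))
})

test_that("core size is non-decreasing in c_k and respects weighting symmetries", {
  ds <- make_dataset(n_genes = 8, n_case = 15, n_ctrl = 15,
                     shift_genes = c("g01", "g02", "g03"), shift = 1.2,
                     seed = 21)
  st <- sam_statistics(ds, "case", "control")
  members <- rownames(ds$values)
  sizes <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5), function(ck)
    reduce_gene_set(ds, members, st, c_k = ck, B = 60, seed = 5)$stop_k, 0L)
  expect_true(all(diff(sizes) >= 0))

  # constant weights give the identical trace
  w <- const_weights(rownames(ds$values), c = 4)
  stw <- sam_statistics(ds, "case", "control", s0 = st$s0, weights = w)
  tu <- reduce_gene_set(ds, members, st, c_k = 0.1, B = 60, seed = 5)
  tw <- reduce_gene_set(ds, members, stw, c_k = 0.1, B = 60, seed = 5)
  expect_identical(tu$ranked_genes, tw$ranked_genes)
  expect_identical(tu$stop_k, tw$stop_k)
  expect_equal(tu$residual_pvalues, tw$residual_pvalues)

  # raising one gene's weight never lowers its rank
  gene <- "g04"
  base_rank <- match(gene, tu$ranked_genes)
  w2 <- const_weights(rownames(ds$values), c = 1)
  w2$weights[gene] <- 10
  st2 <- sam_statistics(ds, "case", "control", s0 = st$s0, weights = w2)
  boosted <- reduce_gene_set(ds, members, st2, c_k = 0.1, B = 60, seed = 5)
  expect_lte(match(gene, boosted$ranked_genes), base_rank)
})

test_that("stage-1 screening selects signal sets and honours alpha boundaries", {
  ds <- make_dataset(n_genes = 30, n_case = 12, n_ctrl = 12,
                     shift_genes = sprintf("g%02d", 1:10), shift = 2,
                     seed = 33)
  gsc <- gene_set_collection(
    list(signal = sprintf("g%02d", 1:10),
         noise1 = sprintf("g%02d", 11:20),
         noise2 = sprintf("g%02d", 21:30)),
    rownames(ds$values))
  res <- select_significant_sets(ds, gsc, alpha = 0.05, B = 100, seed = 2,
                                 case_label = "case", control_label = "control")
  expect_true("signal" %in% res$selected)
  expect_equal(nrow(res$table), 3L)

  all_sets <- select_significant_sets(ds, gsc, alpha = 1, B = 20, seed = 2,
                                      case_label = "case",
                                      control_label = "control")
  expect_setequal(all_sets$selected, names(gsc$sets))
})
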