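test_that("s0 is the median positive pooled sd, with a degenerate fallback", {
  expect_equal(estimate_s0(c(1, 2, 3)), 2)
  expect_equal(estimate_s0(c(0.1, 0.4, 0.2, 0.9)), 0.3)
  expect_equal(estimate_s0(c(0, 0, 0)), 1e-6)
  expect_equal(estimate_s0(c(0, 3, 0, 1)), 2)  # zeros excluded from the median
  expect_error(estimate_s0(numeric(0)), "empty")
})

test_that("SAM statistics follow the pooled-sd formula and its symmetries", {
  # hand case: case values (2,2), control (0,0), s0 = 0.5 -> s = 0, d = 4
  m <- matrix(c(2, 2, 0, 0), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  ds <- expression_dataset(m, setNames(c("case", "case", "control", "control"),
                                       paste0("s", 1:4)))
  st <- sam_statistics(ds, "case", "control", s0 = 0.5)
  expect_equal(unname(st$d["g1"]), 4)
  expect_equal(unname(st$s["g1"]), 0)
  expect_identical(st$d_effective, st$d)  # unweighted: identical, not just equal

  # identical group means -> d = 0
  m2 <- matrix(c(1, 2, 2, 1), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  ds2 <- expression_dataset(m2, ds$labels)
  expect_equal(unname(sam_statistics(ds2, "case", "control", s0 = 1)$d), 0)

  # swapping roles negates d elementwise
  ds3 <- make_dataset(n_genes = 6, n_case = 5, n_ctrl = 7,
                      shift_genes = "g01", seed = 4)
  a <- sam_statistics(ds3, "case", "control", s0 = 0.4)
  b <- sam_statistics(ds3, "control", "case", s0 = 0.4)
  expect_equal(a$d, -b$d)

  expect_error(sam_statistics(ds3, "case", "nope"), "unknown")
  one <- ds3[, c(1, 6:12)]  # a single case sample
  expect_error(sam_statistics(one, "case", "control"), "at least 2",
               class = "samgsr_degenerate_error")
})

test_that("the gene-set score is the sum of squared effective statistics", {
  ds <- make_dataset(n_genes = 3, n_case = 3, n_ctrl = 3, seed = 9)
  st <- sam_statistics(ds, "case", "control", s0 = 1)
  st$d_effective[] <- c(1, -2, 2)
  expect_equal(samgs_score(st, c("g01", "g02", "g03")), 9)
  expect_equal(samgs_score(st, "g03"), 4)
  expect_error(samgs_score(st, character(0)), "empty")
  expect_error(samgs_score(st, "nope"), "not in")

  # homogeneity: constant weights scale the score by exactly c^2
  w <- const_weights(rownames(ds$values), c = 3)
  stw <- sam_statistics(ds, "case", "control", s0 = 1, weights = w)
  stu <- sam_statistics(ds, "case", "control", s0 = 1)
  expect_equal(samgs_score(stw, rownames(ds$values)),
               9 * samgs_score(stu, rownames(ds$values)))
})

test_that("exhaustive permutation p-values match a brute-force enumeration oracle", {
  set.seed(5)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  m["g1", 1:2] <- m["g1", 1:2] + 3
  ds <- expression_dataset(m, setNames(c("case", "case", "control", "control"),
                                       paste0("s", 1:4)))
  members <- c("g1", "g2")
  s0 <- 0.3

  res <- permutation_pvalue(ds, "case", "control", members, B = 1,
                            seed = 1, s0 = s0, exhaustive = TRUE)
  expect_equal(res$B, choose(4, 2))

  # independent oracle: enumerate all 6 case assignments with loop code
  combos <- combn(4, 2)
  scores <- apply(combos, 2, function(cc)
    oracle_score(m[members, , drop = FALSE], cc, s0))
  obs <- oracle_score(m[members, , drop = FALSE], 1:2, s0)
  expect_equal(res$observed_score, obs)
  expect_equal(sort(res$null_scores), sort(scores))
  expect_equal(res$p_value, (1 + sum(scores >= obs)) / (ncol(combos) + 1))
})

test_that("permutation p-values obey their bounds, symmetries, and determinism", {
  ds <- make_dataset(n_genes = 8, n_case = 5, n_ctrl = 7,
                     shift_genes = c("g01", "g02"), seed = 2)
  members <- rownames(ds$values)[1:5]

  r1 <- permutation_pvalue(ds, "case", "control", members, B = 50, seed = 11)
  r2 <- permutation_pvalue(ds, "case", "control", members, B = 50, seed = 11)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 51)

  # exchanging class roles changes nothing
  r3 <- permutation_pvalue(ds, "control", "case", members, B = 50, seed = 11)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$null_scores, r1$null_scores)

  # permuting gene rows changes nothing
  dsr <- expression_dataset(ds$values[rev(seq_len(nrow(ds$values))), ],
                            ds$labels)
  r4 <- permutation_pvalue(dsr, "case", "control", members, B = 50, seed = 11)
  expect_equal(r4$p_value, r1$p_value)

  # constant weights reproduce the unweighted p-values exactly
  w <- const_weights(rownames(ds$values), c = 2.5)
  r5 <- permutation_pvalue(ds, "case", "control", members, weights = w,
                           B = 50, seed = 11)
  expect_equal(r5$p_value, r1$p_value)
  expect_equal(r5$null_scores, 2.5^2 * r1$null_scores)

  # all-zero expression: every labelling gives d = 0, so p = 1
  z <- matrix(0, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  dz <- expression_dataset(z, setNames(rep(c("case", "control"), each = 3),
                                       paste0("s", 1:6)))
  expect_equal(permutation_pvalue(dz, "case", "control", c("a", "b"),
                                  B = 20, seed = 1)$p_value, 1)
})

test_that("null permutation p-values are approximately uniform", {
  # global null: iid noise, balanced labels; type-I error near alpha
  set.seed(31)
  p <- replicate(60, {
    ds <- make_dataset(n_genes = 12, n_case = 10, n_ctrl = 10,
                       seed = sample.int(1e6, 1))
    permutation_pvalue(ds, "case", "control", rownames(ds$values)[1:6],
                       B = 40, seed = sample.int(1e6, 1))$p_value
  })
  # binomial(60, ~0.05) three-sigma band
  expect_lt(mean(p <= 0.05), 0.17)
  expect_gt(mean(p <= 0.5), 0.3)
})
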