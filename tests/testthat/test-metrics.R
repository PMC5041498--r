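pt2 <- function(p_case, truth) {
  p <- cbind(case = p_case, control = 1 - p_case)
  prediction_table(sprintf("s%02d", seq_along(p_case)), truth = truth,
                   probs = p)
}

test_that("error rate counts misclassifications at the 0.5 cutoff", {
  expect_equal(error_rate(pt2(c(0.9, 0.8, 0.1), c("case", "case", "control"))), 0)
  expect_equal(error_rate(pt2(c(0.1, 0.2, 0.9), c("case", "case", "control"))), 1)
  expect_equal(error_rate(pt2(c(rep(0.9, 7), rep(0.1, 3)), rep("case", 10))), 0.3)
  # a confidence of exactly 0.5 classifies to the case class
  expect_equal(error_rate(pt2(0.5, "case")), 0)
  expect_equal(error_rate(pt2(0.5, "control")), 1)
  # two-class cutoff agrees with argmax whenever no confidence is exactly 0.5
  set.seed(2)
  p <- runif(50); p <- p[p != 0.5]
  truth <- sample(c("case", "control"), length(p), replace = TRUE)
  pt <- pt2(p, truth)
  argmax <- colnames(pt$probs)[apply(pt$probs, 1, which.max)]
  expect_equal(error_rate(pt), mean(argmax != truth))
})

test_that("GBS matches hand-evaluated cases", {
  expect_equal(gbs(pt2(c(1, 0), c("case", "control"))), 0)
  expect_equal(gbs(pt2(c(0.5, 0.5), c("case", "control"))), 0.25)
  expect_equal(gbs(pt2(c(0.8, 0.3), c("case", "case"))), 0.265)
  # moving a row toward its indicator decreases GBS
  expect_lt(gbs(pt2(c(0.9, 0.3), c("case", "case"))),
            gbs(pt2(c(0.8, 0.3), c("case", "case"))))
})

test_that("BCM matches hand-evaluated cases and rejects empty classes", {
  expect_equal(bcm(pt2(c(1, 0), c("case", "control"))), 1)
  expect_equal(bcm(pt2(c(0.5, 0.5), c("case", "control"))), 0.5)
  expect_equal(bcm(pt2(c(0.9, 0.7, 0.4), c("case", "case", "control"))), 0.7)
  expect_error(bcm(pt2(c(0.9, 0.7), c("case", "case"))), "no true members")
  # invariant to sample order
  pt <- pt2(c(0.9, 0.7, 0.4), c("case", "case", "control"))
  ptr <- prediction_table(rev(pt$sample_ids), rev(pt$truth),
                          pt$probs[3:1, ])
  expect_equal(bcm(ptr), bcm(pt))
  expect_equal(aupr(ptr), aupr(pt))
})

test_that("AUPR is step-wise average precision, macro-averaged over classes", {
  # perfect ranking in both classes
  expect_equal(aupr(pt2(c(0.9, 0.8, 0.2, 0.1),
                        c("case", "case", "control", "control"))), 1)
  # single positive ranked last among m samples: AUPR_k = 1/m for that class
  m <- 5
  p_case <- c(rep(0.9, m - 1), 0.1)
  truth <- c(rep("control", m - 1), "case")
  pt <- prediction_table(sprintf("s%02d", 1:m), truth,
                         cbind(case = p_case, control = 1 - p_case))
  ap_case <- 1 / m
  # in the control ranking the lone case sample (control-conf 0.9) comes
  # first, so the controls sit at ranks 2..5
  ap_control <- mean(c(1 / 2, 2 / 3, 3 / 4, 4 / 5))
  expect_equal(aupr(pt), mean(c(ap_case, ap_control)))
  # ties broken by sample ID: equal confidences give a deterministic value
  ptt <- pt2(rep(0.6, 4), c("case", "control", "case", "control"))
  expect_equal(aupr(ptt), aupr(ptt))
  expect_equal(aupr(ptt), mean(c(mean(c(1 / 1, 2 / 3)), mean(c(1 / 2, 2 / 4)))))
})

test_that("the stability index is mean pairwise Jaccard with documented edge cases", {
  expect_equal(rand_index(list(c("A", "B"), c("A", "B"))), 1)
  expect_equal(rand_index(list(c("A", "B"), c("C", "D"))), 0)
  expect_equal(rand_index(list(c("A", "B", "C"), c("B", "C", "D"))), 0.5)
  expect_equal(rand_index(list(character(0), character(0))), 1)
  expect_equal(rand_index(list(character(0), "A")), 0)
  expect_error(rand_index(list("A")), "at least 2")
  # symmetric and order-invariant
  l <- list(c("A", "B", "C"), c("B", "C", "D"), c("A", "D"))
  expect_equal(rand_index(rev(l)), rand_index(l))
  expect_equal(rand_index(lapply(l, rev)), rand_index(l))
  # three lists: mean over the 3 pairs
  expect_equal(rand_index(l), mean(c(0.5, 1 / 4, 1 / 4)))
})

test_that("metrics_report bundles the four metrics plus stability", {
  pt <- pt2(c(0.9, 0.2, 0.6), c("case", "control", "control"))
  rep <- metrics_report(pt, gene_lists = list("A", c("A", "B")))
  expect_equal(rep$error_rate, error_rate(pt))
  expect_equal(rep$gbs, gbs(pt))
  expect_equal(rep$rand_gene, 0.5)
})
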