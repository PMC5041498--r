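# fixtures are built in code; nothing is read from disk except what a test
# itself writes to a tempdir

# small dataset with a configurable two-group mean shift on chosen genes
make_dataset <- function(n_genes = 10, n_case = 30, n_ctrl = 30,
                         shift_genes = character(0), shift = 2,
                         seed = 1, gene_ids = sprintf("g%02d", seq_len(n_genes))) {
  set.seed(seed)
  n <- n_case + n_ctrl
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(gene_ids, sprintf("s%03d", seq_len(n))))
  labels <- setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                     colnames(m))
  m[shift_genes, labels == "case"] <-
    m[shift_genes, labels == "case", drop = FALSE] + shift
  expression_dataset(m, labels)
}

# constant-weight ConnectivityWeights over a gene universe
const_weights <- function(universe, c = 1) {
  e <- edge_list(character(0), character(0), numeric(0))
  w <- build_weights(e, universe)
  w$weights[] <- c
  w
}

# direct, loop-based SAM/score oracle, independent of the package kernel
oracle_score <- function(X, case_cols, s0, w = rep(1, nrow(X))) {
  ctrl_cols <- setdiff(seq_len(ncol(X)), case_cols)
  nd <- length(case_cols); nc <- length(ctrl_cols)
  total <- 0
  for (i in seq_len(nrow(X))) {
    xd <- X[i, case_cols]; xc <- X[i, ctrl_cols]
    s <- sqrt((1 / nd + 1 / nc) *
                (sum((xd - mean(xd))^2) + sum((xc - mean(xc))^2)) /
                (nd + nc - 2))
    d <- (mean(xd) - mean(xc)) / (s + s0)
    total <- total + (w[i] * d)^2
  }
  total
}
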