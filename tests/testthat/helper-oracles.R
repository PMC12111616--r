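# Independent oracles and small utilities used across the test files.
# These deliberately re-derive quantities from first principles (or via an
# unrelated library) so they never share code with the implementation.

# adjusted Rand index from the pair-counting definition
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# classic iterative NIPALS PLS1: returns the first-component scores
nipals_pls1_scores <- function(X, y, tol = 1e-12, max_iter = 500) {
  y0 <- y - mean(y)
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(max_iter)) {
    w_new <- drop(crossprod(X, y0))
    w_new <- w_new / sqrt(sum(w_new^2))
    if (max(abs(w_new - w)) < tol) break
    w <- w_new
  }
  drop(X %*% w_new)
}

# Newton-Raphson logistic regression from the score equations
newton_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X1, y - p))
    W <- p * (1 - p)
    H <- crossprod(X1 * W, X1)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Mann-Whitney AUC by direct pair counting with tie-halving
auc_by_pairs <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# orthogonal Procrustes alignment error between two point sets
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(A^2)
  max(abs(B - sc * A %*% t(R)))
}

# small fixed-seed cohort used by several files; generated once per run
tiny_composition <- c(glycerolipid = 8, sphingolipid = 8, fatty_acid = 8)

tiny_cohort <- function(seed = 7, effects = NULL, ...) {
  design <- cohort_design(class_composition = tiny_composition, seed = seed,
                          ...)
  effects <- effects %||% effect_spec(latent_factors = list(),
                                      sparse_fraction = 0,
                                      noisy_qc_fraction = 0)
  simulate_cohort(design, effects)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# analysis-ready table from a cohort (no SERRF, for speed)
analysis_table <- function(cohort, presence = 0.8) {
  pres <- presence_filter(cohort$features, presence)
  impute_missing(collapse_platforms(pres$table))
}

# all permutations of 1..n (for exact-test enumeration oracles)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, t(apply(sub, 1, function(p) append(p, n, after = i - 1))))
  }
  out
}
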