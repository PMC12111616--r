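# Pareto scaling, OPLS-DA / VIP, univariate testing, selection rule.

test_that("log-Pareto scaling matches hand computation and its variance identity", {
  m <- matrix(exp(c(1, 2, 3)), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(unname(log_pareto(m)[, 1]), c(-1, 0, 1))
  set.seed(4)
  m2 <- matrix(rlnorm(60, 10, 0.7), 20, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  sc <- log_pareto(m2)
  # variance of a Pareto-scaled column equals the SD of its log values
  expect_equal(unname(apply(sc, 2, var)), unname(apply(log(m2), 2, sd)))
  m3 <- cbind(m2, const = 5)
  expect_warning(sc3 <- log_pareto(m3), "zero-variance")
  expect_equal(unname(sc3[, "const"]), rep(0, 20))
  expect_error(log_pareto(matrix(c(1, -1), 1)), "positive")
})

test_that("OPLS-DA with no orthogonal component reproduces the NIPALS PLS1 oracle", {
  set.seed(11)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rep(c(0, 1), each = 20)
  X[, 3] <- X[, 3] + y
  X <- scale(X)
  m <- fit_oplsda(X, y, n_ortho = 0)
  t_oracle <- nipals_pls1_scores(X, y)
  expect_lt(max(abs(abs(m$scores) - abs(t_oracle))), 1e-6)
})

test_that("predictive scores are orthogonal to every orthogonal component", {
  set.seed(12)
  X <- matrix(rnorm(30 * 25), 30, 25)
  y <- rep(c(0, 1), each = 15)
  X[, 1] <- X[, 1] + 1.5 * y
  X <- scale(X)
  for (no in 1:3) {
    m <- fit_oplsda(X, y, n_ortho = no)
    for (a in seq_len(m$n_ortho)) {
      expect_lt(abs(cor(m$scores, m$t_o[, a])), 1e-8)
    }
    expect_equal(sum(m$w^2), 1)
  }
})

test_that("duplicating every sample leaves the OPLS-DA model unchanged", {
  set.seed(13)
  X <- scale(matrix(rnorm(20 * 8), 20, 8))
  y <- rep(c(0, 1), each = 10)
  m1 <- fit_oplsda(X, y, n_ortho = 1)
  m2 <- fit_oplsda(rbind(X, X), c(y, y), n_ortho = 1)
  expect_equal(m1$w, m2$w, tolerance = 1e-10)
  expect_equal(m1$p, m2$p, tolerance = 1e-10)
})

test_that("label permutation drives cross-validated Q2 below zero", {
  set.seed(14)
  X <- matrix(rnorm(50 * 40), 50, 40)
  y <- rep(c(0, 1), each = 25)
  X[, 1:4] <- X[, 1:4] + 1.5 * y
  X <- scale(X)
  expect_gt(q2_oplsda(X, y, n_ortho = 1, seed = 1), 0.2)
  null_q2 <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    q2_oplsda(X, sample(y), n_ortho = 1, seed = i)
  }, numeric(1))
  expect_gte(mean(null_q2 <= 0), 0.9)
})

test_that("VIP scores obey the normalization identity and rank planted features first", {
  set.seed(15)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c(0, 1), each = 15)
  X[, 7] <- X[, 7] + 2 * y
  m <- fit_oplsda(scale(X), y, n_ortho = 1)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-6)
  # single-feature model: VIP is identically 1
  m1 <- fit_oplsda(scale(X[, 7, drop = FALSE]), y, n_ortho = 0)
  expect_equal(unname(vip_scores(m1)), 1)
  # a single planted discriminative feature among nulls attains max VIP > 1
  hits <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    Xn <- matrix(rnorm(50 * 51), 50, 51)
    yy <- rep(c(0, 1), each = 25)
    Xn[, 51] <- Xn[, 51] + 2 * yy
    vv <- vip_scores(fit_oplsda(scale(Xn), yy, n_ortho = 1))
    which.max(vv) == 51 && vv[51] > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("univariate tests match hand BH computation and handle degenerate input", {
  tab <- tibble::tibble(
    sample_id = paste0("S", 1:8),
    group = rep(c("HC", "RA"), each = 4),
    injection_order = 1:8, platform = "ALL",
    same = rep(5, 8),
    diff = c(1, 2, 3, 4, 10, 11, 12, 13)
  )
  res <- univariate_test(tab, c("HC", "RA"))
  expect_equal(res$p_value[res$feature_id == "same"], 1)
  expect_equal(res$fold_change[res$feature_id == "same"], 1)
  expect_equal(res$fold_change[res$feature_id == "diff"], 11.5 / 2.5)
  # BH on p = .01,.02,.03,.04 over 4 features gives q = .04 for all
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # q monotone non-decreasing in p rank
  co <- tiny_cohort(seed = 17)
  tabc <- analysis_table(co)
  resc <- univariate_test(tabc, c("HC", "RA"))
  ord <- order(resc$p_value)
  expect_true(all(diff(resc$q_value[ord]) >= -1e-12))
})

test_that("rank-sum statistic equals brute-force concordant pair counting", {
  set.seed(18)
  for (i in 1:5) {
    x1 <- sample(1:40, 6); x2 <- sample(1:40, 5)
    w <- suppressWarnings(wilcox.test(x2, x1)$statistic)
    brute <- sum(outer(x2, x1, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(unname(w), brute)
  }
})

test_that("the selection rule is strict on both thresholds", {
  diff <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    p_value = c(0.001, 0.0001, 0.01, 0.2),
    q_value = c(0.01, 0.001, 0.05, 0.4),
    vip = c(1.5, 0.99, 1.5, 1.5)
  )
  out <- select_features(diff)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, FALSE)) # q = 0.05 exact fails
  out_raw <- select_features(diff, mode = "raw")
  expect_equal(out_raw$selected, c(TRUE, FALSE, TRUE, FALSE))
  vip <- c(a = 1.5, b = 0.99, c = 1.5, d = 1.5)
  expect_equal(select_features(diff[, 1:3], vip = vip)$selected,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(select_features(diff[, 1:3], vip = vip[1:3]), "named")
})

test_that("differential_analysis recovers planted class effects end to end", {
  co <- tiny_cohort(seed = 19)
  tab <- analysis_table(co)
  d <- differential_analysis(tab, c("HC", "RA"))
  expect_s3_class(d, "metab_diff")
  truth_hit <- co$truth$feature_id[abs(co$truth$eff_ra) >= 1]
  sel <- d$feature_id[d$selected]
  expect_gt(length(intersect(sel, truth_hit)) / length(truth_hit), 0.5)
  # glycerolipids planted upward: fold change above 1
  gl <- d$fold_change[grepl("^GL_", d$feature_id)]
  expect_gt(mean(gl > 1), 0.8)
  g <- glance(d)
  expect_equal(g$comparison, "HC vs RA")
  expect_s3_class(autoplot(d), "ggplot")
})
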