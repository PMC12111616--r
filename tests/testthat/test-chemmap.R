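# Fingerprints, Tanimoto clustering, module splitting, WMCSA.

test_that("fingerprints are deterministic and Tanimoto behaves", {
  smi <- c(a = "OC(=O)CCCCCCCC", b = "OC(=O)CCCCCCCC", c = "c1ccccc1")
  fp <- fingerprint(smi)
  expect_equal(fp["a", ], fp["b", ])
  expect_equal(tanimoto(fp["a", ], fp["b", ]), 1)
  # molecules with disjoint substructure: similarity frozen from a fixed
  # toy pair (nonanoic acid vs benzene share no linear path)
  t_ab <- tanimoto(fp["a", ], fp["c", ])
  expect_lt(t_ab, 0.1)
  # Tanimoto equals brute-force bit counting
  set.seed(1)
  for (i in 1:10) {
    x <- rbinom(64, 1, 0.3); y <- rbinom(64, 1, 0.3)
    inter <- 0; un <- 0
    for (b in 1:64) {
      inter <- inter + (x[b] == 1 && y[b] == 1)
      un <- un + (x[b] == 1 || y[b] == 1)
    }
    expect_equal(tanimoto(x, y), if (un == 0) 1 else inter / un)
  }
  # unparseable SMILES flagged, not fatal
  expect_warning(bad <- fingerprint(c("OC(=O)CCC", "not_a_smiles(((")),
                 "could not be parsed")
  expect_false(anyNA(bad[1, ]))
  expect_true(all(is.na(bad[2, ])))
})

test_that("the distance matrix is a proper bounded metric input", {
  smi <- vapply(seq_len(12), function(i)
    class_smiles(c("fatty_acid", "sphingolipid")[1 + i %% 2], i),
    character(1))
  fp <- fingerprint(smi)
  d <- tanimoto_distance(fp)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  # zero distance iff identical fingerprints
  same <- which(d < 1e-12, arr.ind = TRUE)
  for (k in seq_len(nrow(same))) {
    expect_equal(fp[same[k, 1], ], fp[same[k, 2], ])
  }
})

test_that("two homologous series are recovered as two clusters", {
  smi <- c(vapply(1:10, function(i) class_smiles("fatty_acid", i), ""),
           vapply(1:10, function(i) class_smiles("sphingolipid", i), ""))
  names(smi) <- paste0("m", 1:20)
  truth <- rep(1:2, each = 10)
  cl <- detect_clusters(tanimoto_distance(fingerprint(smi)))
  expect_equal(cl$k, 2)
  expect_equal(ari(cl$clusters, truth), 1)
})

test_that("degenerate and invalid distance inputs are handled", {
  d0 <- matrix(0, 5, 5)
  expect_warning(cl <- detect_clusters(d0), "single cluster")
  expect_equal(cl$k, 1)
  expect_error(detect_clusters(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("silhouette-based K selection matches the direct formula on a hand case", {
  # 6 points, two tight triangles far apart
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  cl <- detect_clusters(d, k_range = 2:4)
  expect_equal(cl$k, 2)
  # direct silhouette formula for this configuration: a = 0.1, b = 0.9
  s_hand <- (0.9 - 0.1) / 0.9
  got <- cl$silhouette$mean_width[cl$silhouette$k == 2]
  expect_equal(got, s_hand, tolerance = 1e-12)
})

test_that("modules refine clusters, partition the set, and honor min_size", {
  # one cluster with two clear sub-series plus a distant second cluster
  d <- matrix(0.95, 12, 12)
  d[1:8, 1:8] <- 0.5
  d[1:4, 1:4] <- 0.05
  d[5:8, 5:8] <- 0.05
  d[9:12, 9:12] <- 0.05
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("m", 1:12)
  # cluster level fixed at 2; the sub-series live below it
  cl <- detect_clusters(d, k_range = 2:2)
  expect_equal(cl$k, 2)
  out <- split_modules(cl, min_size = 3)
  mods <- out$modules
  expect_false(anyNA(mods))                      # no orphans
  expect_equal(length(unique(mods[1:8])), 2)     # sub-series split
  expect_equal(length(unique(mods[9:12])), 1)
  # modules nest inside clusters
  expect_true(all(tapply(cl$clusters, mods, function(x) length(unique(x))) == 1))
  # a cluster of size 3 with min_size 3 stays one module
  d3 <- as.matrix(stats::dist(c(0, 0.01, 0.02, 5, 5.01, 5.02)) / 10)
  cl3 <- detect_clusters(d3, k_range = 2:3)
  out3 <- split_modules(cl3, min_size = 3)
  expect_equal(length(unique(out3$modules)), 2)
  expect_error(split_modules(cl, min_size = 1), "min_size")
})

test_that("WMCSA summaries are standardized, oriented, and first-PC optimal", {
  co <- tiny_cohort(seed = 23)
  tab <- analysis_table(co)
  mods <- setNames(paste0("c", as.integer(factor(co$truth$class)), ".m1"),
                   co$truth$feature_id)
  s <- wmcsa(tab, mods)
  for (m in names(s$members)) {
    sc <- s$scores[[m]]
    expect_equal(mean(sc), 0, tolerance = 1e-12)
    expect_equal(sd(sc), 1, tolerance = 1e-12)
    Z <- scale(log(as.matrix(tab[, s$members[[m]]])))
    expect_gte(cor(sc, rowMeans(Z)), 0)
    # first-PC optimality: summary explains at least as much member
    # variance as any single member profile
    expl <- function(v) sum(cor(Z, v)^2)
    best_single <- max(apply(Z, 2, expl))
    expect_gte(expl(sc) + 1e-8, best_single)
  }
  # a module of identical features reduces to the standardized feature
  tab2 <- tab
  tab2$GL_002 <- tab2$GL_001
  s2 <- wmcsa(tab2, c(GL_001 = "c9.m1", GL_002 = "c9.m1"))
  z <- drop(scale(log(tab2$GL_001)))
  expect_equal(abs(cor(s2$scores[["c9.m1"]], z)), 1, tolerance = 1e-12)
  expect_gte(cor(s2$scores[["c9.m1"]], z), 0)
})

test_that("a planted coherent module effect reaches Kruskal-Wallis significance", {
  hits <- vapply(1:20, function(s) {
    eff <- effect_spec(
      class_effects = tibble::tibble(class = "sphingolipid",
                                     group = "RA", effect = -1),
      cytokine_effects = default_cytokine_effects()[0, ],
      latent_factors = list(), drift_amplitude = 0,
      missingness = 0, sparse_fraction = 0, noisy_qc_fraction = 0)
    co <- tiny_cohort(seed = 300 + s, effects = eff)
    tab <- analysis_table(co)
    mods <- setNames(paste0("c", as.integer(factor(co$truth$class)), ".m1"),
                     co$truth$feature_id)
    s_ <- wmcsa(tab, mods)
    sp_mod <- paste0("c", which(levels(factor(co$truth$class)) ==
                                  "sphingolipid"), ".m1")
    vals <- split(s_$scores[[sp_mod]], s_$scores$group)
    kruskal_wallis(vals)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("module group tests: Dunn z matches hand computation, Bonferroni bound", {
  # 3 groups x 3 observations, no ties; hand-computed mean ranks
  vals <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  dn <- dunn_test(vals)
  # mean ranks 2, 5, 8; SE = sqrt((9*10/12)*(2/3)) = sqrt(5)
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], -3 / sqrt(5))
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "c"], -6 / sqrt(5))
  dnb <- dunn_test(vals, adjust = "bonferroni")
  expect_equal(dnb$p_adj, pmin(1, dn$p_value * 3))
  expect_true(all(dnb$p_adj >= dn$p_value))
  # equal mean ranks give z = 0, p = 1
  vals0 <- list(a = c(1, 5, 9), b = c(2, 6, 7), c = c(3, 4, 8))
  dn0 <- dunn_test(vals0)
  expect_equal(dn0$z[1], 0, tolerance = 1e-12)
  expect_equal(dn0$p_value[1], 1)
})
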