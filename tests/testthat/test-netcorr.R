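# Spearman edges, Floyd-Warshall geodesics, MDS layout, network recovery.

test_that("Spearman correlation: hand values, monotone invariance, exact p", {
  s <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(s$rho, 0.6)
  set.seed(2)
  x <- rnorm(20)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, exp(x))$p_value, 0)
  expect_error(spearman_cor(1:10, rep(1, 10)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "4 complete pairs")
  # exact small-n p equals full permutation enumeration
  for (n in c(5, 6)) {
    set.seed(n)
    x <- sample(100, n); y <- sample(100, n)
    obs <- abs(cor(rank(x), rank(y)))
    perms <- combinat_perms(n)
    rhos <- apply(perms, 1, function(pp) abs(cor(rank(x), rank(y[pp]))))
    p_exact <- mean(rhos >= obs - 1e-12)
    expect_equal(spearman_cor(x, y)$p_value, p_exact, tolerance = 1e-10)
  }
})

test_that("correlation distance follows the 1 - |rho| convention", {
  edges <- tibble::tibble(from = c("a", "a"), to = c("b", "c"),
                          rho = c(1, -0.8), p_value = c(0.001, 0.01),
                          sign = c("positive", "negative"))
  net <- structure(list(nodes = tibble::tibble(name = c("a", "b", "c"),
                                               type = "metabolite"),
                        edges = edges, distance = "abs"),
                   class = "corr_network")
  d <- correlation_distance(net)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.2) # sign lives on the edge, not the metric
  expect_equal(net$edges$sign[2], "negative")
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["b", "c"], Inf)
})

test_that("Floyd-Warshall matches hand values, Dijkstra, and is idempotent", {
  expect_equal(floyd_warshall(matrix(0, 1, 1)), matrix(0, 1, 1))
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[2, 3] <- d[3, 2] <- 0.1
  d[1, 3] <- d[3, 1] <- 0.5
  g <- floyd_warshall(d)
  expect_equal(g[1, 3], 0.2)
  expect_identical(floyd_warshall(g), g) # idempotent
  expect_error(floyd_warshall(matrix(c(0, -1, -1, 0), 2)), "negative")
  skip_if_not_installed("igraph")
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    d <- matrix(Inf, n, n); diag(d) <- 0
    for (k in seq_len(n * 2)) {
      ij <- sample(n, 2)
      w <- runif(1, 0.05, 1)
      d[ij[1], ij[2]] <- d[ij[2], ij[1]] <- w
    }
    g <- floyd_warshall(d)
    adj <- d; adj[!is.finite(adj)] <- 0
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              weighted = TRUE)
    ref <- igraph::distances(ig, algorithm = "dijkstra")
    expect_equal(unname(g), unname(ref), tolerance = 1e-12)
  }
})

test_that("classical MDS reproduces planar configurations and degenerate cases", {
  set.seed(10)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(pts))
  emb <- mds_layout(d)
  expect_lt(procrustes_error(pts, emb$coordinates), 1e-6)
  expect_lt(emb$stress, 1e-6)
  # recovered inter-point distances unaffected by translating coordinates
  d2 <- as.matrix(stats::dist(emb$coordinates + 5))
  expect_equal(unname(d2), unname(d), tolerance = 1e-6)
  # three equidistant points form an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  tri <- mds_layout(d3)$coordinates
  side <- as.matrix(stats::dist(tri))
  expect_equal(unname(side[upper.tri(side)]), rep(1, 3), tolerance = 1e-8)
  expect_error(mds_layout(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("network edges are invariant under monotone transforms", {
  co <- tiny_cohort(seed = 25)
  tab <- analysis_table(co)
  diff <- differential_analysis(tab, c("HC", "RA"))
  panel <- node_panel(diff, "RA", "cytokines")
  net1 <- build_network(tab, co$metadata, panel)
  md2 <- co$metadata
  md2$gm_csf <- log(md2$gm_csf) # strictly monotone
  tab2 <- tab
  tab2$SP_001 <- tab2$SP_001^3
  net2 <- build_network(tab2, md2, panel)
  expect_equal(net1$edges[, c("from", "to", "sign")],
               net2$edges[, c("from", "to", "sign")])
  expect_equal(net1$edges$rho, net2$edges$rho, tolerance = 1e-12)
})

test_that("planted latent edges are recovered and an empty network is valid", {
  eff <- effect_spec(
    latent_factors = list(infl = list(
      covariate = "gm_csf", covariate_loading = 0.8,
      features = c("SP_001", "SP_002", "SP_003"),
      feature_loading = rep(0.8, 3))),
    drift_amplitude = 0, missingness = 0, sparse_fraction = 0,
    noisy_qc_fraction = 0)
  recov <- vapply(1:10, function(s) {
    co <- tiny_cohort(seed = 400 + s, effects = eff)
    tab <- analysis_table(co)
    panel <- list(metabolites = c("SP_001", "SP_002", "SP_003"),
                  covariates = ra_cytokine_panel(), disease = "RA")
    net <- build_network(tab, co$metadata, panel)
    wanted <- paste0("SP_00", 1:3)
    hit <- vapply(wanted, function(m) {
      any((net$edges$from == m & net$edges$to == "gm_csf") |
            (net$edges$to == m & net$edges$from == "gm_csf"))
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(recov), 0.9)
  # no planted structure, tiny alpha: an empty edge set is still a network
  co0 <- tiny_cohort(seed = 550, effects = null_effect_spec())
  tab0 <- analysis_table(co0)
  panel0 <- list(metabolites = c("FA_001", "FA_002"),
                 covariates = "hdl", disease = "RA")
  net0 <- build_network(tab0, co0$metadata, panel0, alpha = 1e-6)
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(is.infinite(net0$geodesic[upper.tri(net0$geodesic)])))
  expect_equal(nrow(net0$layout), 3)
})

test_that("the planted hub cytokine dominates the network degree", {
  eff <- effect_spec(drift_amplitude = 0, missingness = 0,
                     sparse_fraction = 0, noisy_qc_fraction = 0)
  wins <- vapply(1:10, function(s) {
    co <- simulate_cohort(
      cohort_design(class_composition = c(sphingolipid = 12,
                                          glycerolipid = 8,
                                          phospholipid_pe = 4),
                    seed = 600 + s), eff)
    tab <- analysis_table(co)
    panel <- list(metabolites = sprintf("SP_%03d", 1:12),
                  covariates = ra_cytokine_panel(), disease = "RA")
    net <- build_network(tab, co$metadata, panel)
    deg <- node_degree(net)
    names(which.max(deg)) == "gm_csf"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
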