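# QC %CV, SERRF normalization, presence/CV filters, imputation.

# hand-built two-platform table: 6 biological + QC rows per platform
mini_table <- function(lc_qc = c(100, 100, 100), gc_qc = c(50, 55, 60),
                       lc_bio = c(90, 95, 100, 105, 110, 115)) {
  tibble::tibble(
    sample_id = c(paste0("S", 1:6), paste0("QC_LC_", seq_along(lc_qc)),
                  paste0("S", 1:6), paste0("QC_GC_", seq_along(gc_qc))),
    group = c(rep(c("HC", "RA", "SLE"), 2), rep("QC", length(lc_qc)),
              rep(c("HC", "RA", "SLE"), 2), rep("QC", length(gc_qc))),
    injection_order = c(seq_len(6 + length(lc_qc)),
                        seq_len(6 + length(gc_qc))),
    platform = c(rep("LC", 6 + length(lc_qc)), rep("GC", 6 + length(gc_qc))),
    feat_lc = c(lc_bio, lc_qc, rep(NA_real_, 6 + length(gc_qc))),
    feat_gc = c(rep(NA_real_, 6 + length(lc_qc)), lc_bio, gc_qc)
  )
}

test_that("QC %CV matches hand computation and handles edge cases", {
  tab <- mini_table(lc_qc = c(100, 100, 100), gc_qc = c(90, 100, 110))
  expect_equal(qc_cv(tab, "feat_lc"), 0)
  expect_equal(qc_cv(tab, "feat_gc"), 10) # sample SD 10, mean 100
  tab1 <- mini_table(lc_qc = c(100, NA, NA))
  expect_error(qc_cv(tab1, "feat_lc"), "fewer than 2")
  expect_error(qc_cv(tab, "nope"), "unknown feature")
})

test_that("CV filter applies the per-platform thresholds, boundary passes", {
  # LC %CV just over / under 20; GC at 25 (kept, GC threshold is 30)
  mk <- function(cv_target) {
    m <- 100
    s <- cv_target * m / 100
    m + c(-1, 0, 1) * s * sqrt(1) # sd of (-s,0,s) = s
  }
  tab <- mini_table(lc_qc = mk(20.1), gc_qc = mk(25))
  res <- cv_filter(tab)
  expect_false(res$report$detail$pass[res$report$detail$feature_id == "feat_lc"])
  expect_true(res$report$detail$pass[res$report$detail$feature_id == "feat_gc"])
  tab2 <- mini_table(lc_qc = mk(19.9))
  expect_true(cv_filter(tab2)$report$detail$pass[1])
  # boundary: exactly at threshold passes (<= convention)
  tab3 <- mini_table(lc_qc = mk(20))
  expect_true(cv_filter(tab3)$report$detail$pass[1])
  # unknown platform
  tab4 <- tab
  tab4$platform[tab4$platform == "GC"] <- "CE"
  expect_error(cv_filter(tab4), "CE")
})

test_that("presence filter keeps a feature present in one group only", {
  set.seed(1)
  n_hc <- 27; n_ra <- 23; n_sle <- 22
  groups <- rep(c("HC", "RA", "SLE"), c(n_hc, n_ra, n_sle))
  x <- rep(NA_real_, length(groups))
  x[which(groups == "HC")[1:22]] <- rlnorm(22, 10) # 22/27 = 81.5%
  x[which(groups == "RA")[1:2]] <- rlnorm(2, 10)
  x[which(groups == "SLE")[1:2]] <- rlnorm(2, 10)
  y <- rlnorm(length(groups), 10)          # present everywhere
  z <- x; z[which(groups == "HC")[1:4]] <- NA # 18/27 = 66% max
  tab <- tibble::tibble(
    sample_id = paste0("S", seq_along(groups)), group = groups,
    injection_order = seq_along(groups), platform = "LC",
    one_group = x, everywhere = y, nowhere = z
  )
  res <- presence_filter(tab, 0.8)
  keep <- res$report$detail
  expect_true(keep$pass[keep$feature_id == "one_group"])
  expect_true(keep$pass[keep$feature_id == "everywhere"])
  expect_false(keep$pass[keep$feature_id == "nowhere"])
  expect_equal(feature_cols(res$table), c("one_group", "everywhere"))
  expect_equal(res$report$after, 2)
})

test_that("presence and CV filters commute", {
  co <- tiny_cohort(seed = 11, effects = effect_spec(
    latent_factors = list(), sparse_fraction = 0.1, noisy_qc_fraction = 0.1))
  a <- cv_filter(presence_filter(co$features)$table)$table
  b <- presence_filter(cv_filter(co$features)$table)$table
  expect_identical(sort(feature_cols(a)), sort(feature_cols(b)))
})

test_that("half-minimum imputation alters only missing cells", {
  tab <- mini_table()
  tab$feat_lc[2] <- NA
  out <- impute_missing(tab)
  lc_rows <- tab$platform == "LC"
  expect_equal(out$feat_lc[2], min(tab$feat_lc[lc_rows], na.rm = TRUE) / 2)
  expect_equal(out$feat_lc[-2][lc_rows[-2]], tab$feat_lc[-2][lc_rows[-2]])
  expect_false(anyNA(out$feat_lc[lc_rows]))
  # identity when nothing is missing
  expect_identical(impute_missing(mini_table()), mini_table())
})

test_that("SERRF leaves a drift-free table essentially unchanged", {
  co <- tiny_cohort(seed = 21, effects = effect_spec(
    latent_factors = list(), drift_amplitude = 0, missingness = 0,
    sparse_fraction = 0, noisy_qc_fraction = 0))
  norm <- serrf_normalize(co$features, trees = 200)
  fc <- feature_cols(co$features)
  rel <- abs(as.matrix(norm[, fc]) / as.matrix(co$features[, fc]) - 1)
  expect_lt(median(rel, na.rm = TRUE), 0.05)
})

test_that("SERRF removes planted drift and strictly reduces QC %CV", {
  fracs <- c(); cv_drop <- c(); raw_frac <- c()
  for (s in 1:3) {
    co <- tiny_cohort(seed = 100 + s, effects = effect_spec(
      class_effects = default_class_effects()[0, ],
      latent_factors = list(), drift_amplitude = 0.5, missingness = 0,
      sparse_fraction = 0, noisy_qc_fraction = 0))
    norm <- serrf_normalize(co$features, trees = 300)
    fc <- feature_cols(co$features)
    rho <- function(tab) {
      vapply(fc, function(f) {
        pf <- co$truth$platform[co$truth$feature_id == f]
        r <- tab$platform == pf & tab$group != "QC"
        abs(cor(log(tab[[f]][r]), tab$injection_order[r],
                method = "spearman"))
      }, numeric(1))
    }
    fracs <- c(fracs, mean(rho(norm) < 0.3))
    raw_frac <- c(raw_frac, mean(rho(co$features) < 0.3))
    cvs <- function(tab) median(vapply(fc, function(f) qc_cv(tab, f),
                                       numeric(1)))
    cv_drop <- c(cv_drop, cvs(norm) < cvs(co$features))
  }
  # the forest removes the bulk of the drift-order association; a residual
  # above the pure-noise floor remains because biological predictor noise
  # leaks into the per-sample drift estimate
  expect_gt(mean(fracs), 0.7)
  expect_gt(mean(fracs) - mean(raw_frac), 0.15)
  expect_true(all(cv_drop))            # QC %CV strictly decreases
})

test_that("SERRF is scale-equivariant and preserves QC medians and missingness", {
  co <- tiny_cohort(seed = 31, effects = effect_spec(
    latent_factors = list(), drift_amplitude = 0.3, missingness = 0.1,
    sparse_fraction = 0, noisy_qc_fraction = 0))
  tab <- co$features
  norm <- serrf_normalize(tab, trees = 100)
  expect_identical(is.na(norm$GL_001), is.na(tab$GL_001))
  qc_lc <- tab$group == "QC" & tab$platform == "LC"
  expect_equal(median(norm$GL_001[qc_lc], na.rm = TRUE),
               median(tab$GL_001[qc_lc], na.rm = TRUE))
  tab2 <- tab
  tab2$GL_001 <- tab2$GL_001 * 7
  norm2 <- serrf_normalize(tab2, trees = 100)
  expect_equal(norm2$GL_001, norm$GL_001 * 7, tolerance = 1e-12)
})

test_that("constant features and sparse QC fall back gracefully", {
  tab <- mini_table(lc_qc = rep(80, 6), lc_bio = rep(80, 6))
  tab_const <- tab[tab$platform == "LC", ]
  out <- serrf_normalize(tab_const, trees = 50)
  expect_equal(out$feat_lc, tab_const$feat_lc)
  # fewer than 5 QC injections per platform: LOESS fallback with warning
  tab_few <- mini_table()
  w <- capture_warnings(serrf_normalize(tab_few, trees = 50))
  expect_true(any(grepl("LOESS", w)))
})

test_that("collapse_platforms merges platform runs into one row per sample", {
  co <- tiny_cohort(seed = 41)
  tab <- collapse_platforms(co$features)
  expect_equal(nrow(tab), 72)
  expect_false(any(tab$group == "QC"))
  expect_setequal(feature_cols(tab), feature_cols(co$features))
  # values survive the merge untouched
  f <- "SP_001"
  pf <- co$truth$platform[co$truth$feature_id == f]
  src <- co$features[co$features$platform == pf &
                       co$features$sample_id == "S001", f][[1]]
  expect_identical(tab[[f]][tab$sample_id == "S001"], src)
})
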