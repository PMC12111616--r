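# Synthetic cohort generator.

# TRUE marks a QC injection in the run sequence: `initial` leading QCs, then
# one QC after every `interval` biological samples (one closing QC if the
# final block is partial).
run_sequence <- function(n_bio, initial, interval) {
  flags <- logical(0)
  flags <- c(flags, rep(TRUE, initial))
  done <- 0L
  while (done < n_bio) {
    block <- min(interval, n_bio - done)
    flags <- c(flags, rep(FALSE, block), TRUE)
    done <- done + block
  }
  flags # TRUE = QC injection, in run order
}

#' Simulate a two-platform untargeted metabolomics cohort
#'
#' Generates a feature intensity table (biological and pooled-QC injections
#' on each platform), a sample metadata table (clinical lipid panel,
#' cytokines, disease-activity scores) and a metabolite annotation table
#' (SMILES, class, platform), following a log-normal intensity model:
#' log intensity = feature baseline + group effect (in within-group SD
#' units) + injection-order drift + latent-factor contribution + noise.
#' Pooled-QC injections are noisy replicates of the cohort mean modulated
#' by the same drift. Values below a per-feature low quantile are reported
#' missing (left-censoring).
#'
#' @param design A [cohort_design()].
#' @param effects An [effect_spec()].
#' @param seed Integer seed; defaults to the design's seed. The function
#'   sets the global RNG state.
#' @return A `metab_cohort` list with elements `features` (feature table),
#'   `metadata`, `annotations`, and `truth` (per-feature planted effects,
#'   loadings and flags, for use in recovery tests).
#' @export
simulate_cohort <- function(design, effects = effect_spec(),
                            seed = design$seed) {
  if (!inherits(design, "cohort_design")) abort("`design` must be a cohort_design")
  if (!inherits(effects, "effect_spec")) abort("`effects` must be an effect_spec")
  set.seed(seed)

  comp <- design$class_composition
  classes <- rep(names(comp), comp)
  idx_in_class <- unlist(lapply(comp, seq_len), use.names = FALSE)
  feature_id <- sprintf("%s_%03d", chem_classes[classes], idx_in_class)
  p <- length(feature_id)
  platform <- unname(class_platform[classes])

  smiles <- mapply(class_smiles, classes, idx_in_class)
  ann <- tibble::tibble(
    feature_id = feature_id,
    name = paste0(gsub("_", " ", classes), " ", idx_in_class),
    class = classes,
    formula = vapply(smiles, smiles_formula, character(1)),
    mass = vapply(smiles, smiles_mass, numeric(1)),
    rt = round(ifelse(platform == "LC", 1 + 11 * idx_in_class / pmax(comp[classes], 1),
                      5 + 20 * idx_in_class / pmax(comp[classes], 1)), 3),
    smiles = unname(smiles),
    platform = platform,
    cv_qc = NA_real_,
    msi_level = 1L + (seq_len(p) %% 3L)
  )

  # --- biological samples ----------------------------------------------
  groups <- rep(c("HC", "RA", "SLE"), c(design$n_hc, design$n_ra, design$n_sle))
  n_b <- length(groups)
  sample_id <- sprintf("S%03d", seq_len(n_b))

  # latent factors shared between metabolites and cytokines / HDL
  factors <- effects$latent_factors
  Z <- matrix(rnorm(n_b * max(1L, length(factors))), nrow = n_b)
  colnames(Z) <- if (length(factors)) names(factors) else "none"

  lambda <- rep(0, p)
  factor_of <- rep(NA_character_, p)
  for (fn in names(factors)) {
    f <- factors[[fn]]
    hit <- match(f$features, feature_id)
    if (anyNA(hit)) {
      abort(paste0("latent factor '", fn, "' names unknown features: ",
                   paste(f$features[is.na(hit)], collapse = ", ")))
    }
    lambda[hit] <- f$feature_loading
    factor_of[hit] <- fn
  }

  # per-feature planted group effects in SD units
  eff <- matrix(0, nrow = p, ncol = 3,
                dimnames = list(feature_id, c("HC", "RA", "SLE")))
  ce <- effects$class_effects
  for (k in seq_len(nrow(ce))) {
    eff[classes == ce$class[k], ce$group[k]] <- ce$effect[k]
  }
  fe <- effects$feature_effects
  for (k in seq_len(nrow(fe))) {
    j <- match(fe$feature_id[k], feature_id)
    if (is.na(j)) abort(paste0("feature_effects names unknown feature: ",
                               fe$feature_id[k]))
    eff[j, fe$group[k]] <- fe$effect[k]
  }

  # feature nuisance parameters
  mu <- runif(p, log(1e4), log(1e6))
  sigma <- effects$noise_sd
  qc_sd <- rep(effects$qc_noise_sd, p)
  protected <- which(!is.na(factor_of) | feature_id %in% fe$feature_id)
  free <- setdiff(seq_len(p), protected)
  noisy <- sample(free, round(effects$noisy_qc_fraction * p))
  qc_sd[noisy] <- 0.35
  sparse <- sample(setdiff(free, noisy), round(effects$sparse_fraction * p))
  miss_prob <- rep(effects$missingness, p)
  miss_prob[sparse] <- 0.85

  # Drift model: each platform has one shared instrument trend (sensitivity
  # drift affects all features together); each feature follows it with its
  # own amplitude and direction plus a smaller feature-specific wobble.
  drift_amp <- runif(p, 0.2, 1) * effects$drift_amplitude
  drift_dir <- sample(c(-1, 1), p, replace = TRUE)
  drift_wm <- runif(p, 0.3, 1)
  drift_freq <- runif(p, 1, 2)
  drift_phase <- runif(p, 0, 2 * pi)
  drift_share <- 0.7
  plat_wm <- setNames(runif(2, 0.5, 1), c("LC", "GC"))
  plat_freq <- setNames(runif(2, 1, 2), c("LC", "GC"))
  plat_phase <- setNames(runif(2, 0, 2 * pi), c("LC", "GC"))

  drift_block <- function(j, s, pf) {
    # s in [-0.5, 0.5]; monotone + smooth periodic components, mean-centred
    shared <- plat_wm[[pf]] * 2 * s +
      (1 - plat_wm[[pf]]) * sin(2 * pi * plat_freq[[pf]] * s + plat_phase[[pf]])
    own <- drift_wm[j] * 2 * s +
      (1 - drift_wm[j]) * sin(2 * pi * drift_freq[j] * s + drift_phase[j])
    tr <- drift_dir[j] * drift_amp[j] *
      (drift_share * shared + (1 - drift_share) * own)
    tr - mean(tr)
  }

  pooled_eff <- as.numeric(eff %*% c(design$n_hc, design$n_ra, design$n_sle)) / n_b

  # --- per-platform run simulation -------------------------------------
  blocks <- list()
  for (pf in unique(platform)) {
    sched <- design$qc_schedule[[pf]]
    if (is.null(sched)) abort(paste0("no QC schedule for platform ", pf))
    flags <- run_sequence(n_b, sched$initial, sched$interval)
    n_pos <- length(flags)
    run_order_bio <- sample(n_b) # which biological sample at each bio slot
    bio_slot <- which(!flags)
    qc_slot <- which(flags)
    row_sample <- character(n_pos)
    row_group <- character(n_pos)
    row_sample[bio_slot] <- sample_id[run_order_bio]
    row_group[bio_slot] <- groups[run_order_bio]
    row_sample[qc_slot] <- sprintf("QC_%s_%02d", pf, seq_along(qc_slot))
    row_group[qc_slot] <- "QC"

    feats <- which(platform == pf)
    s <- (seq_len(n_pos) - 1) / max(1L, n_pos - 1L) - 0.5
    logx <- matrix(NA_real_, n_pos, length(feats))
    for (jj in seq_along(feats)) {
      j <- feats[jj]
      base <- rep(mu[j] + pooled_eff[j] * sigma, n_pos)
      base[bio_slot] <- mu[j] + eff[j, groups[run_order_bio]] * sigma
      noise <- numeric(n_pos)
      noise[qc_slot] <- qc_sd[j] * rnorm(length(qc_slot))
      lj <- lambda[j]
      zj <- if (lj != 0) Z[run_order_bio, factor_of[j]] else 0
      noise[bio_slot] <- sigma * (lj * zj + sqrt(1 - lj^2) * rnorm(length(bio_slot)))
      logx[, jj] <- base + drift_block(j, s, pf) + noise
    }
    # left-censoring below the per-feature low quantile of biological values
    for (jj in seq_along(feats)) {
      pr <- miss_prob[feats[jj]]
      if (pr > 0) {
        thr <- quantile(logx[bio_slot, jj], pr, names = FALSE)
        logx[logx[, jj] < thr, jj] <- NA_real_
      }
    }
    tab <- tibble::tibble(
      sample_id = row_sample, group = row_group,
      injection_order = seq_len(n_pos), platform = pf
    )
    tab[ann$feature_id[feats]] <- as.data.frame(exp(logx))
    blocks[[pf]] <- tab
  }
  features <- dplyr::bind_rows(blocks)
  # fill off-platform feature columns with NA, fix column order
  for (fid in ann$feature_id) {
    if (!fid %in% names(features)) features[[fid]] <- NA_real_
  }
  features <- features[, c(META_COLS, ann$feature_id)]

  # --- metadata: clinical panel + cytokines ----------------------------
  # latent contribution of a covariate, possibly spread over several
  # factors: sum of loading * factor score, residual variance 1 - sum(l^2)
  cov_latent <- function(name) {
    part <- rep(0, n_b)
    l2 <- 0
    for (fn in names(factors)) {
      f <- factors[[fn]]
      if (identical(f$covariate, name)) {
        part <- part + f$covariate_loading * Z[, fn]
        l2 <- l2 + f$covariate_loading^2
      }
    }
    part + sqrt(max(0, 1 - l2)) * rnorm(n_b)
  }
  ln <- function(med_by_group, sdlog, zvec = NULL, shift = NULL) {
    med <- med_by_group[groups]
    if (!is.null(shift)) med <- med * exp(ifelse(groups == "HC", 0, shift[groups]))
    z <- zvec %||% rnorm(n_b)
    unname(exp(log(med) + sdlog * z))
  }
  meta <- tibble::tibble(
    sample_id = sample_id, group = groups,
    hdl = ln(c(HC = 52.5, RA = 52.5, SLE = 52.5), 0.2, cov_latent("hdl"),
             shift = effects$hdl_shift),
    ldl = ln(c(HC = 123.6, RA = 109, SLE = 93.5), 0.25),
    tc = ln(c(HC = 202.4, RA = 172.9, SLE = 164.4), 0.18),
    tg = ln(c(HC = 106.1, RA = 129.4, SLE = 122.7), 0.3),
    esr = ln(c(HC = 7, RA = 13, SLE = 9.5), 0.5),
    lymphocytes = ln(c(HC = 1900, RA = 1700, SLE = 1450), 0.2),
    neutrophils = ln(c(HC = 3300, RA = 4400, SLE = 3700), 0.25),
    duration = ifelse(groups == "HC", NA,
                      ln(c(HC = 1, RA = 4.5, SLE = 5.8), 0.5)),
    activity_score = dplyr::case_when(
      groups == "RA" ~ ln(c(HC = 1, RA = 3.6, SLE = 1), 0.12),
      groups == "SLE" ~ ln(c(HC = 1, RA = 1, SLE = 6), 0.2),
      TRUE ~ NA_real_
    )
  )
  cyt_base <- setNames(round(runif(length(all_cytokines()), 5, 50), 1),
                       all_cytokines())
  cyt_sd <- 0.5
  for (cy in all_cytokines()) {
    shift <- rep(0, n_b)
    cef <- dplyr::filter(effects$cytokine_effects, .data$cytokine == cy)
    for (k in seq_len(nrow(cef))) {
      shift[groups == cef$group[k]] <- cef$effect[k] * cyt_sd
    }
    meta[[cy]] <- exp(log(cyt_base[cy]) + shift + cyt_sd * cov_latent(cy))
  }

  ann$cv_qc <- vapply(ann$feature_id, function(f) {
    tryCatch(qc_cv(features, f), error = function(e) NA_real_)
  }, numeric(1))

  truth <- tibble::tibble(
    feature_id = feature_id, class = classes, platform = platform,
    eff_ra = eff[, "RA"], eff_sle = eff[, "SLE"],
    latent_factor = factor_of, latent_loading = lambda,
    drift_amplitude = drift_amp,
    sparse = seq_len(p) %in% sparse,
    noisy_qc = seq_len(p) %in% noisy
  )

  structure(
    list(features = features, metadata = meta, annotations = ann,
         truth = truth, design = design, effects = effects, seed = seed),
    class = "metab_cohort"
  )
}

#' @export
print.metab_cohort <- function(x, ...) {
  cat("<metab_cohort> ", sum(bio_rows(x$features)), " biological + ",
      sum(!bio_rows(x$features)), " QC injections; ",
      nrow(x$annotations), " features; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Closed-form AUC for a planted biomarker
#'
#' For features following the generator's equal-covariance Gaussian
#' log-intensity model, the two-class AUC of the optimal linear score is
#' `pnorm(sqrt(t(delta) %*% solve(Sigma) %*% delta) / sqrt(2))`. With the
#' generator's independent features (`Sigma = sigma^2 I`) and effects given
#' in SD units, this reduces to `pnorm(sqrt(sum(delta_sd^2)) / sqrt(2))`.
#' Serves as the independent oracle for biomarker-recovery tests.
#'
#' @param design A [cohort_design()].
#' @param effects An [effect_spec()].
#' @param features Character vector of feature ids (one or two).
#' @param groups Length-2 character vector, the two classes compared.
#' @return AUC in \[0.5, 1\] for the direction separating the groups.
#' @export
theoretical_auc <- function(design, effects, features,
                            groups = c("HC", "RA")) {
  comp <- design$class_composition
  classes <- rep(names(comp), comp)
  idx_in_class <- unlist(lapply(comp, seq_len), use.names = FALSE)
  ids <- sprintf("%s_%03d", chem_classes[classes], idx_in_class)
  j <- match(features, ids)
  if (anyNA(j)) abort(paste0("unknown feature(s): ",
                             paste(features[is.na(j)], collapse = ", ")))
  latent <- unlist(lapply(effects$latent_factors, `[[`, "features"))
  if (any(features %in% latent)) {
    abort(paste0("theoretical_auc assumes independent equal-covariance ",
                 "features; latent-factor features are not supported"))
  }
  eff_of <- function(fid, cls, grp) {
    fe <- effects$feature_effects
    hit <- fe$feature_id == fid & fe$group == grp
    if (any(hit)) return(fe$effect[which(hit)[1]])
    ce <- effects$class_effects
    hit <- ce$class == cls & ce$group == grp
    if (any(hit)) return(ce$effect[which(hit)[1]])
    0
  }
  delta <- vapply(seq_along(j), function(k) {
    eff_of(features[k], classes[j[k]], groups[2]) -
      eff_of(features[k], classes[j[k]], groups[1])
  }, numeric(1))
  pnorm(sqrt(sum(delta^2)) / sqrt(2))
}
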