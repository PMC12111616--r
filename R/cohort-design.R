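# Cohort design and effect specification for the synthetic generator.

#' Chemical classes emulated by the synthetic cohort
#'
#' Six chemical classes mirroring the composition of an untargeted plasma
#' metabolomics panel in an autoimmune case-control study: glycerolipids,
#' cyclic compounds (aromatics, cyclic amino acids), two phospholipid
#' classes (choline- and ethanolamine-type head groups), sphingolipids, and
#' fatty acids / small organic acids.
#'
#' @format Named character vector mapping class name to feature-id prefix.
#' @export
chem_classes <- c(
  glycerolipid    = "GL",
  cyclic          = "CY",
  phospholipid_pc = "PC",
  phospholipid_pe = "PE",
  sphingolipid    = "SP",
  fatty_acid      = "FA"
)

# platform each class is measured on: lipids on LC, small polars on GC
class_platform <- c(
  glycerolipid = "LC", phospholipid_pc = "LC", phospholipid_pe = "LC",
  sphingolipid = "LC", cyclic = "GC", fatty_acid = "GC"
)

#' Cytokine panels
#'
#' Cytokines significantly elevated in each disease, used as default node
#' panels for the metabolite-cytokine correlation networks. Both panels
#' share a pro-inflammatory core (GM-CSF, CX3CL1, IFN-alpha2, IL-12p70,
#' IL-17A, TNF-alpha, IL-1beta, IFN-gamma); IL-2 is specific to rheumatoid
#' arthritis, while MCP-1 and IL-10 are specific to lupus.
#'
#' @return Character vector of cytokine column names.
#' @export
ra_cytokine_panel <- function() {
  c("gm_csf", "cx3cl1", "ifn_a2", "il_12p70", "il_17a",
    "tnf_a", "il_1b", "ifn_g", "il_2")
}

#' @rdname ra_cytokine_panel
#' @export
sle_cytokine_panel <- function() {
  c("gm_csf", "cx3cl1", "ifn_a2", "il_12p70", "il_17a",
    "tnf_a", "il_1b", "ifn_g", "mcp_1", "il_10")
}

all_cytokines <- function() union(ra_cytokine_panel(), sle_cytokine_panel())

CLINICAL_VARS <- c("hdl", "ldl", "tc", "tg", "esr", "lymphocytes",
                   "neutrophils", "duration", "activity_score")

default_class_composition <- function() {
  c(glycerolipid = 80, cyclic = 50, phospholipid_pc = 90,
    phospholipid_pe = 80, sphingolipid = 60, fatty_acid = 71)
}

#' Describe a synthetic cohort
#'
#' Defines the sampling frame of the synthetic study: group sizes, feature
#' panel composition by chemical class, and per-platform pooled-QC injection
#' schedules. The defaults emulate a 72-woman cohort (27 healthy controls,
#' 23 rheumatoid arthritis, 22 lupus) profiled for 431 annotated metabolites
#' on two platforms, with QC pools injected 10 times up front and then every
#' 8 samples on LC, and 6 times up front then every 5 samples on GC.
#'
#' @param n_hc,n_ra,n_sle Group sizes (healthy controls, RA, SLE).
#' @param class_composition Named integer vector, features per chemical
#'   class (names must be a subset of `names(chem_classes)`).
#' @param qc_schedule Per-platform list with elements `initial` (number of
#'   leading QC injections) and `interval` (a QC after every this many
#'   biological samples).
#' @param seed Integer seed making the generated cohort reproducible.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_hc = 27, n_ra = 23, n_sle = 22,
                          class_composition = default_class_composition(),
                          qc_schedule = list(
                            LC = list(initial = 10, interval = 8),
                            GC = list(initial = 6, interval = 5)
                          ),
                          seed = 1L) {
  n_hc <- assert_count(n_hc, "n_hc")
  n_ra <- assert_count(n_ra, "n_ra")
  n_sle <- assert_count(n_sle, "n_sle")
  if (is.null(names(class_composition)) ||
      !all(names(class_composition) %in% names(chem_classes))) {
    abort("`class_composition` must be named by known chemical classes")
  }
  class_composition <- vapply(class_composition, assert_count, integer(1),
                              name = "class_composition")
  for (p in names(qc_schedule)) {
    assert_count(qc_schedule[[p]]$initial, paste0("qc_schedule$", p, "$initial"))
    assert_count(qc_schedule[[p]]$interval, paste0("qc_schedule$", p, "$interval"))
  }
  structure(
    list(n_hc = n_hc, n_ra = n_ra, n_sle = n_sle,
         n_features = sum(class_composition),
         class_composition = class_composition,
         qc_schedule = qc_schedule, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", x$n_hc, " HC / ", x$n_ra, " RA / ", x$n_sle,
      " SLE; ", x$n_features, " features in ",
      length(x$class_composition), " classes\n", sep = "")
  invisible(x)
}

default_class_effects <- function() {
  tibble::tribble(
    ~class,            ~group, ~effect,
    "phospholipid_pc", "RA",   -1.0,
    "phospholipid_pc", "SLE",  -1.0,
    "phospholipid_pe", "RA",   -1.0,
    "phospholipid_pe", "SLE",  -1.0,
    "sphingolipid",    "RA",   -1.0,
    "sphingolipid",    "SLE",  -1.0,
    "glycerolipid",    "RA",    1.0,
    "glycerolipid",    "SLE",   1.0,
    "fatty_acid",      "RA",   -0.5,
    "fatty_acid",      "SLE",  -0.5
  )
}

default_cytokine_effects <- function() {
  dplyr::bind_rows(
    tibble::tibble(cytokine = ra_cytokine_panel(), group = "RA", effect = 0.8),
    tibble::tibble(cytokine = sle_cytokine_panel(), group = "SLE", effect = 0.8)
  )
}

default_latent_factors <- function() {
  # The inflammation hub is split over two factors with disjoint
  # sphingolipid groups: a single shared factor would force the linked
  # metabolites to inter-correlate as strongly as they correlate with the
  # cytokine, which no real hub structure shows.
  list(
    inflammation_a = list(
      covariate = "gm_csf", covariate_loading = 0.7,
      features = sprintf("SP_%03d", 1:5),
      feature_loading = rep(-0.95, 5)
    ),
    inflammation_b = list(
      covariate = "gm_csf", covariate_loading = 0.7,
      features = sprintf("SP_%03d", 6:10),
      feature_loading = rep(-0.95, 5)
    ),
    hdl_axis = list(
      covariate = "hdl", covariate_loading = 0.9,
      features = c(sprintf("PE_%03d", 1:3), sprintf("GL_%03d", 1:2)),
      feature_loading = c(rep(0.6, 3), rep(-0.6, 2))
    )
  )
}

#' Specify the planted effects of the synthetic cohort
#'
#' Collects every "truth" parameter of the generator: additive group effects
#' on log intensity (in units of within-group SD), injection-order drift,
#' residual noise, left-censoring, cytokine elevations, HDL reduction, and
#' latent factors tying selected metabolites to a cytokine or to HDL (the
#' planted structure the correlation-network stage should recover).
#'
#' Default effects encode the qualitative disease signature of the emulated
#' study: phospholipids and sphingolipids decreased and glycerolipids
#' increased in both diseases, panel cytokines elevated, HDL reduced.
#'
#' @param class_effects Tibble with columns `class`, `group`, `effect`
#'   (standardized mean shift of every feature of the class in that group).
#' @param feature_effects Tibble `feature_id`, `group`, `effect`; overrides
#'   the class effect for the named features.
#' @param cytokine_effects Tibble `cytokine`, `group`, `effect` (standardized
#'   log-scale shifts).
#' @param hdl_shift Named numeric, additive log-scale shift of HDL per
#'   disease group (defaults follow the observed median ratios).
#' @param latent_factors List of latent factors; each has a `covariate`
#'   (cytokine column or `"hdl"`), `covariate_loading`, `features`, and
#'   `feature_loading` (correlation-scale loadings in \[-1, 1\]).
#' @param drift_amplitude Log-scale SD ceiling of per-feature injection-order
#'   drift (0 disables drift).
#' @param noise_sd Within-group residual SD of log intensity.
#' @param qc_noise_sd Residual SD of pooled-QC replicate injections.
#' @param missingness Left-censoring probability per feature (values below
#'   the corresponding low quantile of the feature are reported missing).
#' @param sparse_fraction Fraction of features censored heavily (85%),
#'   emulating near-detection-limit features that the presence filter drops.
#' @param noisy_qc_fraction Fraction of features given poor QC repeatability
#'   (log SD 0.35), emulating features the %CV filter drops.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(class_effects = default_class_effects(),
                        feature_effects = tibble::tibble(
                          feature_id = character(), group = character(),
                          effect = numeric()),
                        cytokine_effects = default_cytokine_effects(),
                        hdl_shift = c(RA = -0.09, SLE = -0.14),
                        latent_factors = default_latent_factors(),
                        drift_amplitude = 0.3,
                        noise_sd = 0.4,
                        qc_noise_sd = 0.05,
                        missingness = 0.10,
                        sparse_fraction = 0.02,
                        noisy_qc_fraction = 0.03) {
  if (!is.finite(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (!is.finite(qc_noise_sd) || qc_noise_sd <= 0) abort("`qc_noise_sd` must be > 0")
  if (!is.finite(drift_amplitude) || drift_amplitude < 0) {
    abort("`drift_amplitude` must be >= 0")
  }
  missingness <- assert_prob(missingness, "missingness")
  sparse_fraction <- assert_prob(sparse_fraction, "sparse_fraction")
  noisy_qc_fraction <- assert_prob(noisy_qc_fraction, "noisy_qc_fraction")
  if (!all(is.finite(class_effects$effect))) abort("class effects must be finite")
  if (!all(is.finite(feature_effects$effect))) abort("feature effects must be finite")
  cov_l2 <- list()
  feat_seen <- character(0)
  for (f in latent_factors) {
    if (length(f$feature_loading) != length(f$features)) {
      abort("latent factor feature_loading must align with features")
    }
    if (any(abs(c(f$covariate_loading, f$feature_loading)) > 1)) {
      abort("latent loadings are correlations and must lie in [-1, 1]")
    }
    if (any(f$features %in% feat_seen)) {
      abort("a feature may load on at most one latent factor")
    }
    feat_seen <- c(feat_seen, f$features)
    cov_l2[[f$covariate]] <- (cov_l2[[f$covariate]] %||% 0) +
      f$covariate_loading^2
  }
  for (cv in names(cov_l2)) {
    if (cov_l2[[cv]] > 1 + 1e-12) {
      abort(paste0("squared covariate loadings for '", cv,
                   "' sum to more than 1"))
    }
  }
  structure(
    list(class_effects = class_effects, feature_effects = feature_effects,
         cytokine_effects = cytokine_effects, hdl_shift = hdl_shift,
         latent_factors = latent_factors, drift_amplitude = drift_amplitude,
         noise_sd = noise_sd, qc_noise_sd = qc_noise_sd,
         missingness = missingness, sparse_fraction = sparse_fraction,
         noisy_qc_fraction = noisy_qc_fraction),
    class = "effect_spec"
  )
}

#' A null effect specification
#'
#' Convenience constructor for global-null simulations: no group effects, no
#' drift, no latent structure, no censoring.
#'
#' @param ... Passed on to [effect_spec()] to override individual fields.
#' @return An `effect_spec`.
#' @export
null_effect_spec <- function(...) {
  defaults <- list(
    class_effects = default_class_effects()[0, ],
    feature_effects = tibble::tibble(feature_id = character(),
                                     group = character(), effect = numeric()),
    cytokine_effects = default_cytokine_effects()[0, ],
    hdl_shift = c(RA = 0, SLE = 0),
    latent_factors = list(),
    drift_amplitude = 0, missingness = 0,
    sparse_fraction = 0, noisy_qc_fraction = 0
  )
  dots <- list(...)
  defaults[names(dots)] <- dots # flat override, never a recursive merge
  do.call(effect_spec, defaults)
}
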