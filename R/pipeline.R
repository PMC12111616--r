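# Config-driven pipeline driver: simulate/load -> preprocess -> diff ->
# chemmap -> network -> biomarker -> cohort stats, with an artifact
# manifest.

default_config <- function() {
  list(
    out_dir = "metabnet_out",
    seed = 1L,
    log_level = "info",
    simulate = list(enabled = TRUE, null_effects = FALSE,
                    n_hc = 27L, n_ra = 23L, n_sle = 22L,
                    class_composition = NULL),
    inputs = list(features = NULL, metadata = NULL, annotations = NULL),
    preprocess = list(serrf = TRUE, trees = 500L, k_correlated = 10L,
                      presence = 0.8, cv_lc = 20, cv_gc = 30),
    diff = list(comparisons = list(c("HC", "RA"), c("HC", "SLE"),
                                   c("RA", "SLE")),
                n_ortho = 1L, mode = "fdr", alpha = 0.05),
    chemmap = list(enabled = TRUE, k_min = 2L, k_max = 10L, min_module = 3L),
    network = list(enabled = TRUE, diseases = c("RA", "SLE"),
                   targets = "cytokines", alpha = 0.05),
    biomarker = list(enabled = TRUE, ra_features = NULL, sle_features = NULL),
    cohort = list(enabled = TRUE,
                  numeric = c("hdl", "ldl", "tc", "esr", "lymphocytes",
                              "neutrophils"),
                  categorical = character())
  )
}

check_config_keys <- function(config, defaults = default_config(),
                              prefix = "") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste0(prefix, unknown, collapse = ", ")))
  }
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(config[[k]]) && !is.null(names(config[[k]])) &&
        k != "diff") {
      check_config_keys(config[[k]], defaults[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Merges a YAML file or list onto the package defaults; unknown keys are
#' rejected before any stage runs.
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return The merged configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  check_config_keys(config)
  utils::modifyList(default_config(), config)
}

pipe_log <- function(level, msg, threshold = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, silent = 4)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", msg)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every
#' artifact (CSV/TSV tables) plus a JSON manifest recording input hashes,
#' parameters, seed and package version. Any stage failure aborts the
#' downstream stages.
#'
#' @param config A configuration (path, list, or `NULL`; see
#'   [pipeline_config()]).
#' @param seed Optional seed overriding the configured one.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL, seed = NULL) {
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  lvl <- cfg$log_level
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  save_tab <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_csv(x, path, na = "NA")
    artifacts[length(artifacts) + 1L] <<- path
    path
  }

  # --- inputs -----------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    pipe_log("info", paste0("simulating cohort (seed ", cfg$seed, ")"), lvl)
    eff <- if (isTRUE(cfg$simulate$null_effects)) null_effect_spec() else effect_spec()
    des_args <- list(n_hc = cfg$simulate$n_hc, n_ra = cfg$simulate$n_ra,
                     n_sle = cfg$simulate$n_sle, seed = cfg$seed)
    if (!is.null(cfg$simulate$class_composition)) {
      des_args$class_composition <- unlist(cfg$simulate$class_composition)
    }
    cohort <- simulate_cohort(do.call(cohort_design, des_args), eff)
    features <- cohort$features
    metadata <- cohort$metadata
    annotations <- cohort$annotations
    save_tab(features, "features_raw.csv")
    save_tab(metadata, "metadata.csv")
    save_tab(annotations, "annotations.csv")
  } else {
    pipe_log("info", "reading input tables", lvl)
    features <- read_feature_table(cfg$inputs$features)
    metadata <- read_metadata(cfg$inputs$metadata)
    annotations <- read_annotations(cfg$inputs$annotations)
  }
  validate_cohort_tables(features, metadata, annotations)

  # --- preprocess -------------------------------------------------------
  pp <- cfg$preprocess
  if (isTRUE(pp$serrf)) {
    pipe_log("info", "SERRF drift normalization", lvl)
    features <- serrf_normalize(features, k_correlated = pp$k_correlated,
                                trees = pp$trees, seed = cfg$seed)
  }
  pres <- presence_filter(features, min_fraction = pp$presence)
  cvf <- cv_filter(pres$table, thresholds = c(LC = pp$cv_lc, GC = pp$cv_gc))
  pipe_log("info", paste0("filters: ", pres$report$before, " -> ",
                          pres$report$after, " -> ", cvf$report$after,
                          " features"), lvl)
  report <- dplyr::bind_rows(tidy(pres$report), tidy(cvf$report))
  path <- file.path(cfg$out_dir, "filter_report.tsv")
  readr::write_tsv(report, path)
  artifacts <- c(artifacts, path)
  analysis <- impute_missing(collapse_platforms(impute_missing(cvf$table)))
  save_tab(analysis, "features_analysis.csv")

  # --- differential analysis -------------------------------------------
  diffs <- list()
  for (cmp in cfg$diff$comparisons) {
    key <- paste(cmp, collapse = "_")
    pipe_log("info", paste0("differential analysis ", key), lvl)
    d <- differential_analysis(analysis, cmp, n_ortho = cfg$diff$n_ortho,
                               mode = cfg$diff$mode, alpha = cfg$diff$alpha)
    diffs[[key]] <- d
    path <- file.path(cfg$out_dir, paste0("diff_", key, ".tsv"))
    readr::write_tsv(tidy(d), path)
    artifacts <- c(artifacts, path)
  }

  # --- chemical mapping -------------------------------------------------
  modules_tests <- NULL
  if (isTRUE(cfg$chemmap$enabled)) {
    pipe_log("info", "chemical-similarity mapping", lvl)
    ann_used <- annotations[annotations$feature_id %in% feature_cols(analysis), ]
    fp <- annotation_fingerprints(ann_used)
    d <- tanimoto_distance(fp)
    clusters <- detect_clusters(d, k_range = cfg$chemmap$k_min:cfg$chemmap$k_max)
    clusters <- split_modules(clusters, min_size = cfg$chemmap$min_module)
    path <- file.path(cfg$out_dir, "chem_modules.tsv")
    readr::write_tsv(tidy(clusters), path)
    artifacts <- c(artifacts, path)
    summ <- wmcsa(analysis, clusters)
    save_tab(summ$scores, "module_scores.csv")
    modules_tests <- module_group_tests(summ)
    path <- file.path(cfg$out_dir, "module_tests.tsv")
    readr::write_tsv(modules_tests, path)
    artifacts <- c(artifacts, path)
  }

  # --- correlation networks --------------------------------------------
  networks <- list()
  if (isTRUE(cfg$network$enabled)) {
    for (dis in cfg$network$diseases) {
      key <- paste0(dis, "_HC")
      if (is.null(diffs[[paste0("HC_", dis)]])) next
      pipe_log("info", paste0("correlation network ", dis), lvl)
      panel <- node_panel(diffs[[paste0("HC_", dis)]], disease = dis,
                          targets = cfg$network$targets)
      if (length(panel$metabolites) < 1) {
        pipe_log("warn", paste0("no differential metabolites for ", dis,
                                "; skipping network"), lvl)
        next
      }
      net <- build_network(analysis, metadata, panel,
                           alpha = cfg$network$alpha)
      networks[[dis]] <- net
      path <- file.path(cfg$out_dir, paste0("network_", dis, "_edges.tsv"))
      readr::write_tsv(net$edges, path)
      artifacts <- c(artifacts, path)
      lay <- tibble::tibble(name = rownames(net$layout),
                            x = net$layout[, 1], y = net$layout[, 2])
      save_tab(lay, paste0("network_", dis, "_layout.csv"))
    }
  }

  # --- biomarkers -------------------------------------------------------
  biomarkers <- list()
  if (isTRUE(cfg$biomarker$enabled)) {
    pick <- function(dis, configured) {
      if (!is.null(configured)) return(configured)
      d <- diffs[[paste0("HC_", dis)]]
      if (is.null(d)) return(NULL)
      sel <- d[d$selected, ]
      if (nrow(sel) < 2) return(NULL)
      sel$feature_id[order(sel$q_value)][1:2]
    }
    for (dis in c("RA", "SLE")) {
      feats <- pick(dis, cfg$biomarker[[paste0(tolower(dis), "_features")]])
      if (is.null(feats)) next
      pipe_log("info", paste0("biomarker ", dis, ": ",
                              paste(feats, collapse = " + ")), lvl)
      bm <- combined_biomarker(analysis, feats, groups = c("HC", dis))
      biomarkers[[dis]] <- bm
      path <- file.path(cfg$out_dir, paste0("roc_", dis, ".csv"))
      readr::write_csv(bm$roc$points, path)
      artifacts <- c(artifacts, path)
      path <- file.path(cfg$out_dir, paste0("biomarker_", dis, ".json"))
      jsonlite::write_json(
        list(features = feats,
             coefficients = as.list(bm$fit$coefficients),
             auc = bm$roc$auc, separation = bm$fit$separation),
        path, auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, path)
    }
  }

  # --- cohort statistics ------------------------------------------------
  if (isTRUE(cfg$cohort$enabled)) {
    pipe_log("info", "clinical group comparison", lvl)
    tab1 <- group_comparison(metadata,
                             numeric_vars = intersect(cfg$cohort$numeric,
                                                      names(metadata)),
                             categorical_vars = intersect(cfg$cohort$categorical,
                                                          names(metadata)))
    path <- file.path(cfg$out_dir, "cohort_table.tsv")
    readr::write_tsv(tab1, path)
    artifacts <- c(artifacts, path)
  }

  manifest <- list(
    package = "metabnet",
    version = as.character(utils::packageVersion("metabnet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "inputs")],
    artifacts = lapply(setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log("info", "pipeline complete", lvl)
  invisible(list(manifest = manifest, analysis = analysis, diffs = diffs,
                 networks = networks, biomarkers = biomarkers,
                 module_tests = modules_tests))
}
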