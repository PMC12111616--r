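# QC-based drift normalization and feature filtering.

# platform each feature was measured on (the platform whose rows carry data)
feature_platforms <- function(table) {
  fc <- feature_cols(table)
  plats <- unique(table$platform)
  out <- setNames(rep(NA_character_, length(fc)), fc)
  for (pf in plats) {
    sub <- table[table$platform == pf, fc, drop = FALSE]
    has <- vapply(sub, function(x) any(!is.na(x)), logical(1))
    out[has & is.na(out)] <- pf
  }
  out
}

#' Percent coefficient of variation over pooled-QC injections
#'
#' Computes 100 * SD / mean of a feature's intensity across the QC
#' injections of its platform, the repeatability statistic behind the
#' reproducibility filter (features with QC %CV above 20% on LC or 30% on
#' GC are conventionally excluded).
#'
#' @param table A feature table.
#' @param feature Feature id (single string).
#' @return %CV as a single number.
#' @export
qc_cv <- function(table, feature) {
  assert_feature_table(table)
  if (!feature %in% feature_cols(table)) {
    abort(paste0("unknown feature: ", feature))
  }
  x <- table[[feature]][table$group == "QC"]
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    abort(paste0("QC %CV undefined for '", feature,
                 "': fewer than 2 non-missing QC values"))
  }
  100 * sd(x) / mean(x)
}

#' SERRF-style QC-based drift normalization
#'
#' Removes systematic intensity drift using a per-feature random-forest
#' regression trained on the pooled-QC injections of each platform. For a
#' feature, the regression predicts log intensity from injection order plus
#' the `k_correlated` features most correlated with it across QC
#' injections; every sample's intensity is then divided by the predicted /
#' QC-median ratio, so the feature's QC median is preserved and the
#' systematic component is flattened. Platforms with fewer than 5 QC
#' injections fall back to a LOESS fit on injection order (span 0.75), with
#' a warning. The missingness pattern is preserved.
#'
#' @param table A feature table with QC rows on every platform.
#' @param k_correlated Number of QC-correlated features used as predictors.
#' @param trees Random-forest size.
#' @param seed Integer seed for the forests.
#' @return The normalized feature table (same shape).
#' @export
serrf_normalize <- function(table, k_correlated = 10, trees = 500, seed = 1L) {
  assert_feature_table(table)
  plat_of <- feature_platforms(table)
  out <- table
  for (pf in unique(table$platform)) {
    rows <- which(table$platform == pf)
    feats <- names(plat_of)[!is.na(plat_of) & plat_of == pf]
    if (length(feats) == 0) next
    qc <- rows[table$group[rows] == "QC"]
    if (length(qc) < 5) {
      warn(paste0("platform ", pf, ": only ", length(qc),
                  " QC injections; falling back to LOESS drift correction"))
      out[rows, feats] <- loess_normalize(table, rows, qc, feats)
      next
    }
    ord <- table$injection_order[rows]
    logm <- log(intensity_matrix(table[rows, ], feats))
    qi <- match(qc, rows)
    # predictor matrix: NAs filled with the feature's platform median
    filled <- apply(logm, 2, function(x) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
      x
    })
    # standardize predictors within QC and within biological injections
    # separately: biological variation is much larger than QC repeatability,
    # so unstandardized predictors would push the forest outside its
    # training range and attenuate the drift estimate
    zstd <- function(x, idx) {
      s <- sd(x[idx])
      if (!is.finite(s) || s < .Machine$double.eps) s <- 1
      (x - mean(x[idx])) / s
    }
    bi <- setdiff(seq_along(rows), qi)
    filled_z <- filled
    for (cc in seq_len(ncol(filled))) {
      filled_z[qi, cc] <- zstd(filled[, cc], qi)[qi]
      filled_z[bi, cc] <- zstd(filled[, cc], bi)[bi]
    }
    qc_cor <- suppressWarnings(cor(filled[qi, , drop = FALSE]))
    qc_cor[!is.finite(qc_cor)] <- 0
    for (jj in seq_along(feats)) {
      x_raw <- table[[feats[jj]]][rows]
      obs <- !is.na(x_raw)
      y_qc <- logm[qi, jj]
      if (all(is.na(y_qc)) || sum(!is.na(y_qc)) < 2) {
        warn(paste0("feature ", feats[jj],
                    ": too few observed QC values; left unnormalized"))
        next
      }
      k <- min(k_correlated, length(feats) - 1)
      top <- order(abs(qc_cor[jj, ]), decreasing = TRUE)
      top <- setdiff(top, jj)[seq_len(k)]
      pred_mat <- cbind(order = ord, filled_z[, top, drop = FALSE])
      colnames(pred_mat) <- c("inj", if (ncol(pred_mat) > 1)
        paste0("f", seq_len(ncol(pred_mat) - 1)))
      train_keep <- !is.na(y_qc)
      # standardize the target so the fit is exactly scale/shift-equivariant
      y_tr <- y_qc[train_keep]
      y_c <- mean(y_tr)
      y_s <- sd(y_tr)
      if (!is.finite(y_s) || y_s < .Machine$double.eps) y_s <- 1
      df_train <- data.frame(y = (y_tr - y_c) / y_s,
                             pred_mat[qi[train_keep], , drop = FALSE])
      fit <- ranger::ranger(
        y ~ ., data = df_train, num.trees = trees,
        min.node.size = 5, seed = seed + jj, num.threads = 1
      )
      pred <- y_c + y_s * predict(fit, data.frame(pred_mat),
                                  num.threads = 1)$predictions
      med_qc <- median(x_raw[qi], na.rm = TRUE)
      norm <- x_raw * med_qc / exp(pred)
      # re-anchor so the QC median is exactly preserved
      med_norm_qc <- median(norm[qi], na.rm = TRUE)
      if (is.finite(med_norm_qc) && med_norm_qc > 0) {
        norm <- norm * med_qc / med_norm_qc
      }
      out[[feats[jj]]][rows] <- norm
    }
  }
  out
}

loess_normalize <- function(table, rows, qc, feats, span = 0.75) {
  ord <- table$injection_order[rows]
  qi <- match(qc, rows)
  res <- table[rows, feats, drop = FALSE]
  for (f in feats) {
    x <- table[[f]][rows]
    y <- log(x[qi])
    keep <- !is.na(y)
    if (sum(keep) < 3) next
    fit <- suppressWarnings(
      loess(y[keep] ~ ord[qi][keep], span = span, degree = 1,
            control = loess.control(surface = "direct"))
    )
    pred <- suppressWarnings(predict(fit, newdata = ord))
    med_qc <- median(x[qi], na.rm = TRUE)
    norm <- x * med_qc / exp(pred)
    med_norm_qc <- median(norm[qi], na.rm = TRUE)
    if (is.finite(med_norm_qc) && med_norm_qc > 0) {
      norm <- norm * med_qc / med_norm_qc
    }
    res[[f]] <- norm
  }
  res
}

new_filter_report <- function(rule, detail) {
  structure(
    list(rule = rule, before = nrow(detail), after = sum(detail$pass),
         detail = detail),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> rule '", x$rule, "': ", x$before, " -> ", x$after,
      " features\n", sep = "")
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$detail

#' Presence filter
#'
#' Keeps a feature if it is observed (non-missing) in at least
#' `min_fraction` of the samples of at least one biological study group.
#' Fractions are computed on biological samples of the feature's platform;
#' QC injections are excluded.
#'
#' @param table A feature table.
#' @param min_fraction Minimum per-group presence fraction (default 0.8).
#' @return List with elements `table` (filtered) and `report`
#'   (a `filter_report`).
#' @export
presence_filter <- function(table, min_fraction = 0.8) {
  assert_feature_table(table)
  min_fraction <- assert_prob(min_fraction, "min_fraction", strict_upper = FALSE)
  groups_present <- intersect(BIO_GROUPS, unique(table$group))
  if (length(groups_present) == 0) abort("no biological study groups in table")
  plat_of <- feature_platforms(table)
  fc <- feature_cols(table)
  stat <- vapply(fc, function(f) {
    pf <- plat_of[[f]]
    if (is.na(pf)) return(0)
    sub <- table[table$platform == pf & table$group != "QC", ]
    if (nrow(sub) == 0) abort("no biological samples on platform ", pf)
    fr <- vapply(groups_present, function(g) {
      x <- sub[[f]][sub$group == g]
      if (length(x) == 0) abort(paste0("empty group ", g, " on platform ", pf))
      mean(!is.na(x))
    }, numeric(1))
    max(fr)
  }, numeric(1))
  detail <- tibble::tibble(rule = "presence", feature_id = fc,
                           statistic = unname(stat),
                           pass = unname(stat) >= min_fraction)
  keep <- detail$feature_id[detail$pass]
  list(table = table[, c(META_COLS, keep)],
       report = new_filter_report("presence", detail))
}

#' QC reproducibility (%CV) filter
#'
#' Keeps a feature if its QC %CV is at or below the threshold of its
#' platform (boundary values pass; exclusion applies to CVs strictly
#' greater than the threshold). Features with fewer than 2 observed QC
#' values fail, since repeatability cannot be demonstrated.
#'
#' @param table A feature table.
#' @param thresholds Named numeric vector of %CV thresholds per platform
#'   (default `c(LC = 20, GC = 30)`).
#' @return List with elements `table` and `report`.
#' @export
cv_filter <- function(table, thresholds = c(LC = 20, GC = 30)) {
  assert_feature_table(table)
  plat_of <- feature_platforms(table)
  fc <- feature_cols(table)
  unknown <- setdiff(unique(plat_of[!is.na(plat_of)]), names(thresholds))
  if (length(unknown) > 0) {
    abort(paste0("no %CV threshold for platform(s): ",
                 paste(unknown, collapse = ", ")))
  }
  stat <- vapply(fc, function(f) {
    tryCatch(qc_cv(table, f), error = function(e) NA_real_)
  }, numeric(1))
  thr <- unname(thresholds[plat_of[fc]])
  pass <- !is.na(stat) & stat <= thr
  detail <- tibble::tibble(rule = "qc_cv", feature_id = fc,
                           statistic = unname(stat), pass = unname(pass))
  keep <- detail$feature_id[detail$pass]
  list(table = table[, c(META_COLS, keep)],
       report = new_filter_report("qc_cv", detail))
}

#' Half-minimum imputation of left-censored values
#'
#' Replaces each remaining missing value by half the smallest observed
#' value of that feature (within the feature's platform), the standard
#' stand-in for intensities below the detection limit. Observed values are
#' never altered. Intended to run after the presence filter, so no feature
#' is fully missing.
#'
#' @param table A feature table (stacked platforms or collapsed).
#' @return The imputed table.
#' @export
impute_missing <- function(table) {
  assert_feature_table(table)
  plat_of <- feature_platforms(table)
  out <- table
  for (f in feature_cols(table)) {
    pf <- plat_of[[f]]
    if (is.na(pf)) {
      abort(paste0("feature ", f, " is fully missing; ",
                   "run the presence filter before imputation"))
    }
    rows <- which(table$platform == pf)
    x <- table[[f]][rows]
    if (anyNA(x)) {
      x[is.na(x)] <- min(x, na.rm = TRUE) / 2
      out[[f]][rows] <- x
    }
  }
  out
}

#' Collapse platform runs to one row per biological sample
#'
#' Drops QC injections and merges each biological sample's per-platform
#' rows into a single row carrying all features, yielding the analysis-ready
#' samples-by-features table used by the differential, module, network and
#' biomarker stages.
#'
#' @param table A feature table with per-platform rows.
#' @return A feature table with platform `"ALL"` and one row per sample.
#' @export
collapse_platforms <- function(table) {
  assert_feature_table(table)
  fc <- feature_cols(table)
  bio <- table[bio_rows(table), ]
  out <- bio |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      dplyr::across(dplyr::all_of(fc),
                    ~ if (all(is.na(.x))) NA_real_ else .x[!is.na(.x)][1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(injection_order = NA_integer_, platform = "ALL",
                  .after = "group")
  out[, c(META_COLS, fc)]
}
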