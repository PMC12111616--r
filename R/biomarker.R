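# Combined-metabolite logistic biomarker scoring and ROC analysis.

#' Binomial GLM for biomarker scoring
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) of a
#' binary class on one or two predictor columns. Quasi-separation is
#' detected (diverging coefficients / fitted probabilities at the
#' boundary) and flagged rather than corrected: the fitted probabilities,
#' and hence the ROC curve, remain well defined. A constant predictor
#' degrades to an intercept-only fit with a warning.
#'
#' @param X Numeric matrix or data frame of predictors (1 or 2 columns).
#' @param y Binary labels (0/1, logical, or 2-level factor).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the deviance.
#' @return A `metab_glm` object: `coefficients` (log-odds units),
#'   `fitted` (probabilities), `converged`, `iterations`, `separation`.
#' @export
fit_logistic <- function(X, y, max_iter = 50, tol = 1e-10) {
  X <- as.data.frame(X)
  if (ncol(X) > 2) abort("at most two predictors are supported")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary")
  if (length(unique(y)) != 2) abort("both classes must be present")
  const <- vapply(X, function(x) sd(x) < .Machine$double.eps, logical(1))
  if (any(const)) {
    warn(paste0("constant predictor(s) dropped: ",
                paste(names(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  df <- cbind(data.frame(.y = y), X)
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!sep_flag && any(abs(coef(fit)[-1]) > 50, na.rm = TRUE)) sep_flag <- TRUE
  structure(
    list(coefficients = coef(fit), fitted = unname(fitted(fit)),
         converged = fit$converged, iterations = fit$iter,
         separation = sep_flag, y = y, model = fit),
    class = "metab_glm"
  )
}

#' @export
print.metab_glm <- function(x, ...) {
  cat("<metab_glm> coefficients: ",
      paste(names(x$coefficients), round(x$coefficients, 3),
            sep = " = ", collapse = ", "),
      if (x$separation) " [quasi-separation]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.metab_glm <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.metab_glm <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 separation = x$separation,
                 deviance = x$model$deviance, aic = x$model$aic)
}

#' ROC curve and AUC
#'
#' Sweeps the unique score thresholds, recording (FPR, TPR) from (0, 0)
#' to (1, 1). Tied scores advance the curve diagonally, so the trapezoidal
#' AUC equals the Mann-Whitney statistic with tie-halving,
#' `AUC = U / (n1 * n2)`.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param y Binary labels (1 = case).
#' @return A `roc_result`: `points` (tibble with `threshold`, `fpr`,
#'   `tpr`), `auc`, class counts.
#' @export
roc_curve <- function(scores, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(scores) != length(y)) abort("`scores` and `y` differ in length")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  uniq <- !duplicated(s)
  # cumulative counts at each unique threshold (score >= threshold called positive)
  tp <- cumsum(yy)[c(which(uniq)[-1] - 1L, length(yy))]
  fp <- cumsum(1 - yy)[c(which(uniq)[-1] - 1L, length(yy))]
  pts <- tibble::tibble(
    threshold = c(Inf, s[uniq]),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  )
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", round(x$auc, 4), " (", x$n_pos, " cases vs ",
      x$n_neg, " controls)\n", sep = "")
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = paste0("AUC = ", round(object$auc, 3))) +
    ggplot2::theme_minimal()
}

#' Combined-metabolite biomarker evaluation
#'
#' The end-to-end biomarker workflow on a disease vs control comparison:
#' extract one or two metabolites, log-transform, fit the binomial GLM,
#' score every sample with its predicted probability, and compute the
#' apparent (in-sample) ROC curve - the same procedure used to report
#' combined two-lipid panels. Optional k-fold cross-validated scoring is
#' available but off by default, matching the apparent-performance
#' convention.
#'
#' @param table Analysis-ready feature table.
#' @param features Character vector of 1 or 2 feature ids.
#' @param groups Length-2 groups, control first (e.g. `c("HC", "RA")`).
#' @param cv Number of cross-validation folds (0 = apparent performance).
#' @param seed Seed for the CV fold split.
#' @return A `metab_biomarker` object with elements `fit` (`metab_glm`)
#'   and `roc` (`roc_result`).
#' @export
combined_biomarker <- function(table, features, groups = c("HC", "RA"),
                               cv = 0, seed = 1L) {
  assert_feature_table(table)
  missing <- setdiff(features, feature_cols(table))
  if (length(missing) > 0) {
    abort(paste0("feature(s) not in table: ", paste(missing, collapse = ", ")))
  }
  if (!length(features) %in% 1:2) abort("supply one or two features")
  sub <- table[table$group %in% groups, ]
  X <- log(intensity_matrix(sub, features))
  y <- as.numeric(sub$group == groups[2])
  fit <- fit_logistic(X, y)
  scores <- fit$fitted
  if (cv > 1) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv), length(y)))
    scores <- numeric(length(y))
    for (k in seq_len(cv)) {
      tr <- fold != k
      fk <- fit_logistic(X[tr, , drop = FALSE], y[tr])
      eta <- cbind(1, X[!tr, , drop = FALSE]) %*%
        ifelse(is.na(fk$coefficients), 0, fk$coefficients)
      scores[!tr] <- 1 / (1 + exp(-eta))
    }
  }
  roc <- roc_curve(scores, y)
  structure(list(fit = fit, roc = roc, features = features, groups = groups,
                 cv = cv),
            class = "metab_biomarker")
}

#' @export
print.metab_biomarker <- function(x, ...) {
  cat("<metab_biomarker> ", paste(x$features, collapse = " + "), ": ",
      x$groups[2], " vs ", x$groups[1], ", ",
      if (x$cv > 1) paste0(x$cv, "-fold CV") else "apparent",
      " AUC = ", round(x$roc$auc, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.metab_biomarker <- function(x, ...) tidy(x$fit)

#' @export
glance.metab_biomarker <- function(x, ...) {
  tibble::tibble(features = paste(x$features, collapse = "+"),
                 comparison = paste(x$groups[2], "vs", x$groups[1]),
                 auc = x$roc$auc, separation = x$fit$separation,
                 cv_folds = x$cv)
}

#' @export
autoplot.metab_biomarker <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(subtitle = paste(object$features, collapse = " + "))
}
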