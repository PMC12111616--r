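# Scaling, OPLS-DA / VIP, univariate testing and the feature-selection rule.

#' Log-transform and Pareto-scale a feature table
#'
#' Per feature: `x -> (log x - mean(log x)) / sqrt(sd(log x))`. Pareto
#' scaling divides by the square root of the standard deviation, a
#' compromise between unit-variance scaling and no scaling that keeps
#' large fold changes influential without letting them dominate. The
#' variance of a Pareto-scaled feature equals the SD of its log values.
#'
#' @param table A feature table with strictly positive intensities
#'   (impute first), or a numeric matrix of intensities.
#' @return Numeric matrix (samples x features) of scaled log intensities.
#' @export
log_pareto <- function(table) {
  m <- if (is.matrix(table)) table else intensity_matrix(table)
  if (any(is.na(m))) abort("intensities must be complete; impute first")
  if (any(m <= 0)) abort("intensities must be strictly positive")
  lm_ <- log(m)
  ctr <- colMeans(lm_)
  s <- apply(lm_, 2, sd)
  zero <- s < .Machine$double.eps
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-variance feature(s) scaled to zeros"))
    s[zero] <- 1
  }
  out <- sweep(sweep(lm_, 2, ctr), 2, sqrt(s), "/")
  out[, zero] <- 0
  out
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome, fitted NIPALS-style: `n_ortho` orthogonal components
#' (class-unrelated variation) are estimated and deflated sequentially,
#' then a single predictive component is fitted on the deflated matrix.
#' With `n_ortho = 0` the fit reduces exactly to single-component PLS1.
#' The fit is deterministic given `X` and `y`.
#'
#' @param X Column-scaled numeric matrix (samples x features).
#' @param y Binary class coding (0/1 vector, logical, or 2-level factor).
#' @param n_ortho Number of orthogonal components (default 1).
#' @return An object of class `opls_model` with predictive weights `w`,
#'   scores `t`, loadings `p`, orthogonal counterparts, the regression
#'   coefficient `b` of y on the predictive score, and explained sums of
#'   squares.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) != 2) abort("`y` must have exactly two classes")
  if (min(table(y)) < 3) abort("each class needs at least 3 samples")
  if (nrow(X) != length(y)) abort("X rows and y length differ")
  n_ortho <- assert_count(n_ortho, "n_ortho", min = 0L)

  y0 <- y - mean(y)
  Xd <- X
  W_o <- T_o <- P_o <- NULL
  a_done <- 0L
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(Xd, y0)) / sum(y0^2)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- drop(Xd %*% w)
    p_ <- drop(crossprod(Xd, t_)) / sum(t_^2)
    w_o <- p_ - sum(w * p_) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) break # no orthogonal variation left
    w_o <- w_o / nwo
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    a_done <- a
  }
  w <- drop(crossprod(Xd, y0)) / sum(y0^2)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("X carries no covariance with y; cannot fit")
  w <- w / nw
  t_ <- drop(Xd %*% w)
  p_ <- drop(crossprod(Xd, t_)) / sum(t_^2)
  b <- sum(t_ * y0) / sum(t_^2)
  ssy_total <- sum(y0^2)
  ssy_explained <- b^2 * sum(t_^2)
  structure(
    list(w = w, scores = t_, p = p_, b = b,
         w_o = W_o, t_o = T_o, p_o = P_o, n_ortho = a_done,
         y = y, y_mean = mean(y),
         ssy_total = ssy_total, ssy_explained = ssy_explained,
         features = colnames(X)),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> 1 predictive + ", x$n_ortho, " orthogonal component(s); ",
      length(x$w), " features; R2Y = ",
      round(x$ssy_explained / x$ssy_total, 3), "\n", sep = "")
  invisible(x)
}

#' Predict class scores from an OPLS-DA model
#'
#' Removes the model's orthogonal variation from new observations, then
#' projects onto the predictive component.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix on the same column scale as the training `X`.
#' @param ... Unused.
#' @return List with `scores` (predictive scores) and `y_hat` (continuous
#'   class prediction).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (object$n_ortho > 0) {
    for (a in seq_len(object$n_ortho)) {
      t_o <- drop(Xn %*% object$w_o[, a])
      Xn <- Xn - tcrossprod(t_o, object$p_o[, a])
    }
  }
  sc <- drop(Xn %*% object$w)
  list(scores = sc, y_hat = object$y_mean + object$b * sc)
}

#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature_id = x$features %||% paste0("V", seq_along(x$w)),
                 weight = x$w, loading = x$p, vip = vip_scores(x))
}

#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(n_ortho = x$n_ortho, r2y = x$ssy_explained / x$ssy_total,
                 n = length(x$y), p = length(x$w))
}

#' Variable importance in projection (VIP)
#'
#' Per-feature contribution to the predictive component(s):
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_aj / ||w_a||)^2) / sum_a(SSY_a))`
#' where `p` is the feature count. With the single predictive component
#' used here, the SSY weights cancel and the mean of squared VIPs is
#' exactly 1, so VIP > 1 flags features contributing more than average.
#'
#' @param model An `opls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "opls_model")) abort("`model` must be an opls_model")
  if (model$ssy_explained <= 0) {
    abort("model explains no class variance; VIP undefined")
  }
  p <- length(model$w)
  vip <- sqrt(p * model$w^2) # single predictive component, unit-norm w
  setNames(vip, model$features %||% paste0("V", seq_len(p)))
}

#' Cross-validated Q2 of an OPLS-DA fit
#'
#' K-fold cross-validation of the full fitting procedure (orthogonal
#' removal refitted per fold); `Q2 = 1 - PRESS / SS`. Used mainly for
#' permutation diagnostics: under a shuffled class labelling Q2 should not
#' exceed 0.
#'
#' @param X Column-scaled matrix.
#' @param y Binary classes.
#' @param n_ortho Orthogonal components.
#' @param folds Number of folds (default 7).
#' @param seed Seed for the fold assignment.
#' @return Q2 (a single number, at most 1).
#' @export
q2_oplsda <- function(X, y, n_ortho = 1, folds = 7, seed = 1L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  press <- 0
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 3) next
    fit <- fit_oplsda(X[tr, , drop = FALSE], y[tr], n_ortho)
    pr <- predict(fit, X[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - pr$y_hat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Per-feature Wilcoxon-Mann-Whitney tests with FDR correction
#'
#' Two-sided rank-sum test per feature between two study groups
#' (tie-corrected; exact for small untied samples, normal approximation
#' otherwise), Benjamini-Hochberg q-values across the features of the
#' comparison, and fold change as the ratio of raw-scale group medians
#' (second group over first).
#'
#' @param table An analysis-ready (collapsed, imputed) feature table.
#' @param groups Length-2 character vector, e.g. `c("HC", "RA")`; fold
#'   change and test direction are group 2 relative to group 1.
#' @return A tibble with `feature_id`, `p_value`, `q_value`, `fold_change`.
#' @export
univariate_test <- function(table, groups) {
  assert_feature_table(table)
  if (length(groups) != 2) abort("`groups` must name exactly two groups")
  g1 <- table$group == groups[1]
  g2 <- table$group == groups[2]
  if (sum(g1) < 2 || sum(g2) < 2) abort("each group needs at least 2 samples")
  fc <- feature_cols(table)
  res <- purrr::map(fc, function(f) {
    x1 <- table[[f]][g1]; x2 <- table[[f]][g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      return(tibble::tibble(feature_id = f, p_value = NA_real_,
                            fold_change = NA_real_))
    }
    p <- if (sd(c(x1, x2)) < .Machine$double.eps) {
      1
    } else {
      suppressWarnings(wilcox.test(x2, x1, alternative = "two.sided")$p.value)
    }
    tibble::tibble(feature_id = f, p_value = p,
                   fold_change = median(x2) / median(x1))
  }) |> purrr::list_rbind()
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res[, c("feature_id", "p_value", "q_value", "fold_change")]
}

#' Differential analysis of one pairwise comparison
#'
#' The full per-comparison workflow: restrict to the two groups,
#' log-transform and Pareto-scale, fit OPLS-DA on that comparison's
#' samples, compute VIP scores, run per-feature Wilcoxon tests with BH
#' correction, and apply the selection rule (default: VIP > 1 and
#' FDR q < 0.05, both strict).
#'
#' @param table Analysis-ready feature table (all groups).
#' @param groups Length-2 character vector of groups to compare.
#' @param n_ortho Orthogonal OPLS-DA components (default 1).
#' @param mode `"fdr"` (default) thresholds the BH q-value; `"raw"`
#'   thresholds the unadjusted p-value.
#' @param alpha Significance threshold (default 0.05, strict).
#' @param vip_threshold VIP threshold (default 1, strict).
#' @return A `metab_diff` tibble with per-feature `p_value`, `q_value`,
#'   `fold_change`, `vip`, `selected`; the fitted `opls_model` is attached
#'   as attribute `"opls"`.
#' @export
differential_analysis <- function(table, groups, n_ortho = 1,
                                  mode = c("fdr", "raw"), alpha = 0.05,
                                  vip_threshold = 1) {
  mode <- match.arg(mode)
  sub <- table[table$group %in% groups, , drop = FALSE]
  X <- log_pareto(sub)
  y <- as.numeric(sub$group == groups[2])
  model <- fit_oplsda(X, y, n_ortho = n_ortho)
  vip <- vip_scores(model)
  uni <- univariate_test(sub, groups)
  res <- uni |>
    dplyr::mutate(vip = unname(vip[.data$feature_id]))
  res <- select_features(res, mode = mode, alpha = alpha,
                         vip_threshold = vip_threshold)
  attr(res, "opls") <- model
  attr(res, "comparison") <- groups
  class(res) <- c("metab_diff", class(res))
  res
}

#' Apply the VIP / significance selection rule
#'
#' Flags features with VIP strictly above `vip_threshold` and q-value
#' (or raw p-value in `"raw"` mode) strictly below `alpha`.
#'
#' @param diff Tibble with columns `feature_id`, `p_value`, `q_value`;
#'   VIP either as a `vip` column or supplied separately.
#' @param vip Optional named numeric vector of VIP scores aligned to
#'   `diff$feature_id`.
#' @param mode `"fdr"` or `"raw"`.
#' @param alpha Significance threshold (strict).
#' @param vip_threshold VIP threshold (strict).
#' @return `diff` with a logical `selected` column.
#' @export
select_features <- function(diff, vip = NULL, mode = c("fdr", "raw"),
                            alpha = 0.05, vip_threshold = 1) {
  mode <- match.arg(mode)
  if (!is.null(vip)) {
    if (is.null(names(vip)) || !setequal(names(vip), diff$feature_id)) {
      abort("`vip` must be named by exactly the features of `diff`")
    }
    diff$vip <- unname(vip[diff$feature_id])
  }
  if (!"vip" %in% names(diff)) abort("no VIP scores available")
  crit <- if (mode == "fdr") diff$q_value else diff$p_value
  diff$selected <- !is.na(crit) & !is.na(diff$vip) &
    diff$vip > vip_threshold & crit < alpha
  diff
}

#' @export
tidy.metab_diff <- function(x, ...) {
  out <- x
  attr(out, "opls") <- NULL
  attr(out, "comparison") <- NULL
  class(out) <- setdiff(class(out), "metab_diff")
  out
}

#' @export
glance.metab_diff <- function(x, ...) {
  groups <- attr(x, "comparison")
  tibble::tibble(comparison = paste(groups, collapse = " vs "),
                 n_features = nrow(x), n_selected = sum(x$selected),
                 r2y = glance(attr(x, "opls"))$r2y)
}

#' Volcano-style plot of a differential result
#'
#' @param object A `metab_diff` result.
#' @param ... Unused.
#' @return A ggplot object (log2 fold change vs -log10 q, VIP as size,
#'   selected features highlighted).
#' @export
autoplot.metab_diff <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$q_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected,
                                     size = .data$vip), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR q",
                  colour = "selected", size = "VIP") +
    ggplot2::theme_minimal()
}
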