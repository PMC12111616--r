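# Clinical/demographic group statistics (Table-1 machinery).

as_group_list <- function(values, groups = NULL) {
  if (is.data.frame(values)) {
    values <- split(values[[1]], values[[2]])
  }
  if (!is.list(values)) abort("`values` must be a named list of group samples")
  if (!is.null(groups)) values <- values[groups]
  values <- lapply(values, function(x) x[!is.na(x)])
  values
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1
#' degrees of freedom (delegates to `stats::kruskal.test`). If every
#' observation is identical the statistic is 0 and p = 1, with a warning.
#'
#' @param values Named list of per-group numeric vectors (or a two-column
#'   data frame of value, group).
#' @return One-row tibble with `h`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values) {
  values <- as_group_list(values)
  if (length(values) < 2) abort("need at least 2 groups")
  if (any(lengths(values) < 2)) abort("each group needs at least 2 observations")
  pooled <- unlist(values, use.names = FALSE)
  if (sd(pooled) < .Machine$double.eps) {
    warn("all observations identical; H = 0, p = 1")
    return(tibble::tibble(h = 0, df = length(values) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values)
  tibble::tibble(h = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn's post-hoc test
#'
#' Pairwise mean-rank comparisons after a Kruskal-Wallis test:
#' `z = (mean rank_i - mean rank_j) / SE` with the tie-corrected
#' `SE = sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided normal
#' p-values, optionally Bonferroni-adjusted over the pairs.
#'
#' @param values Named list of per-group numeric vectors.
#' @param adjust `"none"` or `"bonferroni"`.
#' @return Tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  values <- as_group_list(values)
  if (length(values) < 2) abort("need at least 2 groups")
  if (any(lengths(values) < 2)) abort("Dunn's test needs >= 2 observations per group")
  g <- rep(names(values), lengths(values))
  x <- unlist(values, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  sizes <- lengths(values)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(values), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  }) |> purrr::list_rbind()
  res$p_adj <- if (adjust == "bonferroni") {
    pmin(1, res$p_value * nrow(res))
  } else {
    res$p_value
  }
  res
}

# log-probability of an r x c table under fixed margins (multivariate
# hypergeometric)
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

# enumerate all non-negative integer tables with the given margins,
# returning their log-probabilities
all_table_probs <- function(row_margin, col_margin) {
  r <- length(row_margin); cc <- length(col_margin)
  row_margin <- as.integer(row_margin)
  col_margin <- as.integer(col_margin)
  probs <- numeric(0)
  cell <- matrix(0L, r, cc)
  rec <- function(i, j, row_left, col_left) {
    if (i == r) {
      # last row fully determined by the column remainders
      cell[r, ] <<- col_left
      probs[length(probs) + 1L] <<- log_table_prob(cell)
      return(invisible())
    }
    if (j == cc) {
      # last cell of a row determined by the row remainder
      if (row_left > col_left[j]) return(invisible())
      cell[i, j] <<- row_left
      cl <- col_left; cl[j] <- cl[j] - row_left
      rec(i + 1L, 1L, row_margin[i + 1L], cl)
      return(invisible())
    }
    hi <- min(row_left, col_left[j])
    for (v in 0:hi) {
      cell[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      rec(i, j + 1L, row_left - v, cl)
    }
    invisible()
  }
  rec(1L, 1L, row_margin[1L], col_margin)
  probs
}

#' Freeman-Halton (Fisher) exact test for an r x c table
#'
#' Two-sided exact test by complete enumeration of the tables sharing the
#' observed margins: the p-value is the total probability of tables whose
#' hypergeometric probability does not exceed the observed table's
#' (within a small relative tolerance for floating-point ties), the
#' convention of mainstream statistical software. Enumeration is intended
#' for small tables (up to 3 rows and 3 columns).
#'
#' @param table Matrix of non-negative integer counts.
#' @return One-row tibble with `p_value` and the observed table's
#'   probability `p_table`.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (nrow(m) > 3 || ncol(m) > 3) {
    abort("exact enumeration supports tables up to 3 x 3")
  }
  rm_ <- rowSums(m); cm_ <- colSums(m)
  if (any(rm_ == 0) || any(cm_ == 0)) {
    warn("zero margin; p = 1")
    return(tibble::tibble(p_value = 1, p_table = 1))
  }
  lp_obs <- log_table_prob(m)
  lp_all <- all_table_probs(rm_, cm_)
  p <- sum(exp(lp_all[lp_all <= lp_obs + 1e-7]))
  tibble::tibble(p_value = min(1, p), p_table = exp(lp_obs))
}

#' Clinical-table group comparison
#'
#' Builds a Table-1-style summary from sample metadata: numeric variables
#' as median (IQR) per group with a Kruskal-Wallis p-value and Dunn
#' pairwise flags; categorical variables as counts with a Freeman-Halton
#' Fisher exact p-value.
#'
#' @param metadata Metadata tibble with a `group` column.
#' @param numeric_vars Character vector of numeric column names.
#' @param categorical_vars Character vector of categorical column names.
#' @param groups Groups to compare (default the biological groups present).
#' @return Tibble with one row per variable: per-group `median [IQR]` (or
#'   counts), the overall p-value, and significant Dunn pairs.
#' @export
group_comparison <- function(metadata, numeric_vars = character(),
                             categorical_vars = character(),
                             groups = NULL) {
  groups <- groups %||% intersect(BIO_GROUPS, unique(metadata$group))
  md <- metadata[metadata$group %in% groups, ]
  rows <- list()
  for (v in numeric_vars) {
    vals <- as_group_list(split(md[[v]], md$group)[groups])
    vals <- vals[lengths(vals) >= 2]
    summ <- vapply(groups, function(g) {
      x <- md[[v]][md$group == g]
      x <- x[!is.na(x)]
      if (length(x) == 0) return("-")
      sprintf("%.3g [%.3g-%.3g]", median(x), quantile(x, 0.25),
              quantile(x, 0.75))
    }, character(1))
    if (length(vals) >= 2) {
      kw <- kruskal_wallis(vals)
      dn <- dunn_test(vals)
      flags <- paste(dn$group1[dn$p_value < 0.05], dn$group2[dn$p_value < 0.05],
                     sep = "-", collapse = "; ")
      p <- kw$p_value
    } else {
      flags <- ""
      p <- NA_real_
    }
    rows[[v]] <- tibble::tibble(
      variable = v, type = "numeric",
      !!!setNames(as.list(summ), groups),
      p_value = p, significant_pairs = flags
    )
  }
  for (v in categorical_vars) {
    tab <- table(md$group, md[[v]])
    tab <- tab[intersect(groups, rownames(tab)), , drop = FALSE]
    p <- if (all(dim(tab) >= 2)) fisher_exact(tab)$p_value else NA_real_
    counts <- vapply(groups, function(g) {
      if (!g %in% rownames(tab)) return("-")
      paste(paste0(colnames(tab), ": ", tab[g, ]), collapse = ", ")
    }, character(1))
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      !!!setNames(as.list(counts), groups),
      p_value = p, significant_pairs = ""
    )
  }
  purrr::list_rbind(rows)
}
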