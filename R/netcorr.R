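# Metabolite-cytokine / metabolite-HDL Spearman correlation networks.

#' Spearman rank correlation with significance
#'
#' Average-rank tie handling; two-sided p-value by exact permutation null
#' for n <= 9 untied pairs and by the t-approximation otherwise. Pairs
#' with missing values are dropped.
#'
#' @param x,y Paired numeric vectors (>= 4 complete pairs).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps) {
    abort("correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Variables entering a disease correlation network
#'
#' Assembles the node panel: metabolites differential for the comparison
#' (FDR q < 0.05 by default, i.e. the `selected` flag of the differential
#' result), plus either the disease's cytokine panel, HDL alone, or the
#' clinical variable set (HDL, LDL, total cholesterol, ESR, lymphocyte and
#' neutrophil counts, disease duration and the activity score).
#'
#' @param diff A `metab_diff` result for the disease vs HC comparison.
#' @param disease `"RA"` or `"SLE"`.
#' @param targets `"cytokines"`, `"hdl"`, or `"clinical"`.
#' @return A `node_panel` list with `metabolites`, `covariates`, `disease`.
#' @export
node_panel <- function(diff, disease = c("RA", "SLE"),
                       targets = c("cytokines", "hdl", "clinical")) {
  disease <- match.arg(disease)
  targets <- match.arg(targets)
  mets <- unique(diff$feature_id[diff$selected])
  covs <- switch(targets,
    cytokines = if (disease == "RA") ra_cytokine_panel() else sle_cytokine_panel(),
    hdl = "hdl",
    clinical = CLINICAL_VARS
  )
  structure(list(metabolites = mets, covariates = covs, disease = disease,
                 targets = targets),
            class = "node_panel")
}

#' Build a disease correlation network
#'
#' Computes all pairwise Spearman correlations among the panel variables
#' over the disease-group samples only, keeps an edge wherever p < `alpha`
#' (raw p, as in the underlying analysis), records the sign, builds the
#' correlation distance `d = 1 - |rho|` over significant edges, completes
#' it to geodesics with the Floyd-Warshall algorithm, and embeds the nodes
#' in 2D by classical multidimensional scaling of the geodesic matrix
#' (disconnected pairs are placed at 1.5x the largest finite geodesic for
#' the embedding only).
#'
#' @param table Analysis-ready feature table (for metabolite intensities).
#' @param metadata Metadata tibble with cytokine/clinical columns.
#' @param panel A [node_panel()] (or a list with `metabolites`,
#'   `covariates`, `disease`).
#' @param alpha Edge significance level (default 0.05).
#' @param distance `"abs"` (default) uses `1 - |rho|`; `"signed"` uses
#'   `1 - rho`.
#' @return A `corr_network` object: `nodes`, `edges`, `dist`, `geodesic`,
#'   `layout`, `stress`, `alpha`.
#' @export
build_network <- function(table, metadata, panel, alpha = 0.05,
                          distance = c("abs", "signed")) {
  distance <- match.arg(distance)
  disease <- panel$disease
  samp <- metadata$sample_id[metadata$group == disease]
  sub <- table[table$sample_id %in% samp & bio_rows(table), ]
  if (nrow(sub) < 4) abort("fewer than 4 disease-group samples")
  missing_met <- setdiff(panel$metabolites, feature_cols(table))
  if (length(missing_met) > 0) {
    abort(paste0("metabolites absent from table: ",
                 paste(missing_met, collapse = ", ")))
  }
  missing_cov <- setdiff(panel$covariates, names(metadata))
  if (length(missing_cov) > 0) {
    abort(paste0("covariates absent from metadata: ",
                 paste(missing_cov, collapse = ", ")))
  }
  md <- metadata[match(sub$sample_id, metadata$sample_id), ]
  dat <- cbind(
    as.data.frame(intensity_matrix(sub, panel$metabolites)),
    as.data.frame(md[, panel$covariates, drop = FALSE])
  )
  types <- c(rep("metabolite", length(panel$metabolites)),
             ifelse(panel$covariates %in% all_cytokines(),
                    "cytokine", "clinical"))
  const <- vapply(dat, function(x) sd(x, na.rm = TRUE) < .Machine$double.eps ||
                    sum(!is.na(x)) < 4, logical(1))
  if (any(const)) {
    warn(paste0("dropping constant/insufficient variable(s): ",
                paste(names(dat)[const], collapse = ", ")))
    dat <- dat[, !const, drop = FALSE]
    types <- types[!const]
  }
  vars <- names(dat)
  nv <- length(vars)
  nodes <- tibble::tibble(name = vars, type = types)
  edges <- list()
  for (i in seq_len(max(0, nv - 1))) {
    for (j in (i + 1):nv) {
      sc <- spearman_cor(dat[[i]], dat[[j]])
      if (!is.na(sc$p_value) && sc$p_value < alpha) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          from = vars[i], to = vars[j], rho = sc$rho, p_value = sc$p_value,
          sign = ifelse(sc$rho >= 0, "positive", "negative")
        )
      }
    }
  }
  edges <- if (length(edges)) purrr::list_rbind(edges) else
    tibble::tibble(from = character(), to = character(), rho = numeric(),
                   p_value = numeric(), sign = character())
  net <- structure(
    list(nodes = nodes, edges = edges, disease = disease, alpha = alpha,
         distance = distance),
    class = "corr_network"
  )
  net$dist <- correlation_distance(net)
  net$geodesic <- floyd_warshall(net$dist)
  emb <- mds_layout(net$geodesic)
  net$layout <- emb$coordinates
  net$stress <- emb$stress
  net
}

#' @export
print.corr_network <- function(x, ...) {
  cat("<corr_network> ", x$disease, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (p < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.corr_network <- function(x, ...) x$edges

#' @export
glance.corr_network <- function(x, ...) {
  deg <- node_degree(x)
  tibble::tibble(disease = x$disease, n_nodes = nrow(x$nodes),
                 n_edges = nrow(x$edges),
                 prop_negative = if (nrow(x$edges)) mean(x$edges$sign == "negative") else NA_real_,
                 max_degree_node = if (length(deg)) names(which.max(deg)) else NA_character_,
                 stress = x$stress)
}

#' Node degrees of a correlation network
#'
#' @param network A `corr_network`.
#' @return Named integer vector (every node, zero degrees included).
#' @export
node_degree <- function(network) {
  deg <- setNames(rep(0L, nrow(network$nodes)), network$nodes$name)
  tab <- table(c(network$edges$from, network$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Correlation distance matrix of a network
#'
#' Significant (connected) pairs get `d = 1 - |rho|` (or `1 - rho` in
#' signed mode, rescaled to \[0, 1\]); non-significant pairs are `Inf`
#' (no direct edge) until shortest-path completion. The sign of each
#' correlation stays on the edge attribute, not in the metric.
#'
#' @param network A `corr_network`.
#' @return Symmetric matrix with zero diagonal.
#' @export
correlation_distance <- function(network) {
  vars <- network$nodes$name
  d <- matrix(Inf, length(vars), length(vars), dimnames = list(vars, vars))
  diag(d) <- 0
  e <- network$edges
  if (nrow(e)) {
    val <- if (identical(network$distance, "signed")) {
      (1 - e$rho) / 2
    } else {
      1 - abs(e$rho)
    }
    for (k in seq_len(nrow(e))) {
      d[e$from[k], e$to[k]] <- d[e$to[k], e$from[k]] <- val[k]
    }
  }
  d
}

#' All-pairs shortest paths (Floyd-Warshall)
#'
#' Dynamic-programming completion of a non-negative distance matrix to
#' geodesic distances; disconnected pairs remain `Inf`.
#'
#' @param dist Square matrix of non-negative weights (`Inf` = no edge).
#' @return Geodesic distance matrix.
#' @export
floyd_warshall <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) abort("`dist` must be square")
  if (any(d < 0, na.rm = TRUE)) abort("negative weights are not allowed")
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

#' Classical MDS embedding of a geodesic matrix
#'
#' Torgerson double-centering eigendecomposition to 2 dimensions.
#' `Inf` entries (disconnected pairs) are replaced by 1.5x the largest
#' finite distance before embedding. Kruskal-type stress
#' (`sqrt(sum((d - d_hat)^2) / sum(d^2))`) is reported.
#'
#' @param geodesic Symmetric hollow distance matrix.
#' @return List with `coordinates` (n x 2) and `stress`.
#' @export
mds_layout <- function(geodesic) {
  d <- as.matrix(geodesic)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("`geodesic` must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("`geodesic` must have a zero diagonal")
  n <- nrow(d)
  if (n == 1) {
    return(list(coordinates = matrix(0, 1, 2,
                                     dimnames = list(rownames(d), NULL)),
                stress = 0))
  }
  finite <- d[is.finite(d) & d > 0]
  if (any(!is.finite(d))) {
    pen <- if (length(finite)) 1.5 * max(finite) else 1
    d[!is.finite(d)] <- pen
  }
  xy <- cmdscale(as.dist(d), k = min(2, n - 1))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  rownames(xy) <- rownames(d)
  dhat <- as.matrix(stats::dist(xy))
  stress <- sqrt(sum((d - dhat)^2) / max(sum(d^2), .Machine$double.eps))
  list(coordinates = xy, stress = stress)
}

#' Plot a correlation network
#'
#' Nodes at their MDS coordinates, positive edges blue and negative edges
#' red, node shape by variable type.
#'
#' @param object A `corr_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corr_network <- function(object, ...) {
  lay <- tibble::tibble(name = rownames(object$layout),
                        x = object$layout[, 1], y = object$layout[, 2]) |>
    dplyr::left_join(object$nodes, by = "name")
  e <- object$edges
  seg <- if (nrow(e)) {
    e |>
      dplyr::left_join(lay[, c("name", "x", "y")], by = c(from = "name")) |>
      dplyr::left_join(lay[, c("name", "x", "y")], by = c(to = "name"),
                       suffix = c("", "_to"))
  } else {
    NULL
  }
  p <- ggplot2::ggplot(lay, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$x_to, yend = .data$y_to,
                   colour = .data$sign),
      alpha = 0.6
    ) +
      ggplot2::scale_colour_manual(values = c(positive = "steelblue",
                                              negative = "firebrick"))
  }
  p + ggplot2::geom_point(ggplot2::aes(shape = .data$type), size = 3) +
    ggplot2::labs(colour = "correlation", shape = "node type",
                  x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}
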