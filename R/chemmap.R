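# Chemical-similarity clustering, module detection and WMCSA summarization.

#' Structural fingerprints from SMILES
#'
#' Computes deterministic 1024-bit hashed path-based structural
#' fingerprints (OpenBabel FP2 via ChemmineOB) for a vector of SMILES
#' strings. Unparseable SMILES are flagged with a warning and returned as
#' all-NA rows so the caller can exclude them from mapping.
#'
#' @param smiles Character vector of SMILES.
#' @param n_bits Fingerprint length; must divide 1024. Shorter lengths are
#'   produced by OR-folding the 1024-bit vector.
#' @return Integer matrix (molecules x bits) of 0/1, NA rows for failures;
#'   row names follow `names(smiles)` when present.
#' @export
fingerprint <- function(smiles, n_bits = 1024) {
  n_bits <- assert_count(n_bits, "n_bits")
  if (1024 %% n_bits != 0) abort("`n_bits` must divide 1024")
  out <- matrix(NA_integer_, length(smiles), 1024)
  ok <- !is.na(smiles) & nzchar(smiles)
  fp_one <- function(smi) {
    tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
      fpset <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "FP2"))
      m <- fpset@fpma
      if (ncol(m) != 1024) stop("unexpected fingerprint length")
      matrix(as.integer(m > 0), nrow = nrow(m))
    }, error = function(e) NULL)
  }
  if (any(ok)) {
    # one batch call when every SMILES parses; per-molecule fallback so a
    # single bad structure does not take the whole panel down
    batch <- fp_one(smiles[ok])
    if (!is.null(batch) && nrow(batch) == sum(ok)) {
      out[ok, ] <- batch
    } else {
      fps <- lapply(which(ok), function(i) fp_one(smiles[i]))
      failed <- vapply(fps, is.null, logical(1))
      if (any(failed)) {
        warn(paste0(sum(failed), " SMILES could not be parsed; ",
                    "affected metabolites are excluded from chemical mapping"))
      }
      for (k in seq_along(fps)) {
        if (!is.null(fps[[k]])) out[which(ok)[k], ] <- fps[[k]][1, ]
      }
    }
  }
  if (n_bits < 1024) {
    fold <- matrix(0L, length(smiles), n_bits)
    for (b in seq_len(1024 / n_bits)) {
      blk <- out[, ((b - 1) * n_bits + 1):(b * n_bits), drop = FALSE]
      fold <- pmax(fold, blk)
    }
    out <- fold
  }
  rownames(out) <- names(smiles)
  out
}

#' Tanimoto similarity of two fingerprint bit vectors
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors count as identical
#' (similarity 1).
#'
#' @param a,b Integer/logical bit vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) abort("fingerprints differ in length")
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Pairwise Tanimoto distance matrix
#'
#' `1 - Tanimoto` over all fingerprint pairs; rows with NA fingerprints are
#' dropped.
#'
#' @param fp Fingerprint matrix from [fingerprint()].
#' @return Symmetric distance matrix with zero diagonal, values in \[0, 1\].
#' @export
tanimoto_distance <- function(fp) {
  keep <- !apply(fp, 1, anyNA)
  fp <- fp[keep, , drop = FALSE] > 0
  inter <- tcrossprod(fp * 1)
  n_on <- rowSums(fp)
  un <- outer(n_on, n_on, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1))
  d <- 1 - sim
  diag(d) <- 0
  d
}

#' Cluster metabolites by chemical similarity
#'
#' Ward-linkage hierarchical clustering of a Tanimoto distance matrix,
#' cutting at the number of clusters that maximizes the mean silhouette
#' width over `k_range` (smallest K on ties). A degenerate input where all
#' molecules are identical yields a single cluster with a warning. Also
#' computes a classical-MDS 2D layout of the metabolites.
#'
#' @param dist Symmetric distance matrix, zero diagonal (e.g. from
#'   [tanimoto_distance()]).
#' @param k_range Candidate cluster counts (default 2:10).
#' @return A `chem_clusters` object: `tree`, `k`, `clusters` (named
#'   integer vector), `silhouette` (mean width per candidate K), `layout`,
#'   `dist`.
#' @export
detect_clusters <- function(dist, k_range = 2:10) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) abort("`dist` must be symmetric")
  if (any(abs(diag(dist)) > 1e-12)) abort("`dist` must have a zero diagonal")
  n <- nrow(dist)
  ids <- rownames(dist) %||% paste0("x", seq_len(n))
  rownames(dist) <- colnames(dist) <- ids
  tree <- hclust(as.dist(dist), method = "ward.D2")
  if (all(dist < 1e-12)) {
    warn("all pairwise distances are zero; returning a single cluster")
    cl <- setNames(rep(1L, n), ids)
    return(structure(list(tree = tree, k = 1L, clusters = cl,
                          silhouette = tibble::tibble(k = integer(),
                                                      mean_width = numeric()),
                          layout = matrix(0, n, 2, dimnames = list(ids, NULL)),
                          dist = dist),
                     class = "chem_clusters"))
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  sil <- purrr::map_dbl(k_range, function(k) {
    ct <- cutree(tree, k)
    if (length(unique(ct)) < 2) return(NA_real_)
    mean(cluster::silhouette(ct, dmatrix = dist)[, "sil_width"])
  })
  best <- k_range[which.max(sil)] # which.max takes the first (smallest K) tie
  cl <- cutree(tree, best)
  names(cl) <- ids
  lay <- cmdscale(as.dist(dist), k = 2)
  if (ncol(lay) < 2) lay <- cbind(lay, 0)
  rownames(lay) <- ids
  structure(
    list(tree = tree, k = best, clusters = cl,
         silhouette = tibble::tibble(k = k_range, mean_width = sil),
         layout = lay, dist = dist),
    class = "chem_clusters"
  )
}

#' @export
print.chem_clusters <- function(x, ...) {
  cat("<chem_clusters> ", length(x$clusters), " metabolites in ", x$k,
      " cluster(s)", if (!is.null(x$modules))
        paste0(", ", length(unique(x$modules)), " modules"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.chem_clusters <- function(x, ...) {
  tibble::tibble(
    feature_id = names(x$clusters),
    cluster = unname(x$clusters),
    module = if (is.null(x$modules)) NA_character_ else
      unname(x$modules[names(x$clusters)]),
    dim1 = x$layout[, 1], dim2 = x$layout[, 2]
  )
}

#' Plot a chemical clustering in 2D
#'
#' @param object A `chem_clusters` object.
#' @param ... Unused.
#' @return A ggplot of the MDS layout coloured by cluster.
#' @export
autoplot.chem_clusters <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(colour = "cluster", x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Split clusters into chemically coherent modules
#'
#' Refines each cluster into modules by cutting its own Ward subtree,
#' choosing the number of sub-branches that maximizes the mean silhouette
#' width among cuts whose smallest module still has `min_size` members
#' (a cluster too small to split stays a single module). Modules therefore
#' always partition the metabolite set and refine the clusters.
#'
#' @param clustering A `chem_clusters` object.
#' @param min_size Minimum module size (default 3; must be >= 2).
#' @return The `chem_clusters` object with a `modules` character vector
#'   added (named by metabolite, values like `"c1.m2"`).
#' @export
split_modules <- function(clustering, min_size = 3) {
  if (!inherits(clustering, "chem_clusters")) {
    abort("`clustering` must come from detect_clusters()")
  }
  if (min_size < 2) abort("`min_size` must be at least 2")
  cl <- clustering$clusters
  d <- clustering$dist
  modules <- setNames(rep(NA_character_, length(cl)), names(cl))
  for (c_id in sort(unique(cl))) {
    members <- names(cl)[cl == c_id]
    n <- length(members)
    k_max <- n %/% min_size
    if (k_max < 2) {
      modules[members] <- paste0("c", c_id, ".m1")
      next
    }
    sub_d <- d[members, members, drop = FALSE]
    sub_tree <- hclust(as.dist(sub_d), method = "ward.D2")
    best_k <- 1L
    best_sil <- -Inf
    for (k in 2:min(k_max, 10L)) {
      ct <- cutree(sub_tree, k)
      if (min(table(ct)) < min_size || length(unique(ct)) < 2) next
      s <- mean(cluster::silhouette(ct, dmatrix = sub_d)[, "sil_width"])
      if (s > best_sil + 1e-12) {
        best_sil <- s
        best_k <- k
      }
    }
    ct <- if (best_k == 1L) setNames(rep(1L, n), members)
          else cutree(sub_tree, best_k)
    modules[members] <- paste0("c", c_id, ".m", ct[members])
  }
  clustering$modules <- modules
  clustering
}

#' Weighted module summarization (WMCSA)
#'
#' Summarizes the abundances of each chemically coherent module into one
#' per-sample score: the first principal component of the standardized
#' log-abundance submatrix of the module's members, sign-oriented to
#' correlate positively with the members' mean profile and standardized to
#' zero mean / unit variance. Size-1 modules pass the standardized feature
#' through. As a first principal component, the summary explains at least
#' as much member variance as any single member's standardized profile.
#'
#' @param table Analysis-ready feature table (collapsed, imputed).
#' @param modules Named character vector mapping feature id to module (from
#'   [split_modules()]; features absent from the table are ignored).
#' @return A `wmcsa_summary` object: `scores` (tibble sample x module),
#'   `members` (list), `orientation` (named sign vector), `var_explained`.
#' @export
wmcsa <- function(table, modules) {
  assert_feature_table(table)
  if (inherits(modules, "chem_clusters")) modules <- modules$modules
  if (is.null(modules)) abort("run split_modules() first")
  modules <- modules[names(modules) %in% feature_cols(table)]
  if (length(modules) == 0) abort("no module features present in table")
  bio <- table[bio_rows(table), ]
  scores <- tibble::tibble(sample_id = bio$sample_id, group = bio$group)
  members <- list()
  orientation <- numeric(0)
  var_explained <- numeric(0)
  for (m in sort(unique(modules))) {
    ids <- names(modules)[modules == m]
    Z <- log(intensity_matrix(bio, ids))
    sds <- apply(Z, 2, sd)
    if (all(sds < .Machine$double.eps)) {
      abort(paste0("module ", m, " has only zero-variance members"))
    }
    keep <- sds >= .Machine$double.eps
    Z <- scale(Z[, keep, drop = FALSE])
    if (ncol(Z) == 1) {
      sc <- drop(Z)
      ve <- 1
    } else {
      pc <- prcomp(Z, center = FALSE, scale. = FALSE)
      sc <- pc$x[, 1]
      ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    s <- cor(sc, rowMeans(Z))
    sgn <- if (!is.na(s) && s < 0) -1 else 1
    sc <- sgn * sc
    sc <- (sc - mean(sc)) / sd(sc)
    scores[[m]] <- sc
    members[[m]] <- ids
    orientation[m] <- sgn
    var_explained[m] <- ve
  }
  structure(list(scores = scores, members = members,
                 orientation = orientation, var_explained = var_explained),
            class = "wmcsa_summary")
}

#' @export
print.wmcsa_summary <- function(x, ...) {
  cat("<wmcsa_summary> ", length(x$members), " modules, ",
      nrow(x$scores), " samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.wmcsa_summary <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-c("sample_id", "group"),
                        names_to = "module", values_to = "score")
}

#' Kruskal-Wallis / Dunn group comparison of module summaries
#'
#' For each module summary score: Kruskal-Wallis H and p across the study
#' groups, then pairwise Dunn z tests (tie-corrected) with Bonferroni
#' adjustment over the pairwise comparisons.
#'
#' @param summary A `wmcsa_summary`.
#' @param groups Optional character vector restricting/ordering the groups
#'   (default: all groups present).
#' @return Long tibble: one row per module x group pair with `kw_h`,
#'   `kw_p`, `dunn_z`, `dunn_p`, `dunn_p_adj`.
#' @export
module_group_tests <- function(summary, groups = NULL) {
  if (!inherits(summary, "wmcsa_summary")) abort("need a wmcsa_summary")
  sc <- summary$scores
  groups <- groups %||% intersect(BIO_GROUPS, unique(sc$group))
  if (length(groups) < 2) abort("need at least 2 groups")
  sc <- sc[sc$group %in% groups, ]
  if (min(table(sc$group)) < 2) abort("each group needs at least 2 samples")
  purrr::map(names(summary$members), function(m) {
    vals <- split(sc[[m]], sc$group)[groups]
    kw <- kruskal_wallis(vals)
    dn <- dunn_test(vals, adjust = "bonferroni")
    dn$module <- m
    dn$kw_h <- kw$h
    dn$kw_p <- kw$p_value
    dn
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("module")
}
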