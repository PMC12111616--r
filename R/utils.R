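# Shared internal helpers for feature tables.
#
# A feature table is a tibble with one row per injection and the metadata
# columns below followed by one numeric column per metabolite feature.
# Biological samples appear once per platform they were run on; pooled-QC
# injections carry group "QC".

META_COLS <- c("sample_id", "group", "injection_order", "platform")

BIO_GROUPS <- c("HC", "RA", "SLE")

#' Names of the feature (intensity) columns of a feature table
#'
#' @param table A feature table tibble.
#' @return Character vector of feature ids.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), META_COLS)
}

assert_feature_table <- function(table, call = rlang::caller_env()) {
  missing <- setdiff(META_COLS, names(table))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  bad <- setdiff(unique(table$group), c(BIO_GROUPS, "QC"))
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")),
          call = call)
  }
  dup <- table |>
    dplyr::count(.data$sample_id, .data$platform) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated sample id within a platform: ",
                 paste(dup$sample_id, collapse = ", ")), call = call)
  }
  invisible(table)
}

# intensity sub-matrix (rows in table order), features optionally restricted
intensity_matrix <- function(table, features = NULL) {
  features <- features %||% feature_cols(table)
  m <- as.matrix(table[, features, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

bio_rows <- function(table) table$group != "QC"

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x != as.integer(x) || x < min) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

assert_prob <- function(x, name, strict_upper = TRUE) {
  ok <- length(x) == 1 && is.finite(x) && x >= 0 &&
    (if (strict_upper) x < 1 else x <= 1)
  if (!ok) abort(paste0("`", name, "` must be in [0, 1", if (strict_upper) ")" else "]"))
  as.numeric(x)
}
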