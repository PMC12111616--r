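# Reading and writing the pipeline's plain-text table formats.
#
# All three tables are UTF-8 CSV with a header row; missing cells are
# empty or "NA" on read and written as "NA".

#' Read a feature intensity table
#'
#' Expects columns `sample_id`, `group`, `injection_order`, `platform`
#' followed by one numeric column per feature. Validates group labels,
#' duplicate sample ids (per platform) and non-numeric intensities,
#' reporting the offending row/column.
#'
#' @param path CSV file path.
#' @return A feature table tibble.
#' @export
read_feature_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(META_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")))
  }
  fc <- setdiff(names(raw), META_COLS)
  out <- raw
  out$injection_order <- suppressWarnings(as.integer(raw$injection_order))
  for (f in fc) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(v) & !is.na(raw[[f]]))
    if (length(bad) > 0) {
      abort(paste0(path, ": non-numeric intensity at row ", bad[1],
                   ", column '", f, "' (value '", raw[[f]][bad[1]], "')"))
    }
    out[[f]] <- v
  }
  assert_feature_table(out)
  out
}

#' Read a sample metadata table
#'
#' Requires `sample_id` and `group`; clinical and cytokine columns are
#' read as numeric. Duplicate sample ids or unknown group labels are
#' errors naming the offender.
#'
#' @param path CSV file path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  for (col in c("sample_id", "group")) {
    if (!col %in% names(md)) abort(paste0(path, ": missing column ", col))
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(path, ": duplicated sample id: ", dup[1]))
  }
  bad <- setdiff(unique(md$group), BIO_GROUPS)
  if (length(bad) > 0) {
    abort(paste0(path, ": unknown group label(s): ",
                 paste(bad, collapse = ", ")))
  }
  md
}

#' Read a metabolite annotation table
#'
#' Requires `feature_id` and either `smiles` or `fp_bits` (a character
#' column of 0/1 strings). Ids must be unique.
#'
#' @param path CSV file path.
#' @return An annotation tibble.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  if (!"feature_id" %in% names(ann)) {
    abort(paste0(path, ": missing column feature_id"))
  }
  dup <- ann$feature_id[duplicated(ann$feature_id)]
  if (length(dup) > 0) abort(paste0(path, ": duplicated feature id: ", dup[1]))
  if (!any(c("smiles", "fp_bits") %in% names(ann))) {
    abort(paste0(path, ": need a 'smiles' or 'fp_bits' column"))
  }
  ann
}

#' Write the cohort tables
#'
#' @param x A tibble (feature table, metadata, or annotations).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, na = "NA")
  invisible(path)
}

#' Cross-validate the three cohort tables
#'
#' Checks that metadata covers every biological sample of the feature
#' table and that annotations cover every feature column.
#'
#' @param features Feature table.
#' @param metadata Metadata tibble.
#' @param annotations Annotation tibble.
#' @return Invisibly TRUE; aborts with the offending ids otherwise.
#' @export
validate_cohort_tables <- function(features, metadata, annotations) {
  bio <- unique(features$sample_id[bio_rows(features)])
  orphan <- setdiff(bio, metadata$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("samples without metadata: ",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  unann <- setdiff(feature_cols(features), annotations$feature_id)
  if (length(unann) > 0) {
    abort(paste0("features without annotation: ",
                 paste(head(unann, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Fingerprints from an annotation table
#'
#' Uses the `fp_bits` column (0/1 strings) when present, otherwise
#' computes path fingerprints from `smiles`.
#'
#' @param annotations Annotation tibble.
#' @param n_bits Fingerprint width (see [fingerprint()]).
#' @return Fingerprint matrix with feature ids as row names.
#' @export
annotation_fingerprints <- function(annotations, n_bits = 1024) {
  if ("fp_bits" %in% names(annotations) &&
      any(!is.na(annotations$fp_bits))) {
    rows <- lapply(annotations$fp_bits, function(s) {
      if (is.na(s)) return(NULL)
      as.integer(strsplit(s, "")[[1]])
    })
    len <- unique(lengths(rows[!vapply(rows, is.null, logical(1))]))
    if (length(len) != 1) abort("fp_bits strings differ in length")
    fp <- matrix(NA_integer_, nrow(annotations), len)
    for (i in seq_along(rows)) if (!is.null(rows[[i]])) fp[i, ] <- rows[[i]]
  } else {
    fp <- fingerprint(annotations$smiles, n_bits = n_bits)
  }
  rownames(fp) <- annotations$feature_id
  fp
}
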