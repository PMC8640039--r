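#' Read a feature-intensity table with its sample metadata
#'
#' Reads a features-by-samples intensity (or count) table and its companion
#' sample-metadata table, enforces the data-model invariants (unique ids,
#' non-negative values, every sample described by exactly one metadata row),
#' applies the missing-value policy, and puts the samples into the canonical
#' order (the metadata file order), so downstream results are deterministic.
#'
#' The table file is TSV (or CSV, by extension): the first column holds
#' feature ids, an optional `feature_name` column holds display names used
#' for cross-table matching, and every remaining column is one sample. The
#' metadata file has columns `sample_id` and `group`, plus optional
#' `compartment` (one of `diet`, `content`, `tissue`) and `ion_mode`
#' (`positive`, `negative` or `none`), which default to `"content"` and
#' `"none"`.
#'
#' @param path Path to the feature table (TSV/CSV; features in rows).
#' @param metadata_path Path to the sample metadata table.
#' @param missing Missing-cell policy: `"halfmin"` (default) imputes each
#'   missing cell with half the minimum positive value of that feature;
#'   `"drop"` removes any feature with a missing cell.
#' @return A list with elements `table` (tibble: `feature_id`, optional
#'   `feature_name`, one numeric column per sample) and `metadata` (tibble:
#'   `sample_id`, `group`, `compartment`, `ion_mode`), samples ordered as in
#'   the metadata file.
#' @examples
#' tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "m1\t1\t2", "m2\t3\t4"), tf)
#' writeLines(c("sample_id\tgroup", "s1\tFM", "s2\tSBM40"), mf)
#' read_feature_table(tf, mf)$table
#' @export
read_feature_table <- function(path, metadata_path, missing = c("halfmin", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("feature table not found: ", path))
  if (!file.exists(metadata_path)) abort(paste0("metadata not found: ", metadata_path))

  tab <- read_delim_auto(path)
  names(tab)[1] <- "feature_id"
  tab$feature_id <- as.character(tab$feature_id)
  if (anyDuplicated(tab$feature_id)) {
    abort(paste0("duplicate feature ids: ",
                 paste(unique(tab$feature_id[duplicated(tab$feature_id)]), collapse = ", ")))
  }

  metadata <- read_sample_metadata(metadata_path)
  value_cols <- sample_cols(tab)
  not_described <- setdiff(value_cols, metadata$sample_id)
  if (length(not_described) > 0) {
    abort(paste0("samples present in the table but missing from metadata: ",
                 paste(not_described, collapse = ", ")))
  }
  # non-numeric cells: readr will have left such a column as character
  for (cn in value_cols) {
    col <- tab[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "" & toupper(col) != "NA")
      if (length(bad) > 0) {
        abort(paste0("non-numeric value in column '", cn, "', feature '",
                     tab$feature_id[bad[1]], "': ", col[bad[1]]))
      }
      tab[[cn]] <- num
    }
  }

  metadata <- metadata[metadata$sample_id %in% value_cols, , drop = FALSE]
  ord <- metadata$sample_id
  keep <- intersect(c("feature_id", "feature_name"), names(tab))
  tab <- tab[, c(keep, ord), drop = FALSE]

  m <- ft_matrix(tab, ord)
  if (any(m < 0, na.rm = TRUE)) abort("negative values in feature table")
  if (anyNA(m)) {
    if (missing == "drop") {
      keep_rows <- rowSums(is.na(m)) == 0
      tab <- tab[keep_rows, , drop = FALSE]
    } else {
      for (i in which(rowSums(is.na(m)) > 0)) {
        pos <- m[i, !is.na(m[i, ]) & m[i, ] > 0]
        if (length(pos) == 0) {
          abort(paste0("feature ", rownames(m)[i],
                       " has missing cells but no positive value to impute from"))
        }
        m[i, is.na(m[i, ])] <- min(pos) / 2
      }
      tab[, ord] <- as.data.frame(m)
    }
  }
  list(table = tibble::as_tibble(tab), metadata = metadata)
}

#' Read a sample-metadata table
#'
#' @param path TSV/CSV with columns `sample_id`, `group`, and optional
#'   `compartment`, `ion_mode`.
#' @return A tibble with the four metadata columns; `group` keeps the file
#'   order as its factor-level (dose-ladder) order.
#' @export
read_sample_metadata <- function(path) {
  md <- read_delim_auto(path)
  need <- c("sample_id", "group")
  if (!all(need %in% names(md))) {
    abort("metadata must have columns 'sample_id' and 'group'")
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) abort("duplicate sample ids in metadata")
  if (!"compartment" %in% names(md)) md$compartment <- "content"
  if (!"ion_mode" %in% names(md)) md$ion_mode <- "none"
  md$group <- factor(md$group, levels = unique(as.character(md$group)))
  tibble::as_tibble(md[, c("sample_id", "group", "compartment", "ion_mode")])
}

#' Read a feature-to-pathway annotation map
#'
#' @param path TSV/CSV with two columns, feature id and pathway/category id.
#' @return A tibble with columns `feature_id` and `pathway_id`; duplicated
#'   pairs are collapsed. Empty pathway ids are an error.
#' @export
read_annotation_map <- function(path) {
  ann <- read_delim_auto(path)
  if (ncol(ann) < 2) abort("annotation map needs two columns: feature_id, pathway_id")
  names(ann)[1:2] <- c("feature_id", "pathway_id")
  ann <- tibble::as_tibble(ann[, 1:2])
  ann$feature_id <- as.character(ann$feature_id)
  ann$pathway_id <- as.character(ann$pathway_id)
  if (any(is.na(ann$pathway_id) | ann$pathway_id == "")) {
    abort("annotation map contains empty pathway ids")
  }
  dplyr::distinct(ann)
}

#' Write a result table to TSV
#'
#' Writes any tabular result with a header row; re-reading reproduces ids and
#' integers exactly and reals to full double precision.
#'
#' @param records A data frame (possibly zero-row; a header-only file is
#'   written then).
#' @param path Output path; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || ncol(records) == 0) {
    abort("`records` must be a data frame with at least one column")
  }
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)))
  }
  readr::write_tsv(records, path)
  invisible(path)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}
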