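# shared internal helpers

# sample columns of a feature table: everything except the id/name columns
sample_cols <- function(table) {
  setdiff(names(table), c("feature_id", "feature_name"))
}

# features x samples numeric matrix, rownames = feature_id
ft_matrix <- function(table, samples = NULL) {
  samples <- samples %||% sample_cols(table)
  missing <- setdiff(samples, names(table))
  if (length(missing) > 0) {
    abort(paste0("samples not found in feature table: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(table[, samples, drop = FALSE])
  rownames(m) <- table$feature_id
  storage.mode(m) <- "double"
  m
}

# per-sample intensity normalization.
# "pqn": probabilistic quotient normalization - each sample is divided by the
# median of its feature-wise ratios to the median reference spectrum; robust
# to a minority of strongly differential (even very abundant) features.
# "total": classical total-intensity scaling to the median sample total.
normalize_intensities <- function(m, method = c("pqn", "total", "none")) {
  method <- match.arg(method)
  if (method == "none") return(m)
  tot <- colSums(m)
  if (any(tot <= 0)) abort("cannot normalize a sample with non-positive total intensity")
  if (method == "total") {
    return(sweep(m, 2, median(tot) / tot, `*`))
  }
  ref <- apply(m, 1, median)
  use <- ref > 0
  if (!any(use)) abort("PQN reference spectrum is all zero")
  q <- apply(m[use, , drop = FALSE] / ref[use], 2, function(r) median(r[r > 0]))
  sweep(m, 2, q, `/`)
}

normalize_arg <- function(normalize) {
  # accept TRUE/FALSE for convenience in interactive use
  if (isTRUE(normalize)) "pqn" else if (isFALSE(normalize)) "none" else
    match.arg(normalize, c("pqn", "total", "none"))
}

# log2 with per-feature half-minimum replacement of zeros (same rule as the
# missing-value policy), so log-scale tests are defined for sparse features
safe_log2 <- function(m) {
  if (any(m < 0)) abort("negative intensities are not allowed")
  if (any(m == 0)) {
    for (i in which(rowSums(m == 0) > 0)) {
      pos <- m[i, m[i, ] > 0]
      if (length(pos) == 0) abort(paste0("feature ", rownames(m)[i], " is all zero"))
      m[i, m[i, ] == 0] <- min(pos) / 2
    }
  }
  log2(m)
}

# display name used for cross-table matching: feature_name when present,
# feature_id otherwise (core matching is by metabolite name)
match_names <- function(records) {
  if ("feature_name" %in% names(records) && !all(is.na(records$feature_name))) {
    ifelse(is.na(records$feature_name), records$feature_id, records$feature_name)
  } else {
    records$feature_id
  }
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || (positive && x <= 0)) {
    abort(paste0("`", name, "` must be a single finite ",
                 if (positive) "positive " else "", "number"))
  }
  invisible(x)
}
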