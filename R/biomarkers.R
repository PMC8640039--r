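#' Top-k features by VIP among significant records
#'
#' Ranks the significant differential records by VIP descending; ties broken
#' by smaller p-value, then lexicographic feature id. If fewer than `k`
#' records are significant, all of them are returned with a warning.
#'
#' @param records Classified differential records (with `vip`, `p_value`,
#'   `significant`).
#' @param k Panel size (default 10).
#' @return The top-`k` rows, ranked.
#' @export
top_vip <- function(records, k = 10) {
  if (!all(c("vip", "p_value") %in% names(records))) {
    abort("records must carry `vip` and `p_value`")
  }
  sig <- records[isTRUE_vec(records$significant), , drop = FALSE]
  sig <- dplyr::arrange(sig, dplyr::desc(.data$vip), .data$p_value, .data$feature_id)
  if (nrow(sig) < k) {
    warn(paste0("only ", nrow(sig), " significant features for a top-", k, " panel"))
    return(sig)
  }
  sig[seq_len(k), , drop = FALSE]
}

#' Merge biomarker lists across ion modes
#'
#' LC-MS detects features separately in positive and negative electrospray
#' mode; the same metabolite may rank in both. Merging counts each metabolite
#' name once.
#'
#' @param pos_list,neg_list Character vectors of metabolite names.
#' @return A list with `merged` (union, positive-mode order first) and
#'   `co_contained_modes` (intersection).
#' @examples
#' merge_modes(c("Glycitein", "Daidzein"), c("Glycitein", "Genistin"))
#' @export
merge_modes <- function(pos_list, neg_list) {
  pos_list <- unique(as.character(pos_list))
  neg_list <- unique(as.character(neg_list))
  list(merged = union(pos_list, neg_list),
       co_contained_modes = intersect(pos_list, neg_list))
}

#' Intersect biomarker panels across substitution levels into a core panel
#'
#' The metabolites present in the panel of *every* dose level form the "core
#' biomarkers"; the remainder of each panel is that level's specific set.
#'
#' @param panels Named list (>= 2) of character vectors of metabolite names.
#' @return A list with `core` (intersection, in the first panel's order) and
#'   `specific_per_level` (named list of per-level set differences).
#' @export
intersect_levels <- function(panels) {
  if (!is.list(panels) || length(panels) < 2) {
    abort("`panels` must be a list of at least two biomarker panels")
  }
  panels <- purrr::map(panels, ~ unique(as.character(.x)))
  core <- Reduce(intersect, panels)
  list(core = core,
       specific_per_level = purrr::map(panels, ~ setdiff(.x, core)))
}

#' z-scores against a control group
#'
#' `z = (x - mean(control)) / sd(control)` with the n-1 denominator.
#'
#' @param values Intensities to standardize.
#' @param control_values Control-group intensities (sd must be positive).
#' @return Numeric vector, one z per element of `values`.
#' @export
zscore_vs_control <- function(values, control_values) {
  s <- sd(control_values)
  if (is.na(s) || s == 0) abort("control group has zero standard deviation")
  (values - mean(control_values)) / s
}

#' ROC area under the curve via the Mann-Whitney statistic
#'
#' AUC is the probability that a random case value exceeds a random control
#' value, ties counted one half: `U / (n_case * n_control)`. With
#' `direction = "auto"` the orientation giving AUC >= 0.5 is reported.
#'
#' @param case_values,control_values Numeric vectors (non-empty).
#' @param direction `"auto"` (default), `"case_high"` or `"case_low"`.
#' @return A list with `auc` and `direction` (the orientation used).
#' @examples
#' roc_auc(c(3, 5), c(1, 2, 4)) # 5/6
#' @export
roc_auc <- function(case_values, control_values,
                    direction = c("auto", "case_high", "case_low")) {
  direction <- match.arg(direction)
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 == 0 || n2 == 0) abort("both classes need at least one value")
  r <- rank(c(case_values, control_values))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (direction == "case_low" || (direction == "auto" && auc < 0.5)) {
    list(auc = 1 - auc, direction = "case_low")
  } else {
    list(auc = auc, direction = "case_high")
  }
}

#' Per-feature ROC AUC from a feature table
#'
#' @inheritParams plsda_vip
#' @param features Feature ids to evaluate (default: all).
#' @param direction Passed to [roc_auc()].
#' @return Tibble `feature_id`, `feature_name` (if present), `auc`,
#'   `direction`.
#' @export
roc_auc_table <- function(table, metadata, control, treatment,
                          features = NULL, direction = "auto") {
  md <- metadata[metadata$group %in% c(control, treatment) &
                   metadata$sample_id %in% sample_cols(table), ]
  tab <- if (is.null(features)) table else table[table$feature_id %in% features, ]
  m <- ft_matrix(tab, md$sample_id)
  is_trt <- md$group == treatment
  res <- apply(m, 1, function(v) roc_auc(v[is_trt], v[!is_trt], direction))
  out <- tibble::tibble(feature_id = tab$feature_id,
                        auc = purrr::map_dbl(res, "auc"),
                        direction = purrr::map_chr(res, "direction"))
  if ("feature_name" %in% names(tab)) {
    out <- dplyr::mutate(out, feature_name = tab$feature_name, .after = "feature_id")
  }
  out
}

#' Significance-masked pairwise correlation matrix
#'
#' Pearson (or Spearman) correlations between the columns of an
#' intensities-by-feature data frame, with two-sided p-values from the
#' t-distribution transform `t = r sqrt(n-2) / sqrt(1-r^2)` and a mask
#' blanking pairs with `p > alpha`. Constant features yield undefined
#' correlations, which are masked with a warning.
#'
#' @param x Data frame or matrix, samples in rows, features in columns
#'   (>= 3 rows).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Mask level (default 0.05).
#' @return An object of class `sbmie_corr`: list of matrices `r`, `p`,
#'   `mask` (`TRUE` where the pair is blanked), plus `alpha` and `method`.
#'   Plot with [plot_correlation()].
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman"), alpha = 0.05) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 3) abort("correlation needs at least 3 samples")
  constant <- apply(x, 2, sd) == 0
  if (any(constant)) {
    warn(paste0("constant feature(s) masked in correlation matrix: ",
                paste(colnames(x)[constant], collapse = ", ")))
  }
  if (method == "spearman") x <- apply(x, 2, rank)
  r <- suppressWarnings(cor(x))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.finite(tstat)] <- 0       # |r| = 1 exactly
  diag(p) <- 0
  mask <- is.na(r) | p > alpha
  diag(mask) <- FALSE
  diag(mask)[constant] <- TRUE
  structure(list(r = r, p = p, mask = mask, alpha = alpha, method = method),
            class = "sbmie_corr")
}

#' Screen a biomarker panel from classified differential records
#'
#' One-call wrapper for the per-level screening: takes classified positive-
#' and negative-mode differential records, ranks each mode's top-`k` by VIP
#' and merges across modes with deduplication by metabolite name.
#'
#' @param pos_records,neg_records Classified differential records per ion
#'   mode (negative may be `NULL` for a single-mode screen).
#' @param k Per-mode panel size.
#' @return A list with `panel` (merged metabolite names),
#'   `co_contained_modes`, and the per-mode ranked record tables
#'   `top_positive`, `top_negative`.
#' @export
screen_biomarkers <- function(pos_records, neg_records = NULL, k = 10) {
  top_pos <- top_vip(pos_records, k)
  if (is.null(neg_records)) {
    return(list(panel = match_names(top_pos), co_contained_modes = character(),
                top_positive = top_pos, top_negative = NULL))
  }
  top_neg <- top_vip(neg_records, k)
  merged <- merge_modes(match_names(top_pos), match_names(top_neg))
  list(panel = merged$merged, co_contained_modes = merged$co_contained_modes,
       top_positive = top_pos, top_negative = top_neg)
}
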