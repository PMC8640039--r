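#' Log2 fold change of group mean intensities
#'
#' `log2(mean(treatment) / mean(control))`. If a group mean is zero the
#' configured pseudo-mean replaces it; with `pseudo_mean = NULL` (default) a
#' zero mean is an error.
#'
#' @param control_values,treatment_values Non-negative intensity vectors.
#' @param pseudo_mean Replacement for a zero group mean, or `NULL` to forbid.
#' @return A single number.
#' @examples
#' log2_fold_change(c(1, 3), c(2, 6)) # log2(4/2) = 1
#' @export
log2_fold_change <- function(control_values, treatment_values, pseudo_mean = NULL) {
  if (length(control_values) == 0 || length(treatment_values) == 0) {
    abort("both groups must be non-empty")
  }
  if (any(c(control_values, treatment_values) < 0)) abort("intensities must be non-negative")
  mc <- mean(control_values)
  mt <- mean(treatment_values)
  if (mc == 0 || mt == 0) {
    if (is.null(pseudo_mean)) abort("zero group mean and no pseudo_mean configured")
    if (mc == 0) mc <- pseudo_mean
    if (mt == 0) mt <- pseudo_mean
  }
  log2(mt / mc)
}

#' Two-sided univariate group test
#'
#' Welch t (default), Student t, or Wilcoxon rank-sum. When both groups have
#' zero variance and equal values the test is degenerate and `p = 1` by
#' convention; zero variance in both groups with different values gives
#' `p = 0` (perfect separation of point masses).
#'
#' @param control_values,treatment_values Numeric vectors (t tests need n >= 2
#'   per group).
#' @param method One of `"welch_t"`, `"student_t"`, `"wilcoxon"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
group_test <- function(control_values, treatment_values,
                       method = c("welch_t", "student_t", "wilcoxon")) {
  method <- match.arg(method)
  if (method == "wilcoxon") {
    if (length(control_values) < 1 || length(treatment_values) < 1) {
      abort("rank test needs at least one value per group")
    }
    p <- suppressWarnings(
      wilcox.test(treatment_values, control_values, exact = NULL)$p.value)
    return(unname(p))
  }
  if (length(control_values) < 2 || length(treatment_values) < 2) {
    abort("t tests need at least two values per group")
  }
  if (sd(control_values) == 0 && sd(treatment_values) == 0) {
    return(if (mean(control_values) == mean(treatment_values)) 1 else 0)
  }
  p <- t.test(treatment_values, control_values,
              var.equal = (method == "student_t"))$p.value
  unname(p)
}

#' Per-feature differential analysis between two groups
#'
#' For every feature of a table computes the group means, log2 fold change
#' (on normalized group means), a two-sided univariate test on
#' log2 intensities, and the PLS-DA VIP score. The result is an unclassified
#' differential-record table; pipe it into [classify_differential()] to set
#' the `significant` and `trend` columns.
#'
#' @inheritParams plsda_vip
#' @param method Univariate test, see [group_test()].
#' @param p_adjust Multiple-testing correction applied to the p-value column
#'   (default `"none"`, matching raw-P reporting; `"BH"` available).
#' @param pseudo_mean Passed to [log2_fold_change()].
#' @return Tibble with one row per feature: `feature_id`, `feature_name` (if
#'   present), `mean_control`, `mean_treatment`, `log2FC`, `p_value`, `vip`.
#' @examples
#' sim <- simulate_metabolome(sim_spec(n_features = c(positive = 60),
#'                                     n_per_group = 6, seed = 2))
#' diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40") |>
#'   classify_differential() |>
#'   dplyr::count(trend)
#' @export
diff_features <- function(table, metadata, control, treatment,
                          method = c("welch_t", "student_t", "wilcoxon"),
                          normalize = c("pqn", "total", "none"), ncomp = 2,
                          p_adjust = c("none", "BH"), pseudo_mean = NULL) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  normalize <- normalize_arg(normalize)
  md <- metadata[metadata$group %in% c(control, treatment) &
                   metadata$sample_id %in% sample_cols(table), ]
  if (nrow(md) == 0) abort("no samples of the requested groups in the table")
  m <- ft_matrix(table, md$sample_id)
  m <- normalize_intensities(m, normalize)
  lm2 <- safe_log2(m)
  is_ctl <- md$group == control
  is_trt <- md$group == treatment

  mean_c <- rowMeans(m[, is_ctl, drop = FALSE])
  mean_t <- rowMeans(m[, is_trt, drop = FALSE])
  lfc <- purrr::map2_dbl(mean_c, mean_t, function(a, b) {
    if (a == 0 || b == 0) {
      if (is.null(pseudo_mean)) abort("zero group mean and no pseudo_mean configured")
      if (a == 0) a <- pseudo_mean
      if (b == 0) b <- pseudo_mean
    }
    log2(b / a)
  })
  pvals <- apply(lm2, 1, function(v) group_test(v[is_ctl], v[is_trt], method))
  if (p_adjust != "none") pvals <- p.adjust(pvals, method = p_adjust)

  fit <- plsda(t(lm2), factor(as.character(md$group), levels = c(control, treatment)),
               ncomp = ncomp)
  out <- tibble::tibble(
    feature_id = table$feature_id,
    mean_control = unname(mean_c), mean_treatment = unname(mean_t),
    log2FC = unname(lfc), p_value = unname(pvals),
    vip = unname(fit$vip[table$feature_id]))
  if ("feature_name" %in% names(table)) {
    out <- dplyr::mutate(out, feature_name = table$feature_name, .after = "feature_id")
  }
  out
}

#' Classify differential records as significant up/down features
#'
#' Two rules are supported. Metabolite mode (default): significant iff
#' `p_value < p_alpha` and `vip >= vip_min` (and `|log2FC| > lfc_min` when
#' `lfc_min` is given). DEG mode: significant iff `|log2FC| > lfc_min`
#' (default 1) and `p_value < p_alpha`. The `trend` is `up`/`down` by the sign
#' of `log2FC` for significant records and `none` otherwise.
#'
#' @param records A differential-record tibble from [diff_features()] (or any
#'   table with `log2FC`, `p_value`, and `vip` in metabolite mode).
#' @param p_alpha Significance level (default 0.05).
#' @param vip_min Minimum VIP in metabolite mode (default 1).
#' @param lfc_min Minimum |log2FC|; optional in metabolite mode, defaults to 1
#'   in DEG mode.
#' @param mode `"metabolite"` or `"deg"`.
#' @return `records` with `significant` (logical) and `trend`
#'   (`up`/`down`/`none`) columns set.
#' @export
classify_differential <- function(records, p_alpha = 0.05, vip_min = 1,
                                  lfc_min = NULL, mode = c("metabolite", "deg")) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(p_alpha, "p_alpha")
  if (mode == "deg") {
    lfc_min <- lfc_min %||% 1
    sig <- abs(records$log2FC) > lfc_min & records$p_value < p_alpha
  } else {
    if (!"vip" %in% names(records)) abort("metabolite mode needs a `vip` column")
    sig <- records$p_value < p_alpha & records$vip >= vip_min
    if (!is.null(lfc_min)) sig <- sig & abs(records$log2FC) > lfc_min
  }
  records$significant <- sig
  records$trend <- dplyr::case_when(
    sig & records$log2FC > 0 ~ "up",
    sig & records$log2FC < 0 ~ "down",
    TRUE ~ "none")
  records
}

#' Assign monotone dose-trend profiles across the group ladder
#'
#' Profile `A`: group mean intensities strictly increase along the full dose
#' ladder and the extreme-group test is significant; profile `B`: strictly
#' decrease with a significant extreme-group test; otherwise `none`.
#'
#' @inheritParams diff_features
#' @param p_alpha Significance level for the extreme-group test.
#' @return Tibble with `feature_id`, one `mean_<group>` column per dose level
#'   in ladder order, `p_value` (extreme-group test on log2 intensities) and
#'   `profile`.
#' @export
assign_trend_profiles <- function(table, metadata, p_alpha = 0.05,
                                  method = c("welch_t", "student_t", "wilcoxon"),
                                  normalize = c("pqn", "total", "none")) {
  method <- match.arg(method)
  normalize <- normalize_arg(normalize)
  md <- metadata[metadata$sample_id %in% sample_cols(table), ]
  ladder <- if (is.factor(md$group)) {
    intersect(levels(md$group), unique(as.character(md$group)))
  } else {
    unique(as.character(md$group))
  }
  if (length(ladder) < 3) abort("trend profiles need at least 3 dose levels")
  m <- ft_matrix(table, md$sample_id)
  m <- normalize_intensities(m, normalize)
  lm2 <- safe_log2(m)
  grp <- as.character(md$group)

  means <- sapply(ladder, function(g) rowMeans(m[, grp == g, drop = FALSE]))
  lo <- grp == ladder[1]
  hi <- grp == ladder[length(ladder)]
  pvals <- apply(lm2, 1, function(v) group_test(v[lo], v[hi], method))

  inc <- apply(means, 1, function(x) all(diff(x) > 0))
  dec <- apply(means, 1, function(x) all(diff(x) < 0))
  out <- tibble::tibble(feature_id = table$feature_id)
  for (g in ladder) out[[paste0("mean_", g)]] <- unname(means[, g])
  out$p_value <- unname(pvals)
  out$profile <- dplyr::case_when(
    inc & pvals < p_alpha ~ "A",
    dec & pvals < p_alpha ~ "B",
    TRUE ~ "none")
  out
}
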