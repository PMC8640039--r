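#' Classify content/tissue metabolite exchange by inverse trends
#'
#' Metabolites differential in *both* the distal-intestine content and the
#' tissue compartment whose log2 fold changes have strictly opposite signs are
#' interpreted as exchanged between lumen and gut wall:
#' `content_up_tissue_down` (rising in the digesta while falling in the
#' tissue) or `content_down_tissue_up`; everything else is `none`.
#'
#' Records matched by metabolite name. A record counts as differential when
#' its `significant` column is `TRUE`; if the records carry no `significant`
#' column, `p_value < alpha` is used instead.
#'
#' @param content_records,tissue_records Differential-record tibbles for the
#'   two compartments (same treatment-vs-control contrast).
#' @param alpha Significance level for the p-value fallback (default 0.05).
#' @return A tibble with one row per metabolite present in both record sets:
#'   `feature`, `content_log2FC`, `content_p`, `tissue_log2FC`, `tissue_p`,
#'   `exchange_class`. Class counts are `dplyr::count(x, exchange_class)`.
#' @export
exchange_classify <- function(content_records, tissue_records, alpha = 0.05) {
  stopifnot_scalar_number(alpha, "alpha")
  prep <- function(records) {
    sig <- if ("significant" %in% names(records)) {
      !is.na(records$significant) & records$significant
    } else {
      records$p_value < alpha
    }
    tibble::tibble(feature = match_names(records),
                   log2FC = records$log2FC, p = records$p_value, sig = sig)
  }
  ct <- prep(content_records)
  ts <- prep(tissue_records)
  both <- dplyr::inner_join(ct, ts, by = "feature", suffix = c("_content", "_tissue"))
  tibble::tibble(
    feature = both$feature,
    content_log2FC = both$log2FC_content, content_p = both$p_content,
    tissue_log2FC = both$log2FC_tissue, tissue_p = both$p_tissue,
    exchange_class = dplyr::case_when(
      both$sig_content & both$sig_tissue &
        both$log2FC_content > 0 & both$log2FC_tissue < 0 ~ "content_up_tissue_down",
      both$sig_content & both$sig_tissue &
        both$log2FC_content < 0 & both$log2FC_tissue > 0 ~ "content_down_tissue_up",
      TRUE ~ "none"))
}

#' Top-k representative metabolites of an exchange class
#'
#' Ranked by the smaller of the two compartment p-values ascending, ties by
#' |content log2FC| descending.
#'
#' @param records Output of [exchange_classify()].
#' @param class The exchange class to rank.
#' @param k Number of representatives (default 10); a class smaller than `k`
#'   is returned whole.
#' @return The ranked subset of `records`.
#' @export
rank_representatives <- function(records, class, k = 10) {
  sub <- records[records$exchange_class == class, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  sub <- dplyr::mutate(sub, .min_p = pmin(.data$content_p, .data$tissue_p))
  sub <- dplyr::arrange(sub, .data$.min_p, dplyr::desc(abs(.data$content_log2FC)))
  sub$.min_p <- NULL
  head(sub, k)
}
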