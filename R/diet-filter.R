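#' Venn partition of diet-differential and content-differential metabolites
#'
#' @param diet_diff,content_diff Character vectors of metabolite names
#'   (matching is exact, case-sensitive).
#' @return A list with `content_only`, `diet_only` and `co_contained`
#'   (pairwise disjoint; `co_contained` is the intersection).
#' @examples
#' venn_partition(c("a", "b"), c("b", "c"))
#' @export
venn_partition <- function(diet_diff, content_diff) {
  diet_diff <- unique(as.character(diet_diff))
  content_diff <- unique(as.character(content_diff))
  list(content_only = setdiff(content_diff, diet_diff),
       diet_only = setdiff(diet_diff, content_diff),
       co_contained = intersect(diet_diff, content_diff))
}

#' Diet-background filtration of content-differential metabolites
#'
#' Content-differential metabolites that are also diet-differential may merely
#' reflect the diet formulation rather than intestinal physiology. A
#' co-contained metabolite is *kept* when its content trend is contrary to its
#' diet trend, or when the log2FC variation range exceeds `range_threshold`;
#' otherwise it is removed. Content-only metabolites always pass.
#'
#' @param diet_records,content_records Classified differential-record tibbles
#'   (see [classify_differential()]); the differential sets are the records
#'   with `significant = TRUE`, matched across tables by metabolite name
#'   (`feature_name`, falling back to `feature_id`).
#' @param range_threshold Log2FC variation range above which a same-trend
#'   co-contained metabolite is still kept (default 2).
#' @param range_definition How the "variation range" is measured:
#'   `"difference"` (default) is `|log2FC_content - log2FC_diet|`;
#'   `"content_abs"` is `|log2FC_content|`.
#' @return A list with `decisions` (tibble per co-contained metabolite:
#'   `feature`, `lfc_diet`, `lfc_content`, `decision` in
#'   `keep_contrary_trend`/`keep_lfc_range`/`remove`), `kept` (the final
#'   content-differential metabolite names) and `partition` (the
#'   [venn_partition()]).
#' @examples
#' diet <- tibble::tibble(feature_id = c("a", "b"), log2FC = c(1, 1),
#'                        p_value = 0.01, significant = TRUE)
#' content <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                           log2FC = c(-0.5, 1.5, 2), p_value = 0.01,
#'                           significant = TRUE)
#' apply_diet_filter(diet, content)$decisions
#' @export
apply_diet_filter <- function(diet_records, content_records, range_threshold = 2,
                              range_definition = c("difference", "content_abs")) {
  range_definition <- match.arg(range_definition)
  stopifnot_scalar_number(range_threshold, "range_threshold")

  diet_sig <- diet_records[isTRUE_vec(diet_records$significant), , drop = FALSE]
  content_sig <- content_records[isTRUE_vec(content_records$significant), , drop = FALSE]
  diet_names <- match_names(diet_sig)
  content_names <- match_names(content_sig)
  part <- venn_partition(diet_names, content_names)

  if (length(part$co_contained) == 0) {
    decisions <- tibble::tibble(feature = character(), lfc_diet = numeric(),
                                lfc_content = numeric(), decision = character())
    return(list(decisions = decisions, kept = part$content_only, partition = part))
  }

  lfc_of <- function(records, nms, what) {
    idx <- match(part$co_contained, nms)
    lfc <- records$log2FC[idx]
    if (anyNA(lfc)) {
      abort(paste0("missing log2FC in ", what, " records for: ",
                   paste(part$co_contained[is.na(lfc)], collapse = ", ")))
    }
    lfc
  }
  lfc_d <- lfc_of(diet_sig, diet_names, "diet")
  lfc_c <- lfc_of(content_sig, content_names, "content")

  contrary <- lfc_d * lfc_c < 0
  range_val <- if (range_definition == "difference") abs(lfc_c - lfc_d) else abs(lfc_c)
  decisions <- tibble::tibble(
    feature = part$co_contained, lfc_diet = lfc_d, lfc_content = lfc_c,
    decision = dplyr::case_when(
      contrary ~ "keep_contrary_trend",
      range_val > range_threshold ~ "keep_lfc_range",
      TRUE ~ "remove"))
  kept <- c(part$content_only,
            decisions$feature[decisions$decision != "remove"])
  list(decisions = decisions, kept = kept, partition = part)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) abort("records must carry a `significant` column; run classify_differential() first")
  !is.na(x) & x
}
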