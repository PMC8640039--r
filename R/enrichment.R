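#' Hypergeometric pathway over-representation analysis
#'
#' Tests each pathway for over-representation of a selected feature set
#' against an annotation map. The universe is every annotated feature; the
#' selected set is restricted to the universe. For a pathway annotating `K`
#' of the `N` universe features, with `n` selected features of which `k` hit
#' the pathway, the p-value is the hypergeometric upper tail `P(X >= k)`.
#' Features with multiple pathway annotations count once per pathway.
#'
#' @param selected Character vector of selected feature ids.
#' @param annotation Annotation map tibble (`feature_id`, `pathway_id`), e.g.
#'   from [read_annotation_map()].
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default, raw-P reporting) or `"BH"`.
#' @return Tibble sorted by p-value, one row per pathway with at least one
#'   selected feature: `pathway_id`, `N`, `K`, `n`, `k`, `p_value`,
#'   `significant`.
#' @examples
#' ann <- tibble::tibble(feature_id = letters[1:10],
#'                       pathway_id = rep(c("P1", "P2"), 5))
#' enrich_pathways(letters[1:4], ann)
#' @export
enrich_pathways <- function(selected, annotation, alpha = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.data.frame(annotation) || nrow(annotation) == 0) {
    abort("annotation map is empty")
  }
  annotation <- dplyr::distinct(annotation[, c("feature_id", "pathway_id")])
  universe <- unique(annotation$feature_id)
  sel <- intersect(unique(as.character(selected)), universe)
  if (length(sel) == 0) {
    warn("no selected feature is annotated; empty result")
    return(tibble::tibble(pathway_id = character(), N = integer(), K = integer(),
                          n = integer(), k = integer(), p_value = numeric(),
                          significant = logical()))
  }
  N <- length(universe)
  n <- length(sel)
  out <- annotation |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$feature_id),
                     k = sum(unique(.data$feature_id) %in% sel),
                     .groups = "drop") |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(N = N, n = n,
                  p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                                   lower.tail = FALSE)) |>
    dplyr::select("pathway_id", "N", "K", "n", "k", "p_value")
  if (p_adjust != "none") out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out |>
    dplyr::mutate(significant = .data$p_value < alpha) |>
    dplyr::arrange(.data$p_value, .data$pathway_id)
}
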