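#' Alpha-diversity estimators for one sample's OTU counts
#'
#' Computes the standard within-sample diversity index set from a vector of
#' taxon read counts: observed taxa, Shannon entropy (base 2 by default),
#' Gini-Simpson index `1 - sum(p_i^2)`, classical Chao1
#' `S_obs + F1^2 / (2 F2)` (with the `F1 (F1 - 1) / 2` fallback when there are
#' no doubletons), the abundance-based coverage estimator (ACE, rare-taxon
#' threshold 10), and Good's coverage `1 - F1 / N`, where `F1`/`F2` are the
#' singleton/doubleton counts and `N` the total reads.
#'
#' ACE: with `S_rare` rare taxa (count <= `rare_threshold`), `N_rare` rare
#' reads and sample coverage `C = 1 - F1 / N_rare`,
#' `ACE = S_abund + S_rare / C + (F1 / C) * g2` where `g2` is the squared
#' coefficient of variation of rare abundances (floored at 0). When there are
#' no rare taxa ACE equals `S_obs`; when every rare taxon is a singleton
#' (`C = 0`) ACE is undefined and the Chao1 value is reported instead.
#'
#' @param counts Non-negative integer vector with at least one positive entry.
#' @param base Logarithm base for Shannon (default 2).
#' @param rare_threshold ACE rare-taxon cutoff (default 10).
#' @return One-row tibble: `s_obs`, `shannon`, `simpson`, `chao1`, `ace`,
#'   `goods_coverage`, and the intermediates `f1`, `f2`, `n_reads`.
#' @examples
#' alpha_diversity(c(1, 1, 2, 2, 3)) # Chao1 = 5 + 4/4 = 6
#' @export
alpha_diversity <- function(counts, base = 2, rare_threshold = 10) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("all counts are zero")
  n <- sum(counts)
  p <- counts / n
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)

  shannon <- -sum(p * log(p, base = base))
  simpson <- 1 - sum(p^2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2

  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) {
    ace <- s_obs
  } else {
    n_rare <- sum(rare)
    c_ace <- 1 - f1 / n_rare
    if (c_ace <= 0) {
      ace <- chao1   # all rare taxa are singletons; ACE undefined
    } else {
      i <- seq_len(rare_threshold)
      fi <- vapply(i, function(j) sum(rare == j), numeric(1))
      g2 <- if (n_rare > 1) {
        max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
      } else 0
      ace <- s_abund + s_rare / c_ace + f1 / c_ace * g2
    }
  }

  tibble::tibble(s_obs = s_obs, shannon = shannon, simpson = simpson,
                 chao1 = chao1, ace = ace, goods_coverage = 1 - f1 / n,
                 f1 = f1, f2 = f2, n_reads = n)
}

#' Alpha diversity for every sample of an OTU count table
#'
#' @param table OTU feature table (counts; see [read_feature_table()]).
#' @param metadata Optional sample metadata joined onto the result.
#' @param rarefy_to Optional depth for seeded rarefaction (subsampling without
#'   replacement) before computing indices; `NULL` (default) uses raw counts.
#' @param seed Seed for rarefaction.
#' @inheritParams alpha_diversity
#' @return Tibble, one row per sample, `sample_id` plus the
#'   [alpha_diversity()] columns (and metadata columns if given).
#' @export
alpha_diversity_table <- function(table, metadata = NULL, base = 2,
                                  rare_threshold = 10, rarefy_to = NULL,
                                  seed = 1) {
  m <- ft_matrix(table)
  if (!is.null(rarefy_to)) {
    set.seed(seed)
    m <- apply(m, 2, function(v) rarefy_counts(v, rarefy_to))
  }
  out <- purrr::map_dfr(colnames(m), function(s) {
    dplyr::bind_cols(tibble::tibble(sample_id = s),
                     alpha_diversity(m[, s], base = base,
                                     rare_threshold = rare_threshold))
  })
  if (!is.null(metadata)) out <- dplyr::left_join(out, metadata, by = "sample_id")
  out
}

rarefy_counts <- function(v, depth) {
  n <- sum(v)
  if (n < depth) abort("sample depth below rarefaction target")
  drawn <- sample(rep.int(seq_along(v), v), depth)
  tabulate(drawn, nbins = length(v))
}
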