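#' Specify a synthetic multi-compartment metabolome simulation
#'
#' Builds the parameter object for [simulate_metabolome()]. The defaults
#' emulate the design of an SBM-substitution feeding trial: three diet groups
#' on an ordered dose ladder (`FM < SBM20 < SBM40`), 12 distal-intestine
#' content and 12 tissue samples per group, about 2,000 positive-mode and
#' 1,100 negative-mode LC-MS features with log-normally distributed
#' intensities, and planted feature classes that exercise every downstream
#' stage: group-differential features, diet-derived features (differential in
#' both the diet and the content tables, either with the same trend and a
#' small log2FC range, which the diet filter must remove, or with a contrary
#' trend, which it must keep) and "exchanged" features with opposite-signed
#' content and tissue shifts.
#'
#' @param n_features Named integer vector of feature counts per ion mode.
#' @param groups Ordered dose ladder (control first).
#' @param dose_scaling Multiplier of the planted log2 effect per group; the
#'   last group carries the full effect so its contrast against the control
#'   recovers `effect_log2` exactly, and intermediate doses make planted group
#'   means strictly monotone along the ladder.
#' @param n_per_group Content and tissue samples per group (study design: 12).
#' @param n_diet_samples Replicate diet measurements per group.
#' @param frac_differential,frac_diet_derived,frac_exchanged Fractions of
#'   features planted in each class (each split evenly between its up/down or
#'   same-trend/contrary variants); must sum to at most 1.
#' @param effect_log2 Planted full-dose effect on the log2 scale.
#' @param cv Within-group coefficient of variation of intensities.
#' @param meanlog,sdlog Log-normal parameters of baseline feature means.
#' @param passage_factor Attenuation of diet-derived feature intensity in the
#'   content compartment relative to the diet.
#' @param same_trend_gap For diet-derived same-trend features, the planted
#'   |content log2FC - diet log2FC|; kept below the filter range threshold so
#'   these features are removed by the diet filter.
#' @param shared_names Number of planted differential metabolite names shared
#'   verbatim between the two ion modes (exercises cross-mode deduplication).
#' @param compartments Compartments to generate.
#' @param seed Random seed; identical seeds give bit-identical output.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_features = c(positive = 2000, negative = 1100),
                     groups = c("FM", "SBM20", "SBM40"),
                     dose_scaling = c(0, 0.5, 1),
                     n_per_group = 12,
                     n_diet_samples = 6,
                     frac_differential = 0.05,
                     frac_diet_derived = 0.02,
                     frac_exchanged = 0.02,
                     effect_log2 = 2,
                     cv = 0.3,
                     meanlog = 12,
                     sdlog = 1.5,
                     passage_factor = 0.5,
                     same_trend_gap = 1,
                     shared_names = 3,
                     compartments = c("diet", "content", "tissue"),
                     seed = 1) {
  fr <- c(frac_differential, frac_diet_derived, frac_exchanged)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort("planted fractions must lie in [0,1] and sum to at most 1")
  }
  if (n_per_group < 3) abort("`n_per_group` must be at least 3")
  if (length(groups) != length(dose_scaling)) {
    abort("`dose_scaling` must have one entry per group")
  }
  stopifnot_scalar_number(cv, "cv")
  if (!is.finite(effect_log2)) abort("`effect_log2` must be finite")
  if (same_trend_gap >= abs(effect_log2) && frac_diet_derived > 0) {
    abort("`same_trend_gap` must be smaller than |effect_log2|")
  }
  if (seed < 0 || seed != round(seed)) abort("`seed` must be a non-negative integer")
  if (is.null(names(n_features))) {
    names(n_features) <- c("positive", "negative")[seq_along(n_features)]
  }
  structure(
    list(n_features = n_features, groups = groups, dose_scaling = dose_scaling,
         n_per_group = n_per_group, n_diet_samples = n_diet_samples,
         frac_differential = frac_differential,
         frac_diet_derived = frac_diet_derived,
         frac_exchanged = frac_exchanged,
         effect_log2 = effect_log2, cv = cv, meanlog = meanlog, sdlog = sdlog,
         passage_factor = passage_factor, same_trend_gap = same_trend_gap,
         shared_names = shared_names, compartments = compartments, seed = seed),
    class = "sim_spec"
  )
}

#' Simulate multi-compartment metabolome feature tables with ground truth
#'
#' Draws intensities log-normally with multiplicative group effects (so
#' planted log2 fold changes are additive on the log scale), per the design in
#' [sim_spec()]. Feature labels partition the feature set:
#' `null`, `differential_up`/`differential_down` (content only),
#' `diet_derived_same_trend`/`diet_derived_contrary` (differential in diet and
#' content), `exchanged_up_down`/`exchanged_down_up` (opposite content/tissue
#' shifts).
#'
#' @param spec A [sim_spec()] object.
#' @return A list with `tables` (named list of feature tables,
#'   `<compartment>_<mode>`), `metadata` (one row per sample; ion mode is a
#'   property of the table, not the sample), and `ground_truth` (tibble:
#'   `mode`, `feature_id`, `feature_name`, `label`, and the true full-dose
#'   `lfc_diet`, `lfc_content`, `lfc_tissue`).
#' @examples
#' sim <- simulate_metabolome(sim_spec(n_features = c(positive = 50),
#'                                     n_per_group = 4, seed = 7))
#' names(sim$tables)
#' dplyr::count(sim$ground_truth, label)
#' @export
simulate_metabolome <- function(spec = sim_spec()) {
  if (!inherits(spec, "sim_spec")) abort("`spec` must be created by sim_spec()")
  set.seed(spec$seed)

  groups <- spec$groups
  comp_tags <- c(diet = "D", content = "N", tissue = "T")
  n_by_comp <- c(diet = spec$n_diet_samples, content = spec$n_per_group,
                 tissue = spec$n_per_group)

  metadata <- purrr::map_dfr(spec$compartments, function(cp) {
    tibble::tibble(
      sample_id = as.vector(t(outer(groups, seq_len(n_by_comp[[cp]]),
                                    function(g, i) paste(g, comp_tags[[cp]], i, sep = "_")))),
      group = rep(groups, each = n_by_comp[[cp]]),
      compartment = cp, ion_mode = "none")
  })
  metadata$group <- factor(metadata$group, levels = groups)

  truth <- purrr::map_dfr(names(spec$n_features), function(mode) {
    nf <- spec$n_features[[mode]]
    n_diff <- round(spec$frac_differential * nf)
    n_dd <- round(spec$frac_diet_derived * nf)
    n_ex <- round(spec$frac_exchanged * nf)
    labels <- c(rep("differential_up", ceiling(n_diff / 2)),
                rep("differential_down", floor(n_diff / 2)),
                rep("diet_derived_same_trend", ceiling(n_dd / 2)),
                rep("diet_derived_contrary", floor(n_dd / 2)),
                rep("exchanged_up_down", ceiling(n_ex / 2)),
                rep("exchanged_down_up", floor(n_ex / 2)))
    labels <- c(labels, rep("null", nf - length(labels)))
    e <- spec$effect_log2
    tibble::tibble(
      mode = mode,
      feature_id = sprintf("%s_%04d", toupper(substr(mode, 1, 3)), seq_len(nf)),
      feature_name = sprintf("Metabolite_%s_%04d", mode, seq_len(nf)),
      label = labels,
      lfc_diet = dplyr::case_when(
        labels %in% c("diet_derived_same_trend", "diet_derived_contrary") ~ e,
        TRUE ~ 0),
      lfc_content = dplyr::case_when(
        labels == "differential_up" ~ e,
        labels == "differential_down" ~ -e,
        labels == "diet_derived_same_trend" ~ e - spec$same_trend_gap,
        labels == "diet_derived_contrary" ~ -e,
        labels == "exchanged_up_down" ~ e,
        labels == "exchanged_down_up" ~ -e,
        TRUE ~ 0),
      lfc_tissue = dplyr::case_when(
        labels == "exchanged_up_down" ~ -e,
        labels == "exchanged_down_up" ~ e,
        TRUE ~ 0))
  })
  # shared display names across modes exercise cross-mode deduplication
  if (length(spec$n_features) > 1 && spec$shared_names > 0) {
    for (mode in names(spec$n_features)) {
      idx <- which(truth$mode == mode & truth$label == "differential_up")
      k <- min(spec$shared_names, length(idx))
      if (k > 0) truth$feature_name[idx[seq_len(k)]] <- sprintf("SharedMetab_%d", seq_len(k))
    }
  }

  sdlog_w <- sqrt(log1p(spec$cv^2))
  tables <- list()
  for (mode in names(spec$n_features)) {
    tr <- truth[truth$mode == mode, ]
    nf <- nrow(tr)
    base <- rlnorm(nf, spec$meanlog, spec$sdlog)
    for (cp in spec$compartments) {
      lfc <- tr[[paste0("lfc_", cp)]]
      cp_base <- base
      if (cp == "content") {
        dd <- grepl("^diet_derived", tr$label)
        cp_base[dd] <- cp_base[dd] * spec$passage_factor
      }
      md <- metadata[metadata$compartment == cp, ]
      vals <- matrix(0, nf, nrow(md))
      for (gi in seq_along(groups)) {
        cols <- which(md$group == groups[gi])
        mu <- cp_base * 2^(lfc * spec$dose_scaling[gi])
        meanlog_w <- log(mu) - sdlog_w^2 / 2
        vals[, cols] <- matrix(
          rlnorm(nf * length(cols), rep(meanlog_w, length(cols)), sdlog_w),
          nf, length(cols))
      }
      colnames(vals) <- md$sample_id
      tables[[paste0(cp, "_", mode)]] <- dplyr::bind_cols(
        tibble::tibble(feature_id = tr$feature_id, feature_name = tr$feature_name),
        tibble::as_tibble(vals))
    }
  }
  list(tables = tables, metadata = tibble::as_tibble(metadata), ground_truth = truth)
}

#' Simulate an OTU count table along a dysbiosis gradient
#'
#' Draws multinomial read counts per sample from group-specific taxon
#' probabilities. Taxon probabilities decay geometrically; a larger
#' `dysbiosis_gradient` flattens the decay, giving more even and richer
#' communities (monotonically increasing expected Shannon diversity), which
#' emulates the community-richness gradient observed with increasing SBM
#' substitution.
#'
#' @param n_taxa Number of taxa (at least 2).
#' @param n_samples Samples per group.
#' @param depth Reads per sample (at least 100).
#' @param dysbiosis_gradient Named non-negative vector, one entry per group.
#' @param decay Baseline geometric decay rate of ranked taxon probabilities.
#' @param seed Random seed.
#' @return A list with `table` (OTU counts feature table) and `metadata`.
#' @examples
#' sim <- simulate_otu(n_taxa = 50, depth = 1000, seed = 3)
#' alpha_diversity_table(sim$table)
#' @export
simulate_otu <- function(n_taxa = 200, n_samples = 3, depth = 50000,
                         dysbiosis_gradient = c(FM = 0, SBM20 = 1, SBM40 = 3),
                         decay = 0.25, seed = 1) {
  if (n_taxa < 2) abort("`n_taxa` must be at least 2")
  if (depth < 100) abort("`depth` must be at least 100")
  if (any(dysbiosis_gradient < 0)) abort("`dysbiosis_gradient` must be non-negative")
  set.seed(seed)
  groups <- names(dysbiosis_gradient) %||% paste0("G", seq_along(dysbiosis_gradient))
  counts <- list()
  ids <- character()
  for (gi in seq_along(groups)) {
    rate <- decay / (1 + dysbiosis_gradient[[gi]])
    p <- exp(-rate * (seq_len(n_taxa) - 1))
    p <- p / sum(p)
    cnt <- rmultinom(n_samples, depth, p)
    colnames(cnt) <- paste(groups[gi], seq_len(n_samples), sep = "_")
    counts[[gi]] <- cnt
    ids <- c(ids, colnames(cnt))
  }
  m <- do.call(cbind, counts)
  table <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("OTU_%04d", seq_len(n_taxa))),
    tibble::as_tibble(m))
  metadata <- tibble::tibble(
    sample_id = ids,
    group = factor(rep(groups, each = n_samples), levels = groups),
    compartment = "content", ion_mode = "none")
  list(table = table, metadata = metadata)
}
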