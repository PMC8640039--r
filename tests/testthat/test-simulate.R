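test_that("the generator is bit-reproducible under a fixed seed", {
  spec <- sim_spec(n_features = c(positive = 40, negative = 30),
                   n_per_group = 4, seed = 7)
  a <- simulate_metabolome(spec)
  b <- simulate_metabolome(spec)
  expect_identical(a, b)
  c2 <- simulate_metabolome(sim_spec(n_features = c(positive = 40, negative = 30),
                                     n_per_group = 4, seed = 8))
  expect_false(identical(a$tables, c2$tables))
})

test_that("ground-truth labels partition the features with sign-consistent effects", {
  sim <- simulate_metabolome(sim_spec(n_features = c(positive = 200, negative = 100),
                                      n_per_group = 4, seed = 3))
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 300)
  expect_false(any(duplicated(paste(gt$mode, gt$feature_id))))
  expect_true(all(gt$lfc_content[gt$label == "differential_up"] > 0))
  expect_true(all(gt$lfc_content[gt$label == "differential_down"] < 0))
  expect_true(all(gt$lfc_diet[gt$label == "diet_derived_contrary"] *
                    gt$lfc_content[gt$label == "diet_derived_contrary"] < 0))
  expect_true(all(gt$lfc_content[gt$label == "exchanged_up_down"] *
                    gt$lfc_tissue[gt$label == "exchanged_up_down"] < 0))
  expect_true(all(gt[gt$label == "null", c("lfc_diet", "lfc_content", "lfc_tissue")] == 0))
  # shared display names appear in both modes for the cross-mode dedup
  shared <- gt$feature_name[grepl("^SharedMetab_", gt$feature_name)]
  expect_equal(sort(unique(table(shared))), 2)
})

test_that("planted effects are recovered empirically at large n", {
  sim <- simulate_metabolome(sim_spec(
    n_features = c(positive = 40), frac_differential = 0.25,
    frac_diet_derived = 0, frac_exchanged = 0,
    n_per_group = 200, compartments = "content", seed = 5))
  tab <- sim$tables$content_positive
  md <- sim$metadata
  m <- as.matrix(tab[, md$sample_id])
  lfc <- log2(rowMeans(m[, md$group == "SBM40"]) / rowMeans(m[, md$group == "FM"]))
  gt <- sim$ground_truth
  planted <- gt$label != "null"
  expect_true(all(abs(lfc[planted] - gt$lfc_content[planted]) < 0.15))
  expect_true(all(abs(lfc[!planted]) < 0.15))
})

test_that("power: strong planted effects are recovered as significant up-features", {
  recovered <- purrr::map_dbl(1:6, function(s) {
    sim <- simulate_metabolome(sim_spec(
      n_features = c(positive = 500), frac_differential = 0.04,
      frac_diet_derived = 0, frac_exchanged = 0,
      compartments = "content", seed = 400 + s))
    rec <- diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40") |>
      classify_differential()
    gt <- sim$ground_truth
    up <- gt$feature_id[gt$label == "differential_up"]
    down <- gt$feature_id[gt$label == "differential_down"]
    mean(c(rec$trend[match(up, rec$feature_id)] == "up",
           rec$trend[match(down, rec$feature_id)] == "down"))
  })
  expect_gte(mean(recovered), 0.95)
})

test_that("infeasible specifications are rejected", {
  expect_error(sim_spec(frac_differential = 0.8, frac_diet_derived = 0.3), "sum")
  expect_error(sim_spec(n_per_group = 2), "at least 3")
  expect_error(sim_spec(same_trend_gap = 3, effect_log2 = 2), "same_trend_gap")
  expect_error(sim_spec(seed = -1), "seed")
})
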