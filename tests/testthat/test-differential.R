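test_that("log2 fold change matches hand computations and handles zero means", {
  expect_equal(log2_fold_change(c(2, 2), c(8, 8)), 2)
  expect_equal(log2_fold_change(c(5, 5), c(5, 5)), 0)
  expect_equal(log2_fold_change(c(1, 3), c(2, 6)), 1)  # log2(4/2)
  expect_error(log2_fold_change(c(0, 0), c(1, 1)), "pseudo_mean")
  expect_equal(log2_fold_change(c(0, 0), c(2, 2), pseudo_mean = 1), 1)
})

test_that("group tests match known p-values and degenerate conventions", {
  expect_equal(group_test(c(1, 1, 1), c(1, 1, 1), "welch_t"), 1)
  expect_lt(group_test(c(1, 1, 1), c(100, 100, 101), "welch_t"), 0.01)
  # fully separated ranks, 4 vs 4: exact two-sided p = 2 / choose(8, 4)
  expect_equal(group_test(1:4, 5:8, "wilcoxon"), 2 / 70)
  expect_equal(group_test(c(2, 2, 2), c(5, 5, 5), "welch_t"), 0)
  expect_error(group_test(1, c(2, 3), "welch_t"), "at least two")
})

test_that("differential records are antisymmetric in control/treatment", {
  set.seed(42)
  d <- make_table(matrix(rlnorm(30 * 12, 10, 1), 30), rep(c("FM", "SBM40"), each = 6))
  fwd <- diff_features(d$table, d$metadata, "FM", "SBM40") |> classify_differential()
  rev <- diff_features(d$table, d$metadata, "SBM40", "FM") |> classify_differential()
  expect_equal(fwd$log2FC, -rev$log2FC)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(flip[fwd$trend]), rev$trend)
})

test_that("classification rules follow the DEG and metabolite thresholds", {
  rec <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        log2FC = c(1.5, 0.5, -0.2, -1.4),
                        p_value = c(0.01, 0.01, 0.04, 0.2),
                        vip = c(0.4, 1.6, 1.2, 2))
  deg <- classify_differential(rec, mode = "deg")
  expect_equal(deg$trend, c("up", "none", "none", "none"))
  met <- classify_differential(rec, mode = "metabolite")
  expect_equal(met$significant, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(met$trend, c("none", "up", "down", "none"))
})

test_that("trend profiles require strict monotonicity plus extreme-group significance", {
  set.seed(7)
  n <- 5
  up <- rep(c(10, 20, 40), each = n) * exp(rnorm(3 * n, sd = 0.05))
  down <- rep(c(40, 20, 10), each = n) * exp(rnorm(3 * n, sd = 0.05))
  bump <- rep(c(10, 40, 20), each = n) * exp(rnorm(3 * n, sd = 0.05))
  flat <- rep(20, 3 * n) * exp(rnorm(3 * n, sd = 0.05))
  d <- make_table(rbind(up, down, bump, flat),
                  rep(c("FM", "SBM20", "SBM40"), each = n))
  prof <- assign_trend_profiles(d$table, d$metadata, normalize = FALSE)
  expect_equal(prof$profile, c("A", "B", "none", "none"))
  two <- d$metadata[d$metadata$group != "SBM20", ]
  expect_error(assign_trend_profiles(d$table[, c("feature_id", two$sample_id)], two),
               "3 dose levels")
})

test_that("type-I error on null data stays near the nominal level", {
  # 6 seeds x 400 features here keeps the unit suite fast; the acceptance
  # suite runs the full 20-seed version of this property
  alpha <- 0.05
  frac <- purrr::map_dbl(1:6, function(s) {
    sim <- simulate_metabolome(sim_spec(
      n_features = c(positive = 400), frac_differential = 0,
      frac_diet_derived = 0, frac_exchanged = 0,
      compartments = "content", seed = 100 + s))
    rec <- diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40")
    mean(rec$p_value < alpha)
  })
  m <- 6 * 400
  expect_lt(abs(mean(frac) - alpha), 3 * sqrt(alpha * (1 - alpha) / m))
})
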