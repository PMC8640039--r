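test_that("top_vip ranks by VIP with p then id tie-breaks and warns when short", {
  rec <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        vip = c(2, 2, 3, 1.5),
                        p_value = c(0.04, 0.01, 0.02, 0.001),
                        significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(top_vip(rec, k = 1)$feature_id, "c")
  expect_equal(top_vip(rec, k = 3)$feature_id, c("c", "b", "a"))
  expect_warning(all4 <- top_vip(rec, k = 10), "only 3")
  expect_equal(nrow(all4), 3)
})

test_that("cross-mode merging and cross-level intersection are set-exact", {
  m <- merge_modes(letters[1:10], letters[6:15])
  expect_equal(length(m$merged), 15)
  expect_equal(m$co_contained_modes, letters[6:10])
  expect_equal(length(merge_modes(letters[1:10], letters[11:20])$merged), 20)
  same <- merge_modes(letters[1:10], letters[1:10])
  expect_equal(length(same$merged), 10)
  expect_equal(length(same$co_contained_modes), 10)

  lv <- intersect_levels(list(A = letters[1:5], B = letters[3:7]))
  expect_equal(lv$core, c("c", "d", "e"))
  expect_equal(lv$specific_per_level$A, c("a", "b"))
  ident <- intersect_levels(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(ident$core, letters[1:4])
  expect_equal(lengths(ident$specific_per_level), c(A = 0L, B = 0L))
})

test_that("z-scores use the n-1 control sd", {
  expect_equal(zscore_vs_control(2, c(1, 2, 3)), 0)
  expect_equal(zscore_vs_control(4, c(1, 2, 3)), 2)
  expect_length(zscore_vs_control(1:7, c(1, 2, 3)), 7)
  expect_error(zscore_vs_control(1, c(2, 2)), "zero standard deviation")
})

test_that("AUC equals the pairwise Mann-Whitney oracle on all small instances", {
  expect_equal(roc_auc(c(3, 5), c(1, 2, 4))$auc, 5 / 6)
  expect_equal(roc_auc(c(10, 20), c(1, 2))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 1), c(1, 1, 1))$auc, 0.5)
  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    case <- sample(1:5, n1, replace = TRUE)     # ties likely
    control <- sample(1:5, n2, replace = TRUE)
    got <- roc_auc(case, control, direction = "case_high")
    expect_equal(got$auc, oracle_auc(case, control))
  }
})

test_that("AUC is invariant under strictly monotone transforms and auto-orients", {
  set.seed(12)
  case <- rnorm(9, 1); control <- rnorm(7)
  a0 <- roc_auc(case, control)$auc
  expect_equal(roc_auc(exp(case), exp(control))$auc, a0)
  expect_equal(roc_auc(case^3, control^3)$auc, a0)
  lo <- roc_auc(-case, -control)
  expect_equal(lo$auc, a0)
  expect_equal(lo$direction, "case_low")
})

test_that("correlation matrix matches a brute-force covariance oracle and is masked by p", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8.1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cm <- correlation_matrix(data.frame(x = x, y = y))
  expect_equal(cm$r["x", "y"], r_oracle, tolerance = 1e-12)
  expect_equal(diag(cm$r), c(x = 1, y = 1))
  expect_equal(cm$r["x", "y"], cm$r["y", "x"])
  expect_false(cm$mask["x", "x"])

  anti <- correlation_matrix(data.frame(a = x, b = -x))
  expect_equal(anti$r["a", "b"], -1)

  set.seed(13)
  z <- matrix(rnorm(40), 10, 4)
  full <- correlation_matrix(z)
  ev <- eigen(full$r, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))   # positive semidefinite

  expect_warning(cc <- correlation_matrix(data.frame(u = x, v = rep(1, 4))),
                 "constant")
  expect_true(all(cc$mask["v", ]))
})

test_that("planted strong biomarkers dominate the top-10 panel", {
  hits <- purrr::map_int(1:6, function(s) {
    sim <- simulate_metabolome(sim_spec(
      n_features = c(positive = 510), frac_differential = 10 / 510,
      frac_diet_derived = 0, frac_exchanged = 0,
      compartments = "content", seed = 300 + s))
    rec <- diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40") |>
      classify_differential()
    planted <- sim$ground_truth$feature_id[sim$ground_truth$label != "null"]
    sum(top_vip(rec, 10)$feature_id %in% planted)
  })
  expect_gte(mean(hits) / 10, 0.9)
})
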