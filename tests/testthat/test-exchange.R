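rec2 <- function(ids, lfc, p, sig = NULL) {
  out <- tibble::tibble(feature_id = ids, log2FC = lfc, p_value = p)
  if (!is.null(sig)) out$significant <- sig
  out
}

test_that("exchange classes follow the inverse-trend, dual-significance rule", {
  # two-point 'groups' built from printed mean pairs: Docosahexaenoic acid
  # rises in contents (430,387,933 -> 583,271,866) and falls in tissue;
  # Cytosine is the mirror case
  content <- rec2(c("DHA", "Cytosine", "X"),
                  c(log2(583271866 / 430387933), log2(25886.01 / 74390.77), 1),
                  c(5.66e-05, 0.002471, 0.01))
  tissue <- rec2(c("DHA", "Cytosine", "X"),
                 c(log2(200036643 / 238785562), log2(4832.989 / 2765.373), 2),
                 c(0.047525, 0.028388, 0.01))
  out <- exchange_classify(content, tissue)
  cls <- setNames(out$exchange_class, out$feature)
  expect_equal(cls[["DHA"]], "content_up_tissue_down")
  expect_equal(cls[["Cytosine"]], "content_down_tissue_up")
  expect_equal(cls[["X"]], "none")   # same trend in both compartments

  # significance required in BOTH compartments under the p fallback
  weak <- exchange_classify(rec2("a", 2, 0.01), rec2("a", -2, 0.2))
  expect_equal(weak$exchange_class, "none")

  # an upstream significant flag overrides the raw-p fallback
  flagged <- exchange_classify(rec2("a", 2, 0.01, sig = TRUE),
                               rec2("a", -2, 0.2, sig = TRUE))
  expect_equal(flagged$exchange_class, "content_up_tissue_down")
})

test_that("swapping compartments mirrors the classes and counts", {
  set.seed(5)
  ids <- paste0("m", 1:50)
  content <- rec2(ids, rnorm(50), runif(50, 0, 0.2))
  tissue <- rec2(ids, rnorm(50), runif(50, 0, 0.2))
  fwd <- exchange_classify(content, tissue)
  rev <- exchange_classify(tissue, content)
  mirror <- c(content_up_tissue_down = "content_down_tissue_up",
              content_down_tissue_up = "content_up_tissue_down",
              none = "none")
  expect_equal(unname(mirror[fwd$exchange_class]), rev$exchange_class)
  n_fwd <- table(factor(fwd$exchange_class, names(mirror)))
  n_rev <- table(factor(rev$exchange_class, names(mirror)))
  expect_equal(unname(n_fwd[1:2]), unname(n_rev[2:1]))
})

test_that("representatives rank by min p with |content log2FC| tie-break", {
  recs <- tibble::tibble(
    feature = c("a", "b", "c"),
    content_log2FC = c(1, 3, 2), content_p = c(0.001, 0.01, 0.005),
    tissue_log2FC = c(-1, -1, -1), tissue_p = c(0.01, 0.001, 0.5),
    exchange_class = c("content_up_tissue_down", "content_up_tissue_down", "none"))
  top <- rank_representatives(recs, "content_up_tissue_down", k = 10)
  expect_equal(top$feature, c("b", "a"))   # tie on min p 0.001, |lfc| 3 > 1
  expect_equal(nrow(rank_representatives(recs, "content_down_tissue_up")), 0)
})

test_that("planted exchanged features are recovered in their exact class", {
  sim <- simulate_metabolome(sim_spec(
    n_features = c(positive = 400), frac_differential = 0.02,
    frac_diet_derived = 0, frac_exchanged = 0.03,
    compartments = c("content", "tissue"), seed = 31))
  ct <- diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40") |>
    classify_differential()
  tt <- diff_features(sim$tables$tissue_positive, sim$metadata, "FM", "SBM40") |>
    classify_differential()
  out <- exchange_classify(ct, tt)
  truth <- sim$ground_truth
  cls <- setNames(out$exchange_class, out$feature)
  up_down <- truth$feature_name[truth$label == "exchanged_up_down"]
  down_up <- truth$feature_name[truth$label == "exchanged_down_up"]
  expect_true(all(cls[up_down] == "content_up_tissue_down"))
  expect_true(all(cls[down_up] == "content_down_tissue_up"))
  # class counts sum to the total exchanged set
  n_cls <- table(out$exchange_class)
  expect_equal(sum(n_cls[c("content_up_tissue_down", "content_down_tissue_up")]),
               length(up_down) + length(down_up))
})
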