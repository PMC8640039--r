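# Independent oracles, coded separately from the implementations they check.

# AUC by exhaustive pairwise comparison (Mann-Whitney definition)
oracle_auc <- function(case, control) {
  hits <- 0
  for (x in case) for (y in control) {
    hits <- hits + (x > y) + 0.5 * (x == y)
  }
  hits / (length(case) * length(control))
}

# Hypergeometric upper tail by direct enumeration with binomial coefficients
oracle_hyper_tail <- function(k, N, K, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force PLS1 VIP: lm-based deflation instead of matrix algebra
oracle_vip <- function(X, y, ncomp) {
  X <- scale(as.matrix(X))
  y <- y - mean(y)
  p <- ncol(X)
  W <- NULL
  ss <- NULL
  for (a in seq_len(ncomp)) {
    w <- vapply(seq_len(p), function(j) sum(X[, j] * y), numeric(1))
    w <- w / sqrt(sum(w^2))
    t_a <- as.vector(X %*% w)
    fy <- lm(y ~ t_a - 1)
    ss <- c(ss, sum(fitted(fy)^2))
    X <- apply(X, 2, function(col) resid(lm(col ~ t_a - 1)))
    y <- resid(fy)
    W <- cbind(W, w)
  }
  sqrt(p * as.vector(W^2 %*% ss) / sum(ss))
}

# small in-memory feature table + metadata pair
make_table <- function(values, groups, feature_names = NULL,
                       compartment = "content") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  tab <- dplyr::bind_cols(
    tibble::tibble(feature_id = paste0("f", seq_len(nrow(values)))),
    tibble::as_tibble(values))
  if (!is.null(feature_names)) {
    tab <- dplyr::mutate(tab, feature_name = feature_names, .after = "feature_id")
  }
  md <- tibble::tibble(sample_id = colnames(values),
                       group = factor(groups, levels = unique(groups)),
                       compartment = compartment, ion_mode = "none")
  list(table = tab, metadata = md)
}
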