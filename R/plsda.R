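#' Fit a two-class PLS-DA model (NIPALS PLS1) and compute VIP scores
#'
#' Fits partial least squares discriminant analysis with the class coded 0/1
#' and a single response (PLS1), extracted component by component with the
#' NIPALS algorithm, and computes each feature's variable importance in
#' projection:
#' \deqn{VIP_j = \sqrt{p \, \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SS_a}}
#' where \eqn{p} is the number of (non-constant) features, \eqn{w_a} the
#' feature weights of component \eqn{a}, and \eqn{SS_a} the response variance
#' explained by component \eqn{a}. By construction \eqn{\sum_j VIP_j^2 = p}.
#'
#' @param x Numeric matrix or data frame, samples in rows, features in
#'   columns.
#' @param y Class labels: a factor/character with two levels or a 0/1 vector.
#' @param ncomp Number of components; silently reduced (with a warning) if the
#'   residual rank is exhausted first.
#' @param scale Autoscale columns to mean 0, unit variance (default). Constant
#'   columns are excluded from the fit with a warning and get VIP 0.
#' @return A `plsda_fit` object; use [tidy()][generics::tidy] for per-feature
#'   VIP scores and [glance()][generics::glance] for the model summary.
#' @examples
#' x <- cbind(signal = rep(0:1, each = 10) + rnorm(20, sd = 0.2),
#'            noise = rnorm(20))
#' fit <- plsda(x, rep(c("a", "b"), each = 10), ncomp = 1)
#' tidy(fit)
#' @export
plsda <- function(x, y, ncomp = 2, scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (length(y) != nrow(x)) abort("`y` must have one label per row of `x`")
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("numeric `y` must be coded 0/1")
    y <- factor(y, levels = c(0, 1))
  } else {
    y <- factor(y)
  }
  if (nlevels(y) != 2) abort("PLS-DA here is two-class: `y` must have exactly 2 levels")
  if (min(table(y)) < 2) abort("need at least 2 samples per class")

  y0 <- as.numeric(y) - 1
  y0 <- y0 - mean(y0)
  sds <- apply(x, 2, sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warn(paste0(sum(constant), " constant feature(s) excluded from PLS-DA (VIP set to 0)"))
  }
  xi <- x[, !constant, drop = FALSE]
  xi <- scale(xi, center = TRUE, scale = scale)
  p <- ncol(xi)
  if (p == 0) abort("no non-constant features to fit")

  max_rank <- min(nrow(xi) - 1, p)
  W <- matrix(0, p, 0)
  scores <- matrix(0, nrow(xi), 0)
  ss <- numeric(0)
  tol <- 1e-12 * max(abs(xi), 1)
  Xr <- xi; yr <- y0
  for (a in seq_len(ncomp)) {
    if (a > max_rank) break
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_a <- drop(Xr %*% w)
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- drop(crossprod(Xr, t_a)) / tt
    c_a <- sum(yr * t_a) / tt
    W <- cbind(W, w)
    scores <- cbind(scores, t_a)
    ss <- c(ss, c_a^2 * tt)
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - c_a * t_a
  }
  if (ncol(W) < ncomp) {
    warn(paste0("rank exhausted: fitted ", ncol(W), " of ", ncomp, " components"))
  }
  if (ncol(W) == 0) abort("no PLS component could be extracted (response orthogonal to data)")

  vip_in <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  vip <- setNames(numeric(ncol(x)), colnames(x))
  vip[!constant] <- vip_in

  structure(
    list(vip = vip, weights = W, scores = scores, y_ss = ss,
         ncomp = ncol(W), levels = levels(y), n = nrow(x),
         n_features = ncol(x), excluded = colnames(x)[constant],
         total_y_ss = sum(y0^2)),
    class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("PLS-DA fit:", x$ncomp, "component(s),", x$n, "samples,",
      x$n_features, "features (", x$levels[1], "vs", x$levels[2], ")\n")
  cat(sprintf("Y variance explained: %.1f%%\n", 100 * sum(x$y_ss) / x$total_y_ss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-feature VIP scores of a PLS-DA fit
#'
#' @param x A [plsda()] fit.
#' @param ... Unused.
#' @return A tibble with `feature`, `vip` and `excluded` (constant features
#'   excluded from scaling), sorted by VIP descending.
#' @method tidy plsda_fit
#' @export
tidy.plsda_fit <- function(x, ...) {
  tibble::tibble(feature = names(x$vip), vip = unname(x$vip),
                 excluded = names(x$vip) %in% x$excluded) |>
    arrange(desc(.data$vip), .data$feature)
}

#' One-row summary of a PLS-DA fit
#'
#' @param x A [plsda()] fit.
#' @param ... Unused.
#' @return A tibble with component count, sample/feature counts, and the
#'   fraction of response variance explained.
#' @method glance plsda_fit
#' @export
glance.plsda_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, n_features = x$n_features,
                 n_excluded = length(x$excluded),
                 prop_y_variance = sum(x$y_ss) / x$total_y_ss)
}

#' VIP scores for a feature table restricted to two groups
#'
#' Convenience wrapper: selects the two groups' samples, applies the standard
#' metabolomics normalization (per-sample probabilistic quotient scaling,
#' log2, autoscaling), fits [plsda()] and returns the per-feature VIP.
#'
#' @param table A feature table (see [read_feature_table()]).
#' @param metadata Its sample metadata.
#' @param control,treatment Group labels.
#' @param ncomp Number of PLS components.
#' @param normalize Per-sample intensity normalization before log2:
#'   `"pqn"` (probabilistic quotient, default; robust to a minority of
#'   strongly differential features), `"total"` (total-intensity scaling to
#'   the median sample total) or `"none"`. `TRUE`/`FALSE` are accepted as
#'   shorthands for `"pqn"`/`"none"`.
#' @return A tibble `feature_id`, `feature_name` (if present), `vip`.
#' @export
plsda_vip <- function(table, metadata, control, treatment, ncomp = 2,
                      normalize = c("pqn", "total", "none")) {
  normalize <- normalize_arg(normalize)
  md <- metadata[metadata$group %in% c(control, treatment) &
                   metadata$sample_id %in% sample_cols(table), ]
  m <- ft_matrix(table, md$sample_id)
  m <- normalize_intensities(m, normalize)
  fit <- plsda(t(safe_log2(m)), factor(as.character(md$group),
                                       levels = c(control, treatment)),
               ncomp = ncomp)
  out <- tibble::tibble(feature_id = table$feature_id, vip = unname(fit$vip[table$feature_id]))
  if ("feature_name" %in% names(table)) {
    out <- dplyr::mutate(out, feature_name = table$feature_name, .after = "feature_id")
  }
  out
}
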