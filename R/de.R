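# Row-wise two-sample t-tests (vectorized). Returns t, df, p (two-sided)
# and mean_diff = rowMeans(a) - rowMeans(b).
row_ttest <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_diff = ma - mb)
}

#' Variation filter for FPKM-scale matrices
#'
#' Keeps a gene when, across samples, (max + e) / (min + e) >= `min_fold`
#' *and* max - min >= `min_abs`, with pseudo-count e = 0.001 guarding
#' against zero FPKMs. Row order is preserved.
#'
#' @param m Expression table on a non-negative (FPKM-like) scale.
#' @param min_fold Minimum fold variation (default 1.5).
#' @param min_abs Minimum absolute variation (default 1).
#' @return Filtered expression table (subset of input rows).
#' @export
variation_filter <- function(m, min_fold = 1.5, min_abs = 1) {
  vals <- expr_values(m)
  if (any(vals < 0)) abort("variation_filter expects non-negative values")
  eps <- 0.001
  mx <- apply(vals, 1, max)
  mn <- apply(vals, 1, min)
  keep <- (mx + eps) / (mn + eps) >= min_fold & (mx - mn) >= min_abs
  expr_tbl(vals[keep, , drop = FALSE], feature_kind(m))
}

#' Per-gene t-test with Benjamini-Hochberg FDR control
#'
#' Two-sample t-test (pooled variance by default, Welch optional) of
#' control vs knockdown for every gene, followed by Benjamini-Hochberg
#' step-up q-values; genes with q below `fdr` are selected and their
#' direction taken from the sign of the knockdown-minus-control mean
#' difference.
#'
#' @param m Expression table.
#' @param labels Per-sample labels, `"control"` / `"knockdown"`, named by
#'   sample id or aligned with the columns of `m`.
#' @param fdr Selection threshold on q (default 0.1).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return A tibble of class `prognet_de` with per-gene `t`, `p`, `q`,
#'   `direction`, `selected`; [glance()] gives the selection counts.
#' @export
ttest_bh <- function(m, labels, fdr = 0.1, var_equal = TRUE) {
  vals <- expr_values(m)
  if (!is.null(names(labels))) labels <- labels[colnames(vals)]
  if (length(labels) != ncol(vals)) abort("labels must cover every sample")
  if (!all(labels %in% c("control", "knockdown"))) {
    abort("labels must be 'control' or 'knockdown'")
  }
  a <- vals[, labels == "knockdown", drop = FALSE]
  b <- vals[, labels == "control", drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) abort("each group needs >= 2 samples")
  tt <- row_ttest(a, b, var_equal = var_equal)   # knockdown minus control
  q <- p.adjust(tt$p, method = "BH")
  out <- tibble(
    feature_id = rownames(vals), t = unname(tt$t), p = unname(tt$p),
    q = unname(q),
    direction = ifelse(tt$mean_diff < 0, "down_in_kd", "up_in_kd"),
    selected = q < fdr
  )
  structure(out, fdr = fdr, class = c("prognet_de", class(out)))
}

#' @export
glance.prognet_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_selected = sum(x$selected),
    n_up = sum(x$selected & x$direction == "up_in_kd"),
    n_down = sum(x$selected & x$direction == "down_in_kd"),
    fdr = attr(x, "fdr")
  )
}

#' Scale each row to the unit interval
#'
#' Affinely maps every row so its minimum becomes 0 and its maximum 1
#' (the display normalization used for expression heat maps). Constant
#' rows map to 0.5 everywhere, with a warning.
#'
#' @param m Expression table.
#' @return Scaled expression table.
#' @export
row_scale_01 <- function(m) {
  vals <- expr_values(m)
  mn <- apply(vals, 1, min)
  mx <- apply(vals, 1, max)
  rng <- mx - mn
  const <- rng == 0
  if (any(const)) {
    warn(paste0(sum(const), " constant rows mapped to 0.5"))
    rng[const] <- 1
  }
  out <- (vals - mn) / rng
  out[const, ] <- 0.5
  expr_tbl(out, feature_kind(m))
}

#' Meta-gene comparison between two sample groups
#'
#' Computes the per-sample meta-gene (mean over `genes`) and compares the
#' two label groups with a two-sample t-test.
#'
#' @inheritParams ttest_bh
#' @param genes Meta-gene member gene ids.
#' @return List with `scores` (tibble of sample, label, score) and the
#'   `t`, `p`, `mean_control`, `mean_knockdown` statistics.
#' @export
metagene_group_compare <- function(m, genes, labels, var_equal = TRUE) {
  sc <- metagene_score(m, genes)
  if (!is.null(names(labels))) labels <- labels[sc$sample_id]
  if (length(labels) != nrow(sc)) abort("labels must cover every sample")
  a <- sc$score[labels == "knockdown"]
  b <- sc$score[labels == "control"]
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(
    scores = mutate(sc, label = labels),
    t = unname(tt$statistic), p = tt$p.value,
    mean_control = mean(b), mean_knockdown = mean(a)
  )
}

#' Pearson correlation between two per-sample score vectors
#'
#' @param x,y Numeric vectors (or tibbles with `sample_id` and `score`,
#'   matched on sample id).
#' @return Tibble with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (is.data.frame(x) && is.data.frame(y)) {
    j <- left_join(x, y, by = "sample_id", suffix = c("_x", "_y"))
    x <- j$score_x; y <- j$score_y
  }
  if (length(x) != length(y)) abort("x and y must have equal length")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
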