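#' Bias-corrected standardized mean difference (Hedges g*)
#'
#' For two groups with summaries (n1, m1, s1) and (n2, m2, s2):
#' pooled sd s* = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)),
#' g = (m1 - m2) / s*, small-sample correction
#' g* = (1 - 3 / (4 (n1+n2) - 9)) g, and standard error
#' se = sqrt((n1+n2)/(n1 n2) + g*^2 / (2 (n1+n2-3.94))).
#'
#' @param x,y Either numeric value vectors for the two groups, or
#'   one-row data frames / lists with elements `n`, `mean`, `sd`.
#' @return One-row tibble with `g`, `g_star`, `se`, `n1`, `n2`.
#' @examples
#' hedges_g_star(list(n = 10, mean = 1, sd = 1), list(n = 10, mean = 0, sd = 1))
#' @export
hedges_g_star <- function(x, y) {
  sx <- group_summary(x)
  sy <- group_summary(y)
  n1 <- sx$n; n2 <- sy$n
  if (n1 < 2 || n2 < 2) abort("each group needs n >= 2")
  if (n1 + n2 < 4) abort("n1 + n2 must be >= 4")
  s_pool <- sqrt(((n1 - 1) * sx$sd^2 + (n2 - 1) * sy$sd^2) / (n1 + n2 - 2))
  if (s_pool == 0) abort("degenerate groups: pooled sd is zero")
  g <- (sx$mean - sy$mean) / s_pool
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  g_star <- j * g
  se <- sqrt((n1 + n2) / (n1 * n2) + g_star^2 / (2 * (n1 + n2 - 3.94)))
  tibble(g = g, g_star = g_star, se = se, n1 = as.integer(n1),
         n2 = as.integer(n2))
}

group_summary <- function(x) {
  if (is.numeric(x)) {
    list(n = length(x), mean = mean(x), sd = sd(x))
  } else {
    stopifnot(all(c("n", "mean", "sd") %in% names(x)))
    list(n = x$n[[1]], mean = x$mean[[1]], sd = x$sd[[1]])
  }
}

#' Random-effects combination of standardized mean differences
#'
#' DerSimonian-Laird: with fixed-effect weights w_i = 1/se_i^2 and
#' Q = sum w_i (g_i - g_FE)^2, the between-study variance is
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)); random-effects
#' weights are 1/(se_i^2 + tau^2). The combined estimate is their weighted
#' mean, with se = 1/sqrt(sum w_RE), a normal-theory 95% CI and two-sided
#' p-value.
#'
#' @param effects Tibble of per-dataset effects with columns `g_star` and
#'   `se` (as from [hedges_g_star()]); optionally a `dataset` column.
#' @return Object of class `prognet_meta`.
#' @export
random_effects_combine <- function(effects) {
  effects <- as_tibble(effects)
  k <- nrow(effects)
  if (k < 2) abort("need at least 2 effects to combine")
  if (any(effects$se <= 0)) abort("all standard errors must be positive")
  w <- 1 / effects$se^2
  fe <- sum(w * effects$g_star) / sum(w)
  q <- sum(w * (effects$g_star - fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / denom)
  w_re <- 1 / (effects$se^2 + tau2)
  est <- sum(w_re * effects$g_star) / sum(w_re)
  se <- 1 / sqrt(sum(w_re))
  structure(
    list(
      combined_smd = est, se = se,
      ci95 = c(low = est - 1.96 * se, high = est + 1.96 * se),
      p = 2 * pnorm(-abs(est / se)),
      tau2 = tau2, q = q, k = k,
      effects = effects
    ),
    class = "prognet_meta"
  )
}

#' @export
print.prognet_meta <- function(x, ...) {
  cat("Random-effects meta-analysis (DerSimonian-Laird), k =", x$k, "\n")
  cat(sprintf("  combined SMD = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$combined_smd, x$se, x$ci95[["low"]], x$ci95[["high"]]))
  cat(sprintf("  tau^2 = %.4f, Q = %.3f, p = %.4g\n", x$tau2, x$q, x$p))
  invisible(x)
}

#' Grade III vs grade I meta-analysis over multiple datasets
#'
#' Each dataset contributes a bias-corrected standardized mean difference
#' of a gene's (or meta-gene's) expression between grade III and grade I
#' tumors. Datasets must have at least 10 tumors in each grade group;
#' ineligible datasets are excluded with a message. Duplicate patient ids
#' within a dataset are deduplicated keeping the first occurrence.
#'
#' Datasets may be supplied in two shapes: value-pair form (elements
#' `grade1` and `grade3`, numeric vectors, e.g. from
#' [gen_grade_datasets()]), or expression form (elements `expr` — a
#' gene-level expression table — and `clinical` — a tibble with
#' `sample_id`, `grade` and optionally `patient_id`), in which case
#' `genes` selects the gene (length 1) or the meta-gene (length > 1).
#'
#' @param datasets List of datasets (see Details).
#' @param genes Gene id(s) used in expression form; ignored for value-pair
#'   datasets.
#' @param min_per_group Eligibility threshold per grade group.
#' @return Object of class `prognet_meta`, whose `effects` table carries
#'   one row per eligible dataset.
#' @export
run_grade_meta <- function(datasets, genes = NULL, min_per_group = 10) {
  rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    nm <- d$dataset %||% paste0("D", i)
    if (!is.null(d$grade1) && !is.null(d$grade3)) {
      v1 <- d$grade1; v3 <- d$grade3
    } else {
      stopifnot(!is.null(d$expr), !is.null(d$clinical), !is.null(genes))
      cl <- as_tibble(d$clinical)
      if ("patient_id" %in% names(cl)) {
        cl <- cl[!duplicated(cl$patient_id), ]
      }
      sc <- metagene_score(d$expr, genes)
      cl <- left_join(cl, sc, by = "sample_id")
      v1 <- cl$score[cl$grade == "I" & !is.na(cl$score)]
      v3 <- cl$score[cl$grade == "III" & !is.na(cl$score)]
    }
    if (length(v1) < min_per_group || length(v3) < min_per_group) {
      inform(paste0("excluding dataset ", nm, ": fewer than ",
                    min_per_group, " tumors in a grade group"))
      next
    }
    eff <- hedges_g_star(v3, v1)   # grade III minus grade I
    eff$dataset <- nm
    rows[[length(rows) + 1]] <- eff
  }
  if (!length(rows)) abort("no eligible datasets (all failed the n >= 10 rule)")
  if (length(rows) == 1) {
    abort("only one eligible dataset; nothing to combine")
  }
  random_effects_combine(bind_rows(rows))
}
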