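#' Meta-gene score
#'
#' A meta-gene reduces a gene set to a single per-sample score: the
#' unweighted arithmetic mean of the member genes' (log2) expression.
#'
#' @param m Gene-level expression table.
#' @param genes Character vector of member gene ids; all must be present.
#' @return A tibble with columns `sample_id`, `score`.
#' @export
metagene_score <- function(m, genes) {
  vals <- expr_values(m)
  missing <- setdiff(genes, rownames(vals))
  if (length(missing)) {
    abort(paste0("genes absent from matrix: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  sc <- colMeans(vals[genes, , drop = FALSE])
  tibble(sample_id = names(sc), score = unname(sc))
}

#' Stratify samples into high and low score groups
#'
#' Deterministic assignment: a sample is `high` only when its score is
#' strictly greater than the cutoff, so ties go to `low`. The cutoff is the
#' median (default) or the `1 - q` quantile when a top fraction `q` is
#' requested.
#'
#' @param scores Tibble from [metagene_score()] (columns `sample_id`,
#'   `score`).
#' @param rule `"median"` or `"fraction"`.
#' @param q Top fraction labelled high when `rule = "fraction"`.
#' @return Tibble with columns `sample_id`, `score`, `group`.
#' @export
stratify <- function(scores, rule = c("median", "fraction"), q = 0.5) {
  rule <- match.arg(rule)
  cutoff <- if (rule == "median") median(scores$score) else {
    quantile(scores$score, 1 - q, names = FALSE)
  }
  grp <- ifelse(scores$score > cutoff, "high", "low")
  if (all(grp == "low")) warn("all scores at or below cutoff; every sample is 'low'")
  mutate(scores, group = grp)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] to produce the step table of the
#' product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i).
#'
#' @param records Clinical tibble (`sample_id`, `time`, `event`, ...).
#' @return A tibble of class `prognet_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) abort("no survival records")
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1
  )
  out <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  structure(out, class = c("prognet_km", class(out)))
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over distinct event times (computed via
#' [survival::survdiff()]). The signed z statistic is
#' (O_A - E_A) / sqrt(V); the one-sided p-value tests the hypothesis that
#' group A (conventionally the signature-high group) has *worse* survival,
#' p = Phi(-z); the two-sided p-value comes from the chi-square with one
#' degree of freedom.
#'
#' @param group_a,group_b Clinical tibbles for the two groups (group A is
#'   the group hypothesised to do worse).
#' @return Object of class `prognet_logrank` with elements `chi_square`,
#'   `z`, `p_two_sided`, `p_one_sided`, `direction`, `n`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b)) abort("both groups need subjects")
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  g <- factor(rep(c("A", "B"), c(nrow(group_a), nrow(group_b))),
              levels = c("A", "B"))
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  v <- if (is.matrix(fit$var)) fit$var[1, 1] else fit$var[1]
  z <- (fit$obs[1] - fit$exp[1]) / sqrt(v)
  chi <- z^2
  structure(
    list(
      chi_square = unname(chi), z = unname(z),
      p_two_sided = unname(pchisq(chi, df = 1, lower.tail = FALSE)),
      p_one_sided = unname(pnorm(-z)),
      direction = if (z > 0) "a_worse" else "b_worse",
      n = length(time), n_event = sum(event)
    ),
    class = "prognet_logrank"
  )
}

#' @export
print.prognet_logrank <- function(x, ...) {
  cat("Log-rank test (n =", x$n, ")\n")
  cat(sprintf("  chi-square = %.4f, z = %.4f\n", x$chi_square, x$z))
  cat(sprintf("  two-sided p = %.4g, one-sided p (A worse) = %.4g\n",
              x$p_two_sided, x$p_one_sided))
  invisible(x)
}

#' Cox proportional-hazards hazard ratio for a binary covariate
#'
#' Fits the Cox partial likelihood with Breslow tie handling (through
#' [survival::coxph()]) for a single binary covariate and reports the
#' hazard ratio of `high` vs `low` with a Wald 95% confidence interval.
#' Complete separation of event times (monotone likelihood) is flagged
#' rather than silently returning a diverged estimate.
#'
#' @param records Clinical tibble.
#' @param group Character or factor vector aligned with `records`, two
#'   levels; the hazard ratio is for the `"high"` level vs the other (or
#'   the second factor level when no `"high"` label is present).
#' @return Object of class `prognet_cox` with `log_hr`, `hr`, `se`,
#'   `ci95`, `p`, `n_iter`, `n`, `flagged`.
#' @export
cox_hr_binary <- function(records, group) {
  if (length(group) != nrow(records)) abort("group labels must match records")
  g <- as.character(group)
  lev <- unique(g)
  if (length(lev) < 2) abort("binary covariate is constant")
  if (length(lev) > 2) abort("covariate must be binary")
  ref <- if ("high" %in% lev) setdiff(lev, "high") else lev[1]
  x <- as.integer(g != ref)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(records$time, records$event) ~ x,
      ties = "breslow", control = survival::coxph.control(iter.max = 50)
    ),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(b) || abs(b) > 15) flagged <- TRUE
  structure(
    list(
      log_hr = b, hr = exp(b), se = se,
      ci95 = c(low = exp(b - 1.96 * se), high = exp(b + 1.96 * se)),
      p = unname(2 * pnorm(-abs(b / se))),
      n_iter = fit$iter, n = nrow(records), flagged = flagged
    ),
    class = "prognet_cox"
  )
}

#' @export
print.prognet_cox <- function(x, ...) {
  cat("Cox proportional hazards (binary covariate, Breslow ties)\n")
  cat(sprintf("  HR = %.3f [%.3f, %.3f], p = %.4g, n = %d%s\n",
              x$hr, x$ci95[["low"]], x$ci95[["high"]], x$p, x$n,
              if (x$flagged) " [flagged: monotone likelihood]" else ""))
  invisible(x)
}
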