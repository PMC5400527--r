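#' Tidiers for prognet result objects
#'
#' Broom-style accessors: `tidy()` returns the per-component table of a
#' result (per-dataset effects, KM steps, per-gene rows), `glance()` a
#' one-row model-level summary.
#'
#' @param x A prognet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name prognet-tidiers
NULL

#' @rdname prognet-tidiers
#' @export
tidy.prognet_meta <- function(x, ...) {
  eff <- x$effects
  eff$weight_re <- 1 / (eff$se^2 + x$tau2)
  eff$weight_re <- eff$weight_re / sum(eff$weight_re)
  eff
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_meta <- function(x, ...) {
  tibble(combined_smd = x$combined_smd, se = x$se,
         ci_low = x$ci95[["low"]], ci_high = x$ci95[["high"]],
         p = x$p, tau2 = x$tau2, q = x$q, k = x$k)
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_logrank <- function(x, ...) {
  tibble(chi_square = x$chi_square, z = x$z,
         p_two_sided = x$p_two_sided, p_one_sided = x$p_one_sided,
         direction = x$direction, n = x$n, n_event = x$n_event)
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_cox <- function(x, ...) {
  tibble(log_hr = x$log_hr, hr = x$hr, se = x$se,
         ci_low = x$ci95[["low"]], ci_high = x$ci95[["high"]],
         p = x$p, n_iter = x$n_iter, n = x$n, flagged = x$flagged)
}

#' @rdname prognet-tidiers
#' @export
tidy.prognet_gsea <- function(x, ...) {
  tibble(position = seq_along(x$running), running_sum = x$running,
         hit = seq_along(x$running) %in% x$hit_index)
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_gsea <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, p_nominal = x$p_nominal, fdr = x$fdr,
         n_perm = x$n_perm, set_size = x$set_size)
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_permtest <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_counts),
         null_max = max(x$null_counts), p_empirical = x$p_empirical,
         n_perm = x$n_perm, null = x$null)
}

#' @rdname prognet-tidiers
#' @export
glance.prognet_signature <- function(x, ...) {
  f <- attr(x, "funnel")
  tidyr::pivot_wider(f, names_from = "stage", values_from = "n")
}
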