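#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: Kaplan-Meier step curves, forest plots of meta-analysis
#' effects, GSEA running-sum plots, and the derivation funnel.
#'
#' @param object A prognet result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name prognet-autoplot
NULL

#' @rdname prognet-autoplot
#' @export
autoplot.prognet_km <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1), object[c("time", "surv")])
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    labs(x = "Time (months)", y = "Survival probability")
}

#' Kaplan-Meier curves for high/low strata
#'
#' @param clinical Clinical tibble.
#' @param strata Tibble from [stratify()] (columns `sample_id`, `group`).
#' @return A ggplot object with one step curve per stratum.
#' @export
plot_km_strata <- function(clinical, strata) {
  df <- bind_rows(lapply(split(strata$sample_id, strata$group), function(ids) {
    km <- km_estimate(clinical[clinical$sample_id %in% ids, ])
    bind_rows(tibble(time = 0, surv = 1), km[c("time", "surv")])
  }), .id = "group")
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "Time (months)", y = "Survival probability", colour = NULL)
}

#' @rdname prognet-autoplot
#' @export
autoplot.prognet_meta <- function(object, ...) {
  eff <- tidy(object)
  eff$dataset <- eff$dataset %||% paste0("D", seq_len(nrow(eff)))
  df <- bind_rows(
    tibble(dataset = eff$dataset, est = eff$g_star,
           low = eff$g_star - 1.96 * eff$se,
           high = eff$g_star + 1.96 * eff$se, what = "dataset"),
    tibble(dataset = "Combined", est = object$combined_smd,
           low = object$ci95[["low"]], high = object$ci95[["high"]],
           what = "combined")
  )
  df$dataset <- factor(df$dataset, levels = rev(df$dataset))
  ggplot(df, aes(x = .data$est, y = .data$dataset, colour = .data$what)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$low, xmax = .data$high), height = 0.2) +
    geom_hline(yintercept = 0, colour = NA) +
    labs(x = "Standardized mean difference (g*)", y = NULL) +
    ggplot2::guides(colour = "none")
}

#' @rdname prognet-autoplot
#' @export
autoplot.prognet_gsea <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$position, y = .data$running_sum)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "Rank in ordered gene list", y = "Running enrichment score")
}

#' @rdname prognet-autoplot
#' @export
autoplot.prognet_signature <- function(object, ...) {
  f <- attr(object, "funnel")
  f$stage <- factor(f$stage, levels = f$stage)
  ggplot(f, aes(x = .data$stage, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "Features surviving stage") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
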