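#' Probes differentially expressed under both knockdown hairpins
#'
#' A probe qualifies when the control-vs-knockdown Welch t-test is below
#' `alpha` for *both* independent hairpins and the sign of the mean
#' difference agrees between them. The recorded direction is
#' `down_in_kd` when knockdown expression is below control.
#'
#' @param control,kd1,kd2 Probe-level expression tables over an identical
#'   feature space, >= 2 replicate columns each.
#' @param alpha Per-hairpin significance threshold (default 1e-6).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with columns `feature_id`, `direction`, `p_kd1`,
#'   `p_kd2` (qualifying probes only).
#' @export
differential_probes <- function(control, kd1, kd2, alpha = 1e-6,
                                var_equal = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  vc <- expr_values(control)
  v1 <- expr_values(kd1)
  v2 <- expr_values(kd2)
  if (!identical(rownames(vc), rownames(v1)) ||
      !identical(rownames(vc), rownames(v2))) {
    abort("feature ids differ between control and knockdown matrices")
  }
  if (ncol(vc) < 2 || ncol(v1) < 2 || ncol(v2) < 2) {
    abort("each arm needs >= 2 replicates")
  }
  t1 <- row_ttest(v1, vc, var_equal = var_equal)   # kd minus control
  t2 <- row_ttest(v2, vc, var_equal = var_equal)
  keep <- t1$p < alpha & t2$p < alpha &
    sign(t1$mean_diff) == sign(t2$mean_diff) & t1$mean_diff != 0
  keep[is.na(keep)] <- FALSE   # zero-variance, zero-difference probes
  tibble(
    feature_id = rownames(vc)[keep],
    direction = unname(ifelse(t1$mean_diff[keep] < 0, "down_in_kd", "up_in_kd")),
    p_kd1 = unname(t1$p[keep]), p_kd2 = unname(t2$p[keep])
  )
}

#' Per-feature prognostic screen by log-rank test
#'
#' For each feature, the cohort is split at the feature's median expression
#' (values strictly above the median form the high group) and a two-sided
#' log-rank test compares the two groups; features with p below
#' `p_threshold` are retained. Degenerate splits (fewer than two samples
#' on a side) are skipped with a warning.
#'
#' @param cohort Expression table of the training cohort.
#' @param clinical Clinical tibble covering the cohort samples.
#' @param p_threshold Retention threshold for the two-sided log-rank p
#'   (default 0.1).
#' @param features Optional subset of feature ids to screen; defaults to
#'   every feature in `cohort`. Requested features absent from the cohort
#'   are dropped with a message.
#' @param q Split quantile; 0.5 is the median split.
#' @return Tibble of retained features with their log-rank p-values; the
#'   full screen (including non-retained features) is in
#'   `attr(, "screen")`.
#' @export
prognostic_probe_filter <- function(cohort, clinical, p_threshold = 0.1,
                                    features = NULL, q = 0.5) {
  vals <- expr_values(cohort)
  clinical <- as_tibble(clinical)
  missing_samp <- setdiff(colnames(vals), clinical$sample_id)
  if (length(missing_samp)) {
    abort(paste0("cohort samples missing from clinical table: ",
                 paste(head(missing_samp, 5), collapse = ", ")))
  }
  cl <- clinical[match(colnames(vals), clinical$sample_id), ]
  if (is.null(features)) features <- rownames(vals)
  absent <- setdiff(features, rownames(vals))
  if (length(absent)) {
    inform(paste0(length(absent), " requested features absent from cohort"))
    features <- intersect(features, rownames(vals))
  }
  ps <- rep(NA_real_, length(features))
  skipped <- 0L
  for (i in seq_along(features)) {
    v <- vals[features[i], ]
    cutoff <- quantile(v, q, names = FALSE)
    hi <- v > cutoff
    if (sum(hi) < 2 || sum(!hi) < 2) {
      skipped <- skipped + 1L
      next
    }
    lr <- logrank_test(cl[hi, ], cl[!hi, ])
    ps[i] <- lr$p_two_sided
  }
  if (skipped > 0) {
    warn(paste0("skipped ", skipped, " features with degenerate splits"))
  }
  screen <- tibble(feature_id = features, p = ps)
  out <- screen[!is.na(screen$p) & screen$p < p_threshold, ]
  attr(out, "screen") <- screen
  out
}

#' Intersect two cell lines' signatures, keeping shared down-regulation
#'
#' Set intersection on gene ids followed by the direction filter: a gene
#' survives only if it is `down_in_kd` in *both* cell lines.
#'
#' @param sig_a,sig_b Tibbles with columns `gene_id` and `direction`.
#' @return Character vector of gene ids.
#' @export
intersect_and_direction <- function(sig_a, sig_b) {
  common <- intersect(sig_a$gene_id, sig_b$gene_id)
  da <- setNames(sig_a$direction, sig_a$gene_id)[common]
  db <- setNames(sig_b$direction, sig_b$gene_id)[common]
  common[da == "down_in_kd" & db == "down_in_kd"]
}

#' Keep genes over-expressed in poor-prognosis patients
#'
#' Patients are labelled `poor` (event before `horizon_months`) or `good`
#' (event-free with follow-up of at least `horizon_months`); everyone else
#' is excluded. A gene is kept when its median expression within the poor
#' group is above its overall cohort median *and* its median within the
#' good group is below the overall median.
#'
#' @param genes Candidate gene ids.
#' @param cohort Gene-level expression table.
#' @param clinical Clinical tibble.
#' @param horizon_months Prognosis horizon (default 60, i.e. 5 years).
#' @return Tibble with `gene_id`, the three medians and `kept`.
#' @export
poor_prognosis_expression_filter <- function(genes, cohort, clinical,
                                             horizon_months = 60) {
  vals <- expr_values(cohort)
  clinical <- as_tibble(clinical)
  cl <- clinical[match(colnames(vals), clinical$sample_id), ]
  poor <- cl$event & cl$time < horizon_months
  good <- !cl$event & cl$time >= horizon_months
  if (!any(poor) || !any(good)) {
    abort(paste0("empty poor or good prognosis group at horizon ",
                 horizon_months, " months"))
  }
  genes <- intersect(genes, rownames(vals))
  if (!length(genes)) {
    return(tibble(gene_id = character(), median_overall = numeric(),
                  median_poor = numeric(), median_good = numeric(),
                  kept = logical()))
  }
  sub <- vals[genes, , drop = FALSE]
  med_all <- apply(sub, 1, median)
  med_poor <- apply(sub[, poor, drop = FALSE], 1, median)
  med_good <- apply(sub[, good, drop = FALSE], 1, median)
  tibble(
    gene_id = genes, median_overall = unname(med_all),
    median_poor = unname(med_poor), median_good = unname(med_good),
    kept = med_poor > med_all & med_good < med_all
  )
}

#' Derive a poor-prognosis signature from two knockdown cell lines
#'
#' Runs the four-stage derivation funnel: (1) per-cell-line dual-hairpin
#' differential probes at `alpha`; (2) probe-to-gene mapping; (3)
#' per-cell-line prognostic screen of the mapped genes on the training
#' cohort (log-rank p < `logrank_p` at a median split); (4) two-cell-line
#' intersection keeping genes down-regulated in both, then the
#' poor-prognosis expression filter at `horizon_months`. The funnel report
#' (features surviving each stage) is attached to the result.
#'
#' @param kd_a,kd_b Per-cell-line lists with elements `control`, `kd1`,
#'   `kd2` (probe-level expression tables), as produced by
#'   [gen_knockdown_experiment()].
#' @param probe_map Tibble mapping `source_probe_id` to `gene_id`.
#' @param cohort Gene-level training-cohort expression table.
#' @param clinical Clinical tibble for the cohort.
#' @param alpha Differential threshold per hairpin (default 1e-6).
#' @param logrank_p Prognostic screen threshold (default 0.1).
#' @param horizon_months Poor/good prognosis horizon (default 60).
#' @return Object of class `prognet_signature`: tibble of signature genes
#'   with direction and provenance flags; funnel report in
#'   `attr(, "funnel")`.
#' @export
derive_signature <- function(kd_a, kd_b, probe_map, cohort, clinical,
                             alpha = 1e-6, logrank_p = 0.1,
                             horizon_months = 60) {
  probe_map <- as_tibble(probe_map)
  stopifnot(all(c("source_probe_id", "gene_id") %in% names(probe_map)))
  per_line <- function(kd) {
    diff <- differential_probes(kd$control, kd$kd1, kd$kd2, alpha = alpha)
    mapped <- diff |>
      left_join(probe_map[c("source_probe_id", "gene_id")],
                by = c(feature_id = "source_probe_id")) |>
      filter(!is.na(.data$gene_id)) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    prog <- prognostic_probe_filter(cohort, clinical,
                                    p_threshold = logrank_p,
                                    features = mapped$gene_id)
    list(diff = diff, mapped = mapped,
         prognostic = mapped[mapped$gene_id %in% prog$feature_id, ])
  }
  a <- per_line(kd_a)
  b <- per_line(kd_b)
  common_down <- intersect_and_direction(
    a$prognostic[c("gene_id", "direction")],
    b$prognostic[c("gene_id", "direction")]
  )
  pp <- poor_prognosis_expression_filter(common_down, cohort, clinical,
                                         horizon_months = horizon_months)
  final <- pp$gene_id[pp$kept]
  funnel <- tibble(
    stage = c("differential_A", "differential_B", "mapped_A", "mapped_B",
              "prognostic_A", "prognostic_B", "common_down",
              "poor_prognosis"),
    n = c(nrow(a$diff), nrow(b$diff), nrow(a$mapped), nrow(b$mapped),
          nrow(a$prognostic), nrow(b$prognostic), length(common_down),
          length(final))
  )
  out <- tibble(
    gene_id = pp$gene_id,
    direction = "down_in_kd",
    passed_prognostic = TRUE,
    passed_direction = TRUE,
    passed_poor_prognosis = pp$kept
  )
  out <- out[out$passed_poor_prognosis, ]
  attr(out, "funnel") <- funnel
  structure(out, class = c("prognet_signature", class(out)))
}

#' Funnel report of a derived signature
#'
#' @param signature A `prognet_signature` from [derive_signature()].
#' @return Tibble with columns `stage`, `n`.
#' @export
funnel_report <- function(signature) attr(signature, "funnel")
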