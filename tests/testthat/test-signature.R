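test_that("differential screen requires both hairpins to agree", {
  set.seed(2)
  base <- matrix(rnorm(40, 7, 0.1), 4, 10,
                 dimnames = list(paste0("p", 1:4), paste0("c", 1:10)))
  ctrl <- expr_tbl(base, "probe")
  # kd arms identical to control -> empty set
  same1 <- base; colnames(same1) <- paste0("k", 1:10)
  expect_equal(nrow(differential_probes(ctrl, expr_tbl(same1, "probe"),
                                        expr_tbl(same1, "probe"))), 0)
  # strong shifts: p1 down under both, p2 down under kd1 but up under kd2
  kd1 <- base + 0.02 * matrix(rnorm(40), 4, 10); kd2 <- kd1
  kd1[1, ] <- kd1[1, ] - 5; kd2[1, ] <- kd2[1, ] - 5
  kd1[2, ] <- kd1[2, ] - 5; kd2[2, ] <- kd2[2, ] + 5
  colnames(kd1) <- paste0("x", 1:10); colnames(kd2) <- paste0("y", 1:10)
  d <- differential_probes(ctrl, expr_tbl(kd1, "probe"),
                           expr_tbl(kd2, "probe"), alpha = 1e-6)
  expect_equal(d$feature_id, "p1")
  expect_equal(d$direction, "down_in_kd")
  expect_error(differential_probes(ctrl, expr_tbl(kd1, "probe"),
                                   expr_tbl(kd2, "probe"), alpha = 2),
               "alpha")
  rownames(kd2)[1] <- "other"
  expect_error(differential_probes(ctrl, expr_tbl(kd1, "probe"),
                                   expr_tbl(kd2, "probe")), "feature ids")
})

test_that("prognostic screen keeps risk-linked features and skips constants", {
  cfg <- sim_config(seed = 19, n_probes = 120, n_planted = 8,
                    n_patients = 300)
  sig <- sprintf("G%04d", 1:8)
  co <- gen_patient_cohort(cfg, sig)
  scr <- prognostic_probe_filter(co$expr, co$clinical, p_threshold = 0.1,
                                 features = sig)
  expect_gte(length(intersect(scr$feature_id, sig)), 6)
  # a feature that IS the planted risk score is retained decisively
  vals <- expr_values(co$expr)
  vals <- rbind(vals, RISK = co$truth$metagene)
  scr2 <- prognostic_probe_filter(expr_tbl(vals, "gene"), co$clinical,
                                  features = "RISK")
  expect_equal(scr2$feature_id, "RISK")
  expect_lt(scr2$p, 0.001)
  # constant feature: degenerate split, skipped with a warning
  vals["RISK", ] <- 1
  expect_warning(
    out <- prognostic_probe_filter(expr_tbl(vals, "gene"), co$clinical,
                                   features = "RISK"),
    "degenerate"
  )
  expect_equal(nrow(out), 0)
})

test_that("a survival-independent feature is retained about 10% of the time", {
  set.seed(55)
  cl <- toy_clinical(rexp(150, 0.02), runif(150) < 0.7,
                     ids = sprintf("s%03d", 1:150))
  m <- matrix(rnorm(150 * 150), 150, 150,
              dimnames = list(sprintf("f%03d", 1:150), cl$sample_id))
  scr <- prognostic_probe_filter(expr_tbl(m, "gene"), cl, p_threshold = 0.1)
  frac <- nrow(scr) / 150
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.18)
})

test_that("intersection keeps only genes down-regulated in both lines", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      direction = c("down_in_kd", "down_in_kd", "up_in_kd"))
  b <- tibble::tibble(gene_id = c("g2", "g3", "g4"),
                      direction = c("down_in_kd", "down_in_kd", "down_in_kd"))
  expect_equal(intersect_and_direction(a, b), "g2")
  expect_equal(length(intersect_and_direction(a[0, ], b)), 0)
  disj <- tibble::tibble(gene_id = "zz", direction = "down_in_kd")
  expect_equal(length(intersect_and_direction(a, disj)), 0)
})

test_that("poor-prognosis filter keeps risk genes and rejects constants", {
  cfg <- sim_config(seed = 27, n_probes = 60, n_planted = 6, n_patients = 400)
  sig <- sprintf("G%04d", 1:6)
  co <- gen_patient_cohort(cfg, sig)
  vals <- expr_values(co$expr)
  vals <- rbind(vals, RISK = co$truth$metagene,
                ANTI = -co$truth$metagene, CONST = rep(1, ncol(vals)))
  res <- poor_prognosis_expression_filter(c("RISK", "ANTI", "CONST"),
                                          expr_tbl(vals, "gene"),
                                          co$clinical)
  kept <- setNames(res$kept, res$gene_id)
  expect_true(kept[["RISK"]])
  expect_false(kept[["ANTI"]])
  expect_false(kept[["CONST"]])
  expect_error(
    poor_prognosis_expression_filter("RISK", expr_tbl(vals, "gene"),
                                     co$clinical, horizon_months = 1e6),
    "horizon"
  )
})

test_that("the funnel is monotone and recovers a planted signature", {
  cfg <- sim_config(seed = 101, n_probes = 300, n_planted = 15)
  kd <- gen_knockdown_experiment(cfg)
  co <- gen_patient_cohort(cfg, kd$truth$gene_id)
  sig <- derive_signature(kd$cell_lines$A, kd$cell_lines$B, kd$probe_map,
                          co$expr, co$clinical)
  f <- funnel_report(sig)
  n <- setNames(f$n, f$stage)
  expect_lte(n[["mapped_A"]], n[["differential_A"]])
  expect_lte(n[["prognostic_A"]], n[["mapped_A"]])
  expect_lte(n[["common_down"]], min(n[["prognostic_A"]], n[["prognostic_B"]]))
  expect_lte(n[["poor_prognosis"]], n[["common_down"]])
  expect_gte(mean(kd$truth$gene_id %in% sig$gene_id), 0.8)
  expect_lte(length(setdiff(sig$gene_id, kd$truth$gene_id)), 1)
  expect_s3_class(glance(sig), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sig), "ggplot")
})

test_that("an empty differential set propagates to an empty signature", {
  cfg <- sim_config(seed = 3, n_probes = 40, n_planted = 4, noise_sd = 0.8,
                    kd_effect_log2 = 0.01)
  kd <- gen_knockdown_experiment(cfg)
  co <- gen_patient_cohort(cfg, kd$truth$gene_id)
  sig <- derive_signature(kd$cell_lines$A, kd$cell_lines$B, kd$probe_map,
                          co$expr, co$clinical, alpha = 1e-12)
  expect_equal(nrow(sig), 0)
  expect_equal(funnel_report(sig)$n[1], 0)
})
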