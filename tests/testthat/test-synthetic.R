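test_that("generators are deterministic given the configuration", {
  cfg <- sim_config(seed = 9, n_probes = 50, n_planted = 5, n_patients = 40,
                    n_genes = 30, peaks_per_factor = 40, n_fpkm_genes = 60,
                    n_fpkm_planted = 5)
  a <- gen_knockdown_experiment(cfg)
  b <- gen_knockdown_experiment(cfg)
  expect_identical(a, b)
  expect_identical(gen_patient_cohort(cfg, a$truth$gene_id),
                   gen_patient_cohort(cfg, a$truth$gene_id))
  expect_identical(gen_grade_datasets(cfg), gen_grade_datasets(cfg))
  expect_identical(gen_genome_peaks(cfg), gen_genome_peaks(cfg))
  expect_identical(gen_fpkm_knockdown(cfg), gen_fpkm_knockdown(cfg))
  # a different root seed changes the draw
  cfg2 <- sim_config(seed = 10, n_probes = 50, n_planted = 5)
  expect_false(identical(gen_knockdown_experiment(cfg2)$cell_lines$A$control,
                         a$cell_lines$A$control))
})

test_that("noise-free knockdown arms sit exactly one effect below control", {
  cfg <- sim_config(seed = 2, n_probes = 20, n_planted = 3, noise_sd = 1e-12)
  kd <- gen_knockdown_experiment(cfg)
  for (line in kd$cell_lines) {
    ctrl <- rowMeans(expr_values(line$control))
    for (arm in c("kd1", "kd2")) {
      d <- ctrl - rowMeans(expr_values(line[[arm]]))
      expect_equal(unname(d[1:3]), rep(cfg$kd_effect_log2, 3), tolerance = 1e-6)
      expect_equal(unname(d[4:20]), rep(0, 17), tolerance = 1e-6)
    }
  }
})

test_that("planted probes reach p < 1e-6 under both hairpins in most seeds", {
  hits <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = s, n_probes = 60, n_planted = 6)
    kd <- gen_knockdown_experiment(cfg)
    d <- differential_probes(kd$cell_lines$A$control, kd$cell_lines$A$kd1,
                             kd$cell_lines$A$kd2, alpha = 1e-6)
    all(kd$truth$probe_id %in% d$feature_id)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort censoring behaves as configured", {
  cfg0 <- sim_config(seed = 7, n_probes = 30, n_planted = 3, n_patients = 200,
                     censor_rate = 0)
  co0 <- gen_patient_cohort(cfg0, sprintf("G%04d", 1:3))
  expect_true(all(co0$clinical$event))
  cfg3 <- sim_config(seed = 7, n_probes = 30, n_planted = 3,
                     n_patients = 2000, censor_rate = 0.3)
  co3 <- gen_patient_cohort(cfg3, sprintf("G%04d", 1:3))
  expect_lt(abs(mean(!co3$clinical$event) - 0.3), 0.05)
})

test_that("cohort signature genes share a latent factor", {
  cfg <- sim_config(seed = 13, n_probes = 100, n_planted = 10,
                    n_patients = 500)
  sig <- sprintf("G%04d", 1:10)
  co <- gen_patient_cohort(cfg, sig)
  vals <- expr_values(co$expr)
  cors <- cor(t(vals[sig, ]))
  off <- cors[upper.tri(cors)]
  expect_gt(mean(off), 0.35)              # loading 0.7 -> pairwise cor ~0.49
  bg <- cor(t(vals[sprintf("G%04d", 51:60), ]))
  expect_lt(mean(abs(bg[upper.tri(bg)])), 0.2)
  expect_error(gen_patient_cohort(cfg, "NOT_A_GENE"), "not in generated")
})

test_that("grade datasets respect eligibility and plant the stated SMD", {
  expect_error(sim_config(grade_n_min = 5), "at least 10")
  cfg <- sim_config(seed = 4)
  ds <- gen_grade_datasets(cfg)
  expect_length(ds, 10)
  for (d in ds) {
    expect_gte(d$n1, 10)
    expect_gte(d$n3, 10)
    expect_equal(length(d$grade1), d$n1)
  }
  smds <- vapply(ds, `[[`, 0, "true_smd")
  expect_lt(abs(mean(smds) - cfg$planted_smd), 0.4)
})

test_that("direction convention rejects non-positive knockdown effects", {
  expect_error(sim_config(kd_effect_log2 = 0), "kd_effect_log2")
  expect_error(sim_config(kd_effect_log2 = -1), "down-in-knockdown")
})

test_that("toy genome plants recoverable co-binding", {
  cfg <- sim_config(seed = 31, n_genes = 60, peaks_per_factor = 80,
                    cobind_fraction = 0.25)
  gp <- gen_genome_peaks(cfg)
  expect_length(gp$truth, 15)
  win <- promoter_windows(gp$genes, chrom_sizes = gp$chrom_sizes)
  bound <- lapply(gp$peaksets, function(p) {
    unique(assign_peaks_to_genes(p, win)$gene_id)
  })
  four_way <- Reduce(intersect, bound)
  expect_true(all(gp$truth %in% four_way))
  # gene models pass the loader's own validation after a round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(gp$genes, path)
  back <- read_gene_models(path, chrom_sizes = gp$chrom_sizes)
  expect_equal(back$tss, gp$genes$tss)
})

test_that("saturated co-binding marks every gene", {
  cfg <- sim_config(seed = 8, n_genes = 40, peaks_per_factor = 40,
                    cobind_fraction = 1)
  gp <- gen_genome_peaks(cfg)
  expect_setequal(gp$truth, gp$genes$gene_id)
  win <- promoter_windows(gp$genes, chrom_sizes = gp$chrom_sizes)
  bound <- lapply(gp$peaksets, function(p) {
    unique(assign_peaks_to_genes(p, win)$gene_id)
  })
  expect_setequal(Reduce(intersect, bound), gp$genes$gene_id)
})

test_that("FPKM knockdown plants recoverable differential genes", {
  rec <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_fpkm_genes = 300, n_fpkm_planted = 15)
    fp <- gen_fpkm_knockdown(cfg)
    de <- ttest_bh(fp$expr, fp$labels, fdr = 0.1)
    mean(fp$truth$gene_id %in% de$feature_id[de$selected])
  }, numeric(1))
  expect_gte(mean(rec >= 0.9), 0.9)
  cfg <- sim_config(seed = 1, n_fpkm_genes = 100, n_fpkm_planted = 10)
  fp <- gen_fpkm_knockdown(cfg)
  expect_true(all(expr_values(fp$expr) >= 0))
  dirs <- setNames(fp$truth$direction, fp$truth$gene_id)
  vals <- expr_values(fp$expr)
  kd <- grepl("^kd", colnames(vals))
  lfc <- log2(rowMeans(vals[fp$truth$gene_id, kd]) /
                rowMeans(vals[fp$truth$gene_id, !kd]))
  expect_true(all(lfc[dirs == "down_in_kd"] < 0))
  expect_true(all(lfc[dirs == "up_in_kd"] > 0))
})
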