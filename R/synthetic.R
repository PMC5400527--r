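#' Simulation configuration
#'
#' One configuration object drives every synthetic generator. A single root
#' `seed` deterministically derives an independent child seed per generator
#' (Mersenne-Twister streams), so any one input can be regenerated in
#' isolation and identical configurations give identical outputs.
#'
#' Defaults describe the study conditions the generators emulate: a
#' dual-shRNA knockdown with a 2 log2-unit depletion of the planted probes
#' at noise sd 0.1 and 6 replicates per arm; a 509-patient cohort whose
#' hazard depends on a planted meta-gene with hazard ratio 3 and roughly
#' 30% censoring; ten grade-labelled datasets with planted standardized
#' mean difference 0.8 and between-study heterogeneity tau = 0.2; a toy
#' genome of 3 chromosomes x 1 Mb carrying 200 genes and four 300-peak
#' transcription-factor peak sets with 30% coordinated promoter binding;
#' and an 8 vs 8 FPKM knockdown table with 3-fold planted effects.
#'
#' @param seed Root seed (integer).
#' @param n_probes Probes per knockdown array.
#' @param n_planted Number of planted (down-in-knockdown) probes.
#' @param kd_effect_log2 Planted knockdown depletion, log2 units (> 0).
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param n_reps Replicates per arm (>= 2).
#' @param n_patients Cohort size.
#' @param hazard_ratio Hazard ratio of meta-gene-high vs -low patients.
#' @param censor_rate Target fraction of censored patients, in `[0, 1]`.
#' @param n_grade_datasets Number of grade-comparison datasets.
#' @param planted_smd Mean of the per-dataset true standardized mean
#'   difference (grade III minus grade I).
#' @param tau Between-dataset sd of the true standardized mean difference.
#' @param grade_n_min,grade_n_max Range the per-group sample sizes are
#'   drawn from (both groups, uniformly).
#' @param n_chroms,chrom_len Toy genome shape.
#' @param n_genes Genes on the toy genome.
#' @param peaks_per_factor Peaks per transcription factor.
#' @param cobind_fraction Fraction of genes receiving one peak from every
#'   factor inside their promoter window.
#' @param peak_len Peak length, bp.
#' @param n_enhancers,enhancer_len,active_fraction Enhancer-mark regions:
#'   how many, their length, and the fraction also carrying the second
#'   (activity) mark.
#' @param n_fpkm_genes,n_fpkm_planted,fpkm_fold FPKM knockdown table:
#'   number of genes, planted genes per direction, planted fold change.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 1000L, n_planted = 30L,
                       kd_effect_log2 = 2, noise_sd = 0.1, n_reps = 6L,
                       n_patients = 509L, hazard_ratio = 3,
                       censor_rate = 0.3,
                       n_grade_datasets = 10L, planted_smd = 0.8, tau = 0.2,
                       grade_n_min = 10L, grade_n_max = 40L,
                       n_chroms = 3L, chrom_len = 1000000L, n_genes = 200L,
                       peaks_per_factor = 300L, cobind_fraction = 0.3,
                       peak_len = 400L,
                       n_enhancers = 100L, enhancer_len = 1000L,
                       active_fraction = 0.5,
                       n_fpkm_genes = 1000L, n_fpkm_planted = 50L,
                       fpkm_fold = 3) {
  cfg <- as.list(environment())
  counts <- c("n_probes", "n_planted", "n_reps", "n_patients",
              "n_grade_datasets", "grade_n_min", "grade_n_max", "n_chroms",
              "chrom_len", "n_genes", "peaks_per_factor", "peak_len",
              "n_enhancers", "enhancer_len", "n_fpkm_genes", "n_fpkm_planted")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) abort(paste0(f, " must be positive"))
  }
  if (cfg$n_planted >= cfg$n_probes) abort("n_planted must be < n_probes")
  if (cfg$kd_effect_log2 <= 0) {
    abort("kd_effect_log2 must be > 0 (direction convention is down-in-knockdown)")
  }
  if (cfg$n_reps < 2) abort("n_reps must be >= 2")
  for (f in c("censor_rate", "cobind_fraction", "active_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (cfg$hazard_ratio <= 0) abort("hazard_ratio must be > 0")
  if (cfg$tau < 0) abort("tau must be >= 0")
  if (cfg$grade_n_min < 10) abort("grade groups need at least 10 tumors each")
  if (cfg$grade_n_max < cfg$grade_n_min) abort("grade_n_max < grade_n_min")
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a dual-shRNA knockdown experiment in two cell lines
#'
#' For each of two cell lines, draws a per-probe baseline, then control and
#' two independent-hairpin knockdown arms with `n_reps` arrays each.
#' Planted probes are depleted by `kd_effect_log2` under both hairpins in
#' both cell lines; all other probes carry noise only. A probe-to-gene map
#' (one probe per gene, `_at`-suffixed target probe) accompanies the
#' matrices so downstream mapping is exercised.
#'
#' @param config A [sim_config()].
#' @return A list with `cell_lines` (named list of two lists, each holding
#'   `control`, `kd1`, `kd2` expression tables), `probe_map`, and `truth`
#'   (tibble of planted `probe_id`, `gene_id`, `direction`).
#' @export
gen_knockdown_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "knockdown"))
  np <- config$n_probes
  probes <- sprintf("AG%04d", seq_len(np))
  genes <- sim_gene_ids(np)
  planted <- seq_len(config$n_planted)
  arm <- function(baseline, shift) {
    m <- baseline + shift + matrix(rnorm(np * config$n_reps, sd = config$noise_sd),
                                   np, config$n_reps)
    m
  }
  make_line <- function(line) {
    baseline <- rnorm(np, mean = 7, sd = 1)
    shift <- numeric(np)
    shift[planted] <- -config$kd_effect_log2
    arms <- list(control = arm(baseline, 0),
                 kd1 = arm(baseline, shift), kd2 = arm(baseline, shift))
    lapply(names(arms), function(a) {
      m <- arms[[a]]
      rownames(m) <- probes
      colnames(m) <- paste(line, a, seq_len(config$n_reps), sep = "_")
      expr_tbl(m, "probe")
    }) |> setNames(names(arms))
  }
  list(
    cell_lines = list(A = make_line("A"), B = make_line("B")),
    probe_map = tibble(source_probe_id = probes, gene_id = genes,
                       target_probe_id = paste0(genes, "_at")),
    truth = tibble(probe_id = probes[planted], gene_id = genes[planted],
                   direction = "down_in_kd")
  )
}

#' Simulate a patient cohort with a planted prognostic meta-gene
#'
#' Expression covers the full simulated gene universe (`n_probes` genes).
#' Signature genes load on one shared latent factor per patient (loading
#' 0.7), so their meta-gene tracks the latent risk more tightly than any
#' single member; background genes are independent standard normals.
#' Event times are exponential with log-hazard `log(hazard_ratio)` for
#' patients whose true meta-gene exceeds its median; censoring is
#' independent Uniform(0, c) with c solved numerically so the expected
#' censored fraction matches `censor_rate`. Times are in months with a
#' 60-month baseline median survival.
#'
#' @param config A [sim_config()].
#' @param signature Character vector of signature gene ids (must be part of
#'   the simulated gene universe).
#' @return List of `expr` (gene-level table), `clinical` (survival
#'   records) and `truth` (per-patient meta-gene and risk group).
#' @export
gen_patient_cohort <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "cohort"))
  genes <- sim_gene_ids(config$n_probes)
  missing <- setdiff(signature, genes)
  if (length(missing)) {
    abort(paste0("signature gene(s) not in generated universe: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n <- config$n_patients
  samples <- sprintf("S%04d", seq_len(n))
  latent <- rnorm(n)
  loading <- 0.7
  vals <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, samples))
  sig_idx <- match(signature, genes)
  vals[sig_idx, ] <- loading * rep(latent, each = length(sig_idx)) +
    sqrt(1 - loading^2) * vals[sig_idx, ]
  metagene <- colMeans(vals[sig_idx, , drop = FALSE])
  high <- metagene > median(metagene)
  lambda0 <- log(2) / 60
  rate <- lambda0 * ifelse(high, config$hazard_ratio, 1)
  t_event <- rexp(n, rate = rate)
  if (config$censor_rate > 0) {
    p_cens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
    cmax <- uniroot(function(c) p_cens(c) - config$censor_rate,
                    lower = 1e-3, upper = 1e6)$root
    cens <- runif(n, 0, cmax)
    time <- pmin(t_event, cens)
    event <- t_event <= cens
  } else {
    time <- t_event
    event <- rep(TRUE, n)
  }
  clinical <- tibble(
    sample_id = samples, time = time, event = event,
    endpoint = "DMFS", er_status = NA_character_, grade = NA_character_
  )
  list(
    expr = expr_tbl(vals, "gene"),
    clinical = clinical,
    truth = tibble(sample_id = samples, metagene = metagene,
                   group = ifelse(high, "high", "low"))
  )
}

#' Simulate grade I vs grade III datasets for meta-analysis
#'
#' Each dataset draws its per-group sizes uniformly from
#' `[grade_n_min, grade_n_max]` and its true standardized mean difference
#' from Normal(`planted_smd`, `tau`^2); within-group values are unit-variance
#' Gaussians, so the group mean difference equals the SMD.
#'
#' @param config A [sim_config()].
#' @return A list with one element per dataset: `grade1` / `grade3` value
#'   vectors, the drawn sizes, and `true_smd`.
#' @export
gen_grade_datasets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "grade"))
  lapply(seq_len(config$n_grade_datasets), function(i) {
    n1 <- sample(config$grade_n_min:config$grade_n_max, 1)
    n3 <- sample(config$grade_n_min:config$grade_n_max, 1)
    smd <- rnorm(1, config$planted_smd, config$tau)
    list(
      dataset = paste0("D", i),
      grade1 = rnorm(n1, 0, 1),
      grade3 = rnorm(n3, smd, 1),
      n1 = n1, n3 = n3, true_smd = smd
    )
  })
}

#' Simulate a toy genome with gene models, enhancers and four peak sets
#'
#' Genes are placed uniformly (three-exon models, strand-aware TSS); a
#' `cobind_fraction` of them is chosen as truly co-bound and receives one
#' peak from each of the four factors fully inside its promoter window
#' (-2 kb / +2.5 kb around the TSS); remaining peaks are placed uniformly
#' within chromosomes. Enhancer-mark regions (H3K4me1-like) are placed
#' uniformly outside nothing in particular; a fraction also carries the
#' activity mark (H3K27ac-like).
#'
#' @param config A [sim_config()].
#' @return List of `chrom_sizes`, `genes`, `peaksets` (named list of four
#'   peak tables: E2F1, FRA1, MYC, TP53), `mark1`, `mark2`, and `truth`
#'   (co-bound gene ids).
#' @export
gen_genome_peaks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- tibble(chrom = chroms, length = as.integer(config$chrom_len))
  ng <- config$n_genes
  gene_ids <- sim_gene_ids(ng)
  chrom <- sample(chroms, ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  margin <- 12000L
  tss <- as.integer(round(runif(ng, margin, config$chrom_len - margin)))
  exon_off_start <- c(0L, 1500L, 3000L)
  exon_off_end <- c(500L, 2000L, 3500L)
  exon_starts <- vector("list", ng)
  exon_ends <- vector("list", ng)
  for (i in seq_len(ng)) {
    if (strand[i] == "+") {
      exon_starts[[i]] <- tss[i] + exon_off_start
      exon_ends[[i]] <- tss[i] + exon_off_end
    } else {
      exon_starts[[i]] <- sort(tss[i] - exon_off_end)
      exon_ends[[i]] <- sort(tss[i] - exon_off_start)
    }
  }
  genes <- tibble(gene_id = gene_ids, chrom = chrom, strand = strand,
                  tss = tss, exon_starts = exon_starts, exon_ends = exon_ends)
  n_cb <- round(config$cobind_fraction * ng)
  cb_idx <- if (n_cb > 0) sort(sample(seq_len(ng), n_cb)) else integer()
  factors <- c("E2F1", "FRA1", "MYC", "TP53")
  pl <- as.integer(config$peak_len)
  win <- promoter_windows(genes)
  rand_peaks <- function(k) {
    ch <- sample(chroms, k, replace = TRUE)
    st <- as.integer(floor(runif(k, 0, config$chrom_len - pl)))
    list(chrom = ch, start = st)
  }
  # co-bound promoters: one shared anchor position per gene, each factor's
  # peak jittered around it so the four peaks mutually overlap at base level
  jitter <- min(100L, pl %/% 4)
  anchor <- if (length(cb_idx)) {
    w <- win[match(gene_ids[cb_idx], win$gene_id), ]
    lo <- w$start + jitter
    hi <- w$end - pl - jitter
    as.integer(floor(runif(length(cb_idx), lo, pmax(hi, lo + 1))))
  } else integer()
  peaksets <- lapply(factors, function(f) {
    ch <- character(0); st <- integer(0)
    if (length(cb_idx)) {
      w <- win[match(gene_ids[cb_idx], win$gene_id), ]
      st <- anchor + as.integer(round(runif(length(cb_idx), -jitter, jitter)))
      st <- pmax(w$start, pmin(st, w$end - pl))
      ch <- w$chrom
    }
    n_rest <- config$peaks_per_factor - length(cb_idx)
    if (n_rest < 0) abort("peaks_per_factor < number of co-bound genes")
    if (n_rest > 0) {
      r <- rand_peaks(n_rest)
      ch <- c(ch, r$chrom); st <- c(st, r$start)
    }
    peak_tbl(ch, st, st + pl,
             name = sprintf("%s_peak_%d", f, seq_along(st)),
             score = round(runif(length(st), 5, 100), 2),
             factor_name = f)
  }) |> setNames(factors)
  enh <- rand_peaks(config$n_enhancers)
  mark1 <- peak_tbl(enh$chrom, enh$start, enh$start + config$enhancer_len,
                    factor_name = "H3K4me1")
  n_active <- round(config$active_fraction * config$n_enhancers)
  mark2 <- mark1[seq_len(n_active), ]
  mark2$factor_name <- "H3K27ac"
  list(chrom_sizes = sizes, genes = genes, peaksets = peaksets,
       mark1 = mark1, mark2 = mark2, truth = gene_ids[cb_idx])
}

#' Simulate an FPKM control-vs-knockdown table
#'
#' Sixteen samples (8 control, 8 knockdown) of log-normal FPKM values.
#' `n_fpkm_planted` genes are shifted up and as many down by
#' `log2(fpkm_fold)` in the knockdown arm.
#'
#' @param config A [sim_config()].
#' @return List of `expr` (FPKM-scale table), `labels` (per-sample
#'   `control` / `knockdown`), and `truth` (tibble of planted gene ids and
#'   directions).
#' @export
gen_fpkm_knockdown <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "fpkm"))
  ng <- config$n_fpkm_genes
  np <- config$n_fpkm_planted
  if (2 * np > ng) abort("2 * n_fpkm_planted must be <= n_fpkm_genes")
  genes <- sprintf("R%04d", seq_len(ng))
  samples <- c(paste0("ctrl_", 1:8), paste0("kd_", 1:8))
  labels <- setNames(rep(c("control", "knockdown"), each = 8), samples)
  base <- rnorm(ng, mean = 5, sd = 1)
  lfc <- numeric(ng)
  lfc[seq_len(np)] <- -log2(config$fpkm_fold)            # down in knockdown
  lfc[np + seq_len(np)] <- log2(config$fpkm_fold)        # up in knockdown
  logm <- matrix(base, ng, 16) +
    cbind(matrix(0, ng, 8), matrix(lfc, ng, 8)) +
    matrix(rnorm(ng * 16, sd = 0.25), ng, 16)
  fpkm <- 2^logm
  dimnames(fpkm) <- list(genes, samples)
  list(
    expr = expr_tbl(fpkm, "gene"),
    labels = labels,
    truth = tibble(
      gene_id = genes[seq_len(2 * np)],
      direction = rep(c("down_in_kd", "up_in_kd"), each = np)
    )
  )
}
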