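toy_genes <- function(...) {
  rows <- list(...)
  tibble::tibble(
    gene_id = vapply(rows, `[[`, "", 1),
    chrom = vapply(rows, `[[`, "", 2),
    strand = vapply(rows, `[[`, "", 3),
    tss = as.integer(vapply(rows, function(r) r[[4]], numeric(1))),
    exon_starts = lapply(rows, function(r) as.integer(r$ex_s %||% integer())),
    exon_ends = lapply(rows, function(r) as.integer(r$ex_e %||% integer()))
  )
}

test_that("promoter windows are strand-aware and clipped", {
  g <- toy_genes(list("gp", "chr1", "+", 10000),
                 list("gm", "chr1", "-", 10000),
                 list("ge", "chr1", "+", 500))
  w <- promoter_windows(g)
  expect_equal(w$start, c(8000, 7500, 0))
  expect_equal(w$end, c(12500, 12000, 3000))
  sizes <- tibble::tibble(chrom = "chr1", length = 12100L)
  wc <- promoter_windows(g, chrom_sizes = sizes)
  expect_equal(wc$end, c(12100, 12000, 3000))
})

test_that("peak-to-gene assignment uses half-open >=1 bp overlap", {
  g <- toy_genes(list("gp", "chr1", "+", 10000))
  w <- promoter_windows(g)   # [8000, 12500)
  hit <- prognet:::peak_tbl("chr1", 7900, 8100, factor_name = "TF")
  abut <- prognet:::peak_tbl("chr1", 7000, 8000, factor_name = "TF")
  other <- prognet:::peak_tbl("chr2", 8000, 8100, factor_name = "TF")
  expect_equal(assign_peaks_to_genes(hit, w)$gene_id, "gp")
  expect_equal(nrow(assign_peaks_to_genes(abut, w)), 0)
  expect_equal(nrow(assign_peaks_to_genes(other, w)), 0)
  # configurable minimum overlap
  expect_equal(nrow(assign_peaks_to_genes(hit, w, min_overlap = 150)), 0)
})

test_that("peak classification is a priority-ordered partition", {
  g <- toy_genes(list("g1", "chr1", "+", 10000,
                      ex_s = c(10000, 20000), ex_e = c(12000, 25000)))
  mark1 <- prognet:::peak_tbl("chr1", c(40000, 60000), c(41000, 61000),
                              factor_name = "H3K4me1")
  mark2 <- prognet:::peak_tbl("chr1", 40000, 41000, factor_name = "H3K27ac")
  peaks <- prognet:::peak_tbl(
    "chr1",
    c(9000, 11000, 15000, 40100, 60100, 90000),
    c(9200, 11200, 15200, 40300, 60300, 90200),
    factor_name = "TF"
  )
  cls <- classify_peaks(peaks, g, mark1, mark2)
  expect_equal(cls$category,
               c("promoter", "promoter", "intron", "active_enhancer",
                 "enhancer", "intergenic"))
  # a peak in the promoter that also overlaps an exon stays promoter
  expect_equal(cls$category[2], "promoter")
  counts <- attr(cls, "counts")
  expect_equal(sum(counts$n), nrow(peaks))
  # alternative rule: the activity mark alone can define an active enhancer
  mark2b <- prognet:::peak_tbl("chr1", 90000, 90200, factor_name = "H3K27ac")
  clsb <- classify_peaks(peaks, g, mark1, mark2b, active_rule = "mark2_only")
  expect_equal(clsb$category[6], "active_enhancer")
  clsa <- classify_peaks(peaks, g, mark1, mark2b, active_rule = "both")
  expect_equal(clsa$category[6], "intergenic")
})

test_that("multiway intersection matches the worked four-set example", {
  mk <- function(s, e) prognet:::peak_tbl("chr1", s, e, factor_name = "x")
  out <- multiway_intersection(list(mk(0, 100), mk(50, 150), mk(60, 70),
                                    mk(65, 200)))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 65)
  expect_equal(out$end, 70)
  # any empty set gives an empty result; self-intersection merges itself
  expect_equal(nrow(multiway_intersection(list(mk(0, 10), mk(integer(), integer())))), 0)
  self <- mk(c(0, 5, 100), c(7, 20, 150))
  merged <- multiway_intersection(list(self, self))
  expect_equal(merged$start, c(0, 100))
  expect_equal(merged$end, c(20, 150))
  expect_error(multiway_intersection(list()), "at least one")
})

test_that("intersection agrees with the per-base-pair oracle on random genomes", {
  set.seed(71)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    chroms <- paste0("chr", 1:2)
    len <- 5000L
    sets <- lapply(seq_len(k), function(j) {
      random_peakset(sample(5:25, 1), chroms, len, 400, paste0("f", j))
    })
    expect_equal(nrow(multiway_intersection(sets)),
                 perbp_intersection_count(sets, len),
                 info = paste("genome", i))
    # the sweep counter used inside the permutation loop agrees too
    expect_equal(prognet:::count_kway_regions(prognet:::peaks_as_sets(sets)),
                 perbp_intersection_count(sets, len))
  }
})

test_that("permutation overlap test validates inputs and detects identity", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(10000L, 8000L))
  set.seed(5)
  a <- random_peakset(30, sizes$chrom, 8000L, 200, "A")
  expect_error(permutation_overlap_test(list(a, a), sizes, n_perm = 0), "n_perm")
  expect_error(permutation_overlap_test(list(a), sizes), "two peak sets")
  long <- prognet:::peak_tbl("chr2", 0, 8500, factor_name = "L")
  expect_error(
    permutation_overlap_test(list(a, rbind(a, long)), sizes, n_perm = 9),
    "chromosome"
  )
  pt <- permutation_overlap_test(list(a, a), sizes, n_perm = 999, seed = 3)
  expect_equal(pt$p_empirical, 1 / 1000)
  expect_equal(pt$observed, nrow(multiway_intersection(list(a, a))))
  # circular-shift null also runs and preserves peak mass
  ptc <- permutation_overlap_test(list(a, a), sizes, n_perm = 19, seed = 4,
                                  null = "circular")
  expect_equal(ptc$p_empirical, 1 / 20)
  expect_s3_class(glance(pt), "tbl_df")
})

test_that("TSS coverage bins are strand-aware and rankable", {
  g <- toy_genes(list("gp", "chr1", "+", 10000),
                 list("gm", "chr1", "-", 10000))
  # one peak exactly covering the first bin upstream edge of gp's window
  pk <- prognet:::peak_tbl("chr1", 0, 500, factor_name = "TF")
  m <- tss_coverage_matrix(pk, g, flank = 10000, bin_size = 500)
  expect_equal(unname(m["gp", 1]), 500)
  expect_equal(sum(m["gp", ]), 500)
  # the same physical peak lands mirrored for the minus-strand gene
  expect_equal(unname(m["gm", ncol(m)]), 500)
  expect_equal(sum(m["gm", ]), sum(m["gp", ]))
  # no peaks -> zero matrix
  none <- prognet:::peak_tbl("chr2", 0, 100, factor_name = "TF")
  expect_true(all(tss_coverage_matrix(none, g) == 0))
  # ranking factor orders rows by its best in-window score
  rk <- prognet:::peak_tbl("chr1", c(9000, 9100), c(9050, 9150),
                           score = c(1, 50), factor_name = "E2F1")
  g2 <- toy_genes(list("lo", "chr1", "+", 5000), list("hi", "chr1", "+", 9100))
  m2 <- tss_coverage_matrix(pk, g2, flank = 1000, bin_size = 100,
                            rank_by = rk)
  expect_equal(rownames(m2)[1], "hi")
  expect_equal(ncol(m2), 20)
})

test_that("Venn region counts are exclusive and total the union", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
               C = c("g3", "g5"))
  v <- gene_set_overlaps(sets)
  expect_equal(sum(v$count), 5)
  got <- setNames(v$count, v$combination)
  expect_equal(got[["A"]], 1)          # g1
  expect_equal(got[["A&B"]], 1)        # g2
  expect_equal(got[["A&B&C"]], 1)      # g3
  expect_equal(got[["C"]], 1)          # g5
  ident <- gene_set_overlaps(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(setNames(ident$count, ident$combination)[["X&Y"]], 2)
  expect_equal(sum(ident$count), 2)
  disj <- gene_set_overlaps(list(X = "a", Y = "b"))
  expect_equal(setNames(disj$count, disj$combination)[["X&Y"]], 0)
  # brute-force enumeration oracle on random sets
  set.seed(9)
  for (i in 1:10) {
    uni <- paste0("g", 1:30)
    s <- lapply(1:3, function(j) sample(uni, sample(5:20, 1)))
    names(s) <- c("A", "B", "C")
    v <- gene_set_overlaps(s)
    for (r in seq_len(nrow(v))) {
      members <- strsplit(v$combination[r], "&", fixed = TRUE)[[1]]
      inside <- Reduce(intersect, s[members])
      outside <- unique(unlist(s[setdiff(names(s), members)]))
      expect_equal(v$count[r], length(setdiff(inside, outside)))
    }
  }
})
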