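#' Promoter windows around transcription start sites
#'
#' The promoter of a gene is the window from `up` bp upstream to `down` bp
#' downstream of its TSS (defaults -2 kb / +2.5 kb), strand-aware: on the
#' plus strand `[tss - up, tss + down)`, on the minus strand
#' `[tss - down, tss + up)`. Windows are clipped to `[0, chrom length)`
#' when a chromosome-size table is supplied.
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param up,down Upstream / downstream extents in bp.
#' @param chrom_sizes Optional chromosome-size table for clipping.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(genes, up = 2000, down = 2500,
                             chrom_sizes = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down)
  end <- ifelse(plus, genes$tss + down, genes$tss + up)
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    end <- pmin(end, len[genes$chrom])
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(start), end = as.integer(end),
         strand = genes$strand)
}

intervals_to_granges <- function(chrom, start, end, seqlevels = NULL) {
  sl <- seqlevels %||% unique(chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sl),
    # 0-based half-open -> 1-based closed; empty input intervals become
    # zero-width IRanges and overlap nothing
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}

#' Assign peaks to genes through promoter windows
#'
#' A gene is "positive" for a factor when at least one of its peaks
#' overlaps the gene's promoter window by at least `min_overlap` bp
#' (half-open coordinates: abutting intervals do not overlap).
#'
#' @param peaks Peak table (see [read_bed()]).
#' @param windows Promoter windows from [promoter_windows()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Tibble with one row per (gene, peak) hit: `gene_id`,
#'   `factor_name`, `peak_chrom`, `peak_start`, `peak_end`, `peak_name`,
#'   `score`. Positive genes are `unique(result$gene_id)`.
#' @export
assign_peaks_to_genes <- function(peaks, windows, min_overlap = 1) {
  sl <- unique(c(windows$chrom, peaks$chrom))
  gw <- intervals_to_granges(windows$chrom, windows$start, windows$end, sl)
  gp <- intervals_to_granges(peaks$chrom, peaks$start, peaks$end, sl)
  hits <- GenomicRanges::findOverlaps(gp, gw, minoverlap = min_overlap)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tibble(
    gene_id = windows$gene_id[si],
    factor_name = peaks$factor_name[qi],
    peak_chrom = peaks$chrom[qi],
    peak_start = peaks$start[qi],
    peak_end = peaks$end[qi],
    peak_name = peaks$name[qi],
    score = peaks$score[qi]
  )
}

#' Classify peaks into genomic region categories
#'
#' Assigns each peak exactly one category by the priority
#' promoter > exon > intron > active_enhancer > enhancer > intergenic.
#' An enhancer peak overlaps a primary-mark (H3K4me1-like) region outside
#' promoters and gene bodies; an *active* enhancer additionally overlaps
#' the activity mark (H3K27ac-like). With
#' `active_rule = "mark2_only"`, overlap with the activity mark alone
#' (outside promoters/genes) is enough to call a peak an active enhancer.
#'
#' @param peaks Peak table.
#' @param genes Gene-model tibble (exon lists used for exon/intron calls).
#' @param mark1 Primary enhancer-mark regions (peak table).
#' @param mark2 Activity-mark regions (peak table).
#' @param up,down Promoter window extents.
#' @param active_rule `"both"` (default: active = mark1 and mark2) or
#'   `"mark2_only"`.
#' @return The peak table with a `category` column; per-factor category
#'   counts in `attr(, "counts")`.
#' @export
classify_peaks <- function(peaks, genes, mark1, mark2,
                           up = 2000, down = 2500,
                           active_rule = c("both", "mark2_only")) {
  active_rule <- match.arg(active_rule)
  sl <- unique(c(peaks$chrom, genes$chrom, mark1$chrom, mark2$chrom))
  gp <- intervals_to_granges(peaks$chrom, peaks$start, peaks$end, sl)
  win <- promoter_windows(genes, up, down)
  overlaps_any <- function(chrom, start, end) {
    if (!length(chrom)) return(rep(FALSE, nrow(peaks)))
    gr <- intervals_to_granges(chrom, start, end, sl)
    IRanges::overlapsAny(gp, gr)
  }
  in_promoter <- overlaps_any(win$chrom, win$start, win$end)
  ex_chrom <- rep(genes$chrom, lengths(genes$exon_starts))
  ex_start <- unlist(genes$exon_starts)
  ex_end <- unlist(genes$exon_ends)
  in_exon <- overlaps_any(ex_chrom, ex_start, ex_end)
  has_body <- lengths(genes$exon_starts) > 0
  body_start <- vapply(genes$exon_starts[has_body], min, 0L)
  body_end <- vapply(genes$exon_ends[has_body], max, 0L)
  in_body <- overlaps_any(genes$chrom[has_body], body_start, body_end)
  in_m1 <- overlaps_any(mark1$chrom, mark1$start, mark1$end)
  in_m2 <- overlaps_any(mark2$chrom, mark2$start, mark2$end)
  enhancer_base <- if (active_rule == "both") in_m1 else (in_m1 | in_m2)
  category <- rep("intergenic", nrow(peaks))
  category[enhancer_base] <- "enhancer"
  category[enhancer_base & in_m2] <- "active_enhancer"
  category[in_body & !in_exon] <- "intron"
  category[in_exon] <- "exon"
  category[in_promoter] <- "promoter"
  out <- mutate(as_tibble(peaks), category = category)
  counts <- out |>
    dplyr::count(.data$factor_name, .data$category, name = "n")
  attr(out, "counts") <- counts
  out
}

# base-R interval kit used by the permutation loop: per-set merged
# intervals, then a sweep counting maximal regions covered by all k sets.
merge_intervals <- function(start, end) {
  if (!length(start)) return(list(start = integer(), end = integer()))
  o <- order(start)
  s <- start[o]; e <- end[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= me) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

count_kway_regions <- function(sets) {
  # sets: list of list(chrom=, start=, end=)
  k <- length(sets)
  chroms <- unique(unlist(lapply(sets, `[[`, "chrom")))
  total <- 0L
  for (ch in chroms) {
    pos <- list(); delta <- list()
    ok <- TRUE
    for (s in sets) {
      sel <- s$chrom == ch
      if (!any(sel)) { ok <- FALSE; break }
      m <- merge_intervals(s$start[sel], s$end[sel])
      pos[[length(pos) + 1]] <- c(m$start, m$end)
      delta[[length(delta) + 1]] <- c(rep(1L, length(m$start)),
                                      rep(-1L, length(m$end)))
    }
    if (!ok) next
    p <- unlist(pos); d <- unlist(delta)
    o <- order(p, -d)   # starts before ends at the same position
    depth <- cumsum(d[o])
    pp <- p[o]
    at_k <- depth == k
    # count maximal runs at depth k with positive width
    entries <- which(at_k & c(TRUE, !at_k[-length(at_k)]))
    for (i in entries) {
      j <- i
      while (j < length(depth) && depth[j + 1] >= k) j <- j + 1
      if (pp[min(j + 1, length(pp))] > pp[i]) total <- total + 1L
    }
  }
  total
}

peaks_as_sets <- function(peaksets) {
  lapply(peaksets, function(p) list(chrom = p$chrom, start = p$start,
                                    end = p$end))
}

#' Regions covered by every peak set
#'
#' Computes the maximal genomic regions covered by at least one peak from
#' *every* input set (interval algebra through
#' [GenomicRanges::intersect()] over per-set reduced ranges); adjacent or
#' overlapping result regions are merged. The "number of intersecting
#' peaks" reported alongside four-factor co-binding is the count of these
#' regions.
#'
#' @param peaksets List of peak tables, one per factor.
#' @return Peak table of the merged k-way-covered regions
#'   (`factor_name = "intersection"`).
#' @export
multiway_intersection <- function(peaksets) {
  if (!length(peaksets)) abort("need at least one peak set")
  if (any(vapply(peaksets, nrow, 0L) == 0)) {
    return(peak_tbl(character(), integer(), integer(),
                    factor_name = "intersection"))
  }
  sl <- unique(unlist(lapply(peaksets, function(p) p$chrom)))
  grs <- lapply(peaksets, function(p) {
    GenomicRanges::reduce(intervals_to_granges(p$chrom, p$start, p$end, sl))
  })
  acc <- Reduce(function(a, b) GenomicRanges::intersect(a, b), grs)
  acc <- GenomicRanges::reduce(acc)
  granges_to_tbl(acc, "intersection")
}

shuffle_set <- function(set, len_of, null) {
  if (null == "uniform") {
    width <- set$end - set$start
    maxs <- len_of[set$chrom] - width
    ns <- as.integer(floor(runif(length(width), 0, maxs + 1)))
    list(chrom = set$chrom, start = ns, end = ns + width)
  } else { # circular: one offset per chromosome, wrap-around peaks split
    chrom <- character(); start <- integer(); end <- integer()
    for (ch in unique(set$chrom)) {
      sel <- set$chrom == ch
      L <- len_of[[ch]]
      off <- as.integer(floor(runif(1, 0, L)))
      s <- (set$start[sel] + off) %% L
      e <- s + (set$end[sel] - set$start[sel])
      wrap <- e > L
      chrom <- c(chrom, rep(ch, sum(sel) + sum(wrap)))
      start <- c(start, s[!wrap], s[wrap], rep(0L, sum(wrap)))
      end <- c(end, e[!wrap], rep(L, sum(wrap)), as.integer(e[wrap] - L))
    }
    list(chrom = chrom, start = start, end = end)
  }
}

#' Permutation test for multi-way peak-set overlap
#'
#' Holds the first peak set fixed; in each permutation every peak of the
#' remaining sets is independently repositioned uniformly within its own
#' chromosome (length preserved, overlaps among shuffled peaks allowed),
#' the k-way intersection count is recomputed, and the empirical p-value
#' uses the add-one estimator p = (1 + #\{null >= observed\}) / (1 + n_perm),
#' so p is never zero. A circular-shift null (one random rotation per
#' chromosome per set) is available as an alternative.
#'
#' @param peaksets List of peak tables.
#' @param chrom_sizes Chromosome-size table governing all sets.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param null `"uniform"` (default) or `"circular"`.
#' @return Object of class `prognet_permtest` with `observed`,
#'   `null_counts`, `p_empirical`, `n_perm`.
#' @export
permutation_overlap_test <- function(peaksets, chrom_sizes, n_perm = 999,
                                     seed = 1, null = c("uniform", "circular")) {
  null <- match.arg(null)
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (length(peaksets) < 2) abort("need at least two peak sets")
  for (p in peaksets) validate_peaks_against_genome(p, chrom_sizes)
  len_of <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  for (p in peaksets) {
    if (any(p$end - p$start > len_of[p$chrom])) {
      abort("peak longer than its chromosome")
    }
  }
  sets <- peaks_as_sets(peaksets)
  observed <- count_kway_regions(sets)
  set.seed(seed)
  null_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sets
    for (j in 2:length(sets)) perm[[j]] <- shuffle_set(sets[[j]], len_of, null)
    null_counts[i] <- count_kway_regions(perm)
  }
  structure(
    list(
      observed = observed, null_counts = null_counts,
      p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_perm),
      n_perm = n_perm, null = null
    ),
    class = "prognet_permtest"
  )
}

#' @export
print.prognet_permtest <- function(x, ...) {
  cat("Permutation overlap test (", x$null, " null, ", x$n_perm,
      " permutations)\n", sep = "")
  cat(sprintf("  observed k-way regions = %d, null mean = %.2f, p = %.4g\n",
              x$observed, mean(x$null_counts), x$p_empirical))
  invisible(x)
}

#' Binned coverage around transcription start sites
#'
#' For every gene, sums peak coverage (with multiplicity) in fixed-width
#' bins across a window of `flank` bp either side of the TSS. Minus-strand
#' rows are reversed so bins always run 5' to 3'. Rows are ordered by
#' descending maximum score of the ranking factor's peaks within each
#' gene's window (genes without such a peak sort last); without `rank_by`
#' the input gene order is kept.
#'
#' @param peaks Peak table providing the signal.
#' @param genes Gene-model tibble.
#' @param flank Half-window around the TSS in bp (default 10000).
#' @param bin_size Bin width in bp; must divide `2 * flank`.
#' @param rank_by Optional peak table whose scores order the rows.
#' @return Numeric matrix, genes x bins; relative bin start positions in
#'   `attr(, "bin_offsets")`.
#' @export
tss_coverage_matrix <- function(peaks, genes, flank = 10000, bin_size = 500,
                                rank_by = NULL) {
  if ((2 * flank) %% bin_size != 0) abort("bin_size must divide 2 * flank")
  nbin <- as.integer(2 * flank / bin_size)
  mat <- matrix(0, nrow(genes), nbin,
                dimnames = list(genes$gene_id, NULL))
  cov_by_chrom <- list()
  for (ch in unique(peaks$chrom)) {
    sel <- peaks$chrom == ch
    cov_by_chrom[[ch]] <- IRanges::coverage(
      IRanges::IRanges(start = peaks$start[sel] + 1L, end = peaks$end[sel])
    )
  }
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    cov <- cov_by_chrom[[ch]]
    if (is.null(cov)) next
    w0 <- genes$tss[i] - flank       # 0-based window start
    starts <- w0 + (seq_len(nbin) - 1L) * bin_size + 1L   # 1-based
    ends <- starts + bin_size - 1L
    cl <- length(cov)
    vs <- numeric(nbin)
    ok <- ends >= 1 & starts <= cl
    if (any(ok)) {
      s <- pmax(starts[ok], 1L); e <- pmin(ends[ok], cl)
      vs[ok] <- IRanges::viewSums(IRanges::Views(cov, start = s, end = e))
    }
    if (genes$strand[i] == "-") vs <- rev(vs)
    mat[i, ] <- vs
  }
  if (!is.null(rank_by)) {
    win <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                  start = pmax(genes$tss - flank, 0L),
                  end = genes$tss + flank, strand = genes$strand)
    hits <- assign_peaks_to_genes(rank_by, win)
    best <- hits |>
      group_by(.data$gene_id) |>
      summarise(best = max(.data$score, na.rm = TRUE), .groups = "drop")
    key <- setNames(best$best, best$gene_id)[genes$gene_id]
    key[is.na(key)] <- -Inf
    mat <- mat[order(-key), , drop = FALSE]
  }
  attr(mat, "bin_offsets") <- (seq_len(nbin) - 1L) * bin_size - flank
  mat
}

#' Exclusive Venn-region counts for per-factor gene sets
#'
#' Counts, for every non-empty combination of the input sets, the genes
#' belonging to exactly that combination. Counts sum to the size of the
#' union.
#'
#' @param sets Named list of character vectors (gene ids per factor).
#' @return Tibble with `combination` (factor names joined by `&`),
#'   `degree`, `count`, covering all 2^k - 1 regions.
#' @export
gene_set_overlaps <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named")
  }
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(d) {
    apply(utils::combn(names(sets), d), 2, paste, collapse = "&")
  }))
  counts <- table(factor(sig, levels = combos))
  tibble(
    combination = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = as.integer(counts)
  )
}
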