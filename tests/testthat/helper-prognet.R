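# Shared fixture builders and independent oracles.

# tiny expression table built from a vector spec: list(gene = c(values...))
toy_expr <- function(rows, kind = "gene", samples = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expr_tbl(m, kind)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

toy_clinical <- function(time, event, ids = NULL) {
  tibble::tibble(
    sample_id = ids %||% paste0("s", seq_along(time)),
    time = time, event = as.logical(event), endpoint = "DMFS",
    er_status = NA_character_, grade = NA_character_
  )
}

# brute-force Benjamini-Hochberg: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    tail_js <- rank_i:m
    q[i] <- min(1, min(m / tail_js * p[o[tail_js]]))
  }
  q
}

# brute-force weighted running-sum enrichment score
es_bruteforce <- function(ids, scores, set, p = 1) {
  stopifnot(!is.unsorted(rev(scores)))
  hit <- ids %in% set
  nr <- sum(abs(scores[hit])^p)
  run <- 0
  best <- 0
  for (i in seq_along(ids)) {
    run <- run + if (hit[i]) abs(scores[i])^p / nr else -1 / (length(ids) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# per-base-pair boolean AND oracle for multi-way peak intersection: paints
# every chromosome, ANDs the per-set masks, counts maximal covered runs
perbp_intersection_count <- function(peaksets, chrom_len) {
  chroms <- unique(unlist(lapply(peaksets, function(p) p$chrom)))
  total <- 0L
  for (ch in chroms) {
    mask <- rep(TRUE, chrom_len)
    for (p in peaksets) {
      sel <- p$chrom == ch
      m <- rep(FALSE, chrom_len)
      for (i in which(sel)) {
        m[(p$start[i] + 1):min(p$end[i], chrom_len)] <- TRUE
      }
      mask <- mask & m
    }
    r <- rle(mask)
    total <- total + sum(r$values)
  }
  total
}

random_peakset <- function(n, chroms, chrom_len, max_len, factor_name) {
  ch <- sample(chroms, n, replace = TRUE)
  w <- sample(seq_len(max_len), n, replace = TRUE)
  st <- vapply(w, function(wi) sample.int(chrom_len - wi, 1) - 1L, 0L)
  prognet:::peak_tbl(ch, st, st + w, factor_name = factor_name)
}

# brute-force product-limit estimator over distinct event times
km_bruteforce <- function(time, event) {
  ev <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ev))
  for (i in seq_along(ev)) {
    n_i <- sum(time >= ev[i])
    d_i <- sum(time == ev[i] & event)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  list(time = ev, surv = out)
}
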