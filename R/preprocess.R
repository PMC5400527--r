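#' Quantile-normalize an expression table
#'
#' Forces every sample (column) onto a common distribution: after
#' normalization each column's sorted values equal the across-column mean of
#' sorted values. Ties within a column receive the mean of the reference
#' values at the tied ranks. Computation is delegated to
#' [limma::normalizeQuantiles()], whose tie rule is exactly this one.
#'
#' @param m Expression table (see [expr_tbl()]); at least two samples, no
#'   missing values.
#' @return Normalized expression table, same shape and ordering.
#' @export
quantile_normalize <- function(m) {
  vals <- expr_values(m)
  if (ncol(vals) < 2) abort("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(out) <- dimnames(vals)
  expr_tbl(out, feature_kind(m))
}

#' Median-center each feature across samples
#'
#' Subtracts the per-row median so every feature has median exactly zero,
#' the per-dataset centering applied before pooling cohorts.
#'
#' @param m Expression table.
#' @return Centered expression table. Idempotent.
#' @export
median_center_genes <- function(m) {
  vals <- expr_values(m)
  med <- apply(vals, 1, median)
  expr_tbl(vals - med, feature_kind(m))
}

#' Collapse probe-level rows to gene level
#'
#' For each gene, keeps only probes of the best available suffix class in
#' `priority` order (default: `_at` over `_x_at` over `_s_at`), then
#' averages the remaining probe rows element-wise. Genes in the map whose
#' probes are absent from the matrix are dropped with a message.
#'
#' @param m Probe-level expression table.
#' @param map Probe map: tibble with columns `target_probe_id`, `gene_id`
#'   (and optionally `source_probe_id`, ignored here). Target probe ids
#'   must end in one of the `priority` suffixes.
#' @param priority Suffix preference order, best first.
#' @return Gene-level expression table, one row per gene, gene ids sorted.
#' @export
collapse_probes <- function(m, map, priority = c("_at", "_x_at", "_s_at")) {
  vals <- expr_values(m)
  map <- as_tibble(map)
  stopifnot(all(c("target_probe_id", "gene_id") %in% names(map)))
  suffix_of <- function(p) {
    s <- rep(NA_character_, length(p))
    # check longer suffixes first so "_x_at" is not classified as "_at"
    for (suf in priority[order(-nchar(priority))]) {
      hit <- is.na(s) & endsWith(p, suf)
      s[hit] <- suf
    }
    s
  }
  map$suffix <- suffix_of(map$target_probe_id)
  if (any(is.na(map$suffix))) {
    abort(paste0("target probe id without a recognised suffix: ",
                 map$target_probe_id[which(is.na(map$suffix))[1]]))
  }
  map <- dplyr::distinct(map, .data$target_probe_id, .data$gene_id,
                         .keep_all = TRUE)
  genes_all <- unique(map$gene_id)
  map <- map[map$target_probe_id %in% rownames(vals), ]
  rank <- match(map$suffix, priority)
  out <- map |>
    mutate(rank = rank) |>
    group_by(.data$gene_id) |>
    filter(.data$rank == min(.data$rank)) |>
    ungroup()
  gene_ids <- sort(unique(out$gene_id))
  res <- matrix(0, length(gene_ids), ncol(vals),
                dimnames = list(gene_ids, colnames(vals)))
  for (g in gene_ids) {
    pr <- out$target_probe_id[out$gene_id == g]
    res[g, ] <- colMeans(vals[pr, , drop = FALSE])
  }
  n_dropped <- length(setdiff(genes_all, gene_ids))
  if (n_dropped > 0) inform(paste0("dropped ", n_dropped,
                                   " genes with no probes present"))
  expr_tbl(res, "gene")
}
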