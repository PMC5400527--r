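#' Read and write tab-separated expression matrices
#'
#' The on-disk format is a TSV whose header row carries sample ids and whose
#' first column carries feature ids. Lines starting with `#` are treated as
#' provenance comments and skipped. Loading validates the table through
#' [expr_tbl()]: duplicate feature or sample ids and non-numeric or
#' non-finite cells are hard errors.
#'
#' @param path File path.
#' @param feature_kind `"probe"` or `"gene"`.
#' @param allow_na Permit (and mean-impute) missing cells; off by default.
#' @return A `prognet_expr` tibble (see [expr_tbl()]).
#' @export
read_expression_matrix <- function(path, feature_kind = c("probe", "gene"),
                                   allow_na = FALSE) {
  feature_kind <- match.arg(feature_kind)
  hdr <- strsplit(first_data_line(path), "\t", fixed = TRUE)[[1]]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) {
    abort(paste0("duplicate column headers: ", paste(dup, collapse = ", ")))
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE, name_repair = "minimal")
  samp <- names(x)[-1]
  for (s in samp) {
    if (!is.numeric(x[[s]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[s]]))) & !is.na(x[[s]]))
      abort(paste0("non-numeric cell in column '", s, "'",
                   if (length(bad)) paste0(", row ", bad[1]) else ""))
    }
  }
  expr_tbl(x, feature_kind, allow_na = allow_na)
}

first_data_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) abort(paste0("empty file: ", path))
    if (!startsWith(l, "#")) return(l)
  }
}

provenance_line <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("prognet"))
  paste0("# prognet ", v, if (!is.null(seed)) paste0(" seed=", seed))
}

#' @rdname read_expression_matrix
#' @param x Expression table to write.
#' @param seed Optional seed recorded in the provenance comment.
#' @export
write_expression_matrix <- function(x, path, seed = NULL) {
  x <- as_tibble(x)
  writeLines(provenance_line(seed), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read peak intervals from BED / narrowPeak files
#'
#' Accepts BED3, BED6 and ENCODE narrowPeak. Coordinates are kept 0-based
#' half-open, as in the format. For narrowPeak the `signalValue` column
#' (column 7) is stored as `score`; for BED6 the BED score column is used.
#' Comment, `track` and `browser` lines are skipped.
#'
#' @param path File path.
#' @param factor_name Name of the factor or mark the peaks belong to.
#' @param chrom_sizes Optional chromosome-size table (see
#'   [read_chrom_sizes()]); when given, peaks on unknown chromosomes or
#'   running past a chromosome end are errors.
#' @return A tibble of class `prognet_peaks` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `factor_name`.
#' @export
read_bed <- function(path, factor_name, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warn(paste0("empty peak file: ", path))
    return(peak_tbl(character(), integer(), integer(), factor_name = factor_name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("fewer than 3 BED fields at line ", lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    abort(paste0("invalid interval (end <= start or negative) at line ",
                 lineno[bad[1]]))
  }
  nm <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  # narrowPeak: 10 columns, signalValue in col 7; BED6: score in col 5
  score <- rep(NA_real_, length(fields))
  is_np <- nf >= 10
  score[is_np] <- suppressWarnings(as.numeric(vapply(fields[is_np], `[[`, "", 7L)))
  score[!is_np & nf >= 5] <- suppressWarnings(
    as.numeric(vapply(fields[!is_np & nf >= 5], `[[`, "", 5L))
  )
  pk <- peak_tbl(chrom, start, end, name = as.character(nm), score = score,
                 strand = strand, factor_name = factor_name)
  if (!is.null(chrom_sizes)) validate_peaks_against_genome(pk, chrom_sizes)
  pk
}

peak_tbl <- function(chrom, start, end, name = NA_character_,
                     score = NA_real_, strand = ".", factor_name = "peak") {
  out <- tibble(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), name = as.character(name),
    score = as.numeric(score), strand = as.character(strand),
    factor_name = factor_name
  )
  structure(out, class = c("prognet_peaks", class(out)))
}

validate_peaks_against_genome <- function(peaks, chrom_sizes) {
  unk <- setdiff(unique(peaks$chrom), chrom_sizes$chrom)
  if (length(unk)) {
    abort(paste0("unknown chromosome(s): ", paste(unk, collapse = ", ")))
  }
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  over <- peaks$end > len[peaks$chrom]
  if (any(over)) {
    abort(paste0("peak extends past chromosome end on ",
                 peaks$chrom[which(over)[1]]))
  }
  invisible(peaks)
}

#' @rdname read_bed
#' @param peaks Peak table to write (BED6; score column carried in column 5).
#' @export
write_bed <- function(peaks, path) {
  df <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = ifelse(is.na(peaks$name), ".", peaks$name),
    score = ifelse(is.na(peaks$score), 0, peaks$score),
    strand = peaks$strand
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' The gene-model TSV has columns `gene_id`, `chrom`, `strand`, `tss` and
#' optionally `exon_starts`, `exon_ends` (comma-separated lists, 0-based
#' half-open). When exons are present the TSS must equal the start of the
#' first exon on the plus strand and the end of the last exon on the minus
#' strand, and exons must not overlap.
#'
#' @param path File path.
#' @param chrom_sizes Optional chromosome-size table; when given, a TSS
#'   outside its chromosome is an error.
#' @return A tibble with one row per gene; exon coordinates as list-columns.
#' @export
read_gene_models <- function(path, chrom_sizes = NULL) {
  hdr <- strsplit(first_data_line(path), "\t", fixed = TRUE)[[1]]
  # exon lists are comma-separated; never let them be parsed as numbers
  types <- list(gene_id = "c", chrom = "c", strand = "c", tss = "i",
                exon_starts = "c", exon_ends = "c")
  x <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = do.call(readr::cols, types[intersect(names(types), hdr)])
  )
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("gene model file missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (any(!x$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup)) abort(paste0("duplicate gene ids: ", paste(dup, collapse = ", ")))
  parse_list <- function(v) lapply(strsplit(as.character(v), ","), as.integer)
  if (all(c("exon_starts", "exon_ends") %in% names(x))) {
    x$exon_starts <- parse_list(x$exon_starts)
    x$exon_ends <- parse_list(x$exon_ends)
    for (i in seq_len(nrow(x))) {
      s <- x$exon_starts[[i]]; e <- x$exon_ends[[i]]
      if (length(s) != length(e) || any(e <= s)) {
        abort(paste0("invalid exons for gene ", x$gene_id[i]))
      }
      o <- order(s)
      s <- s[o]; e <- e[o]
      if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
        abort(paste0("overlapping exons for gene ", x$gene_id[i]))
      }
      expected_tss <- if (x$strand[i] == "+") s[1] else e[length(e)]
      if (x$tss[i] != expected_tss) {
        abort(paste0("tss does not match exon boundary for gene ", x$gene_id[i]))
      }
      x$exon_starts[[i]] <- s; x$exon_ends[[i]] <- e
    }
  } else {
    x$exon_starts <- rep(list(integer()), nrow(x))
    x$exon_ends <- rep(list(integer()), nrow(x))
  }
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    unk <- setdiff(unique(x$chrom), names(len))
    if (length(unk)) abort(paste0("unknown chromosome(s): ",
                                  paste(unk, collapse = ", ")))
    bad <- x$tss < 0 | x$tss >= len[x$chrom]
    if (any(bad)) abort(paste0("tss outside chromosome for gene ",
                               x$gene_id[which(bad)[1]]))
  }
  as_tibble(x)
}

#' @rdname read_gene_models
#' @param genes Gene-model table to write.
#' @export
write_gene_models <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    exon_starts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, "", collapse = ",")
  )
  if (all(out$exon_starts == "")) out <- out[c("gene_id", "chrom", "strand", "tss")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read clinical (time-to-event) tables
#'
#' Expected columns: `sample_id`, `time`, `event` (0/1 or TRUE/FALSE),
#' `endpoint` (`DMFS` or `RFS`) and optionally `er_status` (`pos`/`neg`)
#' and `grade` (`I`/`II`/`III`). Times are stored in months; pass
#' `time_unit = "years"` to convert on load.
#'
#' @param path File path.
#' @param time_unit Unit of the `time` column in the file.
#' @return A tibble of survival records, time in months.
#' @export
read_clinical <- function(path, time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("sample_id", "time", "event", "endpoint")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("clinical file missing columns: ",
                                 paste(miss, collapse = ", ")))
  x$sample_id <- as.character(x$sample_id)
  if (any(duplicated(x$sample_id))) abort("duplicate sample ids in clinical table")
  if (any(is.na(x$time)) || any(x$time < 0)) abort("survival time must be >= 0")
  if (any(is.na(x$event)) || !all(x$event %in% c(0, 1, TRUE, FALSE))) {
    abort("event flag must be 0/1")
  }
  x$event <- as.logical(x$event)
  if (!all(x$endpoint %in% c("DMFS", "RFS"))) {
    abort("endpoint must be 'DMFS' or 'RFS'")
  }
  if ("er_status" %in% names(x)) {
    x$er_status <- as.character(x$er_status)
    ok <- is.na(x$er_status) | x$er_status %in% c("pos", "neg")
    if (!all(ok)) abort("er_status must be 'pos', 'neg' or missing")
  } else {
    x$er_status <- NA_character_
  }
  if ("grade" %in% names(x)) {
    x$grade <- as.character(x$grade)
    ok <- is.na(x$grade) | x$grade %in% c("I", "II", "III")
    if (!all(ok)) abort("grade must be 'I', 'II', 'III' or missing")
  } else {
    x$grade <- NA_character_
  }
  if (time_unit == "years") x$time <- x$time * 12
  as_tibble(x[c("sample_id", "time", "event", "endpoint", "er_status", "grade")])
}

#' @rdname read_clinical
#' @param clinical Clinical table to write (time written in months).
#' @param seed Optional seed recorded in the provenance comment.
#' @export
write_clinical <- function(clinical, path, seed = NULL) {
  out <- clinical
  out$event <- as.integer(out$event)
  writeLines(provenance_line(seed), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a chromosome-size table
#'
#' Two-column TSV without header: chromosome name and length in bp.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_names = c("chrom", "length"),
                       show_col_types = FALSE, progress = FALSE)
  if (any(is.na(x$length)) || any(x$length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (any(duplicated(x$chrom))) abort("duplicate chromosome names")
  as_tibble(x)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Table to write.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes[c("chrom", "length")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene set (one id per line)
#'
#' GRP-style plain list: one gene id per line, `#` comments skipped,
#' duplicates removed preserving first occurrence.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids[!startsWith(ids, "#") & nzchar(trimws(ids))])
  unique(ids)
}

# Peaks tibble -> GRanges (0-based half-open -> IRanges 1-based closed)
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = ifelse(peaks$strand %in% c("+", "-"), peaks$strand, "*")
  )
}

granges_to_tbl <- function(gr, factor_name = "peak") {
  peak_tbl(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    factor_name = factor_name
  )
}
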