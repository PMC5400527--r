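#' Expression tables
#'
#' Throughout the package an expression matrix travels as a tibble whose
#' first column, `feature_id`, holds probe or gene identifiers and whose
#' remaining columns hold one sample each, on the log2 scale (or FPKM scale
#' for RNA-Seq-style tables). `expr_tbl()` validates and tags such a table;
#' `expr_values()` extracts the numeric matrix (features x samples) for
#' computation.
#'
#' Invariants enforced: unique feature ids, unique sample ids, all cells
#' finite numerics. Missing values are rejected unless `allow_na = TRUE`,
#' in which case they are mean-imputed per feature and the imputation count
#' reported via a message.
#'
#' @param x A data frame with a `feature_id` column followed by numeric
#'   sample columns, or a numeric matrix with rownames (features) and
#'   colnames (samples).
#' @param feature_kind Either `"probe"` or `"gene"`.
#' @param allow_na Permit missing cells (mean-imputed per feature).
#' @return A tibble of class `prognet_expr` with attribute `feature_kind`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' e <- expr_tbl(m, "gene")
#' expr_values(e)[1:2, ]
#' @export
expr_tbl <- function(x, feature_kind = c("probe", "gene"), allow_na = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs rownames (features) and colnames (samples)")
    }
    x <- tibble(feature_id = rownames(x)) |>
      dplyr::bind_cols(as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"feature_id" %in% names(x)) {
    names(x)[1] <- "feature_id"
  }
  x$feature_id <- as.character(x$feature_id)
  dup_f <- unique(x$feature_id[duplicated(x$feature_id)])
  if (length(dup_f)) {
    abort(paste0("duplicate feature ids: ", paste(head(dup_f, 5), collapse = ", ")))
  }
  samp <- setdiff(names(x), "feature_id")
  if (!length(samp)) abort("no sample columns")
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s)) {
    abort(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  for (s in samp) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("non-numeric values in sample column '", s, "'"))
    bad <- !is.finite(v)
    if (any(bad)) {
      if (!allow_na || any(is.nan(v) | is.infinite(v))) {
        abort(paste0(
          "non-finite value in sample '", s, "', feature '",
          x$feature_id[which(bad)[1]], "'"
        ))
      }
    }
  }
  if (allow_na) {
    vals <- as.matrix(x[samp])
    n_na <- sum(is.na(vals))
    if (n_na > 0) {
      rm <- rowMeans(vals, na.rm = TRUE)
      idx <- which(is.na(vals), arr.ind = TRUE)
      vals[idx] <- rm[idx[, 1]]
      x[samp] <- as_tibble(vals, .name_repair = "minimal")
      inform(paste0("mean-imputed ", n_na, " missing cells"))
    }
  }
  structure(x, feature_kind = feature_kind,
            class = c("prognet_expr", class(x)))
}

#' @rdname expr_tbl
#' @export
expr_values <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as_tibble(x)
  stopifnot("feature_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

#' @rdname expr_tbl
#' @export
feature_kind <- function(x) attr(x, "feature_kind") %||% "probe"

# matrix -> expr tibble, keeping kind
as_expr <- function(m, kind) expr_tbl(m, kind)
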