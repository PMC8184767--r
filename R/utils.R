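#' Depth-normalize a count matrix
#'
#' Scales every column (cell) of a count matrix to a fixed library size,
#' counts-per-`scale` ("CP10k" at the default). Cells with zero total counts
#' are left at zero.
#'
#' @param counts sparse or dense numeric matrix, features x cells.
#' @param scale target library size (default 1e4).
#' @return matrix of the same class and dimnames with columns summing to
#'   `scale` (or 0 for empty cells).
#' @export
normalize_depth <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  f <- ifelse(totals > 0, scale / totals, 0)
  out <- counts %*% Matrix::Diagonal(x = f, names = FALSE)
  dimnames(out) <- dimnames(counts)
  out
}

# Deterministic per-module seed derived from one pipeline seed. Kept below
# 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# shared argument checking helpers -------------------------------------------

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_labels <- function(labels, cells) {
  stop_if(is.null(names(labels)) && length(labels) != length(cells),
          "`labels` must be named by barcode or aligned to the cells")
  if (!is.null(names(labels))) {
    missing <- setdiff(cells, names(labels))
    stop_if(length(missing) > 0, "unlabeled cells: ",
            paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[cells]
  }
  as.character(labels)
}
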