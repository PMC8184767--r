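# Linking transcription-factor expression to peak accessibility.

#' Rank genes by cell-type specificity of expression
#'
#' Specificity is a standardized mean difference: (mean in the target type
#' minus mean elsewhere) divided by the pooled SD. Genes expressed only in
#' the target rank top; constant genes score 0. Ties are broken by gene id.
#'
#' @param expr genes x cells matrix (e.g. transferred expression on ATAC
#'   cells).
#' @param labels per-cell cell-type label.
#' @param target_type the type to score specificity for.
#' @return `data.frame` with gene, specificity, sorted descending.
#' @export
specificity_ranking <- function(expr, labels, target_type) {
  labels <- check_labels(labels, colnames(expr))
  stop_if(!target_type %in% labels, "target_type not present in labels")
  x <- as.matrix(expr)
  sel <- labels == target_type
  n1 <- sum(sel); n2 <- sum(!sel)
  m1 <- rowMeans(x[, sel, drop = FALSE])
  m2 <- rowMeans(x[, !sel, drop = FALSE])
  v1 <- apply(x[, sel, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !sel, drop = FALSE], 1, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  spec <- ifelse(pooled > 0, (m1 - m2) / pooled, 0)
  out <- data.frame(gene = rownames(x), specificity = unname(spec))
  out[order(-out$specificity, out$gene), , drop = FALSE]
}

# Vectorized per-row OLS of y_rows on one covariate x: slope, two-sided p.
# Equivalent to stats::lm row by row (checked against it in tests).
ols_rows <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Y <- as.matrix(Y)
  ym <- rowMeans(Y)
  beta <- as.vector(Y %*% xc) / sxx
  ssy <- rowSums(Y^2) - n * ym^2
  rss <- pmax(ssy - beta^2 * sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(beta = beta, se = se, t = tstat, p = p)
}

#' Regress peak accessibility on transcription-factor expression
#'
#' For every peak, an ordinary least-squares fit of depth-normalized
#' accessibility on a per-cell TF expression covariate (typically the
#' kNN-transferred expression), restricted to a relevant cell subset.
#' P-values are BH-corrected across all tested peaks; peaks with `q <
#' alpha` are classified "opening" (positive slope) or "closing" (negative
#' slope), others "null". Peaks with no counts in the subset are excluded.
#'
#' @param atac peaks x cells count matrix.
#' @param tf_expr per-cell covariate, named by barcode or aligned to
#'   columns; must have nonzero variance.
#' @param cells optional barcodes (or logical mask) restricting the cell
#'   subset.
#' @param alpha q-value threshold (default 0.05).
#' @param has_motif optional per-peak logical (named or aligned), recorded
#'   in the result for [motif_fraction()].
#' @param scale depth-normalization target.
#' @return `data.frame` with peak, beta, p, q, class, has_motif.
#' @export
link_tf_to_peaks <- function(atac, tf_expr, cells = NULL, alpha = 0.05,
                             has_motif = NULL, scale = 1e4) {
  if (!is.null(cells)) {
    atac <- atac[, cells, drop = FALSE]
  }
  if (!is.null(names(tf_expr))) {
    stop_if(!all(colnames(atac) %in% names(tf_expr)),
            "tf_expr missing for some cells")
    tf_expr <- unname(tf_expr[colnames(atac)])
  }
  stop_if(length(tf_expr) != ncol(atac),
          "tf_expr must cover every cell in the subset")
  stop_if(stats::var(tf_expr) == 0, "tf_expr has zero variance")
  keep <- Matrix::rowSums(atac) > 0
  if (any(!keep))
    message(sum(!keep), " peak(s) with zero counts in subset excluded")
  norm <- as.matrix(normalize_depth(atac[keep, , drop = FALSE], scale))
  fit <- ols_rows(norm, tf_expr)
  out <- data.frame(peak = rownames(norm), beta = fit$beta, p = fit$p)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$class <- ifelse(out$q < alpha,
                      ifelse(out$beta > 0, "opening", "closing"), "null")
  if (!is.null(has_motif)) {
    if (!is.null(names(has_motif))) has_motif <- has_motif[out$peak]
    else has_motif <- has_motif[keep]
    out$has_motif <- unname(has_motif)
  } else {
    out$has_motif <- NA
  }
  out
}

#' Motif fraction among opening vs closing peaks
#'
#' The fraction of significantly opening and of significantly closing peaks
#' that contain the TF's binding motif -- high among opening and low among
#' closing peaks indicates mostly direct (binding-mediated) activation plus
#' indirect repression.
#'
#' @param result `data.frame` from [link_tf_to_peaks()] with `has_motif`.
#' @return list with `frac_opening`, `frac_closing`, and the class counts.
#' @export
motif_fraction <- function(result) {
  stop_if(anyNA(result$has_motif), "has_motif not recorded in result")
  op <- result$class == "opening"
  cl <- result$class == "closing"
  stop_if(sum(op) == 0 || sum(cl) == 0,
          "need at least one opening and one closing peak")
  list(frac_opening = mean(result$has_motif[op]),
       frac_closing = mean(result$has_motif[cl]),
       n_opening = sum(op), n_closing = sum(cl))
}

#' Split cells into expression-ordered bins
#'
#' Ranks cells by TF expression and cuts them into `n_bins` contiguous
#' groups whose sizes differ by at most one; when the count does not divide
#' evenly, the extra cells go to the lowest-expression bins. Expression
#' ties are broken by barcode.
#'
#' @param tf_expr per-cell expression, named by barcode.
#' @param n_bins number of bins (default 4).
#' @return integer vector of bin labels (1 = lowest expression), named by
#'   barcode.
#' @export
expression_bins <- function(tf_expr, n_bins = 4) {
  stop_if(n_bins < 2, "n_bins must be >= 2")
  n <- length(tf_expr)
  stop_if(n < n_bins, "fewer cells than bins")
  bc <- if (is.null(names(tf_expr))) as.character(seq_len(n))
        else names(tf_expr)
  ord <- order(tf_expr, bc)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), sizes)
  stats::setNames(bins, bc)
}

#' Pseudo-bulk accessibility tracks per expression bin
#'
#' Sums cut counts per expression bin over a genomic region, normalizes
#' each bin's coverage to counts per `scale` of that bin's total in-peak
#' counts, and writes one bedGraph per bin. Each peak contributes its
#' summed count uniformly across its own span intersected with the region.
#'
#' @param atac peaks x cells counts.
#' @param peaks `GRanges` aligned with rows.
#' @param bins per-cell bin labels from [expression_bins()] (named by
#'   barcode).
#' @param region `GRanges` of length 1.
#' @param path_prefix output paths are `<prefix>_bin<i>.bedGraph`.
#' @param scale normalization target (default 1e4).
#' @return named character vector of written paths (one per bin).
#' @export
binned_tracks <- function(atac, peaks, bins, region, path_prefix,
                          scale = 1e4) {
  stop_if(length(region) != 1, "region must be a single interval")
  bc <- names(bins)
  stop_if(is.null(bc) || !all(bc %in% colnames(atac)),
          "bins must be named by barcodes present in the matrix")
  chrom <- as.character(GenomicRanges::seqnames(region))
  r_start <- GenomicRanges::start(region)
  r_end <- GenomicRanges::end(region)
  width <- r_end - r_start + 1
  ov <- GenomicRanges::findOverlaps(peaks, region, ignore.strand = TRUE)
  pk <- S4Vectors::queryHits(ov)
  paths <- character(0)
  for (b in sort(unique(bins))) {
    cells <- bc[bins == b]
    tot <- sum(atac[, cells])
    cov <- numeric(width)
    if (length(pk) > 0 && tot > 0) {
      pb <- Matrix::rowSums(atac[pk, cells, drop = FALSE]) * scale / tot
      for (i in seq_along(pk)) {
        s <- max(GenomicRanges::start(peaks)[pk[i]], r_start) - r_start + 1
        e <- min(GenomicRanges::end(peaks)[pk[i]], r_end) - r_start + 1
        cov[s:e] <- cov[s:e] + pb[i]
      }
    }
    path <- sprintf("%s_bin%d.bedGraph", path_prefix, b)
    write_bedgraph(cov, chrom, r_start - 1, path)
    paths <- c(paths, stats::setNames(path, paste0("bin", b)))
  }
  paths
}
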