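# Gene-activity scoring and cell-type-specific accessibility.

#' Promoter-extended gene window
#'
#' The scoring window for gene activity: the gene body plus `upstream_bp`
#' base pairs upstream of the transcription start site (so upstream of the
#' start on `+` strand genes and of the end on `-` strand genes), clipped at
#' the chromosome start.
#'
#' @param genes `GRanges` of gene bodies with strand.
#' @param upstream_bp upstream extension in bp (default 400).
#' @return `GRanges` of windows, same order and names.
#' @export
gene_window <- function(genes, upstream_bp = 400) {
  stop_if(upstream_bp < 0, "upstream_bp must be >= 0")
  s <- GenomicRanges::start(genes)
  e <- GenomicRanges::end(genes)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  s[plus] <- pmax(1L, s[plus] - as.integer(upstream_bp))
  e[!plus] <- e[!plus] + as.integer(upstream_bp)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(s, e),
                                strand = GenomicRanges::strand(genes))
  names(out) <- names(genes)
  S4Vectors::mcols(out) <- S4Vectors::mcols(genes)
  out
}

# width-1 GRanges at each peak's midpoint (floor of the 0-based midpoint)
peak_midpoints <- function(peaks) {
  w <- GenomicRanges::width(peaks)
  GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                         IRanges::IRanges(GenomicRanges::start(peaks) +
                                            w %/% 2L, width = 1L))
}

#' Gene activity scores from peak-level cut counts
#'
#' For every gene, sums ATAC cut counts of all peaks whose midpoint falls in
#' the gene body + upstream window; a peak whose midpoint lies in several
#' overlapping windows contributes to each of them. The result shares the
#' "gene" feature space with RNA data.
#'
#' @param atac peaks x cells count matrix (rows aligned with `peaks`).
#' @param peaks `GRanges` of peaks.
#' @param genes `GRanges` of gene bodies with strand.
#' @param upstream_bp upstream window, default 400.
#' @return genes x cells sparse matrix of summed cuts.
#' @export
compute_gene_activity <- function(atac, peaks, genes, upstream_bp = 400) {
  stop_if(nrow(atac) != length(peaks),
          "atac rows and peaks differ in length")
  win <- gene_window(genes, upstream_bp)
  hits <- GenomicRanges::findOverlaps(peak_midpoints(peaks), win,
                                      ignore.strand = TRUE)
  ind <- Matrix::sparseMatrix(i = S4Vectors::subjectHits(hits),
                              j = S4Vectors::queryHits(hits), x = 1,
                              dims = c(length(genes), length(peaks)))
  out <- ind %*% atac
  dimnames(out) <- list(names(genes), colnames(atac))
  methods::as(out, "CsparseMatrix")
}

#' Classify peaks as distal or proximal
#'
#' A peak is distal when the gap between the peak interval and the nearest
#' gene body exceeds `threshold_bp` (an overlapping or abutting peak has gap
#' 0). Strand is ignored. Peaks on chromosomes without genes are distal,
#' with a warning.
#'
#' @param peaks,genes `GRanges`.
#' @param threshold_bp gap threshold in bp (default 400).
#' @return logical vector, `TRUE` = distal.
#' @export
classify_distal <- function(peaks, genes, threshold_bp = 400) {
  stop_if(length(genes) == 0, "empty gene set")
  hit <- GenomicRanges::distanceToNearest(peaks, genes, ignore.strand = TRUE)
  dist <- rep(NA_real_, length(peaks))
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  if (anyNA(dist)) {
    warning(sum(is.na(dist)),
            " peak(s) on chromosomes without genes; classified distal")
    dist[is.na(dist)] <- Inf
  }
  dist > threshold_bp
}

# Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie and
# continuity correction), one-vs-rest for every (row, group). Values are
# ranked once per row; equivalent to stats::wilcox.test(exact = FALSE) and
# checked against it in the test suite.
ranksum_one_vs_rest <- function(x, groups) {
  f <- factor(groups)
  n <- ncol(x)
  counts <- as.vector(table(f))
  x <- as.matrix(x)
  ranks <- t(apply(x, 1, rank))
  # tie correction term per row: sum(t^3 - t) over tie groups
  tiecor <- apply(x, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  ind <- stats::model.matrix(~ f - 1)
  rank_sums <- ranks %*% ind                     # rows x groups
  p <- matrix(NA_real_, nrow(x), nlevels(f),
              dimnames = list(rownames(x), levels(f)))
  z_out <- p
  for (g in seq_len(nlevels(f))) {
    n1 <- counts[g]; n2 <- n - n1
    W <- rank_sums[, g] - n1 * (n1 + 1) / 2      # Mann-Whitney U
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tiecor / (n * (n - 1))))
    z <- W - mu
    z <- sign(z) * pmax(abs(z) - 0.5, 0) / sigma # continuity correction
    z[sigma == 0] <- 0
    p[, g] <- 2 * stats::pnorm(-abs(z))
    z_out[, g] <- z
  }
  list(p = pmin(p, 1), z = z_out)
}

#' Cell-type-specific differential accessibility
#'
#' One-vs-rest test per (peak, cell type): a two-sided Wilcoxon rank-sum
#' test on depth-normalized counts, with fold change of group means
#' (pseudocount of 1 normalized count) and Benjamini-Hochberg correction
#' across all (peak, type) pairs. A peak is called significant for a type
#' when `q < alpha` and its accessibility is at least `fc_min`-fold higher
#' in that type.
#'
#' @param atac peaks x cells count matrix.
#' @param labels per-cell cell-type label (named by barcode or aligned).
#' @param alpha q-value threshold (default 0.05).
#' @param fc_min minimum fold change (default 2).
#' @param pseudocount added to both group means (in normalized counts).
#' @param scale depth-normalization target (default 1e4).
#' @return `data.frame` with peak, cell_type, direction, fold_change, p, q,
#'   significant. Types with fewer than 2 cells are excluded with a warning.
#' @export
differential_accessibility <- function(atac, labels, alpha = 0.05,
                                       fc_min = 2, pseudocount = 1,
                                       scale = 1e4) {
  labels <- check_labels(labels, colnames(atac))
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding types with < 2 cells: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    atac <- atac[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  stop_if(length(unique(labels)) < 2, "need at least 2 cell types")
  norm <- normalize_depth(atac, scale)
  rs <- ranksum_one_vs_rest(norm, labels)
  gm <- pseudobulk(norm, labels)                 # summed normalized counts
  n_per <- as.vector(table(factor(labels)))
  mean_in <- sweep(gm, 2, n_per, "/")
  tot <- Matrix::rowSums(norm)
  mean_out <- sweep(-gm + tot, 2, ncol(atac) - n_per, "/")
  fc <- (mean_in + pseudocount) / (mean_out + pseudocount)
  out <- data.frame(
    peak = rep(rownames(atac), ncol(rs$p)),
    cell_type = rep(colnames(rs$p), each = nrow(atac)),
    direction = ifelse(as.vector(mean_in >= mean_out), "up", "down"),
    fold_change = as.vector(fc),
    p = as.vector(rs$p))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha & out$fold_change >= fc_min
  out
}

#' Distal-peak enrichment among cell-type-specific peaks
#'
#' Compares the distal fraction among cell-type-specific peaks with the
#' distal fraction among all peaks, and their ratio (fold enrichment).
#'
#' @param n_distal_specific distal peaks among the cell-type-specific set.
#' @param n_specific cell-type-specific peaks.
#' @param n_distal_all distal peaks overall.
#' @param n_all all peaks.
#' @return list with exact `frac_specific`, `frac_all`, `fold`, and a
#'   `printed` sub-list rounded for reporting: the specific fraction to the
#'   nearest integer percent, the overall fraction truncated to one decimal
#'   percent, the fold to one decimal.
#' @export
distal_enrichment <- function(n_distal_specific, n_specific,
                              n_distal_all, n_all) {
  stop_if(n_specific <= 0 || n_all <= 0, "zero denominator")
  stop_if(n_distal_specific > n_specific || n_distal_all > n_all,
          "numerator exceeds denominator")
  fs <- n_distal_specific / n_specific
  fa <- n_distal_all / n_all
  fold <- fs / fa
  list(frac_specific = fs, frac_all = fa, fold = fold,
       printed = list(pct_specific = round(100 * fs),
                      pct_all = floor(1000 * fa) / 10,
                      fold = round(fold, 1)))
}
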