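# Endoreduplication classification and developmental-progression metrics.

#' Gene-set signature score
#'
#' Per-cell mean of log1p depth-normalized expression over a gene set -- a
#' log-scale signature. With a set of ploidy markers this gives the ploidy
#' signature for that level; with cell-cycle markers, a proliferation
#' score. Invariant to uniform per-cell depth scaling.
#'
#' @param expr genes x cells count matrix.
#' @param gene_set character vector of gene ids; genes absent from `expr`
#'   are ignored (error if none remain).
#' @param scale depth-normalization target (default 1e4).
#' @return numeric vector named by cell.
#' @export
signature_score <- function(expr, gene_set, scale = 1e4) {
  sel <- intersect(gene_set, rownames(expr))
  stop_if(length(sel) == 0, "gene set has no genes in the matrix")
  norm <- log1p(normalize_depth(expr[sel, , drop = FALSE], scale))
  stats::setNames(Matrix::colMeans(norm), colnames(expr))
}

#' Log-ratio of two ploidy signatures
#'
#' The endoreduplication score: the 8n (or other high-ploidy) signature
#' relative to the diploid signature. Both inputs are log-scale signature
#' scores, so the ratio is their difference.
#'
#' @param scores_high,scores_2n per-cell signature scores, aligned on
#'   cells (matched by name when named).
#' @return numeric vector, higher = more endoreduplicated.
#' @export
ploidy_ratio <- function(scores_high, scores_2n) {
  if (!is.null(names(scores_high)) && !is.null(names(scores_2n))) {
    stop_if(!all(names(scores_high) %in% names(scores_2n)),
            "cells of the two signatures do not match")
    scores_2n <- scores_2n[names(scores_high)]
  } else {
    stop_if(length(scores_high) != length(scores_2n),
            "signatures differ in length")
  }
  scores_high - scores_2n
}

# Locally weighted (loess) fit of y on x; returns residuals and the flag
# residual > mean + threshold_sd * SD. Degree-1 local fit, tricube weights,
# no robustness iterations.
loess_residual_flag <- function(x, y, span = 0.5, threshold_sd = 1) {
  stop_if(span <= 0 || span > 1, "span must be in (0, 1]")
  stop_if(threshold_sd <= 0, "threshold_sd must be > 0")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    resid <- y - mean(y)
  } else {
    fit <- stats::loess(y ~ x, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    resid <- stats::residuals(fit)
  }
  resid <- resid - mean(resid)   # report deviations about the fit's center
  s <- stats::sd(resid)
  flag <- if (s == 0) rep(FALSE, length(resid))
          else resid > mean(resid) + threshold_sd * s
  list(residual = unname(resid), flag = unname(flag))
}

#' Accessibility-based endoreduplication classifier
#'
#' A diploid cell rarely shows more than two cuts at one peak, so cells
#' whose mean cuts per (detected) peak exceed what their sequencing depth
#' predicts are likely endoreduplicated. The cuts-per-peak metric is
#' regressed on total in-peak counts with a loess fit; cells whose residual
#' exceeds the mean by more than `threshold_sd` standard deviations are
#' flagged.
#'
#' @param atac peaks x cells count matrix (>= 20 cells).
#' @param span loess span (default 0.5).
#' @param threshold_sd residual threshold in SD units (default 1).
#' @param detected_only divide by peaks with >= 1 cut in the cell (default
#'   TRUE) or by all peaks.
#' @return `data.frame` with barcode, total_umis, cuts_per_peak, residual,
#'   endoreduplicated.
#' @export
atac_endoreduplication <- function(atac, span = 0.5, threshold_sd = 1,
                                   detected_only = TRUE) {
  stop_if(ncol(atac) < 20, "need >= 20 cells for a stable fit")
  total <- Matrix::colSums(atac)
  denom <- if (detected_only) Matrix::colSums(atac > 0)
           else rep(nrow(atac), ncol(atac))
  stop_if(any(denom == 0), "cell with no detected peaks")
  cpp <- total / denom
  lf <- loess_residual_flag(total, cpp, span, threshold_sd)
  data.frame(barcode = colnames(atac), total_umis = unname(total),
             cuts_per_peak = unname(cpp), residual = lf$residual,
             endoreduplicated = lf$flag, row.names = NULL)
}

#' Transcriptional-complexity progression metric
#'
#' The number of unique genes expressed per cell shrinks as a cell matures,
#' but also co-varies with sequencing depth. A loess fit of unique genes on
#' total UMIs removes the depth trend; the progression score is the
#' negated residual, so cells expressing fewer genes than their depth
#' predicts (later cells) score higher.
#'
#' @param expr genes x cells count matrix (>= 20 cells).
#' @param span loess span (default 0.5).
#' @return `data.frame` with barcode, total_umis, unique_genes, residual,
#'   progression_score.
#' @export
transcriptional_complexity <- function(expr, span = 0.5) {
  stop_if(ncol(expr) < 20, "need >= 20 cells for a stable fit")
  total <- Matrix::colSums(expr)
  uniq <- Matrix::colSums(expr > 0)
  lf <- loess_residual_flag(total, uniq, span, threshold_sd = 1)
  data.frame(barcode = colnames(expr), total_umis = unname(total),
             unique_genes = unname(uniq), residual = lf$residual,
             progression_score = -lf$residual, row.names = NULL)
}

#' Accessibility-based progression metric
#'
#' Per cell: total gene-activity counts divided by the number of accessible
#' genes (activity >= 1). As maturation narrows the accessible repertoire,
#' a larger share of cuts concentrates in fewer genes, so the ratio rises
#' with developmental progression.
#'
#' @param activity genes x cells gene-activity matrix.
#' @return numeric vector named by cell; cells with no accessible gene are
#'   `NA` with a warning.
#' @export
atac_progression <- function(activity) {
  total <- Matrix::colSums(activity)
  acc <- Matrix::colSums(activity >= 1)
  out <- ifelse(acc > 0, total / acc, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " cell(s) with no accessible genes")
  stats::setNames(out, colnames(activity))
}

#' Assemble the per-cell state table
#'
#' Convenience wrapper combining the ploidy signatures, the two
#' endoreduplication classifiers and the progression metrics into one
#' table.
#'
#' @param atac peaks x cells counts.
#' @param activity genes x cells gene-activity matrix for the same cells.
#' @param expr genes x RNA-cells counts (for RNA-side metrics), or NULL.
#' @param markers named list of marker gene sets per ploidy level, e.g.
#'   `list("2" = ..., "8" = ...)`; or NULL to skip signatures.
#' @param span,threshold_sd loess parameters.
#' @return `data.frame`, one row per ATAC cell (RNA metrics are reported
#'   separately when `expr` is given, as attribute `rna`).
#' @export
cell_state_table <- function(atac, activity, expr = NULL, markers = NULL,
                             span = 0.5, threshold_sd = 1) {
  out <- atac_endoreduplication(atac, span, threshold_sd)
  out$atac_progression <- unname(atac_progression(activity)[out$barcode])
  if (!is.null(expr)) {
    rna <- transcriptional_complexity(expr, span)
    if (!is.null(markers)) {
      sigs <- lapply(markers, function(g) signature_score(expr, g))
      for (lv in names(sigs)) rna[[paste0("ploidy_sig_", lv)]] <-
        unname(sigs[[lv]][rna$barcode])
      if (all(c("8", "2") %in% names(sigs)))
        rna$ploidy_ratio_8n_2n <-
          unname(ploidy_ratio(sigs[["8"]], sigs[["2"]])[rna$barcode])
    }
    attr(out, "rna") <- rna
  }
  out
}
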