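# Motif content of peaks and its association with cell-type-specific
# accessibility.

#' Read position weight matrices in MEME minimal format
#'
#' Parses the `MOTIF` blocks of a MEME-format file into a named list of
#' column-stochastic probability matrices (rows A, C, G, T; one column per
#' position).
#'
#' @param path MEME-format motif file.
#' @return named list of 4 x width probability matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  stop_if(length(starts) == 0, "no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    i <- s + 1
    while (i <= length(lines) && !grepl("^letter-probability", lines[i]))
      i <- i + 1
    stop_if(i > length(lines), "MOTIF ", nm, ": no letter-probability matrix")
    rows <- list()
    i <- i + 1
    while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    m <- t(do.call(rbind, rows))
    stop_if(nrow(m) != 4, "MOTIF ", nm, ": expected 4 probability columns")
    rownames(m) <- c("A", "C", "G", "T")
    out[[nm]] <- m
  }
  out
}

# log2-odds scoring matrix against a uniform 0.25 background, with
# zero-probability entries floored so scores stay finite
pwm_log_odds <- function(pwm, floor = 1e-4) {
  log2(pmax(pwm, floor) / 0.25)
}

# reverse-complement of a log-odds matrix: reverse columns, swap A<->T, C<->G
pwm_revcomp <- function(m) {
  m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
}

# score every window of one integer-coded sequence (codes 1..4 = ACGT,
# NA = ambiguous) against a log-odds matrix; windows containing NA score -Inf
scan_one <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  score <- numeric(n)
  for (j in seq_len(w)) {
    v <- lo[codes[j:(j + n - 1)], j]
    v[is.na(v)] <- -Inf
    score <- score + v
  }
  score
}

#' Count motif hits in peak sequences
#'
#' A naive PWM scanner: every position on both strands is scored as the
#' log2-odds of the PWM against a uniform 0.25 background, and positions
#' scoring at or above `log_odds_threshold` are counted. Overlapping hits
#' all count; windows containing ambiguous bases never match. Intended as a
#' built-in stand-in for an external scanner -- precomputed counts can be
#' supplied instead via [read_motif_counts()].
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet` of
#'   peak sequences.
#' @param pwms named list of probability matrices, as from [read_meme()].
#' @param log_odds_threshold minimum log2-odds score for a hit.
#' @param prob_floor floor applied to PWM probabilities before log-odds.
#' @return peaks x motifs integer matrix of hit counts.
#' @export
scan_motifs <- function(sequences, pwms, log_odds_threshold = 6,
                        prob_floor = 1e-4) {
  seqs <- as.character(sequences)
  code <- stats::setNames(c(1L, 2L, 3L, 4L), c("A", "C", "G", "T"))
  coded <- lapply(strsplit(toupper(seqs), ""), function(ch)
    unname(code[ch]))
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (m in seq_along(pwms)) {
    lo <- pwm_log_odds(pwms[[m]], prob_floor)
    rc <- pwm_revcomp(lo)
    out[, m] <- vapply(coded, function(cd)
      sum(scan_one(cd, lo) >= log_odds_threshold) +
        sum(scan_one(cd, rc) >= log_odds_threshold), integer(1))
  }
  out
}

#' Read peak sequences from a FASTA file
#'
#' @param path FASTA file of peak sequences, named by peak id.
#' @return named character vector of sequences, suitable for
#'   [scan_motifs()].
#' @export
read_peak_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a precomputed motif-count table
#'
#' Long-format TSV with columns `peak_id`, `motif_id`, `count`, e.g. from an
#' external scan; missing (peak, motif) pairs are 0.
#'
#' @param path TSV path.
#' @param peak_ids optional peak universe fixing row order.
#' @return peaks x motifs integer matrix.
#' @export
read_motif_counts <- function(path, peak_ids = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("peak_id", "motif_id", "count") %in% names(d)),
          "need columns peak_id, motif_id, count")
  if (is.null(peak_ids)) peak_ids <- unique(d$peak_id)
  motifs <- sort(unique(d$motif_id))
  out <- matrix(0L, length(peak_ids), length(motifs),
                dimnames = list(peak_ids, motifs))
  out[cbind(match(d$peak_id, peak_ids), match(d$motif_id, motifs))] <-
    as.integer(d$count)
  out
}

#' Relative accessibility of peaks per cell type
#'
#' Pseudo-bulks depth-normalized counts by cell type and divides each
#' type's per-peak mean accessibility by the pooled all-cell mean for that
#' peak, so a peak with no cell-type preference scores 1 everywhere. Peaks
#' with zero pooled accessibility are dropped with a warning.
#'
#' @param atac peaks x cells count matrix.
#' @param labels per-cell cell-type label.
#' @param scale depth-normalization target (default 1e4).
#' @return peaks x cell-types matrix; attribute `dropped` lists removed
#'   peaks.
#' @export
relative_accessibility <- function(atac, labels, scale = 1e4) {
  labels <- check_labels(labels, colnames(atac))
  stop_if(any(table(labels) == 0), "empty cell type")
  norm <- normalize_depth(atac, scale)
  gm <- pseudobulk(norm, labels)
  n_per <- as.vector(table(factor(labels)))
  type_mean <- sweep(gm, 2, n_per, "/")
  pooled <- Matrix::rowSums(norm) / ncol(norm)
  drop <- pooled == 0
  if (any(drop))
    warning(sum(drop), " peak(s) with zero pooled accessibility dropped")
  out <- type_mean[!drop, , drop = FALSE] / pooled[!drop]
  attr(out, "dropped") <- rownames(atac)[drop]
  out
}

#' Regress relative accessibility on motif counts
#'
#' For each (motif, cell type), an ordinary least-squares fit across peaks
#' of the type's relative accessibility on the motif's count, giving the
#' motif's effect (beta) on cell-type-specific accessibility; p-values are
#' two-sided and BH-corrected within each cell type across motifs. Motifs
#' with zero count variance are flagged undefined and excluded from the
#' correction.
#'
#' @param rel peaks x cell-types matrix from [relative_accessibility()].
#' @param motif_counts peaks x motifs count matrix (rows aligned by name
#'   when both are named).
#' @param family_map optional named character vector motif -> family.
#' @return `data.frame` with motif, cell_type, family, beta, p, q,
#'   undefined.
#' @export
motif_regression <- function(rel, motif_counts, family_map = NULL) {
  if (!is.null(rownames(rel)) && !is.null(rownames(motif_counts))) {
    stop_if(!all(rownames(rel) %in% rownames(motif_counts)),
            "peaks in `rel` missing from `motif_counts`")
    motif_counts <- motif_counts[rownames(rel), , drop = FALSE]
  } else {
    stop_if(nrow(rel) != nrow(motif_counts), "peak sets not aligned")
  }
  motifs <- colnames(motif_counts)
  types <- colnames(rel)
  grid <- expand.grid(motif = motifs, cell_type = types,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- motif_counts[, grid$motif[i]]
    if (stats::var(x) == 0)
      return(c(beta = NA_real_, p = NA_real_))
    fit <- summary(stats::lm(rel[, grid$cell_type[i]] ~ x))$coefficients
    c(beta = fit["x", "Estimate"], p = fit["x", "Pr(>|t|)"])
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$undefined <- is.na(out$beta)
  out$q <- NA_real_
  for (t in types) {
    sel <- out$cell_type == t & !out$undefined
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$family <- if (is.null(family_map)) NA_character_
                else unname(family_map[out$motif])
  out[, c("motif", "cell_type", "family", "beta", "p", "q", "undefined")]
}

#' Mean motif effect per transcription-factor family
#'
#' Motif sequence content within a TF family is redundant, so per-motif
#' effects are averaged (unweighted) over family members; undefined members
#' are excluded.
#'
#' @param effects `data.frame` from [motif_regression()] with a `family`
#'   column, or with `family_map` supplied here.
#' @param family_map optional named character vector motif -> family,
#'   overriding the `family` column.
#' @return families x cell-types matrix of mean betas.
#' @export
family_means <- function(effects, family_map = NULL) {
  fam <- if (!is.null(family_map)) unname(family_map[effects$motif])
         else effects$family
  stop_if(anyNA(fam[!effects$undefined]), "motif without a family")
  ok <- !effects$undefined
  agg <- stats::aggregate(beta ~ family + cell_type,
                          data = data.frame(family = fam[ok],
                                            cell_type = effects$cell_type[ok],
                                            beta = effects$beta[ok]),
                          FUN = mean)
  fams <- sort(unique(agg$family))
  types <- sort(unique(effects$cell_type))
  out <- matrix(NA_real_, length(fams), length(types),
                dimnames = list(fams, types))
  out[cbind(match(agg$family, fams), match(agg$cell_type, types))] <- agg$beta
  out
}

#' Hierarchically cluster cell types by family motif effects
#'
#' Agglomerative clustering of cell types (columns) on correlation distance
#' (1 - Pearson) with average linkage. Columns are put in a canonical
#' (sorted) order first so the result does not depend on input column
#' order.
#'
#' @param family_effects families x cell-types matrix from
#'   [family_means()].
#' @return an `hclust` object over cell types.
#' @export
cluster_cell_types <- function(family_effects) {
  stop_if(ncol(family_effects) < 2, "need at least 2 cell types")
  x <- family_effects[, order(colnames(family_effects)), drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  cc <- suppressWarnings(stats::cor(x))
  cc[is.na(cc)] <- 0        # zero-variance columns: maximally distant
  diag(cc) <- 1
  stats::hclust(stats::as.dist(1 - cc), method = "average")
}
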