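# Synthetic paired scATAC/scRNA data with planted ground truth.
#
# The generator emulates the structures the downstream statistics are built
# to detect: cell-type-specific peak programs, ploidy-dependent cut
# multiplicity (a Tn5 insertion requires a genomic copy, so cuts per peak
# are bounded by ploidy), age-dependent shrinkage of the expressed-gene
# repertoire, ploidy marker-gene programs, and TF-expression-driven
# opening/closing of target peaks.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_multiome()].
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells per type, per modality.
#' @param n_peaks,n_genes,n_motifs feature counts.
#' @param motif_effect_size per-motif-count multiplicative boost of openness
#'   in the motif's target cell type.
#' @param ploidy_levels subset of `c(2, 4, 8, 16)`.
#' @param ploidy_weights mixture weights over `ploidy_levels`; either one
#'   vector (recycled over types) or an `n_cell_types` x levels matrix. Each
#'   type's weights must sum to 1.
#' @param capture_rate probability in (0, 1] that a genomic copy of a fully
#'   open locus yields a cut.
#' @param depth_noise_sd SD (log scale) of the per-cell capture-efficiency
#'   factor; 0 gives deterministic per-copy capture probabilities.
#' @param tn5_damping exponent in \[0, 1\]: the transposase pool of a
#'   nucleus is shared by all genomic copies, so the per-copy capture
#'   probability is scaled by `(ploidy/2)^-tn5_damping`. 0 = copies cut
#'   independently (total depth grows linearly with ploidy); 1 = fully
#'   limiting reagent (expected depth independent of ploidy).
#' @param age_diversity_slope fractional loss of the expressed-gene (and
#'   accessible-peak) repertoire from age 0 to age 1.
#' @param n_ploidy_markers marker genes per ploidy level.
#' @param marker_boost expression fold-up of a ploidy marker in cells of the
#'   matching ploidy.
#' @param tf_gene_index index of the gene treated as the regulating TF.
#' @param n_linked_open,n_linked_close planted peaks whose openness rises /
#'   falls with TF expression.
#' @param linked_effect magnitude of the TF-linkage term.
#' @param frac_open_with_motif,frac_close_with_motif probability that a
#'   planted opening / closing peak carries the TF family's binding motif
#'   (direct vs indirect regulation).
#' @param motif_bg_rate Poisson rate of background motif occurrences per
#'   peak.
#' @param type_boost openness fold-up of a peak in its owning cell type.
#' @param base_openness background openness of every peak.
#' @param nb_size negative-binomial size (inverse dispersion) for RNA
#'   counts.
#' @param seed integer seed; the simulation is deterministic given the
#'   config.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_cell_types = 5,
                              cells_per_type = 200,
                              n_peaks = 2000,
                              n_genes = 1000,
                              n_motifs = 10,
                              motif_effect_size = 0.25,
                              ploidy_levels = c(2, 8),
                              ploidy_weights = c(0.85, 0.15),
                              capture_rate = 0.9,
                              depth_noise_sd = 0.6,
                              tn5_damping = 1,
                              age_diversity_slope = 0.5,
                              n_ploidy_markers = 50,
                              marker_boost = 3,
                              tf_gene_index = 1,
                              n_linked_open = 50,
                              n_linked_close = 50,
                              linked_effect = 0.6,
                              frac_open_with_motif = 0.8,
                              frac_close_with_motif = 0.3,
                              motif_bg_rate = 0.3,
                              type_boost = 10,
                              base_openness = 0.3,
                              nb_size = 2,
                              seed = 1L) {
  cfg <- as.list(environment())
  stop_if(any(c(cfg$n_cell_types, cfg$cells_per_type, cfg$n_peaks,
                cfg$n_genes, cfg$n_motifs) < 1), "all counts must be positive")
  stop_if(cfg$capture_rate <= 0 || cfg$capture_rate > 1,
          "capture_rate must be in (0, 1]")
  stop_if(!all(cfg$ploidy_levels %in% c(2, 4, 8, 16)),
          "ploidy_levels must be a subset of {2, 4, 8, 16}")
  w <- cfg$ploidy_weights
  if (is.null(dim(w)))
    w <- matrix(w, nrow = cfg$n_cell_types, ncol = length(w), byrow = TRUE)
  stop_if(ncol(w) != length(cfg$ploidy_levels),
          "ploidy_weights must have one weight per ploidy level")
  stop_if(any(abs(rowSums(w) - 1) > 1e-8),
          "ploidy_weights must sum to 1 for every cell type")
  cfg$ploidy_weights <- w
  stop_if(cfg$age_diversity_slope < 0 || cfg$age_diversity_slope >= 1,
          "age_diversity_slope must be in [0, 1)")
  stop_if(cfg$n_linked_open + cfg$n_linked_close > cfg$n_peaks,
          "more linked peaks than peaks")
  stop_if(cfg$depth_noise_sd < 0, "depth_noise_sd must be >= 0")
  stop_if(cfg$tn5_damping < 0 || cfg$tn5_damping > 1,
          "tn5_damping must be in [0, 1]")
  stop_if(cfg$tf_gene_index < 1 || cfg$tf_gene_index > cfg$n_genes,
          "tf_gene_index out of range")
  stop_if(cfg$n_motifs < cfg$n_cell_types,
          "need at least one motif per cell type")
  class(cfg) <- "simulation_config"
  cfg
}

# evaluate under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a paired single-cell ATAC + RNA dataset
#'
#' Generates a peak-by-cell cut-count matrix, a gene-by-cell expression
#' matrix, peak/gene coordinate annotations, a peak-by-motif count table,
#' and the full ground truth used by recovery tests.
#'
#' The cut-count model is Binomial(ploidy, p): each genomic copy of a locus
#' can host at most one insertion event, with per-copy probability
#' `capture_rate x cell efficiency x openness` (clipped to \[0, 1\]), so a
#' diploid cell rarely exceeds 2 cuts per peak while an 8n cell can reach 8.
#' Openness multiplies a base level by the owning-type boost, by
#' `(1 + motif_effect_size x motif count)` in a motif's target type, and by
#' `max(0, 1 + linked_effect x sign x TF expression)` for TF-linked peaks.
#' Age silences a growing fraction of each cell's gene and peak repertoire
#' (Bernoulli gate with rate `age x age_diversity_slope`) while scaling the
#' surviving features up so expected depth is age-independent: maturity
#' changes diversity, not depth.
#'
#' @param config a [simulation_config()].
#' @return list with elements `atac` (peaks x cells `dgCMatrix`), `peaks`
#'   (`GRanges`), `rna` (genes x cells `dgCMatrix`), `genes` (`GRanges`),
#'   `motif_counts` (peaks x motifs integer matrix), `family_map` (named
#'   character vector motif -> family), `truth` (list of `cells`, `peaks`,
#'   `motifs`, `genes` data frames), and `config`.
#' @export
simulate_multiome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_multiome_impl(config))
}

simulate_multiome_impl <- function(cfg) {
  n_types <- cfg$n_cell_types
  n_cells <- n_types * cfg$cells_per_type
  types <- paste0("type", seq_len(n_types))

  ## ---- genome layout: one chromosome, evenly spaced genes ----------------
  gene_start <- 2000 + 5000 * (seq_len(cfg$n_genes) - 1)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(gene_start + 1,
                                                   width = 1000),
                                  strand = rep(c("+", "-"),
                                               length.out = cfg$n_genes))
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  names(genes) <- gene_ids
  genes$gene_id <- gene_ids
  genes$tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                      GenomicRanges::start(genes), GenomicRanges::end(genes))

  ## gene programs: half housekeeping, half split into type markers
  n_marker <- floor(cfg$n_genes / 2)
  gene_type <- rep(NA_character_, cfg$n_genes)
  gene_type[seq_len(n_marker)] <- rep(types, length.out = n_marker)

  ## ---- peaks: ~90% placed in a gene body, ~10% intergenic (distal) -------
  n_distal <- max(1, round(0.1 * cfg$n_peaks))
  n_genic <- cfg$n_peaks - n_distal
  host <- rep(seq_len(cfg$n_genes), length.out = n_genic)
  wave <- (seq_len(n_genic) - 1) %/% cfg$n_genes      # stacking offset
  pk_start0 <- gene_start[host] + 100 + 250 * wave    # inside the body
  distal_host <- rep(seq_len(cfg$n_genes), length.out = n_distal)
  dl_start0 <- gene_start[distal_host] + 2800         # mid intergap
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(pk_start0, dl_start0) + 1, width = 200))
  names(peaks) <- peak_ids(peaks)
  # owning program: the host gene's type for genic peaks; distal peaks get
  # round-robin type-specific programs
  peak_type <- c(gene_type[host], rep(types, length.out = n_distal))

  ## ---- cells -------------------------------------------------------------
  cell_type <- rep(types, each = cfg$cells_per_type)
  age <- stats::runif(n_cells)
  lv <- cfg$ploidy_levels
  ploidy <- vapply(seq_len(n_cells), function(i) {
    t_i <- match(cell_type[i], types)
    lv[sample.int(length(lv), 1, prob = cfg$ploidy_weights[t_i, ])]
  }, numeric(1))
  # TF expressed in the first ceiling(T/2) types ("outer layer" program),
  # with continuous within-type variation; near-silent elsewhere. The mean
  # is pinned to exactly 1 within each active type so that peak-TF
  # correlations come only from the planted links, never from chance
  # type-level differences interacting with type-specific accessibility.
  tf_types <- types[seq_len(ceiling(n_types / 2))]
  draw_tf <- function(ct) {
    x <- ifelse(ct %in% tf_types,
                stats::rgamma(length(ct), shape = 2, scale = 0.5),
                stats::rexp(length(ct), rate = 20))
    for (t in tf_types) {
      sel <- ct == t
      x[sel] <- x[sel] / mean(x[sel])
    }
    x
  }
  tf_expr <- draw_tf(cell_type)

  ## ---- motifs: one family per type, members split round-robin ------------
  motif_ids <- sprintf("motif%02d", seq_len(cfg$n_motifs))
  motif_target <- rep(types, length.out = cfg$n_motifs)
  family_map <- stats::setNames(paste0("FAM_", motif_target), motif_ids)
  motif_counts <- matrix(stats::rpois(cfg$n_peaks * cfg$n_motifs,
                                      cfg$motif_bg_rate),
                         nrow = cfg$n_peaks,
                         dimnames = list(names(peaks), motif_ids))

  ## ---- planted TF-linked peaks (direct = with motif, indirect = without) -
  linked_sign <- integer(cfg$n_peaks)
  idx_link <- sample.int(cfg$n_peaks, cfg$n_linked_open + cfg$n_linked_close)
  open_idx <- idx_link[seq_len(cfg$n_linked_open)]
  close_idx <- setdiff(idx_link, open_idx)
  linked_sign[open_idx] <- 1L
  linked_sign[close_idx] <- -1L
  tf_motif <- motif_ids[1]   # the TF's family motif (targets type1)
  motif_counts[open_idx, tf_motif] <-
    motif_counts[open_idx, tf_motif] +
    stats::rbinom(length(open_idx), 1, cfg$frac_open_with_motif)
  motif_counts[close_idx, tf_motif] <-
    motif_counts[close_idx, tf_motif] +
    stats::rbinom(length(close_idx), 1, cfg$frac_close_with_motif)

  ## ---- openness and ATAC cuts -------------------------------------------
  type_idx <- match(cell_type, types)
  own <- outer(peak_type, types, `==`)          # peaks x types, NA-safe
  own[is.na(own)] <- FALSE
  boost <- 1 + (cfg$type_boost - 1) * own       # peaks x types
  # motif boost per (peak, type): product over motifs targeting the type
  mboost <- matrix(1, cfg$n_peaks, n_types)
  for (m in seq_len(cfg$n_motifs)) {
    t_m <- match(motif_target[m], types)
    mboost[, t_m] <- mboost[, t_m] *
      (1 + cfg$motif_effect_size * motif_counts[, m])
  }
  o_type <- cfg$base_openness * boost * mboost   # peaks x types
  openness <- o_type[, type_idx]                 # peaks x cells
  # TF-linkage term, floored at 0
  if (any(linked_sign != 0)) {
    link <- outer(linked_sign, tf_expr)          # peaks x cells
    openness <- openness * pmax(0, 1 + cfg$linked_effect * link)
  }
  # Age-dependent repertoire gate with depth-compensating rescale. Gating
  # acts at the host-gene level (a silenced gene takes all its peaks down
  # with it; distal peaks gate independently), so accessible-gene breadth
  # shrinks linearly with age while the rescale keeps unsaturated loci
  # contributing the same expected depth.
  if (cfg$age_diversity_slope > 0) {
    gate_p <- age * cfg$age_diversity_slope
    gene_gate <- matrix(stats::rbinom(cfg$n_genes * n_cells, 1,
                                      rep(1 - gate_p, each = cfg$n_genes)),
                        cfg$n_genes, n_cells)
    peak_host <- c(host, rep(NA_integer_, n_distal))
    gate <- matrix(0L, cfg$n_peaks, n_cells)
    genic_rows <- which(!is.na(peak_host))
    gate[genic_rows, ] <- gene_gate[peak_host[genic_rows], ]
    gate[-genic_rows, ] <- stats::rbinom(n_distal * n_cells, 1,
                                         rep(1 - gate_p, each = n_distal))
    openness <- openness * gate / rep(1 - gate_p, each = cfg$n_peaks)
  }
  eff <- if (cfg$depth_noise_sd > 0)
    stats::rlnorm(n_cells, -cfg$depth_noise_sd^2 / 2, cfg$depth_noise_sd)
  else rep(1, n_cells)
  percopy <- eff * (ploidy / 2)^(-cfg$tn5_damping)
  prob <- pmin(1, cfg$capture_rate * openness *
                  rep(percopy, each = cfg$n_peaks))
  cuts <- stats::rbinom(length(prob), size = rep(ploidy, each = cfg$n_peaks),
                        prob = prob)
  atac_cells <- sprintf("ATAC_%04d", seq_len(n_cells))
  atac <- methods::as(Matrix::Matrix(matrix(cuts, cfg$n_peaks, n_cells,
                                            dimnames = list(names(peaks),
                                                            atac_cells)),
                                     sparse = TRUE), "CsparseMatrix")

  ## ---- RNA cells (independent draw of the same population) ---------------
  r_type <- rep(types, each = cfg$cells_per_type)
  r_age <- stats::runif(n_cells)
  r_ploidy <- vapply(seq_len(n_cells), function(i) {
    t_i <- match(r_type[i], types)
    lv[sample.int(length(lv), 1, prob = cfg$ploidy_weights[t_i, ])]
  }, numeric(1))
  r_tf <- draw_tf(r_type)

  ## expression means: housekeeping everywhere, markers in their own type
  mu_type <- matrix(0.1, cfg$n_genes, n_types)
  mu_type[is.na(gene_type), ] <- 0.6
  for (t_i in seq_len(n_types))
    mu_type[which(gene_type == types[t_i]), t_i] <- 2.5
  ## ploidy marker genes: drawn from the housekeeping pool, one block per
  ## level, boosted in cells of the matching ploidy
  hk <- which(is.na(gene_type))
  stop_if(length(hk) < cfg$n_ploidy_markers * length(lv) + 1,
          "not enough housekeeping genes for the requested ploidy markers")
  marker_gene <- rep(NA_real_, cfg$n_genes)      # ploidy level marked, or NA
  off <- 0
  for (li in seq_along(lv)) {
    sel <- hk[seq_len(cfg$n_ploidy_markers) + off]
    marker_gene[sel] <- lv[li]
    off <- off + cfg$n_ploidy_markers
  }
  mu <- mu_type[, match(r_type, types)]          # genes x cells
  for (li in seq_along(lv)) {
    rows <- which(marker_gene == lv[li])
    cols <- which(r_ploidy == lv[li])
    if (length(rows) && length(cols))
      mu[rows, cols] <- mu[rows, cols] * cfg$marker_boost
  }
  ## TF gene tracks the latent TF expression level
  mu[cfg$tf_gene_index, ] <- 0.2 + 2 * r_tf
  ## age gate on the repertoire, depth-compensated
  if (cfg$age_diversity_slope > 0) {
    gp <- r_age * cfg$age_diversity_slope
    g <- matrix(stats::rbinom(cfg$n_genes * n_cells, 1,
                              rep(1 - gp, each = cfg$n_genes)),
                cfg$n_genes, n_cells)
    mu <- mu * g / rep(1 - gp, each = cfg$n_genes)
  }
  rna_counts <- stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size)
  rna_cells <- sprintf("RNA_%04d", seq_len(n_cells))
  rna <- methods::as(Matrix::Matrix(matrix(rna_counts, cfg$n_genes, n_cells,
                                           dimnames = list(gene_ids,
                                                           rna_cells)),
                                    sparse = TRUE), "CsparseMatrix")

  truth <- list(
    cells = rbind(
      data.frame(barcode = atac_cells, modality = "ATAC",
                 cell_type = cell_type, ploidy = ploidy, age = age,
                 tf_expr = tf_expr),
      data.frame(barcode = rna_cells, modality = "RNA",
                 cell_type = r_type, ploidy = r_ploidy, age = r_age,
                 tf_expr = r_tf)),
    peaks = data.frame(peak = names(peaks), owner_type = peak_type,
                       linked_class = c("null", "opening",
                                        "closing")[1 + (linked_sign == 1) +
                                                   2 * (linked_sign == -1)],
                       distal = c(rep(FALSE, n_genic), rep(TRUE, n_distal))),
    motifs = data.frame(motif = motif_ids, target_type = motif_target,
                        family = unname(family_map),
                        true_effect = cfg$motif_effect_size),
    genes = data.frame(gene = gene_ids, marker_type = gene_type,
                       ploidy_marker = marker_gene,
                       is_tf = seq_len(cfg$n_genes) == cfg$tf_gene_index))
  list(atac = atac, peaks = peaks, rna = rna, genes = genes,
       motif_counts = motif_counts, family_map = family_map,
       truth = truth, config = cfg)
}

#' Simulate a joint two-dimensional embedding of both modalities
#'
#' Places every cell (ATAC and RNA) at its cell type's centroid, offset
#' radially by developmental age, plus isotropic Gaussian noise. A stand-in
#' for an externally computed co-embedding: cells of one type interleave
#' across modalities.
#'
#' @param truth the `truth` element of a [simulate_multiome()] result.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @return `data.frame` with barcode, modality, dim1, dim2.
#' @export
simulate_joint_embedding <- function(truth, noise_sd = 0.5, seed = 1L) {
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  cells <- truth$cells
  types <- sort(unique(cells$cell_type))
  ang <- 2 * pi * (match(cells$cell_type, types) - 1) / length(types)
  r <- 10 + 2 * cells$age
  with_seed(seed, {
    data.frame(barcode = cells$barcode, modality = cells$modality,
               dim1 = r * cos(ang) + stats::rnorm(nrow(cells), 0, noise_sd),
               dim2 = r * sin(ang) + stats::rnorm(nrow(cells), 0, noise_sd))
  })
}

#' Write all simulated inputs to disk
#'
#' Emits the file set the readers in this package consume: peak BED, gene
#' GFF3, both matrices as MatrixMarket + name files, the motif count table,
#' and the truth tables as TSV.
#'
#' @param sim a [simulate_multiome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_peaks_bed(sim$peaks, p("peaks.bed"))
  write_genes_gff(sim$genes, p("genes.gff3"))
  write_matrix_mtx(sim$atac, p("atac.mtx"), p("atac_peaks.txt"),
                   p("atac_barcodes.txt"))
  write_matrix_mtx(sim$rna, p("rna.mtx"), p("rna_genes.txt"),
                   p("rna_barcodes.txt"))
  mc <- data.frame(peak_id = rep(rownames(sim$motif_counts),
                                 ncol(sim$motif_counts)),
                   motif_id = rep(colnames(sim$motif_counts),
                                  each = nrow(sim$motif_counts)),
                   count = as.vector(sim$motif_counts))
  utils::write.table(mc[mc$count > 0, ], p("motif_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$truth))
    utils::write.table(sim$truth[[nm]], p(paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
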