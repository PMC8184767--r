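# End-to-end driver: simulate (or load) a multiome, then run every stage in
# dependency order with one global seed.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulation = list(),                       # simulation_config() overrides
    activity = list(upstream_bp = 400),
    diff_access = list(alpha = 0.05, fc_min = 2),
    transfer = list(k = 25, d = 10),
    ploidy = list(span = 0.5, threshold_sd = 1),
    linkage = list(alpha = 0.05, n_bins = 4, cell_types = NULL)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  stop_if(length(unknown) > 0, "unknown config key: ",
          paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         k != "simulation")
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

validate_pipeline_config <- function(cfg) {
  stop_if(cfg$transfer$k < 1, "transfer.k must be >= 1")
  stop_if(cfg$activity$upstream_bp < 0, "activity.upstream_bp must be >= 0")
  stop_if(cfg$diff_access$alpha <= 0 || cfg$diff_access$alpha >= 1,
          "diff_access.alpha must be in (0, 1)")
  stop_if(cfg$linkage$alpha <= 0 || cfg$linkage$alpha >= 1,
          "linkage.alpha must be in (0, 1)")
  stop_if(cfg$linkage$n_bins < 2, "linkage.n_bins must be >= 2")
  stop_if(cfg$ploidy$span <= 0 || cfg$ploidy$span > 1,
          "ploidy.span must be in (0, 1]")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the package defaults
#' (400 bp upstream window, k = 25 neighbors, 1 SD residual threshold,
#' q < 0.05, 2-fold change, 4 expression bins).
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  validate_pipeline_config(merge_config(pipeline_defaults(),
                                        if (is.null(user)) list() else user))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline on a simulated multiome
#'
#' Simulates a paired ATAC/RNA dataset, then runs every stage in dependency
#' order: gene-activity scoring, distal classification, differential
#' accessibility, relative accessibility and motif regression with family
#' means, joint embedding and kNN transfer, endoreduplication and
#' progression metrics, TF-peak linkage with expression bins and per-bin
#' tracks. All stage outputs are written as TSV (plus bedGraph tracks) to
#' `out_dir`, with a YAML run manifest; a rerun with the same config
#' reproduces the files byte-identically.
#'
#' @param config list from [read_pipeline_config()], or a path to a YAML
#'   file.
#' @param out_dir output directory (created).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = read_pipeline_config(), out_dir) {
  if (is.character(config)) {
    stop_if(!file.exists(config), "config file not found: ", config)
    config <- read_pipeline_config(config)
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    sc <- do.call(simulation_config,
                  c(config$simulation,
                    list(seed = derive_seed(config$seed, "simulate"))))
    simulate_multiome(sc)
  })
  write_multiome(sim, p("inputs"))
  tr_cells <- sim$truth$cells
  atac_truth <- tr_cells[tr_cells$modality == "ATAC", ]
  rna_truth <- tr_cells[tr_cells$modality == "RNA", ]
  labels <- stats::setNames(atac_truth$cell_type, atac_truth$barcode)

  activity <- stage("gene_activity", compute_gene_activity(
    sim$atac, sim$peaks, sim$genes, config$activity$upstream_bp))
  distal <- stage("classify_distal", classify_distal(
    sim$peaks, sim$genes, config$activity$upstream_bp))
  da <- stage("diff_access", differential_accessibility(
    sim$atac, labels, alpha = config$diff_access$alpha,
    fc_min = config$diff_access$fc_min))
  da$distal <- distal[match(da$peak, rownames(sim$atac))]
  write_tsv(da, p("differential_accessibility.tsv"))

  spec_peaks <- unique(da$peak[da$significant])
  enr <- stage("distal_enrichment", distal_enrichment(
    sum(distal[match(spec_peaks, rownames(sim$atac))]),
    max(length(spec_peaks), 1), sum(distal), length(distal)))
  write_tsv(data.frame(metric = c("frac_specific", "frac_all", "fold"),
                       value = c(enr$frac_specific, enr$frac_all, enr$fold)),
            p("distal_enrichment.tsv"))

  rel <- stage("relative_accessibility",
               relative_accessibility(sim$atac, labels))
  effects <- stage("motif_regression",
                   motif_regression(rel, sim$motif_counts, sim$family_map))
  write_tsv(effects, p("motif_effects.tsv"))
  fam <- stage("family_means", family_means(effects))
  write_tsv(data.frame(family = rownames(fam), fam, check.names = FALSE),
            p("family_means.tsv"))

  emb <- stage("embedding", shared_feature_embedding(
    activity, sim$rna, d = config$transfer$d))
  write_tsv(emb, p("embedding.tsv"))
  tf_gene <- sim$truth$genes$gene[sim$truth$genes$is_tf]
  rna_norm <- log1p(normalize_depth(sim$rna))
  tf_on_atac <- stage("transfer", knn_transfer_mean(
    emb, rna_norm[tf_gene, ], k = config$transfer$k))
  lab_tr <- stage("transfer_labels", knn_transfer_label(
    emb, stats::setNames(rna_truth$cell_type, rna_truth$barcode),
    k = config$transfer$k))

  markers <- split(sim$truth$genes$gene[!is.na(sim$truth$genes$ploidy_marker)],
                   sim$truth$genes$ploidy_marker[
                     !is.na(sim$truth$genes$ploidy_marker)])
  state <- stage("cell_state", cell_state_table(
    sim$atac, activity, expr = sim$rna, markers = markers,
    span = config$ploidy$span, threshold_sd = config$ploidy$threshold_sd))
  state$cell_type <- atac_truth$cell_type
  state$transferred_label <- lab_tr$label[match(state$barcode,
                                                lab_tr$barcode)]
  state$tf_expr_transferred <- unname(tf_on_atac[state$barcode])
  write_tsv(state, p("cell_state_atac.tsv"))
  write_tsv(attr(state, "rna"), p("cell_state_rna.tsv"))

  subset_types <- config$linkage$cell_types
  if (is.null(subset_types)) {
    types <- sort(unique(labels))
    subset_types <- types[seq_len(ceiling(length(types) / 2))]
  }
  sub_cells <- names(labels)[labels %in% subset_types]
  has_motif <- sim$motif_counts[, 1] > 0
  linkage <- stage("tf_linkage", link_tf_to_peaks(
    sim$atac, tf_on_atac, cells = sub_cells,
    alpha = config$linkage$alpha, has_motif = has_motif))
  write_tsv(linkage, p("tf_linkage.tsv"))
  bins <- stage("expression_bins", expression_bins(
    tf_on_atac[sub_cells], config$linkage$n_bins))
  write_tsv(data.frame(barcode = names(bins), bin = unname(bins)),
            p("expression_bins.tsv"))
  opening <- linkage$peak[linkage$class == "opening"]
  region <- if (length(opening) > 0) {
    pk <- sim$peaks[opening[1]]
    GenomicRanges::resize(pk, GenomicRanges::width(pk) + 400, fix = "center")
  } else sim$peaks[1]
  tracks <- stage("binned_tracks", binned_tracks(
    sim$atac, sim$peaks, bins, region, p("track")))

  manifest <- list(package = "scregulome",
                   version = as.character(utils::packageVersion("scregulome")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "seed")],
                   stages = c("simulate", "gene_activity", "diff_access",
                              "distal_enrichment", "motif_assoc", "transfer",
                              "cell_state", "tf_linkage"))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(list(sim = sim, activity = activity, da = da, enrichment = enr,
                 rel = rel, effects = effects, family_means = fam,
                 embedding = emb, state = state, linkage = linkage,
                 bins = bins, tracks = tracks))
}
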