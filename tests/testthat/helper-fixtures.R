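# Shared fixtures. The full-size simulation is expensive, so it is built
# once per test run and reused wherever the study-scale conditions are
# needed.

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 101) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_multiome(simulation_config(seed = seed))
  .fixture_cache[[key]]
}

# small, fast configuration for smoke/structure tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(cells_per_type = 50, n_peaks = 300, n_genes = 200,
         n_ploidy_markers = 15, n_linked_open = 10, n_linked_close = 10),
    list(...))
  do.call(simulation_config, args)
}

atac_truth <- function(sim) subset(sim$truth$cells, modality == "ATAC")
rna_truth <- function(sim) subset(sim$truth$cells, modality == "RNA")

atac_labels <- function(sim) {
  a <- atac_truth(sim)
  stats::setNames(a$cell_type, a$barcode)
}

# random sparse count matrix for property tests
random_counts <- function(n_feat, n_cells, seed, lambda = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_cells, lambda), n_feat, n_cells,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("c%03d", seq_len(n_cells))))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

ploidy_marker_sets <- function(sim) {
  g <- sim$truth$genes
  split(g$gene[!is.na(g$ploidy_marker)],
        g$ploidy_marker[!is.na(g$ploidy_marker)])
}
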