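toy_genes <- function() {
  g <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(1001, 1001, 101),
                                               c(2000, 2000, 300)),
                              strand = c("+", "-", "+"))
  names(g) <- g$gene_id <- c("gPlus", "gMinus", "gEdge")
  g
}

test_that("gene windows extend upstream of the TSS and clip at zero", {
  w <- gene_window(toy_genes(), 400)
  # + strand body (1000,2000) 0-based -> window (600,2000)
  expect_equal(GenomicRanges::start(w)[1], 601L)
  expect_equal(GenomicRanges::end(w)[1], 2000L)
  # - strand: upstream is to the right
  expect_equal(GenomicRanges::start(w)[2], 1001L)
  expect_equal(GenomicRanges::end(w)[2], 2400L)
  # clipping at the chromosome start
  expect_equal(GenomicRanges::start(w)[3], 1L)
  expect_equal(GenomicRanges::end(w)[3], 300L)
  expect_error(gene_window(toy_genes(), -1), "upstream_bp")
})

test_that("gene activity sums cuts of peaks by midpoint membership", {
  # peaks: one inside gPlus only, one in the gPlus/gMinus shared interval,
  # one far away
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1101, 1501, 9001),
                                                   width = 100))
  names(peaks) <- peak_ids(peaks)
  counts <- Matrix::Matrix(matrix(c(5, 0,
                                    2, 3,
                                    7, 7), nrow = 3, byrow = TRUE,
                                  dimnames = list(names(peaks),
                                                  c("cellA", "cellB"))),
                           sparse = TRUE)
  act <- compute_gene_activity(counts, peaks, toy_genes(), upstream_bp = 400)
  # both genic peaks fall in both overlapping windows
  expect_equal(act["gPlus", "cellA"], 5 + 2)
  expect_equal(act["gMinus", "cellA"], 5 + 2)
  expect_equal(act["gPlus", "cellB"], 3)
  # no peak near gEdge
  expect_equal(unname(as.vector(act["gEdge", ])), c(0, 0))
  # oracle: per-gene score equals brute-force interval sum
  win <- gene_window(toy_genes(), 400)
  mid <- GenomicRanges::start(peaks) + GenomicRanges::width(peaks) %/% 2
  for (g in seq_along(win)) {
    inside <- mid >= GenomicRanges::start(win)[g] &
      mid <= GenomicRanges::end(win)[g]
    expect_equal(unname(as.vector(act[g, ])),
                 unname(Matrix::colSums(counts[inside, , drop = FALSE])))
  }
})

test_that("a peak midpoint on the window edge is scored atomically", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1000),
                              strand = "+")
  names(g) <- g$gene_id <- "g1"
  # midpoints 1000 (inside) and 1001 (just outside) of the [501,1000] window
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(950, 951),
                                                           width = 100))
  counts <- Matrix::Matrix(matrix(c(4, 4), 2, 1,
                                  dimnames = list(NULL, "c")), sparse = TRUE)
  act <- compute_gene_activity(counts, peaks, g, upstream_bp = 0)
  expect_equal(as.vector(act), 4)
})

test_that("distal classification uses the gap to the nearest gene body", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1301, 2300),
                                  strand = "+")
  names(genes) <- genes$gene_id <- "g1"
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1001, 1, 1501),
                                                   c(1200, 200, 1600)))
  d <- classify_distal(peaks, genes, threshold_bp = 400)
  expect_equal(d, c(FALSE, TRUE, FALSE))  # gaps 100, 1100, 0 (overlap)
  # monotone in the threshold: larger threshold, subset of distal calls
  thresholds <- c(50, 200, 800, 2000)
  sets <- lapply(thresholds, function(t)
    which(suppressWarnings(classify_distal(peaks, genes, t))))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  # a chromosome without genes is distal, with a warning
  lonely <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100))
  w <- testthat::capture_warnings(dx <- classify_distal(lonely, genes))
  expect_true(any(grepl("without genes", w)))
  expect_true(dx)
})

test_that("the vectorized rank-sum test matches stats::wilcox.test", {
  set.seed(7)
  x <- matrix(rpois(30 * 24, 2), 30, 24,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("c%02d", 1:24)))
  groups <- rep(c("A", "B", "C"), each = 8)
  rs <- scregulome:::ranksum_one_vs_rest(x, groups)
  for (i in c(1, 7, 18, 30)) for (g in c("A", "B", "C")) {
    ref <- stats::wilcox.test(x[i, groups == g], x[i, groups != g],
                              exact = FALSE, correct = TRUE)$p.value
    expect_equal(rs$p[i, g], ref, tolerance = 1e-10)
  }
})

test_that("differential accessibility flags a planted type-specific peak", {
  set.seed(11)
  n_per <- 60
  labels <- rep(c("A", "B"), each = n_per)
  m <- matrix(rpois(20 * 2 * n_per, 1), 20, 2 * n_per)
  m[1, labels == "A"] <- rpois(n_per, 8)   # planted
  dimnames(m) <- list(sprintf("p%02d", 1:20),
                      sprintf("c%03d", seq_len(2 * n_per)))
  da <- differential_accessibility(Matrix::Matrix(m, sparse = TRUE),
                                   stats::setNames(labels, colnames(m)))
  hit <- da[da$peak == "p01" & da$cell_type == "A", ]
  expect_true(hit$significant)
  expect_gt(hit$fold_change, 2)
  # identical counts everywhere: never significant
  flat <- Matrix::Matrix(matrix(3, 5, 2 * n_per,
                                dimnames = list(paste0("q", 1:5),
                                                colnames(m))), sparse = TRUE)
  da_flat <- differential_accessibility(flat,
                                        stats::setNames(labels, colnames(m)))
  expect_true(all(!da_flat$significant))
  expect_true(all(da_flat$p == 1))
})

test_that("label permutation yields uniform rank-sum p-values", {
  set.seed(21)
  n_peaks <- 1000; n_cells <- 200
  m <- matrix(rpois(n_peaks * n_cells, 2), n_peaks, n_cells,
              dimnames = list(sprintf("p%04d", seq_len(n_peaks)),
                              sprintf("c%03d", seq_len(n_cells))))
  labels <- sample(rep(c("A", "B"), each = n_cells / 2))
  da <- differential_accessibility(Matrix::Matrix(m, sparse = TRUE),
                                   stats::setNames(labels, colnames(m)))
  ks <- suppressWarnings(stats::ks.test(da$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted type-specific peaks are recovered with controlled FDR", {
  sim <- default_sim()
  da <- differential_accessibility(sim$atac, atac_labels(sim))
  owner <- sim$truth$peaks$owner_type[match(da$peak, sim$truth$peaks$peak)]
  planted_total <- sum(!is.na(sim$truth$peaks$owner_type))
  correct <- da$significant & !is.na(owner) & da$cell_type == owner
  recall <- length(unique(da$peak[correct])) / planted_total
  expect_gte(recall, 0.9)
  called <- which(da$significant)
  false <- is.na(owner[called]) | da$cell_type[called] != owner[called]
  expect_lte(mean(false), 0.1)
})

test_that("small cell types are excluded with a warning", {
  x <- random_counts(10, 21, seed = 3)
  labels <- stats::setNames(c(rep("A", 10), rep("B", 10), "C"), colnames(x))
  expect_warning(da <- differential_accessibility(x, labels), "< 2 cells")
  expect_false("C" %in% da$cell_type)
})

test_that("distal enrichment arithmetic matches its printed forms", {
  e <- distal_enrichment(707, 4389, 2159, 22749)
  expect_equal(e$printed$pct_specific, 16)
  expect_equal(e$printed$pct_all, 9.4)
  expect_equal(e$printed$fold, 1.7)
  expect_equal(distal_enrichment(10, 100, 10, 100)$fold, 1.0)
  expect_equal(distal_enrichment(10, 10, 10, 100)$fold, 10.0)
  expect_error(distal_enrichment(1, 0, 1, 10), "denominator")
  expect_error(distal_enrichment(5, 4, 1, 10), "exceeds")
})
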