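test_that("specificity ranks exclusive genes first and constants at zero", {
  m <- matrix(c(5, 5, 0, 0,    # exclusive to A
                3, 3, 3, 3,    # constant
                1, 2, 4, 5),   # higher elsewhere
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gConst", "gOther"), paste0("c", 1:4)))
  labels <- stats::setNames(c("A", "A", "B", "B"), colnames(m))
  r <- specificity_ranking(m, labels, "A")
  expect_equal(r$gene[1], "gA")
  expect_equal(r$specificity[r$gene == "gConst"], 0)
  expect_lt(r$specificity[r$gene == "gOther"], 0)
  expect_error(specificity_ranking(m, labels, "Z"), "target_type")
})

test_that("a planted specificity gradient is recovered in rank order", {
  sim <- default_sim()
  a <- atac_truth(sim)
  set.seed(5)
  # synthetic per-cell features with decreasing target enrichment
  target <- a$cell_type == "type1"
  feat <- rbind(g_strong = ifelse(target, 4, 0) + rnorm(nrow(a), 0, 0.3),
                g_mid = ifelse(target, 2, 0) + rnorm(nrow(a), 0, 0.3),
                g_weak = ifelse(target, 0.7, 0) + rnorm(nrow(a), 0, 0.3),
                g_null = rnorm(nrow(a), 0, 0.3))
  colnames(feat) <- a$barcode
  r <- specificity_ranking(feat, stats::setNames(a$cell_type, a$barcode),
                           "type1")
  expect_equal(r$gene, c("g_strong", "g_mid", "g_weak", "g_null"))
})

test_that("vectorized per-peak OLS matches lm exactly", {
  set.seed(7)
  Y <- matrix(rnorm(20 * 30), 20, 30)
  x <- rnorm(30)
  fit <- scregulome:::ols_rows(Y, x)
  for (i in c(1, 5, 20)) {
    ref <- summary(stats::lm(Y[i, ] ~ x))$coefficients
    expect_equal(fit$beta[i], ref["x", "Estimate"], tolerance = 1e-12)
    expect_equal(fit$p[i], ref["x", "Pr(>|t|)"], tolerance = 1e-12)
  }
})

test_that("TF linkage recovers planted opening and closing peaks", {
  # observed FDR with ~5 expected false calls per run is a noisy
  # statistic; pool the estimator over replicate simulations
  n_called <- n_false <- n_planted_called <- n_sign_ok <- 0
  for (s in c(101, 102, 103)) {
    sim <- default_sim(s)
    a <- atac_truth(sim)
    sub <- a$barcode[a$cell_type %in% paste0("type", 1:3)]
    lk <- link_tf_to_peaks(sim$atac, stats::setNames(a$tf_expr, a$barcode),
                           cells = sub,
                           has_motif = sim$motif_counts[, 1] > 0)
    truth <- sim$truth$peaks$linked_class[match(lk$peak,
                                                sim$truth$peaks$peak)]
    called <- lk$class != "null"
    pc <- called & truth != "null"
    n_called <- n_called + sum(called)
    n_false <- n_false + sum(truth[called] == "null")
    n_planted_called <- n_planted_called + sum(pc)
    n_sign_ok <- n_sign_ok + sum(lk$class[pc] == truth[pc])
    if (s == 101) {
      # closed-form identity of the slope
      norm <- as.matrix(normalize_depth(sim$atac[lk$peak, sub]))
      tf <- a$tf_expr[match(sub, a$barcode)]
      i <- which(lk$class == "opening")[1]
      expect_equal(lk$beta[i], stats::cov(norm[i, ], tf) / stats::var(tf),
                   tolerance = 1e-10)
    }
  }
  expect_gte(n_sign_ok / n_planted_called, 0.95)
  expect_lte(n_false / n_called, 0.075)  # 1.5x the nominal q threshold
})

test_that("shuffled TF expression gives a calibrated null", {
  sim <- default_sim()
  a <- atac_truth(sim)
  set.seed(9)
  shuffled <- stats::setNames(sample(a$tf_expr), a$barcode)
  lk <- link_tf_to_peaks(sim$atac, shuffled)
  rate <- mean(lk$p < 0.05)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / nrow(lk)) + 0.01)
  expect_error(link_tf_to_peaks(sim$atac,
                                stats::setNames(rep(1, nrow(a)),
                                                a$barcode)),
               "zero variance")
})

test_that("motif fractions separate direct from indirect linkage", {
  toy <- data.frame(class = c(rep("opening", 5), rep("closing", 4)),
                    has_motif = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                  TRUE, FALSE, FALSE, FALSE))
  mf <- motif_fraction(toy)
  expect_equal(mf$frac_opening, 0.8)
  expect_equal(mf$frac_closing, 0.25)
  expect_error(motif_fraction(data.frame(class = "opening",
                                         has_motif = TRUE)),
               "at least one")
  sim <- default_sim()
  a <- atac_truth(sim)
  sub <- a$barcode[a$cell_type %in% paste0("type", 1:3)]
  lk <- link_tf_to_peaks(sim$atac, stats::setNames(a$tf_expr, a$barcode),
                         cells = sub,
                         has_motif = sim$motif_counts[, 1] > 0)
  mf2 <- motif_fraction(lk)
  expect_gt(mf2$frac_opening, mf2$frac_closing)
})

test_that("expression bins are equal-sized, ordered, and tie-stable", {
  x8 <- stats::setNames(rnorm(8), sprintf("b%02d", 1:8))
  b8 <- expression_bins(x8, 4)
  expect_equal(unname(table(b8)), rep(2L, 4), ignore_attr = TRUE)
  # bins are expression-ordered
  expect_true(max(x8[b8 == 1]) <= min(x8[b8 == 4]))
  x9 <- stats::setNames(rnorm(9), sprintf("b%02d", 1:9))
  b9 <- expression_bins(x9, 4)
  expect_equal(unname(table(b9)), c(3L, 2L, 2L, 2L), ignore_attr = TRUE)
  # all-equal expression: filled in barcode order
  xe <- stats::setNames(rep(1, 8), sprintf("b%02d", 8:1))
  be <- expression_bins(xe, 4)
  expect_equal(unname(be[sort(names(xe))]), rep(1:4, each = 2))
  expect_error(expression_bins(x8, 1), "n_bins")
  expect_error(expression_bins(x8[1:3], 4), "fewer cells")
})

test_that("binned tracks reproduce pseudobulk and planted monotonicity", {
  sim <- default_sim()
  a <- atac_truth(sim)
  sub <- a$barcode[a$cell_type %in% paste0("type", 1:3)]
  tf <- stats::setNames(a$tf_expr[match(sub, a$barcode)], sub)
  open_peak <- sim$truth$peaks$peak[sim$truth$peaks$linked_class ==
                                      "opening"][1]
  region <- sim$peaks[open_peak]
  dir <- withr::local_tempdir()
  # single bin equals the depth-normalized pseudobulk of the subset
  one <- expression_bins(tf, 2) * 0 + 1L
  p1 <- binned_tracks(sim$atac, sim$peaks, one, region,
                      file.path(dir, "single"))
  cov <- read_bedgraph(p1[["bin1"]],
                       as.character(GenomicRanges::seqnames(region)),
                       GenomicRanges::start(region) - 1,
                       GenomicRanges::width(region))
  expected <- sum(sim$atac[open_peak, sub]) * 1e4 / sum(sim$atac[, sub])
  expect_equal(unique(cov), expected, tolerance = 1e-9)
  # four bins: planted opening peak rises with expression bin
  bins <- expression_bins(tf, 4)
  paths <- binned_tracks(sim$atac, sim$peaks, bins, region,
                         file.path(dir, "quad"))
  height <- vapply(paths, function(p)
    max(read_bedgraph(p, as.character(GenomicRanges::seqnames(region)),
                      GenomicRanges::start(region) - 1,
                      GenomicRanges::width(region))), numeric(1))
  expect_true(all(diff(height) >= 0) || stats::cor(seq_along(height),
                                                   height) > 0.8)
  # empty region: empty tracks
  far <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 500))
  pe <- suppressWarnings(binned_tracks(sim$atac, sim$peaks, bins, far,
                                       file.path(dir, "empty")))
  expect_true(all(vapply(pe, function(p) length(readLines(p)) == 0,
                         logical(1))))
})
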