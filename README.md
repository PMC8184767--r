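# scregulome

Integrated analysis of single-cell chromatin accessibility (scATAC-seq)
and single-cell expression (scRNA-seq) for structured tissues such as the
*Arabidopsis thaliana* root, where cell type, developmental age, and
endoreduplication vary jointly across cells.

Bulk accessibility studies in plants see few dynamic regulatory sites,
partly because tissue heterogeneity averages cell-type-specific signal
away. Working at single-cell resolution, this package provides the
statistics needed to ask where that signal lives and what drives it:

* **Gene activity scores** — per gene and cell, the sum of ATAC cuts of
  peaks whose midpoint falls in the gene body + 400 bp upstream of the
  TSS; the shared "gene" feature space that links ATAC to RNA data.
* **Differential accessibility** — one-vs-rest Wilcoxon rank-sum per
  (peak, cell type) on depth-normalized counts, BH-corrected, with
  fold-change filtering; plus distal/proximal classification (> 400 bp
  from the nearest gene body) and the distal-enrichment fold
  `(n_ds/n_s) / (n_da/n_a)`.
* **Motif association** — relative accessibility of peak *p* in type *t*
  (pseudo-bulk mean over pooled mean), regressed on per-peak motif
  counts: the slope β is the motif's effect on type-specific
  accessibility, averaged over transcription-factor families and used to
  cluster cell types.
* **Cross-modality transfer** — each ATAC cell receives the mean feature
  value (or majority label) of its k = 25 nearest RNA neighbors in a
  joint embedding.
* **Endoreduplication** — two independent classifiers: loess residuals
  of cuts-per-peak vs total UMIs (> 1 SD flags polyploid cells, since a
  diploid locus carries at most two insertions), and the 8n-vs-2n
  marker-signature log-ratio.
* **Developmental progression** — negative loess residual of unique
  genes expressed vs total UMIs (transcriptional complexity falls with
  maturity), with an ATAC analogue (cuts per accessible gene).
* **TF–peak linkage** — per-peak OLS of accessibility on a TF's
  (transferred) expression across cells; q < 0.05 peaks are classified
  opening (β > 0) or closing (β < 0), compared by binding-motif content,
  and visualized as expression-binned pseudo-bulk bedGraph tracks.
* **A synthetic multiome generator** that plants all of the above
  structures with known truth, so every stage has a parameter-recovery
  test.

## Worked example

```r
library(scregulome)

sim <- simulate_multiome(simulation_config(seed = 1))
a   <- subset(sim$truth$cells, modality == "ATAC")

# distal-peak arithmetic on published peak counts
enr <- distal_enrichment(707, 4389, 2159, 22749)
unlist(enr$printed)
#> pct_specific      pct_all         fold
#>         16.0          9.4          1.7

# motif -> cell-type effects, family means
rel <- relative_accessibility(sim$atac, setNames(a$cell_type, a$barcode))
eff <- motif_regression(rel, sim$motif_counts, sim$family_map)
fam <- family_means(eff)
rownames(fam)[apply(fam, 2, which.max)]
#> [1] "FAM_type1" "FAM_type2" "FAM_type3" "FAM_type4" "FAM_type5"

# accessibility-based endoreduplication calls vs planted ploidy
er <- atac_endoreduplication(sim$atac)
table(called = er$endoreduplicated, ploidy = a$ploidy)
#>        ploidy
#> called    2   8
#>   FALSE 850  27
#>   TRUE    0 123
```

Each line of the motif output names the planted target family of that
cell type — the regression recovers all five planted motif–type
associations. The endoreduplication table shows the loess-residual
classifier recovering the planted 8n cells (sensitivity 0.82 at
specificity 1.00 here).

The full chain — simulation, gene activity, differential accessibility,
motif regression, embedding + transfer, ploidy and progression metrics,
TF linkage and binned tracks, with TSV/bedGraph outputs and a run
manifest — is driven by:

```r
run_pipeline(read_pipeline_config(), "out/")   # or a YAML config path
```

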