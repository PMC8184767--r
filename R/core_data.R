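#' Read a BED file of peaks
#'
#' Parses a 3+ column, tab-separated BED file into a `GRanges`. BED
#' coordinates (0-based half-open) are converted to the 1-based closed
#' convention `GRanges` uses; the paired writer inverts the conversion, so
#' `read_peaks_bed(write_peaks_bed(x))` is the identity.
#'
#' @param path path to a BED3/BED6 file.
#' @return `GRanges` in file order, named `chrom:start-end` (BED
#'   coordinates). Column 6, when present, supplies the strand.
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  stop_if(length(bad) > 0, "malformed BED line ", bad[1],
          ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  stop_if(length(bad) > 0, "malformed BED line ", bad[1],
          ": non-numeric coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  stop_if(length(bad) > 0, "invalid interval on BED line ", bad[1],
          ": require 0 <= start < end")
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[`, "", 6L)
    strand[has6] <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  names(gr) <- peak_ids(gr)
  gr
}

#' Write peaks to BED3
#'
#' @param peaks `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d",
                     as.character(GenomicRanges::seqnames(peaks)),
                     GenomicRanges::start(peaks) - 1L,
                     GenomicRanges::end(peaks)),
             path)
  invisible(path)
}

#' Canonical peak identifiers
#'
#' `chrom:start-end` labels in BED (0-based half-open) coordinates, used as
#' row names of peak-by-cell matrices throughout.
#'
#' @param peaks `GRanges`.
#' @return character vector.
#' @export
peak_ids <- function(peaks) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(peaks)),
          GenomicRanges::start(peaks) - 1L, GenomicRanges::end(peaks))
}

#' Read gene models from GFF3
#'
#' Imports `gene` features from a GFF3 file. GFF3 1-based closed coordinates
#' map directly onto `GRanges`; the transcription start site (TSS) is the
#' start of the range on the `+` strand and the end on the `-` strand.
#'
#' @param path path to a GFF3 file.
#' @return `GRanges` named by `gene_id` with a `tss` metadata column
#'   (1-based position).
#' @export
read_genes_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  stop_if(length(gr) == 0, "no gene features in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$gene_id
    if (!is.null(alt)) ids[is.na(ids)] <- alt[is.na(ids)]
  }
  stop_if(is.null(ids) || anyNA(ids) || any(!nzchar(ids)),
          "gene feature without an ID attribute")
  stop_if(anyDuplicated(ids) > 0, "duplicate gene_id: ",
          ids[anyDuplicated(ids)])
  str <- as.character(GenomicRanges::strand(gr))
  stop_if(any(str == "*"), "gene without strand: ",
          ids[which(str == "*")[1]])
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr), strand = str)
  names(out) <- ids
  out$gene_id <- ids
  out$tss <- ifelse(str == "+", GenomicRanges::start(out),
                    GenomicRanges::end(out))
  out
}

#' Write gene models to GFF3
#'
#' @param genes `GRanges` with `gene_id`, as from [read_genes_gff()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff <- function(genes, path) {
  header <- "##gff-version 3"
  body <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  as.character(GenomicRanges::seqnames(genes)),
                  "scregulome",
                  GenomicRanges::start(genes), GenomicRanges::end(genes),
                  as.character(GenomicRanges::strand(genes)),
                  genes$gene_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sparse count matrix in MatrixMarket format
#'
#' Reads a MatrixMarket coordinate file plus plain-text row/column name files
#' (one name per line) into a column-compressed sparse matrix, the container
#' used for peak-by-cell and gene-by-cell counts.
#'
#' @param matrix_path MatrixMarket `.mtx` file.
#' @param row_names_path,col_names_path one name per line.
#' @return `dgCMatrix` with dimnames.
#' @export
read_matrix_mtx <- function(matrix_path, row_names_path, col_names_path) {
  m <- methods::as(methods::as(Matrix::readMM(matrix_path),
                               "generalMatrix"), "CsparseMatrix")
  rn <- readLines(row_names_path)
  cn <- readLines(col_names_path)
  stop_if(nrow(m) != length(rn),
          "matrix has ", nrow(m), " rows but ", length(rn), " row names")
  stop_if(ncol(m) != length(cn),
          "matrix has ", ncol(m), " columns but ", length(cn), " column names")
  dimnames(m) <- list(rn, cn)
  m
}

#' Write a sparse count matrix in MatrixMarket format
#'
#' Paired writer for [read_matrix_mtx()]; round-trips exactly.
#'
#' @param counts matrix with dimnames.
#' @param matrix_path,row_names_path,col_names_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_matrix_mtx <- function(counts, matrix_path, row_names_path,
                             col_names_path) {
  # force general storage: writeMM would otherwise emit "symmetric" files
  # whose reader cannot carry asymmetric dimnames
  Matrix::writeMM(methods::as(methods::as(methods::as(counts, "dMatrix"),
                                          "generalMatrix"),
                              "TsparseMatrix"), matrix_path)
  writeLines(rownames(counts), row_names_path)
  writeLines(colnames(counts), col_names_path)
  invisible(matrix_path)
}

#' Pseudo-bulk a single-cell matrix by group
#'
#' Sums counts over cells sharing a label ("pseudo-bulking"), e.g. cluster,
#' cell type, or expression bin. The grand total is conserved exactly.
#'
#' @param counts features x cells matrix.
#' @param groups per-cell label, either named by barcode or aligned to the
#'   columns of `counts`. Every cell must be labeled.
#' @return dense base matrix, features x groups (group columns sorted).
#' @export
pseudobulk <- function(counts, groups) {
  groups <- check_labels(groups, colnames(counts))
  stop_if(anyNA(groups), "unlabeled cells: ",
          paste(utils::head(colnames(counts)[is.na(groups)], 5),
                collapse = ", "))
  f <- factor(groups)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                              x = 1, dims = c(length(f), nlevels(f)))
  out <- as.matrix(counts %*% ind)
  dimnames(out) <- list(rownames(counts), levels(f))
  out
}

#' Write a coverage track as bedGraph
#'
#' Writes per-base coverage over one interval as a bedGraph, merging runs of
#' equal value and omitting zero runs. Output coordinates are 0-based
#' half-open, as the format requires.
#'
#' @param coverage non-negative numeric vector, one value per base.
#' @param chrom chromosome name.
#' @param start0 0-based start position of `coverage[1]`.
#' @param path output path.
#' @param append append to an existing file (default FALSE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, chrom, start0, path, append = FALSE) {
  stop_if(any(coverage < 0), "negative coverage value")
  r <- rle(coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", chrom,
                   as.integer(start0 + starts[keep]),
                   as.integer(start0 + ends[keep]),
                   format(r$values[keep], trim = TRUE, scientific = FALSE,
                          digits = 15))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track into a per-base coverage vector
#'
#' Inverse of [write_bedgraph()] over a stated interval: positions not
#' covered by any record are 0.
#'
#' @param path bedGraph file.
#' @param chrom,start0,width interval to materialize (0-based start).
#' @return numeric vector of length `width`.
#' @export
read_bedgraph <- function(path, chrom, start0, width) {
  out <- numeric(width)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (f in fields) {
    if (f[1] != chrom) next
    s <- max(as.numeric(f[2]) - start0, 0)
    e <- min(as.numeric(f[3]) - start0, width)
    if (e > s) out[(s + 1):e] <- as.numeric(f[4])
  }
  out
}

#' Per-cell summary table
#'
#' Assembles the standard per-cell table: barcode, cluster/cell-type label,
#' total counts in features ("total UMIs": for ATAC this is the in-peak cut
#' total), and modality.
#'
#' @param counts features x cells matrix.
#' @param labels per-cell label (named or aligned); `NA` allowed for
#'   unannotated cells.
#' @param modality `"ATAC"` or `"RNA"`.
#' @return `data.frame` with columns barcode, cell_type, total_umis,
#'   modality.
#' @export
cell_table <- function(counts, labels = NULL, modality = c("ATAC", "RNA")) {
  modality <- match.arg(modality)
  cells <- colnames(counts)
  if (is.null(labels)) labels <- rep(NA_character_, length(cells))
  else if (!is.null(names(labels))) labels <- unname(labels[cells])
  data.frame(barcode = cells, cell_type = as.character(labels),
             total_umis = Matrix::colSums(counts),
             modality = modality, row.names = NULL)
}
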