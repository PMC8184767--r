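# Cross-modality feature transfer through a joint embedding.

as_embedding <- function(embedding) {
  stop_if(!all(c("barcode", "modality") %in% names(embedding)),
          "embedding needs `barcode` and `modality` columns")
  dims <- grep("^dim", names(embedding), value = TRUE)
  stop_if(length(dims) == 0, "embedding needs dim1..dimd columns")
  coords <- as.matrix(embedding[, dims, drop = FALSE])
  stop_if(!all(is.finite(coords)), "non-finite embedding coordinates")
  stop_if(!all(c("ATAC", "RNA") %in% embedding$modality),
          "embedding must contain both modalities")
  list(coords = coords, barcode = embedding$barcode,
       modality = embedding$modality)
}

# Euclidean distances between two coordinate sets, rows of a vs rows of b
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# indices (into the RNA subset) of each ATAC cell's k nearest RNA
# neighbors, ties broken by (distance, RNA cell index)
knn_indices <- function(emb, k) {
  atac <- emb$modality == "ATAC"
  rna <- emb$modality == "RNA"
  stop_if(sum(rna) < k, "fewer RNA cells (", sum(rna), ") than k = ", k)
  d <- cross_dist(emb$coords[atac, , drop = FALSE],
                  emb$coords[rna, , drop = FALSE])
  t(apply(d, 1, function(row) order(row, seq_along(row))[seq_len(k)]))
}

#' Build a joint embedding from shared gene features
#'
#' A simple co-embedding of ATAC and RNA cells: both matrices are
#' restricted to shared genes, depth-normalized, log1p-transformed, and
#' standardized per gene using the RNA-side mean and SD; cells are then
#' projected onto the top `d` principal axes of the RNA side, placing ATAC
#' cells (via gene activity) into RNA PC space. A lightweight stand-in for
#' anchor-based integration.
#'
#' @param activity genes x ATAC-cells gene-activity matrix.
#' @param expr genes x RNA-cells expression matrix.
#' @param d number of principal axes (default 10).
#' @param scale depth-normalization target.
#' @return `data.frame` with barcode, modality, dim1..dimd.
#' @export
shared_feature_embedding <- function(activity, expr, d = 10, scale = 1e4) {
  shared <- intersect(rownames(activity), rownames(expr))
  stop_if(length(shared) == 0, "no shared genes between modalities")
  stop_if(d > length(shared), "d = ", d, " exceeds ", length(shared),
          " shared genes")
  a <- log1p(as.matrix(normalize_depth(activity[shared, , drop = FALSE],
                                       scale)))
  r <- log1p(as.matrix(normalize_depth(expr[shared, , drop = FALSE], scale)))
  mu <- rowMeans(r)
  sd <- apply(r, 1, stats::sd)
  keep <- sd > 0
  stop_if(sum(keep) < d, "fewer informative shared genes than d")
  std <- function(m) (m[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  r_std <- t(std(r)); a_std <- t(std(a))      # cells x genes
  pc <- stats::prcomp(r_std, center = FALSE, scale. = FALSE, rank. = d)
  coords <- rbind(a_std %*% pc$rotation, pc$x[, seq_len(d), drop = FALSE])
  out <- data.frame(barcode = c(colnames(activity), colnames(expr)),
                    modality = rep(c("ATAC", "RNA"),
                                   c(ncol(activity), ncol(expr))))
  colnames(coords) <- paste0("dim", seq_len(d))
  cbind(out, as.data.frame(coords, row.names = seq_len(nrow(coords))))
}

#' Transfer a per-cell feature from RNA to ATAC cells by kNN averaging
#'
#' Each ATAC cell receives the unweighted mean of the feature over its `k`
#' nearest RNA-modality neighbors (Euclidean distance in the embedding;
#' only RNA cells are eligible neighbors). Ties are broken by (distance,
#' cell index), so results are deterministic.
#'
#' @param embedding `data.frame` with barcode, modality, dim1..dimd.
#' @param feature numeric vector named by RNA barcode, or aligned to the
#'   RNA cells of the embedding.
#' @param k neighbors (default 25).
#' @return numeric vector named by ATAC barcode.
#' @export
knn_transfer_mean <- function(embedding, feature, k = 25) {
  stop_if(k < 1, "k must be >= 1")
  emb <- as_embedding(embedding)
  rna_bc <- emb$barcode[emb$modality == "RNA"]
  if (!is.null(names(feature))) {
    stop_if(!all(rna_bc %in% names(feature)),
            "feature missing for some RNA cells")
    feature <- unname(feature[rna_bc])
  }
  stop_if(length(feature) != length(rna_bc),
          "feature must cover every RNA cell")
  stop_if(anyNA(feature), "feature contains NA")
  nn <- knn_indices(emb, k)
  out <- rowMeans(matrix(feature[nn], nrow = nrow(nn)))
  stats::setNames(out, emb$barcode[emb$modality == "ATAC"])
}

#' Transfer categorical labels from RNA to ATAC cells by kNN vote
#'
#' Majority vote among the `k` nearest RNA neighbors; confidence is the
#' winning vote fraction. Vote ties are broken in favor of the label with
#' the smaller summed neighbor distance.
#'
#' @param embedding `data.frame` with barcode, modality, dim1..dimd.
#' @param labels character vector named by RNA barcode, or aligned to the
#'   RNA cells.
#' @param k neighbors (default 25).
#' @return `data.frame` with barcode, label, confidence.
#' @export
knn_transfer_label <- function(embedding, labels, k = 25) {
  stop_if(k < 1, "k must be >= 1")
  emb <- as_embedding(embedding)
  rna_sel <- emb$modality == "RNA"
  rna_bc <- emb$barcode[rna_sel]
  if (!is.null(names(labels))) {
    stop_if(!all(rna_bc %in% names(labels)),
            "labels missing for some RNA cells")
    labels <- unname(labels[rna_bc])
  }
  stop_if(length(labels) != length(rna_bc),
          "labels must cover every RNA cell")
  atac_sel <- emb$modality == "ATAC"
  d <- cross_dist(emb$coords[atac_sel, , drop = FALSE],
                  emb$coords[rna_sel, , drop = FALSE])
  stop_if(ncol(d) < k, "fewer RNA cells than k")
  res <- lapply(seq_len(nrow(d)), function(i) {
    nn <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(l) sum(d[i, nn[labels[nn] == l]]),
                     numeric(1))
      top <- top[order(sums, top)][1]
    }
    c(label = top, confidence = max(votes) / k)
  })
  data.frame(barcode = emb$barcode[atac_sel],
             label = vapply(res, `[[`, "", "label"),
             confidence = as.numeric(vapply(res, `[[`, "", "confidence")),
             row.names = NULL)
}
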