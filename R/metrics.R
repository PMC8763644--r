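# Integration-quality metrics. All scores are mapped to [0, 1]; four measure
# batch-effect removal (EBM, batch ASW, PC regression, graph connectivity)
# and six biological conservation (NMI, ARI, cell-type ASW, kNN accuracy,
# isolated-label F1 and silhouette). The overall score weights the two
# category means 40:60.

emb_coords <- function(emb) {
  if (inherits(emb, "latent_embedding")) emb$coords else as.matrix(emb)
}

emb_meta <- function(emb, labels, col) {
  if (!is.null(labels)) return(as.character(labels))
  if (inherits(emb, "latent_embedding") && !is.null(emb$cell_meta[[col]]))
    return(as.character(emb$cell_meta[[col]]))
  stop("no `", col, "` labels supplied or present in the embedding")
}

#' Entropy of batch mixing
#'
#' For `n_draws` randomly drawn cells, the batch-label frequencies `p_i`
#' among each cell's `k` nearest neighbours are turned into the entropy
#' `-sum(p_i log(p_i))` with the logarithm base set to the number of batches,
#' so a perfectly even local mixture scores 1 and a pure region 0; the
#' reported value is the average over draws (Monte-Carlo standard error in
#' attribute `mc_se`).
#'
#' @param emb a `latent_embedding` or coordinate matrix.
#' @param batch_labels per-cell batch labels (default: the embedding's
#'   `study` column).
#' @param k neighbourhood size.
#' @param n_draws number of sampled regions.
#' @param seed RNG seed for the draws.
#' @return scalar in \[0, 1\].
#' @export
entropy_batch_mixing <- function(emb, batch_labels = NULL, k = 15,
                                 n_draws = 100, seed = 1) {
  coords <- emb_coords(emb)
  batch <- emb_meta(emb, batch_labels, "study")
  nb <- length(unique(batch))
  if (nb < 2) stop("entropy of batch mixing requires at least two batches")
  if (nrow(coords) < k + 1) stop("need at least k + 1 cells")
  nn <- knn_search(coords, k = k)
  set.seed(seed)
  cells <- sample.int(nrow(coords), n_draws, replace = n_draws > nrow(coords))
  ent <- vapply(cells, function(i) {
    p <- tabulate(factor(batch[nn$index[i, ]], levels = unique(batch)), nb) / k
    p <- p[p > 0]
    -sum(p * log(p)) / log(nb)
  }, 0)
  structure(mean(ent), mc_se = stats::sd(ent) / sqrt(n_draws))
}

mean_silhouette <- function(coords, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) stop("silhouette requires at least two label groups")
  if (all(table(f) < 2)) stop("silhouette requires a non-singleton group")
  sil <- cluster::silhouette(as.integer(f), stats::dist(coords))
  mean(sil[, 3])
}

#' Cell-type average silhouette width, scaled to \[0, 1\]
#'
#' Mean silhouette of the cell-type grouping, mapped by `(ASW + 1) / 2`:
#' 1 = compact well-separated types, 0 = strong misclassification.
#'
#' @inheritParams entropy_batch_mixing
#' @param celltype_labels per-cell type labels (default: the embedding's
#'   `cell_type` column).
#' @return scalar in \[0, 1\].
#' @export
asw_celltype <- function(emb, celltype_labels = NULL) {
  coords <- emb_coords(emb)
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  (mean_silhouette(coords, ct) + 1) / 2
}

#' Batch average silhouette width within cell-type clusters
#'
#' Within each cell type the silhouette of the batch grouping is computed and
#' mapped by `1 - abs(ASW)`, so 1 means batches are indistinguishable (well
#' mixed) and 0 means perfectly separated; the score is the mean over cell
#' types (types with fewer than two batches are skipped).
#'
#' @inheritParams asw_celltype
#' @param batch_labels per-cell batch labels.
#' @return scalar in \[0, 1\].
#' @export
asw_batch <- function(emb, batch_labels = NULL, celltype_labels = NULL) {
  coords <- emb_coords(emb)
  batch <- emb_meta(emb, batch_labels, "study")
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  scores <- c()
  for (type in unique(ct)) {
    i <- ct == type
    if (length(unique(batch[i])) < 2) next
    scores <- c(scores, 1 - abs(mean_silhouette(coords[i, , drop = FALSE],
                                                batch[i])))
  }
  if (!length(scores)) stop("no cell type contains two or more batches")
  mean(scores)
}

entropy_of <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two labelings
#'
#' Mutual information scaled by the arithmetic mean of the two label
#' entropies; 1 for identical partitions, 0 for independent ones (and, by
#' convention, when either labeling is constant).
#'
#' @param truth,clusters label vectors over the same cells.
#' @return scalar in \[0, 1\].
#' @export
nmi_score <- function(truth, clusters) {
  stopifnot(length(truth) == length(clusters))
  h1 <- entropy_of(truth); h2 <- entropy_of(clusters)
  if (h1 == 0 || h2 == 0) return(0)
  joint <- table(truth, clusters) / length(truth)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  mi / mean(c(h1, h2))
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting Rand index adjusted for chance agreement. The reported score
#' is clipped to \[0, 1\] (attribute `raw` carries the unclipped value, which
#' can be slightly negative for worse-than-random partitions).
#'
#' @param truth,clusters label vectors over the same cells.
#' @return scalar in \[0, 1\].
#' @export
ari_score <- function(truth, clusters) {
  stopifnot(length(truth) == length(clusters))
  tab <- table(truth, clusters)
  n <- length(truth)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  raw <- if (mx == expected) 1 else (sij - expected) / (mx - expected)
  structure(min(1, max(0, raw)), raw = raw)
}

#' Batch variance explained, via principal-component regression
#'
#' Runs PCA on the matrix, regresses every principal component on the one-hot
#' batch label, and computes the batch-explained variance fraction
#' `sum(Var(PC_i) R2_i) / sum(Var(PC_i))`; the reported score is one minus
#' that fraction, so 1 means no detectable batch variance.
#'
#' @param x cells x features matrix (embedding or expression) or a
#'   `latent_embedding`.
#' @param batch_labels per-cell batch labels.
#' @param n_pcs number of principal components (capped by the matrix rank).
#' @return scalar in \[0, 1\]; attribute `var_explained` carries the raw
#'   batch-variance fraction.
#' @export
pc_regression <- function(x, batch_labels = NULL, n_pcs = 50) {
  coords <- emb_coords(x)
  batch <- factor(emb_meta(x, batch_labels, "study"))
  n_pcs <- min(n_pcs, ncol(coords), nrow(coords) - 1)
  pc <- stats::prcomp(coords, rank. = n_pcs)
  vars <- pc$sdev[seq_len(n_pcs)]^2
  r2 <- vapply(seq_len(n_pcs), function(i) {
    fit <- stats::lm(pc$x[, i] ~ batch)
    summary(fit)$r.squared
  }, 0)
  frac <- sum(vars * r2) / sum(vars)
  structure(1 - frac, var_explained = frac)
}

#' Per-cell-type kNN-graph connectivity
#'
#' For every cell-type label a kNN graph over only that label's cells is
#' built; the score is the mean, over labels, of the fraction of the label's
#' cells in the largest connected component. 1 means every type is connected
#' in the embedding (its batches mix into one body).
#'
#' @inheritParams asw_celltype
#' @param k_graph neighbours per cell in the subset graph.
#' @return scalar in (0, 1\].
#' @export
graph_connectivity <- function(emb, celltype_labels = NULL, k_graph = 15) {
  coords <- emb_coords(emb)
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  fracs <- vapply(unique(ct), function(type) {
    i <- which(ct == type)
    if (length(i) == 1) return(1)
    g <- knn_graph(coords[i, , drop = FALSE], k_graph)
    max(igraph::components(g)$csize) / length(i)
  }, 0)
  mean(fracs)
}

#' Leiden clustering of an embedding
#'
#' Community detection (Leiden, modularity objective) on the symmetrized
#' kNN graph of the embedding; the standard unsupervised partner labeling
#' for NMI / ARI / isolated-label F1.
#'
#' @inheritParams entropy_batch_mixing
#' @param k neighbours for the graph.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @return integer cluster membership vector.
#' @export
cluster_embedding <- function(emb, k = 15, resolution = 1, seed = 1) {
  coords <- emb_coords(emb)
  g <- knn_graph(coords, k)
  set.seed(seed)
  igraph::cluster_leiden(g, objective_function = "modularity",
                         resolution = resolution)$membership
}

isolated_labels <- function(celltype_labels, batch_labels) {
  tab <- table(celltype_labels, batch_labels) > 0
  nb <- rowSums(tab)
  names(nb)[nb == min(nb)]
}

#' Isolated-label F1 score
#'
#' Isolated labels are cell types present in the fewest batches. For each,
#' the cluster holding most of its cells is selected and the one-vs-rest F1
#' of "cell is in that cluster" as a predictor of "cell has the label" is
#' computed; the score is the mean over isolated labels.
#'
#' @inheritParams asw_batch
#' @param cluster_labels precomputed clustering (default: Leiden via
#'   [cluster_embedding()]).
#' @param seed seed for the default clustering.
#' @return scalar in \[0, 1\].
#' @export
isolated_label_f1 <- function(emb, celltype_labels = NULL,
                              batch_labels = NULL, cluster_labels = NULL,
                              seed = 1) {
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  batch <- emb_meta(emb, batch_labels, "study")
  if (is.null(cluster_labels))
    cluster_labels <- cluster_embedding(emb, seed = seed)
  iso <- isolated_labels(ct, batch)
  f1s <- vapply(iso, function(lab) {
    counts <- table(cluster_labels[ct == lab])
    best <- names(counts)[which.max(counts)]
    in_cl <- cluster_labels == best
    is_lab <- ct == lab
    tp <- sum(in_cl & is_lab)
    if (tp == 0) return(0)
    precision <- tp / sum(in_cl)
    recall <- tp / sum(is_lab)
    2 * precision * recall / (precision + recall)
  }, 0)
  mean(f1s)
}

#' Isolated-label silhouette score
#'
#' For each isolated label (see [isolated_label_f1()]) the silhouette of the
#' binary grouping label-vs-rest is computed and the mean silhouette over the
#' label's own cells mapped by `(s + 1) / 2`; the score is the mean over
#' isolated labels.
#'
#' @inheritParams asw_batch
#' @return scalar in \[0, 1\].
#' @export
isolated_label_silhouette <- function(emb, celltype_labels = NULL,
                                      batch_labels = NULL) {
  coords <- emb_coords(emb)
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  batch <- emb_meta(emb, batch_labels, "study")
  iso <- isolated_labels(ct, batch)
  d <- stats::dist(coords)
  scores <- vapply(iso, function(lab) {
    grp <- as.integer(ct == lab) + 1L
    if (length(unique(grp)) < 2)
      stop("isolated label covers all cells; silhouette undefined")
    sil <- cluster::silhouette(grp, d)
    (mean(sil[grp == 2, 3]) + 1) / 2
  }, 0)
  mean(scores)
}

#' kNN label-purity accuracy
#'
#' For each cell, the fraction of its `k` nearest neighbours sharing its
#' cell-type label; averaged within each type and then across types (macro
#' average), so rare types weigh equally with common ones.
#'
#' @inheritParams asw_celltype
#' @param k neighbourhood size.
#' @return scalar in \[0, 1\].
#' @export
knn_accuracy <- function(emb, celltype_labels = NULL, k = 15) {
  coords <- emb_coords(emb)
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  nn <- knn_search(coords, k = min(k, nrow(coords) - 1))
  per_cell <- rowMeans(matrix(ct[nn$index] == rep(ct, ncol(nn$index)),
                              nrow(nn$index)))
  mean(tapply(per_cell, ct, mean))
}

#' Compute the full ten-metric integration report
#'
#' @inheritParams asw_batch
#' @param k neighbourhood size shared by EBM, graph connectivity, the
#'   clustering graph and kNN accuracy.
#' @param n_draws EBM region draws.
#' @param resolution Leiden resolution for the clustering-based metrics.
#' @param n_pcs principal components for PC regression.
#' @param seed seed for EBM draws and clustering.
#' @return a `metric_report`: list with `scores` (named vector of the ten
#'   metrics), `batch_score`, `bio_score` and `overall`
#'   (`0.4 * batch + 0.6 * bio`).
#' @export
evaluate_integration <- function(emb, batch_labels = NULL,
                                 celltype_labels = NULL, k = 15,
                                 n_draws = 100, resolution = 1, n_pcs = 50,
                                 seed = 1) {
  batch <- emb_meta(emb, batch_labels, "study")
  ct <- emb_meta(emb, celltype_labels, "cell_type")
  clusters <- cluster_embedding(emb, k = k, resolution = resolution,
                                seed = seed)
  scores <- c(
    EBM = as.numeric(entropy_batch_mixing(emb, batch, k = k,
                                          n_draws = n_draws, seed = seed)),
    ASW_batch = asw_batch(emb, batch, ct),
    PCR = as.numeric(pc_regression(emb, batch, n_pcs = n_pcs)),
    graph_connectivity = graph_connectivity(emb, ct, k_graph = k),
    NMI = nmi_score(ct, clusters),
    ARI = as.numeric(ari_score(ct, clusters)),
    ASW_celltype = asw_celltype(emb, ct),
    kNN_accuracy = knn_accuracy(emb, ct, k = k),
    isolated_F1 = isolated_label_f1(emb, ct, batch, clusters),
    isolated_silhouette = isolated_label_silhouette(emb, ct, batch))
  make_metric_report(scores)
}

batch_metric_names <- c("EBM", "ASW_batch", "PCR", "graph_connectivity")
bio_metric_names <- c("NMI", "ARI", "ASW_celltype", "kNN_accuracy",
                      "isolated_F1", "isolated_silhouette")

make_metric_report <- function(scores) {
  batch_score <- mean(scores[batch_metric_names])
  bio_score <- mean(scores[bio_metric_names])
  structure(list(scores = scores, batch_score = batch_score,
                 bio_score = bio_score,
                 overall = 0.4 * batch_score + 0.6 * bio_score),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Integration metrics\n")
  for (nm in names(x$scores))
    cat(sprintf("  %-20s %.4f\n", nm, x$scores[nm]))
  cat(sprintf("  batch correction     %.4f\n", x$batch_score))
  cat(sprintf("  bio conservation     %.4f\n", x$bio_score))
  cat(sprintf("  overall (40:60)      %.4f\n", x$overall))
  invisible(x)
}

#' Aggregate metric reports across models
#'
#' With two or more models each metric is min-max scaled across models before
#' aggregation (a metric constant across models is passed through unscaled);
#' with one model the scaling is the identity. Aggregates are the category
#' means and the 40:60 weighted overall score.
#'
#' @param reports a named list of `metric_report`s (or named score vectors),
#'   one per model.
#' @return data frame with one row per model: the (scaled) metric columns,
#'   `batch_score`, `bio_score`, `overall`.
#' @export
aggregate_report <- function(reports) {
  if (length(reports) == 0) stop("at least one report is required")
  mat <- do.call(rbind, lapply(reports, function(r)
    if (inherits(r, "metric_report")) r$scores else unlist(r)))
  rownames(mat) <- names(reports) %||% paste0("model", seq_len(nrow(mat)))
  scaled <- mat
  if (nrow(mat) >= 2) {
    for (j in seq_len(ncol(mat))) {
      rng <- range(mat[, j])
      if (diff(rng) > 0) scaled[, j] <- (mat[, j] - rng[1]) / diff(rng)
    }
  }
  batch_score <- rowMeans(scaled[, batch_metric_names, drop = FALSE])
  bio_score <- rowMeans(scaled[, bio_metric_names, drop = FALSE])
  data.frame(scaled, batch_score = batch_score, bio_score = bio_score,
             overall = 0.4 * batch_score + 0.6 * bio_score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
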