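# End-to-end hold-out experiment: simulate an atlas, hold one cell type out
# of the reference, train the reference model, graft the query batch with
# adaptors, transfer labels, and score the integration against an
# unintegrated PCA baseline.

#' Hold-out-cell-type reference-mapping benchmark
#'
#' Simulates a multi-batch atlas (see [synthetic_spec()]), removes
#' `holdout_type` from the reference batches, trains the conditional
#' autoencoder reference, maps the query batch with adaptors-only surgery,
#' transfers labels with the weighted kNN classifier, and reports:
#' label-transfer accuracy on shared types, the "unknown" rate among held-out
#' query cells, batch-mixing scores (EBM, batch ASW) of the integrated latent
#' versus an unintegrated PCA of the log-normalized expression, and the
#' latent-geometry check that held-out cells sit closer to each other than to
#' any reference type centroid.
#'
#' @param seed integer seed driving the simulation and all training.
#' @param spec a [synthetic_spec]; defaults to the package's standard
#'   3-batch / 5-type / 1,000-gene design with `seed`.
#' @param reference_batches study labels used for reference training.
#' @param holdout_type cell type removed from the reference.
#' @param drop_gene_fraction fraction of reference genes deleted from the
#'   query before mapping (they are zero-filled back by [align_genes()]),
#'   emulating partial feature overlap.
#' @param config optional [model_config]; defaults to an MSE conditional VAE
#'   with latent dimension 10.
#' @param reference optional pre-trained `scgraft_model` to reuse (its config
#'   and gene list must match the simulated reference).
#' @param ref_epochs,map_epochs training epochs for the two stages.
#' @param k_transfer neighbours for label transfer.
#' @param pca_dims dimensionality of the unintegrated PCA baseline.
#' @param full_metrics also compute the full ten-metric report on the
#'   integrated embedding?
#' @return a list with the quantities above plus the fitted `model`, the
#'   split datasets and both embeddings.
#' @export
holdout_benchmark <- function(seed = 1, spec = NULL,
                              reference_batches = c("batch1", "batch2"),
                              holdout_type = "type5",
                              drop_gene_fraction = 0,
                              config = NULL, reference = NULL,
                              ref_epochs = 30, map_epochs = 30,
                              k_transfer = 50, pca_dims = 20,
                              full_metrics = FALSE) {
  if (is.null(spec)) spec <- synthetic_spec(seed = seed)
  atlas <- simulate_atlas(spec)
  atlas <- normalize_lognorm(atlas)
  split <- holdout_split(atlas, reference_batches, holdout_type)

  if (is.null(config))
    config <- model_config(input_dim = length(atlas$genes), latent_dim = 10,
                           likelihood = "mse", epochs = ref_epochs,
                           seed = seed)
  model <- if (is.null(reference)) train_reference(split$reference, config)
           else reference

  query <- split$query
  if (drop_gene_fraction > 0) {
    set.seed(substream_seed(seed, "genedrop"))
    drop <- sample(seq_along(query$genes),
                   round(drop_gene_fraction * length(query$genes)))
    query <- subset_genes(query, setdiff(seq_along(query$genes), drop))
  }
  mapped <- surgery(model, query, strategy = "adaptors", epochs = map_epochs)

  emb_ref <- embed(mapped$model, split$reference)
  emb_query <- mapped$embedding
  ann <- knn_transfer(emb_ref, emb_query, k_neighbors = k_transfer)

  truth <- query$cell_meta$cell_type
  shared <- truth != holdout_type
  accuracy_shared <- mean(ann$predicted[shared] == truth[shared])
  unknown_rate_holdout <- mean(ann$predicted[!shared] == "unknown")

  all_coords <- rbind(emb_ref$coords, emb_query$coords)
  all_meta <- rbind(emb_ref$cell_meta, emb_query$cell_meta)
  emb_all <- latent_embedding(all_coords, all_meta)

  combined <- rbind(as.matrix(split$reference$lognorm),
                    as.matrix(split$query$lognorm))
  pca <- stats::prcomp(combined, rank. = pca_dims)$x
  emb_pca <- latent_embedding(pca, all_meta)

  scores <- function(e) c(
    EBM = as.numeric(entropy_batch_mixing(e, k = 15, n_draws = 100,
                                          seed = seed)),
    ASW_batch = asw_batch(e))
  integrated <- scores(emb_all)
  unintegrated <- scores(emb_pca)

  # latent geometry of the held-out population
  hold_q <- emb_query$coords[!shared, , drop = FALSE]
  d_hold <- as.matrix(stats::dist(hold_q))
  within_mean <- mean(d_hold[upper.tri(d_hold)])
  ref_types <- unique(emb_ref$cell_meta$cell_type)
  centroid_dists <- vapply(ref_types, function(tp) {
    ctr <- colMeans(emb_ref$coords[emb_ref$cell_meta$cell_type == tp, ,
                                   drop = FALSE])
    mean(sqrt(rowSums(sweep(hold_q, 2, ctr)^2)))
  }, 0)

  report <- if (full_metrics)
    evaluate_integration(emb_all, seed = seed) else NULL

  list(accuracy_shared = accuracy_shared,
       unknown_rate_holdout = unknown_rate_holdout,
       integrated = integrated, unintegrated = unintegrated,
       within_holdout_distance = within_mean,
       centroid_distances = centroid_dists,
       holdout_separated = within_mean < min(centroid_dists),
       trainable_parameters = count_trainable(mapped$model),
       total_parameters = total_params(mapped$model),
       annotation = ann, model = mapped$model, reference_model = model,
       reference_data = split$reference, query_data = query,
       embedding_reference = emb_ref, embedding_query = emb_query,
       metric_report = report)
}

#' Restrict a dataset to a gene subset
#' @param ds an [sc_dataset].
#' @param genes integer indices or gene names to keep.
#' @return the restricted dataset (gene order preserved).
#' @export
subset_genes <- function(ds, genes) {
  if (is.character(genes)) genes <- match(genes, ds$genes)
  if (anyNA(genes)) stop("unknown gene in selection")
  genes <- sort(genes)
  sc_dataset(counts = if (!is.null(ds$counts)) ds$counts[, genes, drop = FALSE],
             lognorm = if (!is.null(ds$lognorm)) ds$lognorm[, genes, drop = FALSE],
             genes = ds$genes[genes], cell_meta = ds$cell_meta,
             active = ds$active)
}
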