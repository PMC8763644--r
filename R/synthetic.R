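#' Specification for a synthetic multi-batch atlas
#'
#' Defines the generative conditions for [simulate_atlas()]: a negative
#' binomial count model in which every cell type up-regulates its own disjoint
#' set of marker genes and every batch applies gene-wise multiplicative
#' offsets to the mean (log-scale Gaussian with sd `batch_effect_sd`).
#'
#' Defaults describe the hold-out experiments the package is exercised on:
#' 3 batches x 5 exchangeable cell types, 2,000 cells per batch, 1,000 genes
#' with 50 markers per type boosted by 2 natural-log units (~7.4-fold), a
#' moderate batch effect (sd 0.4) and NB size (inverse dispersion) 2, giving
#' over-dispersed counts with variance mu + mu^2/2.
#'
#' @param n_types number of cell types.
#' @param n_batches number of batches (studies).
#' @param cells_per_batch cells per batch.
#' @param n_genes number of genes.
#' @param de_genes_per_type marker genes per type (disjoint across types);
#'   `de_genes_per_type * n_types <= n_genes`.
#' @param type_effect_logfc natural-log fold change applied to a type's
#'   markers.
#' @param batch_effect_sd sd of gene-wise log-scale batch offsets; 0 disables
#'   batch effects.
#' @param nb_dispersion NB size parameter (inverse dispersion).
#' @param rare_type_fraction optional fraction in (0,1); when set, the last
#'   type is sampled with this probability and the others share the rest.
#' @param seed integer seed; the atlas is fully determined by it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 5, n_batches = 3, cells_per_batch = 2000,
                           n_genes = 1000, de_genes_per_type = 50,
                           type_effect_logfc = 2, batch_effect_sd = 0.4,
                           nb_dispersion = 2, rare_type_fraction = NULL,
                           seed = 1) {
  spec <- list(n_types = as.integer(n_types), n_batches = as.integer(n_batches),
               cells_per_batch = as.integer(cells_per_batch),
               n_genes = as.integer(n_genes),
               de_genes_per_type = as.integer(de_genes_per_type),
               type_effect_logfc = type_effect_logfc,
               batch_effect_sd = batch_effect_sd,
               nb_dispersion = nb_dispersion,
               rare_type_fraction = rare_type_fraction,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_types >= 1, n_batches >= 1, cells_per_batch >= 1,
              n_genes >= 1, de_genes_per_type >= 0,
              type_effect_logfc > 0, batch_effect_sd >= 0, nb_dispersion > 0)
    if (de_genes_per_type * n_types > n_genes)
      stop("de_genes_per_type * n_types exceeds n_genes")
    if (!is.null(rare_type_fraction) &&
        (rare_type_fraction <= 0 || rare_type_fraction >= 1))
      stop("rare_type_fraction must lie in (0, 1)")
  })
  structure(spec, class = "synthetic_spec")
}

# Deterministic independent substream seed for a named block, so that edits to
# one (batch, type) block never perturb draws in another.
substream_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483647L
  as.integer(h)
}

#' Simulate a multi-batch, multi-cell-type count atlas
#'
#' Counts are NB(mu, size = `nb_dispersion`) with
#' `mu = base_mean * exp(logfc * is_marker) * exp(batch_offset)`. Base
#' log-means are standard normal; each (batch, type) block and each batch's
#' offset vector draw from an independent seeded RNG stream, so the atlas is
#' bit-reproducible and block-local.
#'
#' @param spec a [synthetic_spec].
#' @return an [sc_dataset] with a counts layer; `cell_meta` carries true
#'   `study` and `cell_type` labels. Attribute `ground_truth` holds the spec
#'   and the per-type marker gene names.
#' @export
simulate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  G <- spec$n_genes; Tt <- spec$n_types; B <- spec$n_batches
  genes <- sprintf("gene%04d", seq_len(G))
  markers <- lapply(seq_len(Tt), function(t) {
    if (spec$de_genes_per_type == 0) integer(0) else
      seq.int((t - 1) * spec$de_genes_per_type + 1, t * spec$de_genes_per_type)
  })

  rng <- function(seed_args, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(do.call(substream_seed, c(list(spec$seed), seed_args)))
    expr()
  }

  base_logmean <- rng(list("base"), function() stats::rnorm(G, 0, 1))

  type_probs <- if (is.null(spec$rare_type_fraction)) rep(1 / Tt, Tt) else
    c(rep((1 - spec$rare_type_fraction) / (Tt - 1), Tt - 1),
      spec$rare_type_fraction)

  counts <- vector("list", B)
  meta <- vector("list", B)
  for (b in seq_len(B)) {
    offs <- if (spec$batch_effect_sd > 0)
      rng(list("batchoff", b), function() stats::rnorm(G, 0, spec$batch_effect_sd))
    else rep(0, G)
    types <- rng(list("assign", b), function()
      sample.int(Tt, spec$cells_per_batch, replace = TRUE, prob = type_probs))
    block <- matrix(0L, spec$cells_per_batch, G)
    for (t in sort(unique(types))) {
      rows <- which(types == t)
      logmu <- base_logmean + offs
      logmu[markers[[t]]] <- logmu[markers[[t]]] + spec$type_effect_logfc
      mu <- exp(logmu)
      block[rows, ] <- rng(list("block", b, t), function()
        matrix(stats::rnbinom(length(rows) * G, mu = rep(mu, each = length(rows)),
                              size = spec$nb_dispersion),
               nrow = length(rows)))
    }
    counts[[b]] <- block
    meta[[b]] <- data.frame(
      cell_id = sprintf("b%d_c%04d", b, seq_len(spec$cells_per_batch)),
      study = sprintf("batch%d", b),
      cell_type = sprintf("type%d", types),
      stringsAsFactors = FALSE)
  }
  ds <- sc_dataset(counts = do.call(rbind, counts), genes = genes,
                   cell_meta = do.call(rbind, meta))
  attr(ds, "ground_truth") <- list(
    spec = unclass(spec),
    markers = stats::setNames(lapply(markers, function(i) genes[i]),
                              sprintf("type%d", seq_len(Tt))))
  ds
}

#' Split an atlas into reference and query with held-out cell types
#'
#' The reference keeps only `reference_batches`, with cells of
#' `holdout_types` removed; the query keeps all remaining batches with every
#' type intact — mirroring experiments where a population is absent from the
#' reference but present in the mapped query.
#'
#' @param ds an [sc_dataset] with `study` and `cell_type` metadata.
#' @param reference_batches study labels forming the reference.
#' @param holdout_types cell-type labels removed from the reference (may be
#'   empty).
#' @return `list(reference = , query = )` of [sc_dataset]s.
#' @export
holdout_split <- function(ds, reference_batches, holdout_types = character(0)) {
  meta <- ds$cell_meta
  if (!all(reference_batches %in% meta$study))
    stop("unknown reference batch: ",
         paste(setdiff(reference_batches, meta$study), collapse = ", "))
  if (length(holdout_types) && is.null(meta$cell_type))
    stop("dataset has no cell_type metadata")
  if (length(holdout_types) && !all(holdout_types %in% meta$cell_type))
    stop("unknown holdout type: ",
         paste(setdiff(holdout_types, meta$cell_type), collapse = ", "))
  in_ref_batch <- meta$study %in% reference_batches
  ref_idx <- which(in_ref_batch & !(meta$cell_type %in% holdout_types))
  qry_idx <- which(!in_ref_batch)
  if (!length(ref_idx)) stop("reference split is empty")
  if (!length(qry_idx)) stop("query split is empty")
  list(reference = subset_cells(ds, ref_idx),
       query = subset_cells(ds, qry_idx))
}
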