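#' Train a conditional autoencoder reference atlas
#'
#' Fits a conditional (variational) autoencoder to a multi-study dataset: the
#' study label enters the first encoder and first decoder layer as a one-hot
#' condition (`f1 = relu(W_x' x + W_s' s)`, `g1 = relu(W_z' z + W_s' s)`), so
#' the latent posterior mean is depleted of study variation and serves as the
#' integrated embedding. The objective is the evidence lower bound (chosen
#' likelihood minus `alpha` times the Gaussian KL), optionally minus `beta`
#' times a multi-scale-RBF MMD penalty between the study groups' first
#' decoder-layer activations. All parameters are trained at this stage;
#' query studies are added later with [surgery()] / [finetune_query()].
#'
#' @param ds an [sc_dataset]; must carry the layer the likelihood needs
#'   (lognorm for `"mse"`, counts for `"nb"`/`"zinb"`).
#' @param config a [model_config]; `input_dim` must equal the gene count.
#' @param verbose print per-epoch loss?
#' @return an object of class `scgraft_model`.
#' @export
train_reference <- function(ds, config, verbose = FALSE) {
  stopifnot(inherits(ds, "sc_dataset"), inherits(config, "model_config"))
  if (config$input_dim != length(ds$genes))
    stop("config input_dim (", config$input_dim,
         ") does not match gene count (", length(ds$genes), ")")
  registry <- ds$studies
  if (length(registry) < 1) stop("dataset has no study labels")
  set.seed(config$seed)
  par <- init_params(config, length(registry))
  frozen <- empty_masks(par)
  inp <- model_input(ds, config$likelihood)
  sidx <- match(ds$cell_meta$study, registry)
  fit <- adam_train(par, frozen, config, inp$X, sidx, inp$target, inp$lib,
                    epochs = config$epochs, verbose = verbose)
  structure(list(par = fit$par, frozen = frozen, config = config,
                 genes = ds$genes, registry = registry,
                 reference_studies = registry, new_studies = character(0),
                 strategy = NULL, history = fit$history),
            class = "scgraft_model")
}

#' First encoder layer with explicit condition selection
#'
#' Evaluates `f1 = relu(W_x' x + W_s' s)` where `s` selects the study's row of
#' the condition weight matrix; the adaptor weights of a grafted study enter
#' the network exactly here.
#'
#' @param model an `scgraft_model`.
#' @param x numeric vector of length `input_dim` (or a cells x genes matrix).
#' @param study a study label present in the model registry, or a one-hot
#'   vector over the registry.
#' @return the p-dimensional activation (matrix input gives one row per cell).
#' @export
first_layer_encoder <- function(model, x, study) {
  if (is.numeric(study)) {
    if (length(study) != length(model$registry) || sum(study == 1) != 1 ||
        sum(study) != 1)
      stop("`study` must be one-hot over the condition registry")
    study <- model$registry[which(study == 1)]
  }
  i <- match(study, model$registry)
  if (is.na(i)) stop("unknown study label '", study, "'")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  act <- relu(x %*% model$par$enc_x +
                matrix(model$par$enc_s[i, ], nrow(x), ncol(model$par$enc_s),
                       byrow = TRUE))
  if (nrow(act) == 1) drop(act) else act
}

#' Latent embedding of cells under a trained model
#'
#' Returns the posterior mean of the latent variable per cell (no sampling),
#' the model's integration output. The dataset's genes must match the model
#' gene list ([align_genes()] first if needed) and every study must be in the
#' condition registry ([surgery()] first for new studies).
#'
#' @param model an `scgraft_model`.
#' @param ds an [sc_dataset].
#' @return a `latent_embedding`: list with `coords` (cells x k matrix) and
#'   `cell_meta`.
#' @export
embed <- function(model, ds) {
  stopifnot(inherits(model, "scgraft_model"), inherits(ds, "sc_dataset"))
  if (!identical(ds$genes, model$genes))
    stop("dataset genes do not match the model gene list; run align_genes()")
  unknown <- setdiff(ds$studies, model$registry)
  if (length(unknown))
    stop("study not in condition registry: ",
         paste(unknown, collapse = ", "), " (run surgery first)")
  inp <- model_input(ds, model$config$likelihood)
  sidx <- match(ds$cell_meta$study, model$registry)
  fw <- ae_forward(model$par, model$config, inp$X, sidx,
                   eps = matrix(0, nrow(inp$X), model$config$latent_dim))
  latent_embedding(fw$mu, ds$cell_meta)
}

#' Construct a latent embedding object
#' @param coords cells x k numeric matrix.
#' @param cell_meta per-cell metadata data frame.
#' @return a `latent_embedding`.
#' @export
latent_embedding <- function(coords, cell_meta) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite latent coordinates")
  stopifnot(nrow(coords) == nrow(cell_meta))
  rownames(coords) <- cell_meta$cell_id
  structure(list(coords = coords, cell_meta = cell_meta),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat("latent_embedding: ", nrow(x$coords), " cells x ", ncol(x$coords),
      " dims\n", sep = "")
  invisible(x)
}

# -- loss wrappers (full-dataset evaluation) ----------------------------------

#' Evaluate the conditional-VAE objective on a dataset
#'
#' Computes the per-cell mean evidence lower bound: reconstruction
#' log-likelihood minus `alpha` times the KL divergence of the diagonal
#' Gaussian posterior from the standard normal prior, using one seeded
#' reparameterization draw.
#'
#' @param model an `scgraft_model`.
#' @param ds an [sc_dataset] slice with the likelihood-appropriate layer.
#' @param alpha KL scale (defaults to the model's).
#' @param seed seed for the reparameterization draw.
#' @return list with `total` (= `recon - alpha * kl`), `recon`, `kl`.
#' @export
loss_cvae <- function(model, ds, alpha = model$config$alpha, seed = 1) {
  inp <- model_input(ds, model$config$likelihood)
  sidx <- match(ds$cell_meta$study, model$registry)
  if (anyNA(sidx)) stop("dataset contains studies unknown to the model")
  set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(inp$X) * model$config$latent_dim),
                nrow(inp$X), model$config$latent_dim)
  out <- ae_loss_grad(model$par, model$config, inp$X, sidx, inp$target,
                      lib = inp$lib, eps = eps, alpha = alpha, beta = 0,
                      want_grad = FALSE)
  if (!is.finite(out$loss)) {
    bad <- c(recon = out$recon, kl = out$kl)[!is.finite(c(out$recon, out$kl))]
    stop("non-finite loss component: ", paste(names(bad), collapse = ", "))
  }
  list(total = out$recon - alpha * out$kl, recon = out$recon, kl = out$kl)
}

#' Evaluate the MMD-regularized (trVAE-style) objective on a dataset
#'
#' The CVAE objective minus `beta` times the MMD between every unordered pair
#' of study groups, measured on the first decoder layer's activations.
#' A single-study slice gets an MMD component of 0 with a warning.
#'
#' @inheritParams loss_cvae
#' @param beta MMD scale.
#' @return list with `total` (= `recon - alpha*kl - beta*mmd`), `recon`,
#'   `kl`, `mmd`.
#' @export
loss_trvae <- function(model, ds, alpha = model$config$alpha,
                       beta = model$config$beta, seed = 1) {
  base <- loss_cvae(model, ds, alpha = alpha, seed = seed)
  inp <- model_input(ds, model$config$likelihood)
  sidx <- match(ds$cell_meta$study, model$registry)
  set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(inp$X) * model$config$latent_dim),
                nrow(inp$X), model$config$latent_dim)
  fw <- ae_forward(model$par, model$config, inp$X, sidx, eps)
  mm <- mmd_groups(fw$dec_h[[1]], sidx, model$config$gammas, want_grad = FALSE)
  if (mm$n_groups < 2) {
    warning("fewer than two study groups in batch; MMD component set to 0")
    mm$value <- 0
  }
  list(total = base$total - beta * mm$value, recon = base$recon,
       kl = base$kl, mmd = mm$value)
}

# -- S3 methods for the fitted model ------------------------------------------

#' @export
print.scgraft_model <- function(x, ...) {
  cfg <- x$config
  cat("scgraft_model (conditional ", toupper(cfg$likelihood), " autoencoder)\n",
      sep = "")
  cat("  genes: ", length(x$genes), "  latent dim: ", cfg$latent_dim, "\n",
      sep = "")
  cat("  encoder widths: ", paste(cfg$encoder_widths, collapse = "-"),
      "  decoder widths: ", paste(cfg$decoder_widths, collapse = "-"), "\n",
      sep = "")
  cat("  conditions: ", length(x$registry), " (",
      length(x$reference_studies), " reference, ",
      length(x$new_studies), " grafted)\n", sep = "")
  cat("  trainable parameters: ", count_trainable(x), " of ",
      total_params(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.scgraft_model <- function(object, ...) {
  print(object)
  if (length(object$history)) {
    h <- object$history
    cat("  training loss: ", signif(h[1], 5), " -> ", signif(h[length(h)], 5),
        " over ", length(h), " epochs\n", sep = "")
  }
  if (length(object$new_studies))
    cat("  grafted studies: ", paste(object$new_studies, collapse = ", "),
        "\n", sep = "")
  invisible(object)
}

#' @export
coef.scgraft_model <- function(object, ...) object$par

#' Predict latent coordinates for new cells
#' @param object an `scgraft_model`.
#' @param newdata an [sc_dataset] (genes aligned, studies registered).
#' @param ... unused.
#' @return a `latent_embedding`.
#' @export
predict.scgraft_model <- function(object, newdata, ...) embed(object, newdata)

#' Generate cells from the fitted decoder
#'
#' Samples latent vectors from the standard normal prior and decodes them for
#' a given study condition; for count likelihoods the decoded mean proportion
#' is scaled by `library_size` and counts are drawn from the (zero-inflated)
#' negative binomial observation model.
#'
#' @param object an `scgraft_model`.
#' @param nsim number of cells.
#' @param seed optional seed.
#' @param study study label to condition on (default: first in registry).
#' @param library_size library size for count likelihoods.
#' @param ... unused.
#' @return a cells x genes matrix.
#' @export
simulate.scgraft_model <- function(object, nsim = 1, seed = NULL,
                                   study = object$registry[1],
                                   library_size = 1e4, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  i <- match(study, object$registry)
  if (is.na(i)) stop("unknown study label '", study, "'")
  z <- matrix(stats::rnorm(nsim * cfg$latent_dim), nsim, cfg$latent_dim)
  par <- object$par
  g <- relu(z %*% par$dec_z +
              matrix(par$dec_s[i, ], nsim, ncol(par$dec_s), byrow = TRUE))
  for (j in seq_along(cfg$decoder_widths)[-1])
    g <- relu(sweep(g %*% par[[paste0("dec_W", j)]], 2,
                    par[[paste0("dec_b", j)]], "+"))
  if (cfg$likelihood == "mse")
    return(sweep(g %*% par$out_W, 2, par$out_b, "+"))
  gx <- row_softmax(sweep(g %*% par$px_W, 2, par$px_b, "+"))
  mu <- gx * library_size
  S <- exp(par$log_disp)
  cts <- matrix(stats::rnbinom(length(mu), mu = t(mu)[TRUE],
                               size = rep(S, nsim)),
                nsim, ncol(mu), byrow = TRUE)
  if (cfg$likelihood == "zinb") {
    pi <- sigmoid(sweep(g %*% par$pd_W, 2, par$pd_b, "+"))
    cts[matrix(stats::runif(length(pi)), nsim) < pi] <- 0L
  }
  colnames(cts) <- object$genes
  cts
}

#' Plot the latent space of a model on a dataset
#'
#' Scatter of the first two principal components of the latent embedding,
#' colored by study.
#'
#' @param x an `scgraft_model`.
#' @param ds an [sc_dataset].
#' @param color_by metadata column for colors (`"study"` or `"cell_type"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.scgraft_model <- function(x, ds, color_by = "study", ...) {
  emb <- embed(x, ds)
  pc <- stats::prcomp(emb$coords, rank. = 2)$x
  grp <- factor(emb$cell_meta[[color_by]])
  graphics::plot(pc, col = as.integer(grp), pch = 16, cex = 0.5,
                 xlab = "latent PC1", ylab = "latent PC2", ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 16, cex = 0.7)
  invisible(pc)
}

total_params <- function(model) sum(vapply(model$par, length, 1L))

# -- model persistence --------------------------------------------------------

#' Save a model directory
#'
#' Writes a JSON manifest (config, condition registry, gene list, tensor
#' shapes, frozen-row bookkeeping) plus one flat little-endian binary array
#' file per parameter tensor and per frozen mask. The round trip through
#' [load_model()] is bit-exact.
#'
#' @param model an `scgraft_model`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  shapes <- lapply(model$par, function(x) if (is.null(dim(x))) length(x) else dim(x))
  manifest <- list(config = unclass(model$config),
                   registry = model$registry,
                   reference_studies = model$reference_studies,
                   new_studies = model$new_studies,
                   strategy = model$strategy,
                   genes = model$genes,
                   tensors = shapes,
                   history = model$history)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(model$par)) {
    con <- file(file.path(path, paste0(nm, ".bin")), "wb")
    writeBin(as.numeric(model$par[[nm]]), con, size = 8, endian = "little")
    close(con)
    con <- file(file.path(path, paste0(nm, ".mask.bin")), "wb")
    writeBin(as.integer(model$frozen[[nm]]), con, size = 4, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Load a model directory written by [save_model()]
#' @param path model directory.
#' @return an `scgraft_model`.
#' @export
load_model <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  config <- model_config(cfg$input_dim, cfg$latent_dim, cfg$encoder_widths,
                         cfg$decoder_widths, cfg$likelihood, cfg$alpha,
                         cfg$beta, cfg$gammas, cfg$epochs, cfg$batch_size,
                         cfg$learning_rate, cfg$seed)
  par <- list(); frozen <- list()
  for (nm in names(man$tensors)) {
    shp <- unlist(man$tensors[[nm]])
    n <- prod(shp)
    con <- file(file.path(path, paste0(nm, ".bin")), "rb")
    v <- readBin(con, "numeric", n, size = 8, endian = "little")
    close(con)
    con <- file(file.path(path, paste0(nm, ".mask.bin")), "rb")
    mk <- as.logical(readBin(con, "integer", n, size = 4, endian = "little"))
    close(con)
    if (length(shp) == 2) { dim(v) <- shp; dim(mk) <- shp }
    par[[nm]] <- v; frozen[[nm]] <- mk
  }
  structure(list(par = par, frozen = frozen, config = config,
                 genes = man$genes, registry = man$registry,
                 reference_studies = man$reference_studies,
                 new_studies = if (length(man$new_studies)) man$new_studies
                 else character(0),
                 strategy = man$strategy,
                 history = if (length(man$history)) man$history else numeric(0)),
            class = "scgraft_model")
}
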