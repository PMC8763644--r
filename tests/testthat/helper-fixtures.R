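# Fixture builders shared across test files.

# small two-study dataset with both layers
toy_dataset <- function(n_cells = 30, n_genes = 12, n_studies = 2, seed = 99,
                        types = NULL) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes)
  meta <- data.frame(
    cell_id = paste0("c", seq_len(n_cells)),
    study = paste0("s", rep_len(seq_len(n_studies), n_cells)),
    stringsAsFactors = FALSE)
  if (!is.null(types)) meta$cell_type <- rep_len(types, n_cells)
  normalize_lognorm(sc_dataset(counts = counts, cell_meta = meta))
}

tiny_config <- function(d, epochs = 10, ...) {
  model_config(input_dim = d, latent_dim = 4, encoder_widths = c(16, 8),
               decoder_widths = c(8, 16), epochs = epochs, batch_size = 32,
               seed = 5, ...)
}

# gaussian blobs in latent space with labels
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1,
                       batch = NULL, label_prefix = "t") {
  set.seed(seed)
  k <- ncol(centers)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * k, 0, sd), n_per, k) +
      matrix(centers[i, ], n_per, k, byrow = TRUE)))
  n <- nrow(coords)
  meta <- data.frame(
    cell_id = paste0("b", seq_len(n)),
    study = if (is.null(batch)) rep("s1", n) else rep_len(batch, n),
    cell_type = paste0(label_prefix, rep(seq_len(nrow(centers)), each = n_per)),
    stringsAsFactors = FALSE)
  latent_embedding(coords, meta)
}

random_rotation <- function(k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

rotate_embedding <- function(emb, R) {
  latent_embedding(emb$coords %*% R, emb$cell_meta)
}

# flatten / unflatten model parameters, for finite-difference checks
flatten_params <- function(par) unlist(par, use.names = FALSE)
unflatten_params <- function(vec, par) {
  i <- 0
  for (nm in names(par)) {
    n <- length(par[[nm]])
    v <- vec[(i + 1):(i + n)]
    if (!is.null(dim(par[[nm]]))) dim(v) <- dim(par[[nm]])
    par[[nm]] <- v
    i <- i + n
  }
  par
}

# central finite differences of f at v0
numeric_gradient <- function(f, v0, h = 1e-5) {
  vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, 0)
}
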