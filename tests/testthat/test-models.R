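make_untrained <- function(ds, ...) {
  cfg <- tiny_config(length(ds$genes), epochs = 0, ...)
  train_reference(ds, cfg)
}

test_that("first encoder layer is an affine map plus ReLU with condition row", {
  ds <- toy_dataset(n_genes = 6)
  m <- make_untrained(ds)
  # zero input: output is ReLU of the selected condition row
  expect_equal(first_layer_encoder(m, rep(0, 6), "s2"),
               pmax(m$par$enc_s[2, ], 0))
  # all pre-activations negative: ReLU floor at zero
  m2 <- m
  m2$par$enc_s[1, ] <- -10
  expect_equal(first_layer_encoder(m2, rep(0, 6), "s1"),
               rep(0, ncol(m$par$enc_s)))
  # random instance against a direct affine+ReLU oracle
  set.seed(3)
  x <- rnorm(6)
  oracle <- pmax(as.numeric(x %*% m$par$enc_x) + m$par$enc_s[1, ], 0)
  expect_equal(first_layer_encoder(m, x, "s1"), oracle, tolerance = 1e-12)
  # one-hot form selects the same row; malformed one-hot rejected
  expect_equal(first_layer_encoder(m, x, c(1, 0)),
               first_layer_encoder(m, x, "s1"))
  expect_error(first_layer_encoder(m, x, c(1, 1)), "one-hot")
  expect_error(first_layer_encoder(m, x, "nope"), "unknown study")
})

test_that("Gaussian KL closed form matches its anchors and is non-negative", {
  expect_equal(gaussian_kl(1, 0), 0.5)
  expect_equal(gaussian_kl(0, 0), 0)
  expect_equal(gaussian_kl(matrix(0, 3, 2), matrix(0, 3, 2)), rep(0, 3))
  set.seed(8)
  for (i in 1:20) {
    kl <- gaussian_kl(matrix(rnorm(10), 5), matrix(rnorm(10), 5))
    expect_true(all(kl >= 0))
  }
})

test_that("loss_cvae reports ELBO components with the KL scaled by alpha", {
  ds <- toy_dataset(n_genes = 6)
  m <- make_untrained(ds)
  l0 <- loss_cvae(m, ds, alpha = 0, seed = 2)
  expect_equal(l0$total, l0$recon)
  l1 <- loss_cvae(m, ds, alpha = 2, seed = 2)
  expect_equal(l1$total, l1$recon - 2 * l1$kl)
  expect_gte(l1$kl, 0)
})

test_that("MMD estimator matches closed-form anchors", {
  expect_equal(mmd_pairwise(0, 1, gammas = 1), 2 - 2 * exp(-1))
  expect_equal(mmd_pairwise(c(0, 1), c(1, 0), gammas = 1), 0)
  set.seed(12)
  x <- matrix(rnorm(20), 10)
  expect_equal(mmd_pairwise(x, x, gammas = c(0.1, 1)), 0)
  for (i in 1:10) {
    a <- matrix(rnorm(16), 8); b <- matrix(rnorm(12), 6)
    m <- mmd_pairwise(a, b, gammas = c(0.01, 0.1, 1, 10))
    expect_gte(m, -1e-9)
    expect_equal(m, mmd_pairwise(b, a, gammas = c(0.01, 0.1, 1, 10)))
  }
  expect_error(mmd_pairwise(matrix(0, 0, 1), 1), "non-empty")
  expect_error(mmd_pairwise(0, 1, gammas = numeric(0)), "non-empty")
})

test_that("trVAE objective reduces to the CVAE one when beta is 0", {
  ds <- toy_dataset(n_genes = 6)
  m <- make_untrained(ds, beta = 0.5)
  lc <- loss_cvae(m, ds, seed = 4)
  lt <- loss_trvae(m, ds, beta = 0, seed = 4)
  expect_equal(lt$total, lc$total)
  one <- subset_cells(ds, ds$cell_meta$study == "s1")
  expect_warning(l1 <- loss_trvae(m, one, seed = 4), "fewer than two")
  expect_equal(l1$mmd, 0)
})

test_that("library size is the per-cell count total", {
  expect_equal(closed_form_library(matrix(c(1, 2, 3), 1)), 6)
  expect_equal(closed_form_library(rbind(c(1, 0), c(0, 1))), c(1, 1))
  set.seed(5)
  m <- matrix(rpois(30, 3) + 1, 5)
  expect_equal(closed_form_library(m), rowSums(m))
  expect_error(closed_form_library(rbind(c(1, 1), c(0, 0))), "zero total")
})

test_that("ZINB log-pmf matches the closed form and an NB oracle", {
  expect_equal(zinb_logpmf(0, mean_prop = 1, dropout = 0.5, dispersion = 1,
                           library_size = 1), log(0.75))
  expect_equal(zinb_logpmf(0, 1, dropout = 1), 0)
  expect_equal(zinb_logpmf(2, 1, dropout = 1), -Inf)
  # dropout 0 reduces to the negative binomial with mean L * g
  expect_equal(zinb_logpmf(2, mean_prop = 3 / 7, dropout = 0, dispersion = 2,
                           library_size = 7),
               dnbinom(2, mu = 3, size = 2, log = TRUE))
  for (y in c(0, 1, 5, 20))
    expect_equal(zinb_logpmf(y, 0.01, 0, 0.7, 500),
                 dnbinom(y, mu = 5, size = 0.7, log = TRUE))
})

test_that("ZINB probabilities sum to one over the truncated support", {
  grid <- expand.grid(pi = c(0, 0.3, 0.9), S = c(0.5, 2, 10),
                      mu = c(0.5, 5, 50))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; S <- grid$S[i]; pi <- grid$pi[i]
    xmax <- qnbinom(1 - 1e-9, mu = mu, size = S) + 10
    p <- exp(zinb_logpmf(0:xmax, mean_prop = mu / 100, dropout = pi,
                         dispersion = S, library_size = 100))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences on a small instance", {
  B <- 5; d <- 8
  for (lk in c("mse", "nb", "zinb")) {
    set.seed(42)
    cfg <- model_config(d, latent_dim = 3, encoder_widths = c(6, 5),
                        decoder_widths = c(5, 6), likelihood = lk,
                        alpha = 0.7, beta = 0.5, gammas = c(0.5, 2))
    par <- scgraft:::init_params(cfg, 2)
    cts <- matrix(rpois(B * d, 4) + 1, B, d)
    X <- if (lk == "mse") matrix(rnorm(B * d), B, d) else log1p(cts)
    target <- if (lk == "mse") X else cts
    lib <- rowSums(cts)
    sidx <- c(1, 1, 2, 2, 1)
    eps <- matrix(rnorm(B * 3), B, 3)
    out <- scgraft:::ae_loss_grad(par, cfg, X, sidx, target, lib = lib,
                                  eps = eps, alpha = 0.7, beta = 0.5)
    ga <- flatten_params(out$grads[names(par)])
    f <- function(v) scgraft:::ae_loss_grad(
      unflatten_params(v, par), cfg, X, sidx, target, lib = lib, eps = eps,
      alpha = 0.7, beta = 0.5, want_grad = FALSE)$loss
    gn <- numeric_gradient(f, flatten_params(par))
    rel <- abs(ga - gn) / pmax(abs(gn), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("reference training is seeded, deterministic and improves the loss", {
  spec <- synthetic_spec(n_types = 2, n_batches = 2, cells_per_batch = 60,
                         n_genes = 30, de_genes_per_type = 5, seed = 71)
  ds <- normalize_lognorm(simulate_atlas(spec))
  cfg0 <- tiny_config(30, epochs = 0)
  m0a <- train_reference(ds, cfg0)
  set.seed(cfg0$seed)
  expect_identical(m0a$par, scgraft:::init_params(cfg0, 2))
  cfg <- tiny_config(30, epochs = 25)
  m1 <- train_reference(ds, cfg)
  m2 <- train_reference(ds, cfg)
  expect_identical(m1$par, m2$par)
  expect_lt(tail(m1$history, 1), m1$history[1])
})

test_that("embed returns the posterior mean and matches a forward oracle", {
  ds <- toy_dataset(n_cells = 10, n_genes = 6)
  m <- make_untrained(ds)
  e1 <- embed(m, ds)
  e2 <- embed(m, ds)
  expect_identical(e1$coords, e2$coords)
  # duplicated cell gives identical rows
  dup <- subset_cells(ds, c(1, 1, 2))
  ed <- embed(m, dup)
  expect_equal(ed$coords[1, ], ed$coords[2, ], ignore_attr = TRUE)
  # explicit layer-by-layer forward pass
  X <- as.matrix(ds$lognorm)
  sidx <- match(ds$cell_meta$study, m$registry)
  p <- m$par
  h <- pmax(X %*% p$enc_x + p$enc_s[sidx, ], 0)
  h <- pmax(sweep(h %*% p$enc_W2, 2, p$enc_b2, "+"), 0)
  mu <- sweep(h %*% p$enc_mu_W, 2, p$enc_mu_b, "+")
  expect_equal(e1$coords, mu, tolerance = 1e-6, ignore_attr = TRUE)
  bad <- ds
  bad$cell_meta$study[1] <- "new_study"
  bad$studies <- unique(bad$cell_meta$study)
  expect_error(embed(m, bad), "new_study")
})

test_that("model directories round-trip bit-exactly", {
  ds <- toy_dataset(n_genes = 6)
  cfg <- tiny_config(6, epochs = 3, likelihood = "nb")
  m <- train_reference(ds, cfg)
  m <- expand_conditions(m, "q1")
  path <- withr::local_tempdir()
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$par, m$par)
  expect_identical(back$frozen, m$frozen)
  expect_identical(back$registry, m$registry)
  expect_identical(back$genes, m$genes)
  expect_equal(unclass(back$config), unclass(m$config))
})
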