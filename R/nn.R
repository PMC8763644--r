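# Conditional autoencoder internals: parameter initialization, forward pass,
# analytic backprop, Adam. Parameters live in a flat named list of dense
# arrays; a parallel list of logical masks marks frozen entries element-wise
# (adaptor fine-tuning freezes individual condition rows, not whole tensors).

#' Model configuration
#'
#' @param input_dim number of genes `d`.
#' @param latent_dim latent dimension `k`.
#' @param encoder_widths hidden widths of the encoder; the first element is
#'   `p`, the layer that receives the study condition.
#' @param decoder_widths hidden widths of the decoder; the first element is
#'   `q`, the conditioned layer whose activations carry the MMD penalty.
#' @param likelihood `"mse"` (Gaussian on log-normalized data), `"nb"` or
#'   `"zinb"` (counts with closed-form per-cell library size).
#' @param alpha KL scale; ramped linearly over the first tenth of the epochs.
#' @param beta MMD scale between study pairs on the first decoder layer
#'   (0 = plain conditional VAE).
#' @param gammas multi-scale RBF kernel scales for the MMD term.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed governing initialization, shuffling and the
#'   reparameterization noise.
#' @return a `model_config` list.
#' @export
model_config <- function(input_dim, latent_dim = 10,
                         encoder_widths = c(128, 64),
                         decoder_widths = c(64, 128),
                         likelihood = c("mse", "nb", "zinb"),
                         alpha = 1, beta = 0,
                         gammas = c(1e-2, 1e-1, 1, 10, 100),
                         epochs = 30, batch_size = 128,
                         learning_rate = 1e-3, seed = 1) {
  likelihood <- match.arg(likelihood)
  stopifnot(input_dim >= 1, latent_dim >= 1, all(encoder_widths >= 1),
            all(decoder_widths >= 1), alpha >= 0, beta >= 0,
            epochs >= 0, batch_size >= 1, learning_rate > 0)
  if (beta > 0 && length(gammas) == 0)
    stop("`gammas` must be non-empty when beta > 0")
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 likelihood = likelihood, alpha = alpha, beta = beta,
                 gammas = gammas, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(cfg, n_cond) {
  d <- cfg$input_dim; k <- cfg$latent_dim
  ew <- cfg$encoder_widths; dw <- cfg$decoder_widths
  p <- ew[1]; q <- dw[1]
  par <- list(enc_x = glorot(d, p), enc_s = glorot(n_cond, p))
  prev <- p
  for (j in seq_along(ew)[-1]) {
    par[[paste0("enc_W", j)]] <- glorot(prev, ew[j])
    par[[paste0("enc_b", j)]] <- numeric(ew[j])
    prev <- ew[j]
  }
  par$enc_mu_W <- glorot(prev, k); par$enc_mu_b <- numeric(k)
  par$enc_lv_W <- glorot(prev, k); par$enc_lv_b <- numeric(k)
  par$dec_z <- glorot(k, q); par$dec_s <- glorot(n_cond, q)
  prev <- q
  for (j in seq_along(dw)[-1]) {
    par[[paste0("dec_W", j)]] <- glorot(prev, dw[j])
    par[[paste0("dec_b", j)]] <- numeric(dw[j])
    prev <- dw[j]
  }
  if (cfg$likelihood == "mse") {
    par$out_W <- glorot(prev, d); par$out_b <- numeric(d)
  } else {
    par$px_W <- glorot(prev, d); par$px_b <- numeric(d)
    if (cfg$likelihood == "zinb") {
      par$pd_W <- glorot(prev, d); par$pd_b <- numeric(d)
    }
    par$log_disp <- numeric(d)   # inverse dispersion exp(0) = 1 at init
  }
  par
}

empty_masks <- function(par) lapply(par, function(x) {
  m <- x; m[] <- FALSE; storage.mode(m) <- "logical"; m
})

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(o) {
  e <- exp(o - apply(o, 1, max))
  e / rowSums(e)
}

# Forward pass with caches. X: B x d input matrix (already the likelihood-
# appropriate representation); sidx: integer condition index per row;
# eps: B x k reparameterization noise.
ae_forward <- function(par, cfg, X, sidx, eps) {
  ew <- cfg$encoder_widths; dw <- cfg$decoder_widths
  cache <- list()
  pre1e <- X %*% par$enc_x + par$enc_s[sidx, , drop = FALSE]
  h <- relu(pre1e)
  cache$pre1e <- pre1e
  cache$enc_h <- list(h)
  for (j in seq_along(ew)[-1]) {
    pre <- sweep(h %*% par[[paste0("enc_W", j)]], 2,
                 par[[paste0("enc_b", j)]], "+")
    h <- relu(pre)
    cache[[paste0("enc_pre", j)]] <- pre
    cache$enc_h[[j]] <- h
  }
  mu <- sweep(h %*% par$enc_mu_W, 2, par$enc_mu_b, "+")
  lv <- sweep(h %*% par$enc_lv_W, 2, par$enc_lv_b, "+")
  lv <- pmin(pmax(lv, -15), 15)
  z <- mu + exp(0.5 * lv) * eps
  cache$mu <- mu; cache$lv <- lv; cache$z <- z
  pre1d <- z %*% par$dec_z + par$dec_s[sidx, , drop = FALSE]
  g <- relu(pre1d)
  cache$pre1d <- pre1d
  cache$dec_h <- list(g)
  for (j in seq_along(dw)[-1]) {
    pre <- sweep(g %*% par[[paste0("dec_W", j)]], 2,
                 par[[paste0("dec_b", j)]], "+")
    g <- relu(pre)
    cache[[paste0("dec_pre", j)]] <- pre
    cache$dec_h[[j]] <- g
  }
  if (cfg$likelihood == "mse") {
    cache$xhat <- sweep(g %*% par$out_W, 2, par$out_b, "+")
  } else {
    cache$o <- sweep(g %*% par$px_W, 2, par$px_b, "+")
    cache$gx <- row_softmax(cache$o)
    if (cfg$likelihood == "zinb") {
      cache$u <- sweep(g %*% par$pd_W, 2, par$pd_b, "+")
      cache$pi <- sigmoid(cache$u)
    }
  }
  cache
}

# Objective (minimized) and analytic gradients for one minibatch.
#   J = mean(-recon_ll) + alpha * mean(KL) + beta * MMD(first decoder layer)
# `target` is X for mse, the raw count matrix for nb/zinb (with `lib` the
# per-cell library sizes). Returns loss components on the maximized scale
# (recon log-likelihood, KL, MMD) plus gradients per parameter.
ae_loss_grad <- function(par, cfg, X, sidx, target, lib = NULL, eps,
                         alpha = cfg$alpha, beta = cfg$beta,
                         want_grad = TRUE, skip_frozen = NULL) {
  B <- nrow(X)
  fw <- ae_forward(par, cfg, X, sidx, eps)
  ew <- cfg$encoder_widths; dw <- cfg$decoder_widths
  nenc <- length(ew); ndec <- length(dw)

  kl_cell <- gaussian_kl(fw$mu, fw$lv)
  if (cfg$likelihood == "mse") {
    recon_cell <- -0.5 * rowSums((target - fw$xhat)^2)
  } else {
    pim <- if (cfg$likelihood == "zinb") fw$pi else array(0, dim(fw$gx))
    Sm <- matrix(exp(par$log_disp), B, cfg$input_dim, byrow = TRUE)
    m <- fw$gx * lib
    zg <- zinb_ll_grad(as.matrix(target), m, pim, Sm)
    recon_cell <- rowSums(zg$ll)
  }
  mmd <- if (beta > 0)
    mmd_groups(fw$dec_h[[1]], sidx, cfg$gammas, want_grad = want_grad)
  else list(value = 0, grad = NULL, n_groups = 0L)

  loss <- mean(-recon_cell) + alpha * mean(kl_cell) + beta * mmd$value
  comps <- list(loss = loss, recon = mean(recon_cell), kl = mean(kl_cell),
                mmd = mmd$value)
  if (!want_grad) return(comps)

  keep <- function(nm) is.null(skip_frozen) || !isTRUE(skip_frozen[[nm]])
  gr <- list()
  # --- output head ---
  if (cfg$likelihood == "mse") {
    dxhat <- (fw$xhat - target) / B        # d mean(-recon)/d xhat
    hlast <- fw$dec_h[[ndec]]
    if (keep("out_W")) gr$out_W <- crossprod(hlast, dxhat)
    if (keep("out_b")) gr$out_b <- colSums(dxhat)
    dhdec <- dxhat %*% t(par$out_W)
  } else {
    dm <- -zg$dm / B
    tmat <- dm * lib                        # d/d softmax output
    do <- fw$gx * (tmat - rowSums(tmat * fw$gx))
    hlast <- fw$dec_h[[ndec]]
    if (keep("px_W")) gr$px_W <- crossprod(hlast, do)
    if (keep("px_b")) gr$px_b <- colSums(do)
    dhdec <- do %*% t(par$px_W)
    if (cfg$likelihood == "zinb") {
      du <- (-zg$dpi / B) * fw$pi * (1 - fw$pi)
      if (keep("pd_W")) gr$pd_W <- crossprod(hlast, du)
      if (keep("pd_b")) gr$pd_b <- colSums(du)
      dhdec <- dhdec + du %*% t(par$pd_W)
    }
    if (keep("log_disp"))
      gr$log_disp <- colSums(-zg$dS / B) * exp(par$log_disp)
  }
  # --- decoder hidden stack ---
  if (ndec >= 2) for (j in ndec:2) {
    dpre <- dhdec * (fw[[paste0("dec_pre", j)]] > 0)
    hprev <- fw$dec_h[[j - 1]]
    if (keep(paste0("dec_W", j)))
      gr[[paste0("dec_W", j)]] <- crossprod(hprev, dpre)
    if (keep(paste0("dec_b", j)))
      gr[[paste0("dec_b", j)]] <- colSums(dpre)
    dhdec <- dpre %*% t(par[[paste0("dec_W", j)]])
  }
  if (beta > 0 && !is.null(mmd$grad)) dhdec <- dhdec + beta * mmd$grad
  dpre1d <- dhdec * (fw$pre1d > 0)
  if (keep("dec_z")) gr$dec_z <- crossprod(fw$z, dpre1d)
  if (keep("dec_s")) {
    gs <- matrix(0, nrow(par$dec_s), ncol(par$dec_s))
    agg <- rowsum(dpre1d, group = sidx)
    gs[as.integer(rownames(agg)), ] <- agg
    gr$dec_s <- gs
  }
  dz <- dpre1d %*% t(par$dec_z)
  # --- latent ---
  inrange <- (fw$lv > -15) & (fw$lv < 15)
  dmu <- dz + alpha * fw$mu / B
  dlv <- (dz * 0.5 * exp(0.5 * fw$lv) * eps +
            alpha * 0.5 * (exp(fw$lv) - 1) / B) * inrange
  # --- encoder heads ---
  htop <- fw$enc_h[[nenc]]
  if (keep("enc_mu_W")) gr$enc_mu_W <- crossprod(htop, dmu)
  if (keep("enc_mu_b")) gr$enc_mu_b <- colSums(dmu)
  if (keep("enc_lv_W")) gr$enc_lv_W <- crossprod(htop, dlv)
  if (keep("enc_lv_b")) gr$enc_lv_b <- colSums(dlv)
  dhenc <- dmu %*% t(par$enc_mu_W) + dlv %*% t(par$enc_lv_W)
  if (nenc >= 2) for (j in nenc:2) {
    dpre <- dhenc * (fw[[paste0("enc_pre", j)]] > 0)
    hprev <- fw$enc_h[[j - 1]]
    if (keep(paste0("enc_W", j)))
      gr[[paste0("enc_W", j)]] <- crossprod(hprev, dpre)
    if (keep(paste0("enc_b", j)))
      gr[[paste0("enc_b", j)]] <- colSums(dpre)
    dhenc <- dpre %*% t(par[[paste0("enc_W", j)]])
  }
  dpre1e <- dhenc * (fw$pre1e > 0)
  if (keep("enc_x")) gr$enc_x <- crossprod(X, dpre1e)
  if (keep("enc_s")) {
    gs <- matrix(0, nrow(par$enc_s), ncol(par$enc_s))
    agg <- rowsum(dpre1e, group = sidx)
    gs[as.integer(rownames(agg)), ] <- agg
    gr$enc_s <- gs
  }
  c(comps, list(grads = gr))
}

# Adam over minibatches; updates only unfrozen entries. Returns list(par,
# history). Minibatches are stratified by study: within-study shuffled ranks
# are scaled to (0,1) and cells ordered globally by that rank, interleaving
# studies proportionally so MMD pairs are populated.
adam_train <- function(par, frozen, cfg, X, sidx, target, lib, epochs,
                       alpha = cfg$alpha, beta = cfg$beta,
                       lr = cfg$learning_rate, batch_size = cfg$batch_size,
                       warmup_frac = 0.1, verbose = FALSE) {
  if (epochs == 0) return(list(par = par, history = numeric(0)))
  N <- nrow(X)
  mstate <- lapply(par, function(x) { x[] <- 0; x })
  vstate <- lapply(par, function(x) { x[] <- 0; x })
  all_frozen <- vapply(names(par), function(nm) all(frozen[[nm]]), TRUE)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  history <- numeric(epochs)
  warm_epochs <- max(1, ceiling(warmup_frac * epochs))
  for (ep in seq_len(epochs)) {
    a_ep <- alpha * min(1, ep / warm_epochs)
    key <- numeric(N)
    for (s in unique(sidx)) {
      i <- which(sidx == s)
      key[i] <- sample.int(length(i)) / (length(i) + 1)
    }
    ord <- order(key)
    nb <- max(1, ceiling(N / batch_size))
    ep_loss <- 0
    for (mb in seq_len(nb)) {
      idx <- ord[seq.int((mb - 1) * batch_size + 1,
                         min(mb * batch_size, N))]
      eps <- matrix(stats::rnorm(length(idx) * cfg$latent_dim),
                    length(idx), cfg$latent_dim)
      out <- ae_loss_grad(par, cfg, X[idx, , drop = FALSE], sidx[idx],
                          if (is.null(dim(target))) target else
                            target[idx, , drop = FALSE],
                          lib = lib[idx], eps = eps,
                          alpha = a_ep, beta = beta,
                          skip_frozen = as.list(all_frozen))
      ep_loss <- ep_loss + out$loss * length(idx)
      if (!is.finite(out$loss))
        stop("non-finite loss at epoch ", ep,
             " (recon=", signif(out$recon, 4), ", kl=", signif(out$kl, 4),
             ", mmd=", signif(out$mmd, 4), ")")
      step <- step + 1L
      for (nm in names(out$grads)) {
        g <- out$grads[[nm]]
        fz <- frozen[[nm]]
        if (any(fz)) g[fz] <- 0
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    history[ep] <- ep_loss / N
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, epochs,
                                 history[ep]))
  }
  list(par = par, history = history)
}

# Likelihood-appropriate encoder input and reconstruction target for a
# dataset: mse trains on the lognorm layer; nb/zinb target raw counts while
# the encoder sees log1p(counts).
model_input <- function(ds, likelihood) {
  if (likelihood == "mse") {
    X <- unname(as.matrix(get_layer(ds, "lognorm")))
    list(X = X, target = X, lib = rep(1, nrow(X)))
  } else {
    cts <- unname(as.matrix(get_layer(ds, "counts")))
    list(X = log1p(cts), target = cts, lib = closed_form_library(cts))
  }
}
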