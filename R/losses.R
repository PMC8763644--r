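#' Closed-form Gaussian KL divergence to the standard normal prior
#'
#' KL( N(mu, diag(sigma^2)) || N(0, I) ) with `logvar = log sigma^2`, the
#' regularizer of the variational objective. For a single latent dimension
#' with mu = 1, sigma = 1 the divergence is 0.5.
#'
#' @param mu matrix (cells x k) or vector of posterior means.
#' @param logvar matrix or vector of posterior log-variances, same shape.
#' @return per-cell KL (vector; scalar input gives a scalar).
#' @export
gaussian_kl <- function(mu, logvar) {
  if (is.null(dim(mu))) return(0.5 * sum(mu^2 + exp(logvar) - 1 - logvar))
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' Multi-scale RBF maximum mean discrepancy (biased V-statistic)
#'
#' `mean(k(X,X)) + mean(k(X',X')) - 2 mean(k(X,X'))` with the multi-scale
#' radial basis kernel `k(x,x') = sum_i exp(-gamma_i ||x - x'||^2)`. Zero when
#' the two samples are identical point sets; non-negative up to floating error.
#'
#' @param x,xp numeric matrices (rows = observations) or vectors (treated as
#'   one-dimensional observations).
#' @param gammas positive kernel scales.
#' @return scalar MMD estimate.
#' @export
mmd_pairwise <- function(x, xp, gammas = c(1e-2, 1e-1, 1, 10, 100)) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(xp))) xp <- matrix(xp, ncol = 1)
  if (nrow(x) == 0 || nrow(xp) == 0) stop("both samples must be non-empty")
  if (length(gammas) == 0) stop("`gammas` must be non-empty")
  ksum <- function(a, b) {
    d2 <- sqdist(a, b)
    k <- 0
    for (g in gammas) k <- k + exp(-g * d2)
    mean(k)
  }
  ksum(x, x) + ksum(xp, xp) - 2 * ksum(x, xp)
}

# pairwise squared Euclidean distances, rows of a vs rows of b
sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# MMD over all unordered study pairs on rows of `h` grouped by `sidx`,
# with gradient w.r.t. the rows of `h`. Groups with < 2 rows are skipped.
mmd_groups <- function(h, sidx, gammas, want_grad = TRUE) {
  groups <- split(seq_along(sidx), sidx)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  value <- 0
  grad <- if (want_grad) matrix(0, nrow(h), ncol(h)) else NULL
  gn <- names(groups)
  if (length(groups) >= 2) {
    wk <- function(d2) {        # kernel and gamma-weighted kernel
      k <- 0; w <- 0
      for (g in gammas) { e <- exp(-g * d2); k <- k + e; w <- w + g * e }
      list(k = k, w = w)
    }
    for (a in seq_along(groups)[-length(groups)]) for (b in (a + 1):length(groups)) {
      ia <- groups[[a]]; ib <- groups[[b]]
      Xa <- h[ia, , drop = FALSE]; Xb <- h[ib, , drop = FALSE]
      na <- nrow(Xa); nb <- nrow(Xb)
      aa <- wk(sqdist(Xa, Xa)); bb <- wk(sqdist(Xb, Xb)); ab <- wk(sqdist(Xa, Xb))
      value <- value + mean(aa$k) + mean(bb$k) - 2 * mean(ab$k)
      if (want_grad) {
        grad[ia, ] <- grad[ia, ] -
          (4 / na^2) * (rowSums(aa$w) * Xa - aa$w %*% Xa) +
          (4 / (na * nb)) * (rowSums(ab$w) * Xa - ab$w %*% Xb)
        grad[ib, ] <- grad[ib, ] -
          (4 / nb^2) * (rowSums(bb$w) * Xb - bb$w %*% Xb) +
          (4 / (na * nb)) * (colSums(ab$w) * Xb - t(ab$w) %*% Xa)
      }
    }
  }
  list(value = value, grad = grad, n_groups = length(groups))
}

#' Per-cell library size in closed form
#'
#' The scaling factor of the count likelihood is the total count of each cell
#' (no library encoder is used; the library is observed, not inferred).
#'
#' @param counts cells x genes count matrix (dense or sparse).
#' @return numeric vector of per-cell totals.
#' @export
closed_form_library <- function(counts) {
  L <- if (inherits(counts, "Matrix")) Matrix::rowSums(counts) else
    rowSums(counts)
  if (any(L == 0))
    stop("cells with zero total count at indices: ",
         paste(utils::head(which(L == 0), 10), collapse = ", "))
  as.numeric(L)
}

#' Zero-inflated negative binomial log mass function
#'
#' `P(0) = pi + (1 - pi) (S / (S + L g))^S` and for y > 0
#' `P(y) = (1 - pi) * Gamma(y + S) / (Gamma(y + 1) Gamma(S)) *
#'  (S / (S + L g))^S * (L g / (S + L g))^y`, where `g` is the decoded mean
#' proportion, `pi` the dropout probability, `S` the gene inverse dispersion
#' and `L` the cell library size (so the NB mean is `L g`). Computed in
#' log-space with log-gamma. `dropout = 0` gives the plain negative binomial.
#'
#' @param x non-negative integer counts (vectorized).
#' @param mean_prop decoded mean proportion `g` (> 0).
#' @param dropout dropout probability `pi` in \[0, 1\].
#' @param dispersion inverse dispersion `S` (> 0).
#' @param library_size library size `L` (> 0).
#' @return log-probabilities; `-Inf` where `dropout == 1` and `x > 0`.
#' @export
zinb_logpmf <- function(x, mean_prop, dropout = 0, dispersion = 1,
                        library_size = 1) {
  n <- max(length(x), length(mean_prop), length(dropout), length(dispersion),
           length(library_size))
  x <- rep_len(x, n); g <- rep_len(mean_prop, n); pi <- rep_len(dropout, n)
  S <- rep_len(dispersion, n); L <- rep_len(library_size, n)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("x must contain non-negative integers")
  m <- L * g
  lognb0 <- S * (log(S) - log(S + m))
  out <- numeric(n)
  zero <- x == 0
  if (any(zero)) {
    # log(pi + (1-pi) exp(lognb0)), stable in log space
    a <- ifelse(pi[zero] > 0, log(pi[zero]), -Inf)
    b <- log1p(-pi[zero]) + lognb0[zero]
    mx <- pmax(a, b)
    out[zero] <- mx + log(exp(a - mx) + exp(b - mx))
    out[zero][pi[zero] == 1] <- 0
  }
  if (any(!zero)) {
    i <- !zero
    out[i] <- ifelse(pi[i] >= 1, -Inf,
                     log1p(-pi[i]) + lgamma(x[i] + S[i]) - lgamma(x[i] + 1) -
                       lgamma(S[i]) + S[i] * (log(S[i]) - log(S[i] + m[i])) +
                       x[i] * (log(m[i]) - log(S[i] + m[i])))
  }
  out
}

# elementwise ZINB log-likelihood of a count matrix plus derivatives w.r.t.
# mean m = L*g, dropout pi, and inverse dispersion S (matrices / recycled).
zinb_ll_grad <- function(Y, m, pi, S) {
  iszero <- Y == 0
  r <- S
  lognb0 <- r * (log(r) - log(r + m))
  ll <- dm <- dpi <- dS <- array(0, dim(Y))
  if (any(iszero)) {
    A <- exp(lognb0[iszero])
    p0 <- pi[iszero] + (1 - pi[iszero]) * A
    ll[iszero] <- log(p0)
    dm[iszero] <- -(1 - pi[iszero]) * A * r[iszero] / (r[iszero] + m[iszero]) / p0
    dpi[iszero] <- (1 - A) / p0
    dS[iszero] <- (1 - pi[iszero]) * A *
      (log(r[iszero] / (r[iszero] + m[iszero])) +
         m[iszero] / (r[iszero] + m[iszero])) / p0
  }
  if (any(!iszero)) {
    i <- !iszero
    y <- Y[i]; mm <- m[i]; pp <- pi[i]; rr <- r[i]
    ll[i] <- log1p(-pp) + lgamma(y + rr) - lgamma(y + 1) - lgamma(rr) +
      rr * (log(rr) - log(rr + mm)) + y * (log(mm) - log(rr + mm))
    dm[i] <- y / mm - (y + rr) / (rr + mm)
    dpi[i] <- -1 / (1 - pp)
    dS[i] <- digamma(y + rr) - digamma(rr) + log(rr / (rr + mm)) +
      1 - (rr + y) / (rr + mm)
  }
  list(ll = ll, dm = dm, dpi = dpi, dS = dS)
}
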