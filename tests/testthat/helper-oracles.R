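# Independent brute-force oracles (explicit loops; no shared code with the
# package implementations they check).

oracle_silhouette_mean <- function(coords, labels, subset = NULL) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (lab in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == lab]))
    s[i] <- (b - a) / max(a, b)
  }
  if (is.null(subset)) mean(s) else mean(s[subset])
}

oracle_ebm <- function(coords, batch, k = 15, n_draws = 100, seed = 1) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  nb <- length(unique(batch))
  set.seed(seed)
  cells <- sample.int(n, n_draws, replace = n_draws > n)
  vals <- numeric(length(cells))
  for (j in seq_along(cells)) {
    i <- cells[j]
    ord <- order(d[i, -i])
    neigh <- (seq_len(n)[-i])[ord[1:k]]
    e <- 0
    for (b in unique(batch)) {
      p <- sum(batch[neigh] == b) / k
      if (p > 0) e <- e - p * log(p, base = nb)
    }
    vals[j] <- e
  }
  mean(vals)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    e <- 0
    for (v in unique(x)) {
      p <- sum(x == v) / n
      e <- e - p * log(p)
    }
    e
  }
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    pxy <- sum(a == u & b == v) / n
    if (pxy > 0)
      mi <- mi + pxy * log(pxy / ((sum(a == u) / n) * (sum(b == v) / n)))
  }
  if (ent(a) == 0 || ent(b) == 0) return(0)
  mi / mean(c(ent(a), ent(b)))
}

# pair-counting adjusted Rand index over all C(n,2) pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  np <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / np
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - exp_idx) / (max_idx - exp_idx)
}

oracle_knn_accuracy <- function(coords, labels, k = 15) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  per_cell <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    neigh <- (seq_len(n)[-i])[ord[1:k]]
    per_cell[i] <- mean(labels[neigh] == labels[i])
  }
  type_means <- c()
  for (lab in unique(labels))
    type_means <- c(type_means, mean(per_cell[labels == lab]))
  mean(type_means)
}

# largest-connected-component fraction of a symmetric kNN graph, by BFS
oracle_lcc_fraction <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    neigh <- (seq_len(n)[-i])[ord[1:min(k, n - 1)]]
    adj[i, neigh] <- TRUE
    adj[neigh, i] <- TRUE
  }
  seen <- rep(FALSE, n)
  best <- 0
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; size <- 0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1
      nxt <- which(adj[v, ] & !seen)
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    best <- max(best, size)
  }
  best / n
}

# weighted kNN label transfer computed verbatim, loops only
oracle_knn_transfer <- function(ref_coords, ref_labels, q_coords, k) {
  labs <- unique(ref_labels)
  nq <- nrow(q_coords)
  probs <- matrix(0, nq, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(nq)) {
    d <- sqrt(colSums((t(ref_coords) - q_coords[i, ])^2))
    ord <- order(d)[1:k]
    dk <- d[ord]
    sdv <- sqrt(sum(dk^2) / k)
    w <- if (sdv == 0) rep(1, k) else exp(-dk / (2 / sdv)^2)
    for (j in seq_len(k))
      probs[i, ref_labels[ord[j]]] <- probs[i, ref_labels[ord[j]]] + w[j]
    probs[i, ] <- probs[i, ] / sum(probs[i, ])
  }
  probs
}

# acceptance benchmark cache: criteria on the end-to-end hold-out experiment
# share one trained reference model across test blocks
.bench_cache <- new.env(parent = emptyenv())

acceptance_bench <- function() {
  if (is.null(.bench_cache$full)) {
    .bench_cache$full <- holdout_benchmark(seed = 1)
    .bench_cache$zerofill <- holdout_benchmark(
      seed = 1, drop_gene_fraction = 0.1,
      reference = .bench_cache$full$reference_model)
  }
  .bench_cache
}
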