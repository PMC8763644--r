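# Weighted kNN label transfer with uncertainty-based rejection.

#' Transfer reference labels to query cells with a weighted kNN classifier
#'
#' For each query cell the `k_neighbors` Euclidean nearest reference cells are
#' found in latent space. With `sd = sqrt(sum(dist^2) / k)` over those
#' neighbours, each distance receives the kernel weight
#' `D = exp(-dist / (2/sd)^2)` (the kernel divides the raw distance — not its
#' square — by `(2/sd)^2`; weights are computed with a log-space shift that
#' cancels exactly in the normalization). Label probabilities are the
#' normalized label-wise weight sums, the uncertainty is
#' `u = 1 - max(prob)`, and cells with `u > 0.5` (strictly) are reported as
#' `"unknown"`.
#'
#' Degenerate case: if all neighbour distances are zero, weights are uniform.
#' Ties between labels at equal probability resolve to the label seen first
#' in the reference, deterministically.
#'
#' @param ref a `latent_embedding` whose `cell_meta$cell_type` labels every
#'   cell.
#' @param query a `latent_embedding` of query cells.
#' @param k_neighbors number of neighbours (default 50).
#' @return an `annotation_result`: data frame with `cell_id`, `predicted`,
#'   `uncertainty`, plus attribute `label_probs` (cells x labels matrix).
#' @export
knn_transfer <- function(ref, query, k_neighbors = 50) {
  stopifnot(inherits(ref, "latent_embedding"),
            inherits(query, "latent_embedding"))
  labels <- ref$cell_meta$cell_type
  if (is.null(labels) || anyNA(labels))
    stop("reference embedding must carry cell_type labels for every cell")
  if (k_neighbors < 1) stop("k_neighbors must be positive")
  if (k_neighbors > nrow(ref$coords))
    stop("k_neighbors exceeds the reference size")
  lab_levels <- unique(labels)
  nn <- knn_search(ref$coords, query$coords, k = k_neighbors)
  nq <- nrow(query$coords)
  probs <- matrix(0, nq, length(lab_levels),
                  dimnames = list(query$cell_meta$cell_id, lab_levels))
  sdv <- sqrt(rowMeans(nn$dist^2))
  for (i in seq_len(nq)) {
    d <- nn$dist[i, ]
    if (sdv[i] == 0) {
      w <- rep(1 / k_neighbors, k_neighbors)
    } else {
      expo <- -d / (2 / sdv[i])^2
      w <- exp(expo - max(expo))      # shift cancels in the normalization
      w <- w / sum(w)
    }
    li <- match(labels[nn$index[i, ]], lab_levels)
    pr <- numeric(length(lab_levels))
    agg <- rowsum(w, li)
    pr[as.integer(rownames(agg))] <- agg[, 1]
    probs[i, ] <- pr
  }
  best <- apply(probs, 1, which.max)    # first max = registry-order tie-break
  u <- 1 - probs[cbind(seq_len(nq), best)]
  predicted <- ifelse(u > 0.5, "unknown", lab_levels[best])
  res <- data.frame(cell_id = query$cell_meta$cell_id,
                    predicted = predicted,
                    uncertainty = u,
                    stringsAsFactors = FALSE)
  attr(res, "label_probs") <- probs
  class(res) <- c("annotation_result", "data.frame")
  res
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("annotation_result: ", nrow(x), " cells, ",
      sum(x$predicted == "unknown"), " unknown\n", sep = "")
  NextMethod()
}
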