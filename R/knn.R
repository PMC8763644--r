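# Exact k-nearest-neighbour search by chunked brute force. Adequate for the
# atlas sizes this package targets (tens of thousands of cells); distances are
# Euclidean in the latent space.

#' Exact k nearest neighbours
#'
#' @param ref reference matrix (rows = points searched).
#' @param query query matrix (defaults to `ref`; then each point's own row is
#'   excluded from its neighbours).
#' @param k number of neighbours.
#' @param chunk query rows per block (memory/speed trade-off).
#' @return list with `index` (n_query x k matrix of reference row indices,
#'   nearest first) and `dist` (matching Euclidean distances).
#' @export
knn_search <- function(ref, query = NULL, k, chunk = 1024L) {
  ref <- as.matrix(ref)
  self <- is.null(query)
  query <- if (self) ref else as.matrix(query)
  if (k < 1) stop("k must be positive")
  if (k > nrow(ref) - self)
    stop("k (", k, ") exceeds available reference points (",
         nrow(ref) - self, ")")
  n <- nrow(query)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  rn2 <- rowSums(ref^2)
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1, n)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    if (self) d2[cbind(seq_along(rows), rows)] <- Inf
    for (i in seq_along(rows)) {
      ord <- order(d2[i, ])[seq_len(k)]
      idx[rows[i], ] <- ord
      dst[rows[i], ] <- sqrt(pmax(d2[i, ord], 0))
    }
  }
  list(index = idx, dist = dst)
}

# symmetric kNN graph (union of directed edges) as an igraph object
knn_graph <- function(coords, k) {
  nn <- knn_search(coords, k = min(k, nrow(coords) - 1))
  edges <- cbind(rep(seq_len(nrow(coords)), ncol(nn$index)),
                 as.vector(nn$index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(coords) - igraph::vcount(g)))
  igraph::simplify(g)
}
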