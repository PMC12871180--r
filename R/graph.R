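#' Spatial adjacency graph over cell centroids
#'
#' Edges come from the Delaunay triangulation of the centroids. Spuriously
#' long hull-adjacent edges (longer than the 99th percentile of Delaunay
#' edge lengths) are pruned first (disable with `prune_long = FALSE`). If
#' triangulation fails (degenerate or collinear input) or the pruned graph
#' is disconnected, symmetric k-nearest-neighbor edges are added, doubling
#' `k` until the graph is connected. Weights are binary adjacency,
#' row-standardized.
#'
#' @param centroids `n x 2` matrix of `(u, v)` coordinates, n >= 3, no
#'   duplicate points.
#' @param k_fallback starting k for the kNN fallback (default 6).
#' @param prune_long prune Delaunay edges above the 99th length percentile.
#' @return object of class `spatial_graph`: list with `n`, `edges`
#'   (m x 2 matrix, i < j), `W` (sparse row-standardized weight matrix) and
#'   `binary` (sparse symmetric 0/1 adjacency).
#' @export
build_graph <- function(centroids, k_fallback = 6, prune_long = TRUE) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 3) stop("need at least 3 centroids", call. = FALSE)
  if (anyDuplicated(centroids)) stop("duplicate centroids", call. = FALSE)
  edges <- tryCatch({
    d <- deldir::deldir(centroids[, 1], centroids[, 2],
                        suppressMsge = TRUE)
    cbind(pmin(d$delsgs$ind1, d$delsgs$ind2),
          pmax(d$delsgs$ind1, d$delsgs$ind2))
  }, error = function(e) NULL)
  if (!is.null(edges) && nrow(edges) > 0 && prune_long) {
    len <- sqrt(rowSums((centroids[edges[, 1], , drop = FALSE] -
                         centroids[edges[, 2], , drop = FALSE])^2))
    # inverted-ECDF percentile so small edge sets are never pruned
    edges <- edges[len <= quantile(len, 0.99, type = 1), , drop = FALSE]
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  k <- min(k_fallback, n - 1)
  repeat {
    if (nrow(edges) > 0 && is_connected_edges(n, edges)) break
    nn <- FNN::get.knn(centroids, k = k)$nn.index
    knn_edges <- cbind(pmin(rep(seq_len(n), k), as.vector(nn)),
                       pmax(rep(seq_len(n), k), as.vector(nn)))
    edges <- unique(rbind(edges, knn_edges))
    if (is_connected_edges(n, edges)) break
    if (k >= n - 1)
      stop("could not connect spatial graph", call. = FALSE)
    k <- min(2 * k, n - 1)
  }
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  W <- A / Matrix::rowSums(A)
  structure(list(n = n, edges = edges, W = methods::as(W, "CsparseMatrix"),
                 binary = A),
            class = "spatial_graph")
}

#' Build a spatial graph from an explicit edge list
#'
#' Constructs the same `spatial_graph` structure as [build_graph()] from a
#' hand-specified undirected edge list (binary adjacency, row-standardized
#' weights). Useful for closed-form checks on small graphs.
#'
#' @param n number of nodes.
#' @param edges `m x 2` matrix of undirected edges (no self-loops).
#' @return a `spatial_graph`.
#' @export
graph_from_edges <- function(n, edges) {
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  if (nrow(edges) == 0) stop("no edges", call. = FALSE)
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) stop("isolated node", call. = FALSE)
  W <- A / rs
  structure(list(n = n, edges = edges, W = methods::as(W, "CsparseMatrix"),
                 binary = A),
            class = "spatial_graph")
}

#' @noRd
is_connected_edges <- function(n, edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::is_connected(g)
}
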