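# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Moran's I by explicit double loop over a dense weight matrix.
brute_morans <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  S0 <- 0; num <- 0
  for (i in 1:n) for (j in 1:n) {
    S0 <- S0 + W[i, j]
    num <- num + W[i, j] * z[i] * z[j]
  }
  (n / S0) * num / sum(z^2)
}

# Geary's C by explicit double loop.
brute_gearys <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  S0 <- 0; num <- 0
  for (i in 1:n) for (j in 1:n) {
    S0 <- S0 + W[i, j]
    num <- num + W[i, j] * (values[i] - values[j])^2
  }
  ((n - 1) / (2 * S0)) * num / sum(z^2)
}

# Gini by explicit pairwise differences.
brute_gini <- function(v) {
  n <- length(v)
  if (mean(v) == 0) return(0)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + abs(v[i] - v[j])
  s / (2 * n^2 * mean(v))
}

# 8-connected component count via igraph on the pixel adjacency graph.
igraph_blob_count <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2])
  edges <- c()
  for (a in seq_len(nrow(idx))) for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- paste(idx[a, 1] + dr, idx[a, 2] + dc)
    b <- match(nb, key)
    if (!is.na(b)) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(nrow(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Explicit weighted least squares solve of the normal equations.
brute_wls <- function(X, W, y) {
  solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y
}

# Hand-rolled breadth-first search connectivity check (independent of the
# igraph machinery build_graph uses internally).
is_connected_oracle <- function(g) {
  adj <- vector("list", g$n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(g$n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  all(seen)
}

# The 4-cycle graph (nodes in cycle order, no diagonals).
square_graph <- function() {
  graph_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
}

# Small random point cloud with a fixed seed.
random_coords <- function(n, seed, scale = 100) {
  set.seed(seed)
  cbind(runif(n, 0, scale), runif(n, 0, scale))
}
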