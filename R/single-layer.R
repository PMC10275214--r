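# Weighted single-layer topology: shortest-path global efficiency and
# geometric-mean (Onnela-style) clustering coefficient, per density, with AUC.

# igraph from a nonnegative weight matrix, with edge lengths 1/w.
length_graph <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Weighted shortest-path length matrix
#'
#' Connection lengths are inversely proportional to connection weights
#' (length = 1/w); the distance between two nodes is the total length along
#' the shortest weighted path (Dijkstra), `Inf` for disconnected pairs.
#'
#' @param g nonnegative weight matrix or `layer_graph`.
#' @return n x n symmetric matrix of path lengths with zero diagonal.
#' @export
path_length_matrix <- function(g) {
  m <- as_weight_matrix(g)
  gr <- length_graph(m)
  w <- if (igraph::ecount(gr) > 0) igraph::E(gr)$length else numeric(0)
  d <- igraph::distances(gr, weights = w, algorithm = "dijkstra")
  dimnames(d) <- dimnames(m)
  d
}

#' Weighted global efficiency
#'
#' Nodal global efficiency is the average inverse distance from a node to all
#' other nodes, with disconnected pairs contributing zero; the network value
#' is the mean over nodes. An integration measure: it grows as the shortest
#' paths between nodes become shorter.
#'
#' @param g nonnegative weight matrix or `layer_graph`.
#' @return object of class `nodal_measure`: list with per-node `values` and
#'   the `network` mean.
#' @export
global_efficiency <- function(g) {
  m <- as_weight_matrix(g)
  n <- nrow(m)
  if (n < 2) stop("global efficiency undefined for n < 2")
  d <- path_length_matrix(m)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0  # diagonal zeros and disconnected pairs
  values <- rowSums(inv) / (n - 1)
  names(values) <- rownames(m)
  structure(list(values = values, network = mean(values)),
            class = "nodal_measure")
}

#' Weighted clustering coefficient
#'
#' The weighted triangle intensity around node i is
#' `t_i = 1/2 * sum_{j,h} (w_ij w_jh w_hi)^(1/3)` (geometric mean of each
#' triangle's edge weights); the nodal coefficient is `2 t_i / (k_i (k_i-1))`
#' where the degree `k_i` counts nonzero edges regardless of weight. Nodes
#' with degree <= 1 have coefficient 0. A segregation measure. The network
#' value is the mean over all nodes.
#'
#' @param g nonnegative weight matrix or `layer_graph`.
#' @return a `nodal_measure` (see [global_efficiency()]).
#' @export
clustering_coefficient <- function(g) {
  m <- as_weight_matrix(g)
  n <- nrow(m)
  w3 <- m^(1/3)
  t_i <- diag(w3 %*% w3 %*% w3) / 2
  k <- rowSums(m > 0)
  denom <- k * (k - 1)
  values <- ifelse(denom > 0, 2 * t_i / denom, 0)
  names(values) <- rownames(m)
  structure(list(values = values, network = mean(values)),
            class = "nodal_measure")
}

#' @export
print.nodal_measure <- function(x, ...) {
  cat("<nodal_measure> network value", format(x$network), "over",
      length(x$values), "nodes\n")
  invisible(x)
}

#' Density sweep of the single-layer measures
#'
#' Thresholds the layer at each grid density (retaining signed/absolute
#' weights), computes network global efficiency and clustering coefficient at
#' each density, and integrates each curve over density (AUC).
#'
#' @param g nonnegative weight matrix or `layer_graph` (full, unthresholded).
#' @param densities density grid (default [default_density_grid()]).
#' @return list with elements `ge` and `cc`, each a list with `densities`,
#'   `values` and `auc`.
#' @export
sweep_single_layer <- function(g, densities = default_density_grid()) {
  m <- as_weight_matrix(g)
  if (all(m == 0)) stop("cannot sweep an all-zero layer")
  ge <- cc <- numeric(length(densities))
  for (i in seq_along(densities)) {
    mt <- suppressWarnings(proportional_threshold(m, densities[i]))
    ge[i] <- global_efficiency(mt)$network
    cc[i] <- clustering_coefficient(mt)$network
  }
  list(ge = list(densities = densities, values = ge,
                 auc = measure_auc(densities, ge)),
       cc = list(densities = densities, values = cc,
                 auc = measure_auc(densities, cc)))
}
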