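# Multilayer (all-pairs uniformly coupled) two-layer measures: interlayer
# coupling specification, opposite-layer efficiency/clustering via the
# augmented (n+1)-node network, and the multilayer differences ML-Ge(sigma)
# and ML-CC(sigma), swept over sigma and density.

#' Uniform interlayer coupling specification
#'
#' In the multilayer construction every node in one layer is connected to
#' every node in the other layer with a single uniform weight
#' `w_inter = sigma * max(w_max_alpha, w_max_beta)`, a fraction sigma of the
#' subject's strongest absolute intralayer connection. This anchors the
#' coupling to each subject's own connectivity scale.
#'
#' @param pos,neg the two layers (matrices or `layer_graph`s).
#' @param sigma coupling fraction in (0, 1].
#' @return object of class `interlayer_spec`: list with `sigma`,
#'   `w_max_alpha`, `w_max_beta` and `w_inter`.
#' @export
interlayer_weight <- function(pos, neg, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0 || sigma > 1)
    stop("`sigma` must be a single fraction in (0, 1]")
  w_a <- max(abs(as_weight_matrix(pos)))
  w_b <- max(abs(as_weight_matrix(neg)))
  if (w_a == 0 && w_b == 0)
    stop("both layers are empty; interlayer weight undefined")
  structure(list(sigma = sigma, w_max_alpha = w_a, w_max_beta = w_b,
                 w_inter = sigma * max(w_a, w_b)),
            class = "interlayer_spec")
}

inter_weight_value <- function(spec) {
  if (inherits(spec, "interlayer_spec")) spec$w_inter
  else if (is.numeric(spec) && length(spec) == 1 && spec > 0) spec
  else stop("`spec` must be an interlayer_spec or a positive scalar weight")
}

#' Same-layer nodal global efficiency
#'
#' The efficiency of each node within its own (thresholded) layer; identical
#' to the nodal values of [global_efficiency()] and independent of the
#' interlayer coupling.
#'
#' @param g thresholded layer (matrix or `layer_graph`).
#' @return per-node numeric vector.
#' @export
same_layer_efficiency <- function(g) {
  global_efficiency(g)$values
}

#' Same-layer nodal clustering coefficient
#'
#' Nodal values of [clustering_coefficient()] within the node's own layer.
#'
#' @param g thresholded layer (matrix or `layer_graph`).
#' @return per-node numeric vector.
#' @export
same_layer_clustering <- function(g) {
  clustering_coefficient(g)$values
}

#' Opposite-layer efficiency of a node
#'
#' A node i from one layer is carried, without its intralayer edges, into an
#' augmented network of size n + 1 containing all nodes and connections of
#' the opposite layer, to which i is connected by the uniform interlayer
#' weight. The opposite-layer efficiency is the average inverse shortest-path
#' distance from i to the n opposite-layer nodes (lengths = 1/weight).
#'
#' Because the coupling is uniform and identical for all nodes of the source
#' layer, the value does not depend on which node is carried over; it is a
#' per-layer scalar. The direct interlayer edge bounds every distance by
#' `1/w_inter`, so the value is always at least `w_inter`.
#'
#' @param other the opposite layer (matrix or `layer_graph`).
#' @param spec an `interlayer_spec`, or the interlayer weight itself.
#' @return the opposite-layer efficiency (scalar).
#' @export
opposite_layer_efficiency <- function(other, spec) {
  w_inter <- inter_weight_value(spec)
  m <- as_weight_matrix(other)
  n <- nrow(m)
  aug <- rbind(cbind(m, rep(w_inter, n)), c(rep(w_inter, n), 0))
  gr <- length_graph(aug)
  d <- igraph::distances(gr, v = n + 1, weights = igraph::E(gr)$length,
                         algorithm = "dijkstra")[1, seq_len(n)]
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  sum(inv) / n
}

#' Opposite-layer clustering of a node
#'
#' In the same augmented (n+1)-node network as
#' [opposite_layer_efficiency()], the carried node i forms a triangle with
#' every edge (j, h) of the opposite layer via its two interlayer wings:
#' `t_i = 1/2 * sum_{j,h} (w_inter * w_jh * w_inter)^(1/3)`. Its degree is n
#' (one interlayer edge per opposite node), so
#' `OppL-CC_i = 2 t_i / (n (n - 1))`. For fixed opposite layer the value
#' scales as `w_inter^(2/3)`. A layer without edges yields 0.
#'
#' @inheritParams opposite_layer_efficiency
#' @return the opposite-layer clustering coefficient (scalar).
#' @export
opposite_layer_clustering <- function(other, spec) {
  w_inter <- inter_weight_value(spec)
  m <- as_weight_matrix(other)
  n <- nrow(m)
  if (n < 2) stop("opposite layer needs at least 2 nodes")
  up <- m[upper.tri(m)]
  t_i <- sum((w_inter^2 * up[up > 0])^(1/3))
  2 * t_i / (n * (n - 1))
}

# Shared skeleton for the two multilayer difference measures.
multilayer_difference <- function(pos, neg, sigma, same_fun, opp_fun) {
  p <- as_weight_matrix(pos)
  q <- as_weight_matrix(neg)
  if (nrow(p) != nrow(q)) stop("layer size mismatch")
  pos_empty <- all(p == 0)
  neg_empty <- all(q == 0)
  spec <- interlayer_weight(p, q, sigma)
  # Empty-opposite-layer convention: the opposite-layer term is 0 (flagged)
  # so cohort sweeps remain total even when one layer has no edges.
  opp_alpha <- if (neg_empty) 0 else opp_fun(q, spec)
  opp_beta <- if (pos_empty) 0 else opp_fun(p, spec)
  same_alpha <- same_fun(p)
  same_beta <- same_fun(q)
  values_alpha <- opp_alpha - same_alpha
  values_beta <- opp_beta - same_beta
  structure(list(
    sigma = sigma, spec = spec,
    opp_alpha = opp_alpha, opp_beta = opp_beta,
    same_alpha = same_alpha, same_beta = same_beta,
    values_alpha = values_alpha, values_beta = values_beta,
    network = mean(c(values_alpha, values_beta)),
    flags = c(pos_empty = pos_empty, neg_empty = neg_empty)
  ), class = "multilayer_nodal")
}

#' Multilayer global efficiency
#'
#' For each node replica, the difference between its opposite-layer and
#' same-layer efficiency: `ML-Ge_i(sigma) = OppL-Ge_i(sigma) - SameL-Ge_i`,
#' computed for replicas of both layers. The network value is the mean over
#' all 2n replicas, which makes the measure symmetric in the layer labels.
#' Positive values mean a node reaches the opposite layer more efficiently
#' than its own; the measure is nondecreasing in sigma.
#'
#' @param pos,neg the two thresholded layers.
#' @param sigma interlayer coupling fraction in (0, 1].
#' @return object of class `multilayer_nodal`: per-replica `values_alpha` /
#'   `values_beta`, the per-layer opposite terms, the `network` mean over all
#'   2n replicas, and empty-layer `flags`.
#' @export
multilayer_global_efficiency <- function(pos, neg, sigma) {
  multilayer_difference(pos, neg, sigma,
                        same_fun = same_layer_efficiency,
                        opp_fun = opposite_layer_efficiency)
}

#' Multilayer clustering coefficient
#'
#' `ML-CC_i(sigma) = OppL-CC_i(sigma) - SameL-CC_i` per node replica, with
#' the network value the mean over all 2n replicas. Compares the clustering
#' (segregation) a node attains through the opposite layer with that in its
#' own layer.
#'
#' @inheritParams multilayer_global_efficiency
#' @return a `multilayer_nodal` (see [multilayer_global_efficiency()]).
#' @export
multilayer_clustering <- function(pos, neg, sigma) {
  multilayer_difference(pos, neg, sigma,
                        same_fun = same_layer_clustering,
                        opp_fun = opposite_layer_clustering)
}

#' @export
print.multilayer_nodal <- function(x, ...) {
  cat("<multilayer_nodal> sigma", format(x$sigma),
      "network value", format(x$network), "\n")
  invisible(x)
}

#' Density-and-sigma sweep of the multilayer measures
#'
#' For each sigma on the grid: threshold both layers at each density, compute
#' the network multilayer global efficiency and clustering, and integrate
#' each curve over density. Returns tidy AUC rows, one per (measure, sigma).
#'
#' @param x a `signed_connectome` (or signed matrix).
#' @param densities density grid.
#' @param sigmas interlayer coupling grid (default [default_sigma_grid()]).
#' @return data.frame with columns `measure` (`"ML-Ge"`/`"ML-CC"`), `sigma`
#'   and `value` (the density AUC).
#' @export
multilayer_sweep <- function(x, densities = default_density_grid(),
                             sigmas = default_sigma_grid()) {
  layers <- split_signed_layers(x)
  nd <- length(densities)
  ns <- length(sigmas)
  ge <- cc <- matrix(NA_real_, nd, ns)
  for (i in seq_len(nd)) {
    p <- suppressWarnings(proportional_threshold(layers$positive$weights, densities[i]))
    q <- suppressWarnings(proportional_threshold(layers$negative$weights, densities[i]))
    # same-layer terms are sigma-free; hoist them out of the sigma loop
    pos_empty <- all(p == 0); neg_empty <- all(q == 0)
    same_ge <- mean(c(same_layer_efficiency(p), same_layer_efficiency(q)))
    same_cc <- mean(c(same_layer_clustering(p), same_layer_clustering(q)))
    for (j in seq_len(ns)) {
      spec <- interlayer_weight(p, q, sigmas[j])
      oge_a <- if (neg_empty) 0 else opposite_layer_efficiency(q, spec)
      oge_b <- if (pos_empty) 0 else opposite_layer_efficiency(p, spec)
      occ_a <- if (neg_empty) 0 else opposite_layer_clustering(q, spec)
      occ_b <- if (pos_empty) 0 else opposite_layer_clustering(p, spec)
      ge[i, j] <- (oge_a + oge_b) / 2 - same_ge
      cc[i, j] <- (occ_a + occ_b) / 2 - same_cc
    }
  }
  data.frame(
    measure = rep(c("ML-Ge", "ML-CC"), each = ns),
    sigma = c(sigmas, sigmas),
    value = c(vapply(seq_len(ns), function(j) measure_auc(densities, ge[, j]), numeric(1)),
              vapply(seq_len(ns), function(j) measure_auc(densities, cc[, j]), numeric(1))),
    stringsAsFactors = FALSE
  )
}
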