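# Multiplex (replica-coupled) two-layer measures: supra-adjacency
# construction, multiplex participation and multiplex clustering.

#' Build a replica-coupled multiplex network
#'
#' Combines the positive and negative layers (thresholded at a common
#' density) into a 2n x 2n supra-adjacency matrix with the intralayer
#' matrices on the block diagonal and identity replica couplings of weight 1
#' off the diagonal: a node in one layer is connected only to its own replica
#' in the other layer.
#'
#' @param pos,neg nonnegative weight matrices or `layer_graph`s of equal size
#'   and node order.
#' @return object of class `multiplex_network`: list with intralayer blocks
#'   `pos` and `neg`, the `supra` matrix, node count `n` and layer count
#'   `n_layers = 2`.
#' @export
build_multiplex <- function(pos, neg) {
  p <- as_weight_matrix(pos)
  q <- as_weight_matrix(neg)
  n <- nrow(p)
  if (nrow(q) != n) stop("layer size mismatch: ", n, " vs ", nrow(q))
  eye <- diag(n)
  supra <- rbind(cbind(p, eye), cbind(eye, q))
  structure(list(pos = p, neg = q, supra = supra, n = n, n_layers = 2L),
            class = "multiplex_network")
}

#' Multiplex participation coefficient
#'
#' Quantifies how evenly a node's intralayer strength is spread over the two
#' layers: `MP-Pt_i = (L/(L-1)) (1 - sum_a (s_ia / o_i)^2)` with L = 2
#' layers, `s_ia` the node's strength (sum of absolute intralayer weights) in
#' layer a and `o_i = sum_a s_ia` the overlapping strength. Ranges from 0
#' (all strength in one layer) to 1 (perfectly balanced); nodes with
#' `o_i = 0` are assigned 0. Replica couplings are structural and excluded
#' from the strengths.
#'
#' @param m a `multiplex_network` from [build_multiplex()].
#' @return object of class `multiplex_nodal`: list with per-node strengths
#'   `s_alpha`, `s_beta`, overlapping strength `o`, nodal `values` and the
#'   `network` mean.
#' @export
multiplex_participation <- function(m) {
  stopifnot(inherits(m, "multiplex_network"))
  s_a <- rowSums(m$pos)
  s_b <- rowSums(m$neg)
  o <- s_a + s_b
  values <- ifelse(o > 0,
                   2 * (1 - ((s_a / o)^2 + (s_b / o)^2)),
                   0)
  # guard against tiny negative round-off at perfectly concentrated nodes
  values <- pmin(pmax(values, 0), 1)
  structure(list(s_alpha = s_a, s_beta = s_b, o = o,
                 values = values, network = mean(values)),
            class = "multiplex_nodal")
}

#' Multiplex clustering coefficient
#'
#' Counts weighted triangles that use one edge from one layer and two edges
#' from the other: for node i,
#' `MP-CC_i = sum_a sum_{b != a} sum_{j != m} (w_ija w_jmb w_mia)^(1/3) /
#' ((M-1) sum_a k_ia (k_ia - 1))`
#' with M = 2 layers, ordered pairs (j, m) of distinct nodes different from
#' i, and `k_ia` the intralayer degree. Nodes with a zero denominator get 0.
#' For unit triangles in both layers the coefficient is 1.
#'
#' @param m a `multiplex_network`.
#' @return a `multiplex_nodal` (see [multiplex_participation()]) whose
#'   `values` are the nodal coefficients.
#' @export
multiplex_clustering <- function(m) {
  stopifnot(inherits(m, "multiplex_network"))
  a <- m$pos^(1/3)
  b <- m$neg^(1/3)
  # sum over ordered (j, m): one intralayer "wing" pair in layer a, the
  # closing edge in layer b -> diag(A B A); plus the layer-swapped term.
  num <- diag(a %*% b %*% a) + diag(b %*% a %*% b)
  k_a <- rowSums(m$pos > 0)
  k_b <- rowSums(m$neg > 0)
  den <- k_a * (k_a - 1) + k_b * (k_b - 1)  # (M - 1) = 1
  values <- ifelse(den > 0, num / den, 0)
  s_a <- rowSums(m$pos)
  s_b <- rowSums(m$neg)
  structure(list(s_alpha = s_a, s_beta = s_b, o = s_a + s_b,
                 values = values, network = mean(values)),
            class = "multiplex_nodal")
}

#' @export
print.multiplex_nodal <- function(x, ...) {
  cat("<multiplex_nodal> network value", format(x$network), "over",
      length(x$values), "nodes\n")
  invisible(x)
}

#' Density sweep of the multiplex measures
#'
#' Thresholds both layers at each grid density, builds the multiplex network
#' and computes the network multiplex participation and clustering
#' coefficients, each integrated over density (AUC).
#'
#' @param pos,neg full (unthresholded) layers.
#' @param densities density grid.
#' @return list with elements `pt` and `cc` (each `densities`, `values`,
#'   `auc`).
#' @export
sweep_multiplex <- function(pos, neg, densities = default_density_grid()) {
  p <- as_weight_matrix(pos)
  q <- as_weight_matrix(neg)
  pt <- cc <- numeric(length(densities))
  for (i in seq_along(densities)) {
    pt_p <- suppressWarnings(proportional_threshold(p, densities[i]))
    pt_q <- suppressWarnings(proportional_threshold(q, densities[i]))
    mx <- build_multiplex(pt_p, pt_q)
    pt[i] <- multiplex_participation(mx)$network
    cc[i] <- multiplex_clustering(mx)$network
  }
  list(pt = list(densities = densities, values = pt,
                 auc = measure_auc(densities, pt)),
       cc = list(densities = densities, values = cc,
                 auc = measure_auc(densities, cc)))
}
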