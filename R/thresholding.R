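# Layer splitting, sign-preserving proportional thresholding over a density
# grid, and AUC integration of measures over density.

#' Default density grid
#'
#' Proportional-thresholding grid from 6% to 33% of possible edges in steps
#' of 1%. Below ~6% a 21-node correlation network becomes largely
#' disconnected (fewer edges than nodes); 33% is a typical upper bound that
#' both the positive and the (sparser) negative layer can reach.
#'
#' @param density_min,density_max,density_step grid parameters as fractions.
#' @return numeric vector of densities.
#' @export
default_density_grid <- function(density_min = 0.06, density_max = 0.33,
                                 density_step = 0.01) {
  g <- seq(round(density_min * 100), round(density_max * 100),
           by = round(density_step * 100)) / 100
  if (length(g) < 2) stop("density grid needs at least 2 points")
  g
}

#' Default interlayer coupling grid
#'
#' Interlayer coupling fractions sigma from 0.05 to 1 in steps of 0.05.
#'
#' @param sigma_min,sigma_max,sigma_step grid parameters.
#' @return numeric vector of sigma values.
#' @export
default_sigma_grid <- function(sigma_min = 0.05, sigma_max = 1,
                               sigma_step = 0.05) {
  seq(round(sigma_min * 100), round(sigma_max * 100),
      by = round(sigma_step * 100)) / 100
}

#' Construct a single-layer graph
#'
#' A layer graph is one layer of a signed connectome: a nonnegative weighted
#' undirected graph. The negative layer stores the absolute values of the
#' negative weights (network measures are undefined for negative weights);
#' its provenance is recorded in `layer_id`.
#'
#' @param weights nonnegative symmetric matrix with zero diagonal.
#' @param layer_id `"positive"` or `"negative"`.
#' @param source identifier of the parent connectome.
#' @return object of class `layer_graph` with elements `layer_id`, `weights`,
#'   `source` and `empty` (TRUE when the layer has no edges).
#' @export
layer_graph <- function(weights, layer_id = c("positive", "negative"),
                        source = NA_character_) {
  layer_id <- match.arg(layer_id)
  if (!is.matrix(weights) || !is.numeric(weights) || nrow(weights) != ncol(weights))
    stop("`weights` must be a square numeric matrix")
  if (any(weights < 0)) stop("layer weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-9) stop("layer weights must be symmetric")
  diag(weights) <- 0
  structure(list(layer_id = layer_id, weights = weights,
                 source = source, empty = all(weights == 0)),
            class = "layer_graph")
}

# Extract the weight matrix from a layer_graph / signed_connectome / matrix.
as_weight_matrix <- function(x) {
  if (inherits(x, "layer_graph") || inherits(x, "signed_connectome")) x$weights
  else if (is.matrix(x)) x
  else stop("expected a matrix, layer_graph or signed_connectome")
}

#' Split a signed connectome into positive and negative layers
#'
#' The positive layer keeps weights where w > 0; the negative layer keeps
#' |w| where w < 0. Zero weights belong to neither layer, so the two layers
#' partition the nonzero off-diagonal entries, and
#' `positive - negative` reconstructs the signed matrix exactly.
#'
#' @param x a `signed_connectome` (or signed square matrix).
#' @return list with elements `positive` and `negative`, both `layer_graph`s.
#' @export
split_signed_layers <- function(x) {
  w <- as_weight_matrix(x)
  src <- if (inherits(x, "signed_connectome")) x$subject_id else NA_character_
  pos <- ifelse(w > 0, w, 0)
  neg <- ifelse(w < 0, -w, 0)
  dimnames(pos) <- dimnames(neg) <- dimnames(w)
  list(positive = layer_graph(pos, "positive", src),
       negative = layer_graph(neg, "negative", src))
}

#' Sign-preserving proportional threshold
#'
#' Ranks the undirected edges by absolute weight (descending) and retains the
#' top `k = floor(density * n(n-1)/2)` edges with their original signed
#' weights; all other entries are set to zero. Ties straddling the cut are
#' broken deterministically in favour of the lexicographically smaller
#' (i, j) node pair. Thresholds at increasing densities are nested.
#'
#' @param w signed or nonnegative square matrix, or a `layer_graph`.
#' @param density fraction of possible edges to retain, in (0, 1].
#' @return thresholded object of the same type as the input. If fewer nonzero
#'   edges than `k` are available, all nonzero edges are kept with a warning.
#' @export
proportional_threshold <- function(w, density) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1)
    stop("`density` must be a single fraction in (0, 1]")
  is_layer <- inherits(w, "layer_graph")
  m <- as_weight_matrix(w)
  n <- nrow(m)
  n_possible <- n * (n - 1) / 2
  k <- floor(density * n_possible)
  if (k == 0)
    stop(sprintf("density %.4g retains no edges (k = 0) for n = %d", density, n))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  aw <- abs(m[ut])
  ord <- order(-aw, ut[, 1], ut[, 2])
  n_nonzero <- sum(aw > 0)
  if (k > n_nonzero) {
    warning(sprintf(
      "density %.4g asks for %d edges but only %d nonzero edges exist; keeping all",
      density, k, n_nonzero))
    k <- n_nonzero
  }
  out <- matrix(0, n, n, dimnames = dimnames(m))
  if (k > 0) {
    keep <- ut[ord[seq_len(k)], , drop = FALSE]
    out[keep] <- m[keep]
    out[keep[, c(2, 1), drop = FALSE]] <- m[keep]
  }
  if (is_layer) {
    w$weights <- out
    w$empty <- all(out == 0)
    w
  } else out
}

#' Edge density of a graph
#'
#' Number of nonzero off-diagonal undirected edges divided by n(n-1)/2.
#'
#' @param w square symmetric matrix or `layer_graph`.
#' @return density fraction in \[0, 1\].
#' @export
edge_density <- function(w) {
  m <- as_weight_matrix(w)
  n <- nrow(m)
  if (n < 2) stop("edge density undefined for n < 2")
  sum(m[upper.tri(m)] != 0) / (n * (n - 1) / 2)
}

#' Maximum density reachable by every graph in a cohort
#'
#' The minimum over graphs of their nonzero-support edge density: the largest
#' proportional-threshold density at which no graph runs out of edges. Used
#' to validate the upper bound of a density sweep against a cohort.
#'
#' @param graphs non-empty list of matrices or `layer_graph`s.
#' @return density fraction.
#' @export
max_common_density <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0)
    stop("`graphs` must be a non-empty list")
  min(vapply(graphs, edge_density, numeric(1)))
}

#' Integrate a measure over the density grid (AUC)
#'
#' Trapezoidal integral of per-density measure values against density,
#' yielding one threshold-robust scalar per measure per subject. For a
#' constant value c over the default 0.06-0.33 grid the AUC is 0.27 * c.
#'
#' @param densities strictly increasing density grid (at least 2 points).
#' @param values measure values on the grid.
#' @return the integral as a single numeric.
#' @export
measure_auc <- function(densities, values) {
  if (length(densities) < 2) stop("AUC needs at least 2 grid points")
  if (length(values) != length(densities))
    stop("`values` and `densities` lengths differ")
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  if (any(!is.finite(values))) stop("non-finite measure values in AUC input")
  pracma::trapz(densities, values)
}
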