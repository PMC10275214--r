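# Independent brute-force oracles and random fixtures for the network
# measures. The oracles enumerate paths and triangles explicitly and never
# share code with the implementation they check.

# All-pairs shortest weighted path lengths by exhaustive simple-path
# enumeration (lengths = 1/weight). Feasible for n <= 8.
oracle_distances <- function(m) {
  n <- nrow(m)
  len <- ifelse(m > 0, 1 / m, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    rec <- function(v, visited, acc) {
      if (acc < best[s, v]) best[s, v] <<- acc
      for (u in which(m[v, ] > 0)) {
        if (!visited[u]) {
          vv <- visited
          vv[u] <- TRUE
          rec(u, vv, acc + len[v, u])
        }
      }
    }
    vis <- rep(FALSE, n)
    vis[s] <- TRUE
    rec(s, vis, 0)
  }
  best
}

oracle_global_efficiency <- function(m) {
  n <- nrow(m)
  d <- oracle_distances(m)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    inv <- 1 / d[i, -i]
    vals[i] <- sum(inv[is.finite(inv)]) / (n - 1)
  }
  vals
}

# Nodal weighted clustering by explicit triple loop.
oracle_clustering <- function(m) {
  n <- nrow(m)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        t_i <- t_i + (m[i, j] * m[j, h] * m[h, i])^(1 / 3)
    }
    t_i <- t_i / 2
    k <- sum(m[i, ] > 0)
    vals[i] <- if (k > 1) 2 * t_i / (k * (k - 1)) else 0
  }
  vals
}

oracle_mp_participation <- function(p, q) {
  n <- nrow(p)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    s <- c(sum(p[i, ]), sum(q[i, ]))
    o <- sum(s)
    vals[i] <- if (o > 0) 2 * (1 - sum((s / o)^2)) else 0
  }
  vals
}

oracle_mp_clustering <- function(p, q) {
  n <- nrow(p)
  lays <- list(p, q)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (a in 1:2) {
      A <- lays[[a]]
      B <- lays[[3 - a]]
      for (j in seq_len(n)) for (h in seq_len(n)) {
        if (j != i && h != i && j != h)
          num <- num + (A[i, j] * B[j, h] * A[h, i])^(1 / 3)
      }
    }
    den <- 0
    for (a in 1:2) {
      k <- sum(lays[[a]][i, ] > 0)
      den <- den + k * (k - 1)
    }
    vals[i] <- if (den > 0) num / den else 0
  }
  vals
}

# Opposite-layer efficiency through the explicit augmented network and the
# path-enumeration distance oracle.
oracle_opposite_efficiency <- function(other, w_inter) {
  n <- nrow(other)
  aug <- rbind(cbind(other, rep(w_inter, n)), c(rep(w_inter, n), 0))
  d <- oracle_distances(aug)[n + 1, seq_len(n)]
  inv <- 1 / d
  sum(inv[is.finite(inv)]) / n
}

# Random nonnegative symmetric layer matrix with zero diagonal.
random_layer_matrix <- function(n, p_edge = 0.5, w_min = 0.1, w_max = 1) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  sel <- up[stats::runif(length(up)) < p_edge]
  m[sel] <- stats::runif(length(sel), w_min, w_max)
  m + t(m)
}

# Random signed symmetric matrix with zero diagonal, weights in [-1, 1].
random_signed_matrix <- function(n, p_edge = 0.9) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  sel <- up[stats::runif(length(up)) < p_edge]
  m[sel] <- stats::runif(length(sel), -1, 1)
  m + t(m)
}

# Small symmetric matrix from its upper-triangle edge list.
edge_matrix <- function(n, edges) {
  m <- matrix(0, n, n)
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  m
}

unit_triangle <- function(w = 1) edge_matrix(3, list(c(1, 2, w), c(2, 3, w), c(1, 3, w)))
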