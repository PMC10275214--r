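# Simple connection statistics on the unthresholded signed connectome.

#' Connection summary of a signed connectome
#'
#' The four connection-level statistics of a signed network A with
#' N = n(n-1)/2 possible connections, where A = A_pos + A_neg splits the
#' network into its strictly positive and strictly negative connections
#' (zero entries belong to neither):
#' \describe{
#'   \item{Conn-Ave}{mean weight over all N connections (zeros included).}
#'   \item{PosConn-Ave}{mean of the strictly positive weights.}
#'   \item{NegConn-Ave}{mean of the strictly negative weights, on the signed
#'     scale (a nonpositive number).}
#'   \item{NegConn-No}{count of strictly negative connections.}
#' }
#' These are computed on the unthresholded weighted network. An empty layer's
#' mean is reported as 0 and flagged. The weighted-mean identity
#' `Conn-Ave * N = PosConn-Ave * N_pos + NegConn-Ave * N_neg` always holds.
#'
#' @param x a `signed_connectome` or signed square matrix.
#' @return object of class `connection_summary`: list with `conn_ave`,
#'   `pos_conn_ave`, `neg_conn_ave`, `neg_conn_no`, the layer connection
#'   counts `n_pos`/`n_neg`, total `n_connections`, and logical flags
#'   `pos_empty`/`neg_empty`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.5
#' w[1, 3] <- w[3, 1] <- -0.2
#' w[2, 3] <- w[3, 2] <- 0.3
#' connection_summary(w)
#' @export
connection_summary <- function(x) {
  w <- as_weight_matrix(x)
  up <- w[upper.tri(w)]
  n_total <- length(up)
  pos <- up[up > 0]
  neg <- up[up < 0]
  structure(list(
    conn_ave = sum(up) / n_total,
    pos_conn_ave = if (length(pos)) mean(pos) else 0,
    neg_conn_ave = if (length(neg)) mean(neg) else 0,
    neg_conn_no = length(neg),
    n_pos = length(pos),
    n_neg = length(neg),
    n_connections = n_total,
    pos_empty = length(pos) == 0,
    neg_empty = length(neg) == 0
  ), class = "connection_summary")
}

#' @export
print.connection_summary <- function(x, ...) {
  cat(sprintf(
    "<connection_summary> Conn-Ave %.4f | PosConn-Ave %.4f | NegConn-Ave %.4f | NegConn-No %d (of %d)\n",
    x$conn_ave, x$pos_conn_ave, x$neg_conn_ave, x$neg_conn_no, x$n_connections))
  invisible(x)
}
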