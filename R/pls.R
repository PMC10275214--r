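# Partial least squares regression (univariate outcome, NIPALS) with
# BIC-based component selection and variable-importance-in-projection
# scores.

# NIPALS PLS1 on a centered/scaled X and centered y. Deflates X and y per
# component; stops early if the residual covariance vanishes.
nipals_pls1 <- function(x, y, ncomp) {
  n <- nrow(x)
  p <- ncol(x)
  w_mat <- matrix(0, p, ncomp)
  scores <- matrix(0, n, ncomp)
  load_p <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  ssy <- numeric(ncomp)
  xr <- x
  yr <- y
  a <- 0L
  for (k in seq_len(ncomp)) {
    wv <- crossprod(xr, yr)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- xr %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(xr, tv) / tt
    qk <- sum(yr * tv) / tt
    xr <- xr - tv %*% t(pv)
    yr <- yr - qk * tv
    a <- k
    w_mat[, k] <- wv
    scores[, k] <- tv
    load_p[, k] <- pv
    qv[k] <- qk
    ssy[k] <- qk^2 * tt  # variance in y captured by component k
  }
  if (a == 0L) stop("PLS: predictors carry no covariance with the outcome")
  keep <- seq_len(a)
  list(weights = w_mat[, keep, drop = FALSE],
       scores = scores[, keep, drop = FALSE],
       x_loadings = load_p[, keep, drop = FALSE],
       y_loadings = qv[keep],
       ssy = ssy[keep],
       residuals = yr,
       ncomp = a)
}

#' PLS regression with BIC-selected components and VIP scores
#'
#' Fits univariate-outcome partial least squares regressions (NIPALS) with
#' every number of latent variables (LVs) in `lv_range`, selects the LV
#' count minimizing the Bayesian information criterion
#' `n log(RSS/n) + (LVs + 1) log(n)`, and scores each predictor by its
#' variable importance in projection:
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`
#' (PLS weights summed over LVs, weighted by the variance in the outcome
#' explained by each LV; weight vectors are unit norm). Predictors with
#' VIP > 1 are flagged as significant contributors. The identity
#' `mean(VIP^2) = 1` holds for every fit.
#'
#' Predictor columns are standardized and the outcome centered; an optional
#' covariate matrix is regressed out of the outcome first (residualization).
#'
#' @param x numeric predictor matrix (subjects x measures).
#' @param y numeric outcome vector.
#' @param lv_range candidate LV counts (default 2:12, capped at the number
#'   of predictors and n - 1).
#' @param covariates optional numeric matrix of nuisance covariates.
#' @return object of class `pls_vip`: list with `n_components`,
#'   `vip_scores`, `significant` (names with VIP > 1), `explained_variance`
#'   per LV (fraction of outcome variance), `bic_table`, `r2` and the
#'   internal `fit`.
#' @export
pls_vip <- function(x, y, lv_range = 2:12, covariates = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  p <- ncol(x)
  if (p < 1) stop("need at least one predictor")
  if (length(y) != n) stop("outcome length mismatch")
  if (stats::sd(y) == 0) stop("constant outcome")
  if (n <= max(lv_range)) stop("need more observations than the largest LV count")
  if (!is.null(covariates))
    y <- stats::residuals(stats::lm(y ~ ., data = as.data.frame(covariates)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  ys <- y - mean(y)
  lv_range <- lv_range[lv_range <= min(p, n - 1)]
  if (!length(lv_range)) stop("no admissible LV count in `lv_range`")
  fits <- list()
  bic <- rep(NA_real_, length(lv_range))
  for (i in seq_along(lv_range)) {
    fit <- nipals_pls1(xs, ys, lv_range[i])
    rss <- sum(fit$residuals^2)
    bic[i] <- n * log(max(rss, 1e-300) / n) + (fit$ncomp + 1) * log(n)
    fits[[i]] <- fit
  }
  best_i <- which.min(bic)
  fit <- fits[[best_i]]
  vip <- sqrt(p * as.vector(fit$weights^2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- colnames(x)
  ss_tot <- sum(ys^2)
  structure(list(
    n_components = fit$ncomp,
    vip_scores = vip,
    significant = names(vip)[vip > 1],
    explained_variance = fit$ssy / ss_tot,
    bic_table = data.frame(lv = lv_range, bic = bic),
    r2 = 1 - sum(fit$residuals^2) / ss_tot,
    fit = fit
  ), class = "pls_vip")
}

#' @export
print.pls_vip <- function(x, ...) {
  cat("<pls_vip>", x$n_components, "latent variables, R2 =",
      format(x$r2, digits = 3), "\n  VIP > 1:",
      if (length(x$significant)) paste(x$significant, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
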