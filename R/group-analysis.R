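# Group-comparison statistics: per-age permutation tests with BH-FDR,
# polynomial age/sex models with exhaustive AIC subset selection, ICC
# test-retest reliability, and subsample reproducibility.

#' Two-sample permutation test of a sex difference
#'
#' Tests the difference of group means (men minus women) against the
#' permutation distribution obtained by shuffling group labels. The
#' two-tailed p-value uses the add-one convention
#' `p = (1 + #(|perm| >= |observed|)) / (n_perm + 1)`, which never returns 0
#' and keeps the test valid. Constant pooled data yield p = 1.
#'
#' @param values_men,values_women numeric vectors (each length >= 2).
#' @param n_perm number of label permutations (>= 100).
#' @param seed optional seed for the permutation draws.
#' @return object of class `permutation_test`: list with `observed_diff`
#'   (mean men - mean women), `p_value` and `n_permutations`.
#' @export
permutation_sex_test <- function(values_men, values_women, n_perm = 10000,
                                 seed = NULL) {
  n1 <- length(values_men)
  n2 <- length(values_women)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 subjects")
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  pool <- c(values_men, values_women)
  if (any(!is.finite(pool))) stop("non-finite values in input")
  obs <- mean(values_men) - mean(values_women)
  if (max(pool) == min(pool)) {
    return(structure(list(observed_diff = obs, p_value = 1,
                          n_permutations = as.integer(n_perm)),
                     class = "permutation_test"))
  }
  n <- n1 + n2
  tot <- sum(pool)
  perm <- vapply(seq_len(n_perm), function(i) {
    s <- sum(pool[sample.int(n, n1)])
    s / n1 - (tot - s) / n2
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(observed_diff = obs, p_value = p,
                 n_permutations = as.integer(n_perm)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> diff (men - women) = %.4g, p = %.4g (%d permutations)\n",
              x$observed_diff, x$p_value, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up rule: with sorted p-values p(1) <= ... <= p(m), reject
#' all p <= p(k*) where `k* = max(k : p(k) <= k q / m)`.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return logical vector, TRUE where rejected.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p_values <= ps[max(ok)]
}

#' Per-age permutation profile of a measure
#'
#' Runs [permutation_sex_test()] at every age present in the table and
#' applies BH-FDR across the age groups (one FDR family per measure).
#' Per-age permutation seeds are derived deterministically from `seed` so
#' the profile is reproducible and independent of table order.
#'
#' @param df data.frame with columns `sex` (`female`/`male`), `age` and
#'   `value` (one measure).
#' @param n_perm permutations per age.
#' @param q FDR level across ages.
#' @param seed base seed; the test at the i-th age uses `seed + i`.
#' @return data.frame with columns `age`, `observed_diff`, `p_value`,
#'   `significant_fdr`.
#' @export
permutation_age_profile <- function(df, n_perm = 10000, q = 0.05, seed = 1L) {
  stopifnot(all(c("sex", "age", "value") %in% names(df)))
  ages <- sort(unique(df$age))
  res <- lapply(seq_along(ages), function(i) {
    d <- df[df$age == ages[i], ]
    # groups are sorted so the drawn permutations (hence the p-value) do not
    # depend on the row order of the input table
    t <- permutation_sex_test(sort(d$value[d$sex == "male"]),
                              sort(d$value[d$sex == "female"]),
                              n_perm = n_perm, seed = seed + i)
    data.frame(age = ages[i], observed_diff = t$observed_diff,
               p_value = t$p_value)
  })
  out <- do.call(rbind, res)
  out$significant_fdr <- bh_fdr(out$p_value, q = q)
  out
}

#' Per-(age, sex) cell means of a measure
#'
#' Summarizes per-subject values by their average within each (age, sex)
#' cell, the summary on which the age/sex polynomial models are fit.
#'
#' @param df data.frame with columns `sex`, `age`, `value`.
#' @return data.frame with columns `age`, `sex`, `value` (cell mean).
#' @export
cell_means <- function(df) {
  stopifnot(all(c("sex", "age", "value") %in% names(df)))
  out <- stats::aggregate(value ~ age + sex, data = df, FUN = mean)
  out[order(out$age, out$sex), c("age", "sex", "value")]
}

#' Age/sex polynomial model with exhaustive AIC subset selection
#'
#' Fits ordinary least squares models of per-(age, sex) mean measure values
#' on subsets of the five predictors age, sex, age^2, age x sex and
#' age^2 x sex (age centered before the polynomial expansion; sex coded
#' female = 0, male = 1; intercept always included). All 32 subsets are
#' enumerated and the minimum-AIC model returned; no hierarchy constraint is
#' imposed, so interactions may enter without their main effects.
#'
#' @param cells data.frame of cell means with columns `age`, `sex`, `value`
#'   (from [cell_means()]); needs >= 6 cells and both sexes.
#' @return object of class `age_sex_fit`: list with `selected_predictors`,
#'   `coefficients`, `r2`, `aic`, `mse`, `overall_F_p`, the `lm` object
#'   (`fit`), the full-model AIC (`full_aic`) and the per-subset `aic_table`.
#' @export
fit_age_sex_models <- function(cells) {
  stopifnot(all(c("age", "sex", "value") %in% names(cells)))
  if (nrow(cells) < 6) stop("need at least 6 (age, sex) cells")
  sx <- as.integer(factor(as.character(cells$sex),
                          levels = c("female", "male"))) - 1L
  if (length(unique(sx)) < 2 || anyNA(sx)) stop("both sexes must be present")
  ac <- cells$age - mean(cells$age)
  d <- data.frame(y = cells$value, age = ac, sex = sx,
                  age2 = ac^2, age_sex = ac * sx, age2_sex = ac^2 * sx)
  if (stats::var(d$y) < .Machine$double.eps * max(1, mean(d$y)^2)) {
    # constant outcome: every subset fits perfectly up to rounding noise;
    # the intercept-only model is the unambiguous minimum-complexity answer
    fit <- stats::lm(y ~ 1, data = d)
    return(structure(list(
      selected_predictors = character(0),
      coefficients = stats::coef(fit), r2 = 0, aic = stats::AIC(fit),
      mse = mean(stats::residuals(fit)^2), overall_F_p = NA_real_,
      fit = fit, full_aic = NA_real_, aic_table = NULL
    ), class = "age_sex_fit"))
  }
  terms <- c("age", "sex", "age2", "age_sex", "age2_sex")
  best <- NULL
  aic_table <- data.frame(subset = character(32), aic = NA_real_,
                          stringsAsFactors = FALSE)
  for (mask in 0:31) {
    vars <- terms[bitwAnd(mask, 2^(0:4)) > 0]
    f <- stats::reformulate(if (length(vars)) vars else "1", response = "y")
    fit <- stats::lm(f, data = d)
    aic_table$subset[mask + 1] <- paste(vars, collapse = "+")
    if (fit$rank < length(vars) + 1) next  # rank-deficient subset skipped
    a <- stats::AIC(fit)
    aic_table$aic[mask + 1] <- a
    if (is.null(best) || a < best$aic)
      best <- list(fit = fit, aic = a, vars = vars)
  }
  sm <- summary(best$fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant outcome: no variance to explain
  fst <- sm$fstatistic
  f_p <- if (is.null(fst)) NA_real_ else
    stats::pf(fst[1], fst[2], fst[3], lower.tail = FALSE)
  structure(list(
    selected_predictors = best$vars,
    coefficients = stats::coef(best$fit),
    r2 = r2,
    aic = best$aic,
    mse = mean(stats::residuals(best$fit)^2),
    overall_F_p = unname(f_p),
    fit = best$fit,
    full_aic = aic_table$aic[32],
    aic_table = aic_table
  ), class = "age_sex_fit")
}

#' @export
print.age_sex_fit <- function(x, ...) {
  cat("<age_sex_fit> predictors {",
      paste(x$selected_predictors, collapse = ", "),
      sprintf("} R2 = %.3f, AIC = %.2f, MSE = %.4g\n", x$r2, x$aic, x$mse))
  invisible(x)
}

#' Test-retest intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation between two sessions, with the 95% confidence
#' interval of McGraw and Wong (F-distribution with Satterthwaite degrees of
#' freedom).
#'
#' @param session1,session2 paired numeric vectors (length >= 3).
#' @param conf confidence level.
#' @return object of class `icc_result`: list with `icc`, `ci95` and the
#'   ANOVA mean squares.
#' @export
icc_test_retest <- function(session1, session2, conf = 0.95) {
  if (length(session1) != length(session2)) stop("session length mismatch")
  n <- length(session1)
  if (n < 3) stop("need at least 3 paired observations")
  y <- cbind(session1, session2)
  k <- 2
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  gm <- mean(y)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (den <= 0) NA_real_ else (msr - mse) / den
  alpha <- 1 - conf
  if (mse < .Machine$double.eps * max(1, msr)) {
    ci <- c(icc, icc)  # perfect agreement: degenerate interval
  } else {
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, lower), min(1, upper))
  }
  structure(list(icc = icc, ci95 = ci,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.3f [%.3f, %.3f]\n",
              x$icc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Subsample reproducibility of per-age sex differences
#'
#' Repeatedly subsamples each (age, sex) cell without replacement at each
#' fraction of the original size, reruns the per-age permutation + BH-FDR
#' analysis, and reports the proportion of repeats in which each age is
#' significant. At fraction 1 every "subsample" is the full cohort, so the
#' full-cohort significance pattern is reproduced exactly (the permutation
#' seeds are shared across fractions and repeats).
#'
#' @param df data.frame with columns `sex`, `age`, `value` (one measure).
#' @param fractions subsample fractions in (0, 1].
#' @param n_repeats subsamples per fraction.
#' @param n_perm,q permutation-test and FDR parameters.
#' @param seed base seed (permutation streams and subsampling streams are
#'   derived from it).
#' @return data.frame with columns `fraction`, `age`, `prop_significant`.
#' @export
subsample_reproducibility <- function(df, fractions = seq(0.5, 1, 0.1),
                                      n_repeats = 20, n_perm = 1000,
                                      q = 0.05, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  ages <- sort(unique(df$age))
  cellsplit <- split(seq_len(nrow(df)), interaction(df$age, df$sex, drop = TRUE))
  out <- list()
  for (f in fractions) {
    hits <- matrix(FALSE, n_repeats, length(ages))
    for (r in seq_len(n_repeats)) {
      set.seed(seed + 7919L * r + round(1e6 * f))
      idx <- unlist(lapply(cellsplit, function(ix) {
        m <- floor(f * length(ix))
        if (m < 2) stop("fraction ", f, " yields fewer than 2 subjects in a cell")
        ix[sample.int(length(ix), m)]
      }), use.names = FALSE)
      prof <- permutation_age_profile(df[idx, ], n_perm = n_perm, q = q,
                                      seed = seed)
      hits[r, ] <- prof$significant_fdr[match(ages, prof$age)]
    }
    out[[length(out) + 1]] <- data.frame(fraction = f, age = ages,
                                         prop_significant = colMeans(hits))
  }
  do.call(rbind, out)
}
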