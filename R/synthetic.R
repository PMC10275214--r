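# Synthetic cross-sectional cohorts of signed connectomes with controllable
# sex- and age-dependent connectivity structure.

eval_curve <- function(coef, age_centered) {
  coef[1] + coef[2] * age_centered + coef[3] * age_centered^2
}

curve_ok <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x))

#' Specify a synthetic cohort
#'
#' Defines a cross-sectional cohort of signed connectomes whose mean positive
#' weight, mean absolute negative weight and expected negative-connection
#' count vary by sex and quadratically with (centered) age. Each curve is a
#' coefficient triple `c(intercept, linear, quadratic)` evaluated at
#' `age - age_center`, per sex. Edge signs are drawn independently per
#' connection with probability `kappa(age, sex) / N` of being negative
#' (N = n(n-1)/2 connections), so the negative-connection count is
#' binomially distributed around the kappa curve; negative connections get
#' weight `-|Normal(mu_neg, noise_sd)|` and positive ones
#' `+|Normal(mu_pos, noise_sd)|`, clipped to \[-1, 1\].
#'
#' The defaults (also returned by [aging_cohort_spec()]) emulate a
#' middle-to-old-age cohort in which women have higher average connectivity
#' and men more negative connections at mid-age, with the sex gap closing
#' linearly to zero at the top of the age range; positive and negative mean
#' strengths carry no sex effect. Effects are parametrized on the same
#' quadratic-in-age basis that the analysis models fit, so
#' parameter-recovery checks are well-posed.
#'
#' @param n_nodes nodes per connectome.
#' @param age_range integer pair of youngest and oldest age.
#' @param subjects_per_cell subjects per (age, sex) cell (>= 1; cohort-level
#'   group comparisons assume >= 50).
#' @param age_center age subtracted before evaluating the curves.
#' @param mu_pos,mu_neg,kappa per-sex lists (`female`, `male`) of coefficient
#'   triples for the mean positive weight, mean absolute negative weight and
#'   expected negative-connection count.
#' @param noise_sd standard deviation of the weight noise (> 0).
#' @param psd_project project each matrix to the nearest correlation-like
#'   (positive semidefinite, unit-diagonal) matrix before re-zeroing the
#'   diagonal.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nodes = 21,
                        age_range = c(47L, 79L),
                        subjects_per_cell = 50,
                        age_center = 63,
                        mu_pos = list(female = c(0.30, 0.0015, 0),
                                      male = c(0.30, 0.0015, 0)),
                        mu_neg = list(female = c(0.25, 0, 0),
                                      male = c(0.25, 0, 0)),
                        kappa = list(female = c(97, -0.3125, -0.01),
                                     male = c(103, -0.6875, -0.01)),
                        noise_sd = 0.12,
                        psd_project = FALSE) {
  stopifnot(n_nodes >= 3, length(age_range) == 2, age_range[1] <= age_range[2],
            subjects_per_cell >= 1)
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  for (curves in list(mu_pos, mu_neg, kappa)) {
    if (!is.list(curves) || !all(c("female", "male") %in% names(curves)))
      stop("each curve set needs `female` and `male` coefficient triples")
    if (!all(vapply(curves, curve_ok, logical(1))))
      stop("curve coefficients must be finite numeric triples")
  }
  n_conn <- n_nodes * (n_nodes - 1) / 2
  ages <- seq(age_range[1], age_range[2])
  for (sex in c("female", "male")) {
    ac <- ages - age_center
    k <- eval_curve(kappa[[sex]], ac)
    if (any(k < 0) || any(k > n_conn))
      stop("kappa curve for ", sex, " leaves [0, ", n_conn, "] over the age range")
    if (any(eval_curve(mu_pos[[sex]], ac) <= 0) ||
        any(eval_curve(mu_neg[[sex]], ac) <= 0))
      stop("mean weight curves must stay positive over the age range")
  }
  structure(list(n_nodes = n_nodes, age_range = as.integer(age_range),
                 subjects_per_cell = subjects_per_cell,
                 age_center = age_center,
                 mu_pos = mu_pos, mu_neg = mu_neg, kappa = kappa,
                 noise_sd = noise_sd, psd_project = psd_project),
            class = "cohort_spec")
}

#' Default aging-cohort specification
#'
#' The package's reference synthetic cohort: 21-node connectomes, ages 47-79
#' with 50 subjects per (age, sex) cell, women with fewer negative
#' connections (hence higher average connectivity) than men at mid-age, and
#' the sex differences shrinking linearly to zero at the oldest age. See
#' [cohort_spec()] for the parameter values, which are its defaults.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
aging_cohort_spec <- function(...) {
  cohort_spec(...)
}

#' Generate one synthetic signed connectome
#'
#' Draws a single subject's connectome under a [cohort_spec()] at a given sex
#' and age, using the current RNG state (seed it, or use
#' [generate_cohort()], for reproducibility).
#'
#' @param spec a `cohort_spec`.
#' @param sex `"female"` or `"male"`.
#' @param age integer age within the spec's range.
#' @param subject_id identifier for the generated subject.
#' @return a `signed_connectome`.
#' @export
generate_connectome <- function(spec, sex = c("female", "male"), age,
                                subject_id = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  sex <- match.arg(sex)
  if (age < spec$age_range[1] || age > spec$age_range[2])
    stop("age ", age, " outside the spec's range")
  n <- spec$n_nodes
  n_conn <- n * (n - 1) / 2
  ac <- age - spec$age_center
  kappa <- eval_curve(spec$kappa[[sex]], ac)
  p_neg <- min(max(kappa / n_conn, 0), 1)
  m_pos <- eval_curve(spec$mu_pos[[sex]], ac)
  m_neg <- eval_curve(spec$mu_neg[[sex]], ac)
  is_neg <- stats::runif(n_conn) < p_neg
  w <- ifelse(is_neg,
              -abs(stats::rnorm(n_conn, m_neg, spec$noise_sd)),
              abs(stats::rnorm(n_conn, m_pos, spec$noise_sd)))
  w <- pmin(pmax(w, -1), 1)
  mat <- matrix(0, n, n)
  mat[upper.tri(mat)] <- w
  mat <- mat + t(mat)
  if (isTRUE(spec$psd_project)) {
    diag(mat) <- 1
    mat <- as.matrix(Matrix::nearPD(mat, corr = TRUE, conv.tol = 1e-8)$mat)
    mat <- (mat + t(mat)) / 2
    mat <- pmin(pmax(mat, -1), 1)
    diag(mat) <- 0
  }
  signed_connectome(mat, subject_id = subject_id)
}

#' Generate a synthetic cohort
#'
#' Generates `subjects_per_cell` connectomes for every (age, sex) cell across
#' the spec's age range, reproducibly from the seed.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed for the generation.
#' @return object of class `synthetic_cohort`: list with `cohort_table`
#'   (subject_id, sex, age), `connectomes` (named list of
#'   `signed_connectome`s in table order), the generating `spec` and `seed`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  ages <- seq(spec$age_range[1], spec$age_range[2])
  rows <- expand.grid(idx = seq_len(spec$subjects_per_cell),
                      sex = c("female", "male"), age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ids <- sprintf("sub_%s_%03d_%03d", substr(rows$sex, 1, 1), rows$age, rows$idx)
  connectomes <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    connectomes[[i]] <- generate_connectome(spec, rows$sex[i], rows$age[i],
                                            subject_id = ids[i])
  }
  names(connectomes) <- ids
  cohort_table <- data.frame(subject_id = ids,
                             sex = factor(rows$sex, levels = c("female", "male")),
                             age = as.integer(rows$age),
                             stringsAsFactors = FALSE)
  structure(list(cohort_table = cohort_table, connectomes = connectomes,
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$cohort_table), "subjects, ages",
      x$spec$age_range[1], "-", x$spec$age_range[2], ", seed", x$seed, "\n")
  invisible(x)
}
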