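test_that("permutation test handles degenerate and separated groups", {
  x <- c(1.2, 0.7, 1.9, 0.4)
  t0 <- permutation_sex_test(x, x, n_perm = 500, seed = 1)
  expect_equal(t0$observed_diff, 0)
  expect_equal(t0$p_value, 1)

  t1 <- permutation_sex_test(rep(2, 5), rep(2, 6), n_perm = 500, seed = 1)
  expect_equal(t1$p_value, 1)  # constant pooled data

  # fully separated groups, checked against exhaustive labeling on 6 + 6
  men <- c(5.1, 5.4, 5.9, 6.2, 5.7, 5.3)
  women <- c(1.1, 1.4, 0.9, 1.2, 1.6, 1.0)
  pool <- c(men, women)
  obs <- mean(men) - mean(women)
  labelings <- utils::combn(12, 6)
  stats <- apply(labelings, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
  p_exact <- sum(abs(stats) >= abs(obs)) / ncol(labelings)
  tt <- permutation_sex_test(men, women, n_perm = 10000, seed = 7)
  expect_gte(tt$p_value, 1 / 10001)
  expect_lt(abs(tt$p_value - p_exact), 0.005)

  # moderate effect: Monte Carlo p close to the exhaustive p
  set.seed(11)
  a <- rnorm(6)
  b <- rnorm(6) + 0.8
  pool2 <- c(a, b)
  obs2 <- mean(a) - mean(b)
  stats2 <- apply(labelings, 2, function(ix) mean(pool2[ix]) - mean(pool2[-ix]))
  p2_exact <- sum(abs(stats2) >= abs(obs2)) / ncol(labelings)
  t2 <- permutation_sex_test(a, b, n_perm = 10000, seed = 8)
  expect_lt(abs(t2$p_value - p2_exact), 0.03)

  expect_error(permutation_sex_test(1, rnorm(5)), "at least 2")
  expect_error(permutation_sex_test(rnorm(5), rnorm(5), n_perm = 10), "at least 100")
})

test_that("BH step-up matches hand evaluation and p.adjust", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_identical(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(bh_fdr(0.049, 0.05), TRUE)
  expect_identical(bh_fdr(0.051, 0.05), FALSE)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(90)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q), p.adjust(p, "BH") <= q)
  }
})

test_that("per-age profiles apply one FDR family across ages", {
  set.seed(301)
  df <- do.call(rbind, lapply(40:45, function(a) {
    shift <- if (a <= 42) 1 else 0  # effect only at the younger ages
    data.frame(sex = rep(c("female", "male"), each = 30), age = a,
               value = c(rnorm(30), rnorm(30) + shift))
  }))
  prof <- permutation_age_profile(df, n_perm = 500, q = 0.05, seed = 3)
  expect_equal(prof$age, 40:45)
  expect_true(all(prof$significant_fdr[prof$age <= 42]))
  expect_identical(prof$significant_fdr, bh_fdr(prof$p_value, 0.05))
  # deterministic given the seed, regardless of row order
  prof2 <- permutation_age_profile(df[sample(nrow(df)), ], n_perm = 500,
                                   q = 0.05, seed = 3)
  expect_equal(prof, prof2)
})

test_that("AIC subset selection recovers simple generating models", {
  ages <- rep(47:79, each = 2)
  sex <- rep(c("female", "male"), times = 33)
  ac <- ages - mean(ages)
  set.seed(12)
  cells <- data.frame(age = ages, sex = sex,
                      value = 2 + 0.1 * ac + rnorm(66, 0, 0.01))
  fit <- fit_age_sex_models(cells)
  expect_true("age" %in% fit$selected_predictors)
  expect_false(any(c("sex", "age_sex", "age2_sex") %in% fit$selected_predictors))
  expect_equal(unname(fit$coefficients["age"]), 0.1, tolerance = 0.01)
  expect_gt(fit$r2, 0.99)
  expect_lte(fit$aic, fit$full_aic)

  const <- data.frame(age = ages, sex = sex, value = 3)
  fit0 <- fit_age_sex_models(const)
  expect_length(fit0$selected_predictors, 0)
  expect_equal(fit0$r2, 0)

  # interaction with a known sign is recovered
  set.seed(13)
  sx <- as.integer(sex == "male")
  cells2 <- data.frame(age = ages, sex = sex,
                       value = 10 + sx * (6 - 0.4 * ac) + rnorm(66, 0, 0.3))
  fit2 <- fit_age_sex_models(cells2)
  expect_true(all(c("sex", "age_sex") %in% fit2$selected_predictors))
  expect_lt(fit2$coefficients["age_sex"], 0)

  expect_error(fit_age_sex_models(cells[cells$sex == "male", ]), "both sexes")
  expect_error(fit_age_sex_models(cells[1:4, ]), "at least 6")
})

test_that("ICC(A,1) is exact on agreement and near zero on independence", {
  set.seed(41)
  s1 <- rnorm(30, 10, 2)
  perfect <- icc_test_retest(s1, s1)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$ci95, c(1, 1))

  set.seed(42)
  a <- rnorm(200)
  b <- rnorm(200)
  null_icc <- icc_test_retest(a, b)
  expect_lt(abs(null_icc$icc), 0.15)
  expect_lte(null_icc$icc, 1)
  expect_lt(null_icc$ci95[1], null_icc$icc)
  expect_gt(null_icc$ci95[2], null_icc$icc)

  # strong but imperfect agreement: ICC high, CI inside (0, 1)
  set.seed(43)
  base <- rnorm(50, 0, 3)
  strong <- icc_test_retest(base + rnorm(50, 0, 0.5), base + rnorm(50, 0, 0.5))
  expect_gt(strong$icc, 0.9)
  expect_gt(strong$ci95[1], 0.7)
  expect_error(icc_test_retest(1:5, 1:6), "mismatch")
  expect_error(icc_test_retest(1:2, 1:2), "at least 3")
})

test_that("subsample reproducibility is exact at fraction one and tracks power", {
  set.seed(61)
  df <- do.call(rbind, lapply(60:63, function(a) {
    shift <- if (a <= 61) 2.5 else 0  # strong effect at two ages, null at two
    data.frame(sex = rep(c("female", "male"), each = 40), age = a,
               value = c(rnorm(40), rnorm(40) + shift))
  }))
  full <- permutation_age_profile(df, n_perm = 400, q = 0.05, seed = 17)
  rep1 <- subsample_reproducibility(df, fractions = 1, n_repeats = 2,
                                    n_perm = 400, q = 0.05, seed = 17)
  expect_equal(rep1$prop_significant, as.numeric(full$significant_fdr))

  reps <- subsample_reproducibility(df, fractions = c(0.5, 0.75, 1),
                                    n_repeats = 5, n_perm = 400,
                                    q = 0.05, seed = 17)
  strong <- reps[reps$age <= 61, ]
  # a large planted effect is detected at every fraction
  expect_true(all(strong$prop_significant == 1))
  agg <- aggregate(prop_significant ~ fraction, reps[reps$age >= 62, ], mean)
  expect_true(all(agg$prop_significant <= 0.3))  # null ages stay mostly quiet

  expect_error(subsample_reproducibility(df, fractions = 0.01, n_repeats = 1,
                                         n_perm = 400), "fewer than 2")
})
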