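test_that("connectome validation symmetrizes, zeroes the diagonal and clips", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.5
  w[2, 1] <- 0.5000004
  w[1, 1] <- 0.9  # nonzero diagonal must be discarded
  c1 <- signed_connectome(w)
  expect_equal(c1$weights[1, 2], 0.5000002)
  expect_equal(c1$weights[2, 1], 0.5000002)
  expect_true(all(diag(c1$weights) == 0))

  w2 <- w
  w2[2, 1] <- 0.51  # asymmetry far above tolerance
  expect_error(signed_connectome(w2), "asymmetry")

  w3 <- diag(0, 3)
  w3[1, 2] <- w3[2, 1] <- 1 + 5e-10
  expect_warning(c3 <- signed_connectome(w3), "clipping")
  expect_equal(c3$weights[1, 2], 1)
  w4 <- diag(0, 3)
  w4[1, 2] <- w4[2, 1] <- 1.1
  expect_error(signed_connectome(w4), "exceeds")

  expect_error(signed_connectome(matrix(0, 2, 2)), "at least 3")
  expect_error(signed_connectome(matrix(0, 3, 4)), "square")
  w5 <- diag(0, 3)
  w5[1, 2] <- w5[2, 1] <- NaN
  expect_error(signed_connectome(w5), "NaN")
})

test_that("matrix files round-trip, autodetect dialect, and load idempotently", {
  set.seed(11)
  w <- random_signed_matrix(21)
  c0 <- signed_connectome(w, "s21")

  path_csv <- withr::local_tempfile(fileext = ".csv")
  write_connectome_matrix(c0, path_csv)
  c1 <- read_connectome_matrix(path_csv)
  expect_s3_class(c1, "signed_connectome")
  expect_length(c1$nodes, 21)
  expect_equal(unname(c1$weights), unname(c0$weights), tolerance = 1e-10)

  # idempotence: write the validated matrix again, reload, nothing changes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_connectome_matrix(c1, path2)
  c2 <- read_connectome_matrix(path2)
  expect_identical(c2$weights, c1$weights)

  # tab-delimited without header
  path_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_matrix(c0, path_tsv, delimiter = "\t", header = FALSE)
  c3 <- read_connectome_matrix(path_tsv)
  expect_equal(unname(c3$weights), unname(c0$weights), tolerance = 1e-10)

  # a 3x3 all-zero matrix is a valid (null) connectome
  path0 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), path0)
  c4 <- read_connectome_matrix(path0)
  expect_true(all(c4$weights == 0))

  # non-numeric cells are rejected
  pathx <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "0,x,0", "0,0,0", "1,0,0"), pathx)
  expect_error(read_connectome_matrix(pathx), "non-numeric")
})

test_that("cohort tables are validated and small cells dropped", {
  make_tab <- function(ages, n_f, n_m) {
    do.call(rbind, lapply(ages, function(a) {
      data.frame(
        subject_id = sprintf("s%d_%s_%d", a, c(rep("f", n_f), rep("m", n_m)),
                             seq_len(n_f + n_m)),
        sex = c(rep("female", n_f), rep("male", n_m)),
        age = a, stringsAsFactors = FALSE)
    }))
  }
  tab <- make_tab(47:50, 60, 55)
  keep <- validate_cohort_table(tab, min_group_size = 50)
  expect_equal(nrow(keep), nrow(tab))
  expect_identical(levels(keep$sex), c("female", "male"))

  small <- make_tab(80, 12, 12)
  small$subject_id <- paste0("x", small$subject_id)
  both <- rbind(tab, small)
  expect_message(keep2 <- validate_cohort_table(both, min_group_size = 50),
                 "dropping")
  expect_false(80 %in% keep2$age)
  expect_equal(sort(unique(keep2$age)), 47:50)

  expect_error(validate_cohort_table(tab[0, ]), "no rows")
  expect_error(validate_cohort_table(tab[, c("subject_id", "age")]), "missing")
  bad <- tab
  bad$sex[1] <- "M"
  expect_error(validate_cohort_table(bad), "unknown sex")
  bad2 <- tab
  bad2$age <- bad2$age + 0.5
  expect_error(validate_cohort_table(bad2), "integer")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_equal(nrow(read_cohort_table(path, min_group_size = 50)), nrow(tab))
})

test_that("measure tables round-trip losslessly and keep the sigma schema", {
  sigmas <- default_sigma_grid()
  tab <- expand.grid(subject_id = c("a", "b"),
                     measure = c("Conn-Ave", "NegConn-No", "SLpos-Ge",
                                 "SLneg-Ge", "SLpos-CC", "SLneg-CC",
                                 "PosConn-Ave", "NegConn-Ave", "MP-Pt",
                                 "MP-CC", "ML-Ge", "ML-CC"),
                     stringsAsFactors = FALSE)
  tab$sigma <- ifelse(tab$measure %in% c("ML-Ge", "ML-CC"), 0.2, NA_real_)
  set.seed(5)
  tab$value <- rnorm(nrow(tab)) * 10^sample(-3:2, nrow(tab), TRUE)
  expect_equal(nrow(tab), 24)  # 2 subjects x 12 measures

  path <- withr::local_tempfile(fileext = ".csv")
  write_measure_table(tab, path)
  back <- read_measure_table(path)
  expect_equal(nrow(back), 24)
  key <- function(d) order(d$subject_id, d$measure, d$sigma)
  expect_equal(back$value[key(back)], tab$value[key(tab)], tolerance = 1e-12)
  # sigma column is empty exactly for the non-multilayer rows
  expect_identical(is.na(back$sigma[key(back)]),
                   !(tab$measure[key(tab)] %in% c("ML-Ge", "ML-CC")))

  dup <- rbind(tab, tab[1, ])
  expect_error(write_measure_table(dup, path), "duplicate")
  expect_error(write_measure_table(tab[0, ], path), "empty")
})
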