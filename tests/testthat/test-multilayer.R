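test_that("interlayer weight is sigma times the larger layer maximum", {
  p <- edge_matrix(3, list(c(1, 2, 0.9)))
  q <- edge_matrix(3, list(c(1, 3, 0.5)))
  spec <- interlayer_weight(p, q, 0.2)
  expect_equal(spec$w_inter, 0.18)
  expect_equal(spec$w_max_alpha, 0.9)
  expect_equal(spec$w_max_beta, 0.5)
  expect_equal(interlayer_weight(unit_triangle(), unit_triangle(), 1)$w_inter, 1)
  expect_error(interlayer_weight(matrix(0, 3, 3), matrix(0, 3, 3), 0.5),
               "both layers are empty")
  expect_error(interlayer_weight(p, q, 0), "fraction")
  expect_error(interlayer_weight(p, q, 1.2), "fraction")
  expect_identical(default_sigma_grid(), seq(5, 100, 5) / 100)
})

test_that("same-layer terms equal the single-layer measures", {
  p3 <- edge_matrix(3, list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(unname(same_layer_efficiency(p3)), c(0.75, 1, 0.75))
  u2 <- edge_matrix(2, list(c(1, 2, 1)))
  expect_equal(unname(same_layer_efficiency(u2)), c(1, 1))
  set.seed(301)
  for (i in 1:100) {
    m <- random_layer_matrix(sample(4:10, 1), p_edge = runif(1, 0.2, 0.9))
    expect_identical(same_layer_efficiency(m), global_efficiency(m)$values)
    expect_identical(same_layer_clustering(m), clustering_coefficient(m)$values)
  }
})

test_that("opposite-layer efficiency follows the augmented network", {
  u2 <- edge_matrix(2, list(c(1, 2, 1)))
  expect_equal(opposite_layer_efficiency(u2, 1), 1)
  # no intralayer edges: only the direct interlayer edges remain
  expect_equal(opposite_layer_efficiency(matrix(0, 2, 2), 0.5), 0.5)

  set.seed(302)
  sg <- default_sigma_grid()
  for (i in 1:100) {
    n <- sample(4:8, 1)
    other <- random_layer_matrix(n, p_edge = runif(1, 0.2, 0.8))
    if (max(other) == 0) other[1, 2] <- other[2, 1] <- 0.5
    w_max <- max(other)
    vals <- vapply(sg, function(s) opposite_layer_efficiency(other, s * w_max),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))        # nondecreasing in sigma
    expect_true(all(vals >= sg * w_max - 1e-12))  # direct-edge lower bound
  }
  # brute-force augmented-network oracle
  set.seed(303)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    other <- random_layer_matrix(n, p_edge = 0.6)
    w_inter <- runif(1, 0.05, 1)
    expect_equal(opposite_layer_efficiency(other, w_inter),
                 oracle_opposite_efficiency(other, w_inter), tolerance = 1e-10)
  }
})

test_that("opposite-layer clustering counts interlayer-wing triangles", {
  expect_equal(opposite_layer_clustering(unit_triangle(), 1), 1)
  expect_equal(opposite_layer_clustering(matrix(0, 4, 4), 0.7), 0)
  set.seed(304)
  other <- random_layer_matrix(7, 0.5)
  v1 <- opposite_layer_clustering(other, 0.3)
  v2 <- opposite_layer_clustering(other, 0.6)
  expect_equal(v2 / v1, 2^(2 / 3))  # scales as w_inter^(2/3)
})

test_that("multilayer differences follow the opposite-minus-same convention", {
  u2 <- edge_matrix(2, list(c(1, 2, 1)))
  ge0 <- multilayer_global_efficiency(u2, u2, 1)
  expect_equal(unname(ge0$values_alpha), c(0, 0))
  expect_equal(ge0$network, 0)

  cc0 <- multilayer_clustering(unit_triangle(), unit_triangle(), 1)
  expect_equal(unname(cc0$values_alpha), rep(0, 3))
  expect_equal(cc0$network, 0)

  # empty negative layer: opposite-layer terms are zero and flagged
  complete4 <- matrix(1, 4, 4) - diag(4)
  ge_e <- multilayer_global_efficiency(complete4, matrix(0, 4, 4), 0.5)
  expect_true(ge_e$flags["neg_empty"])
  expect_equal(unname(ge_e$values_alpha), rep(-1, 4))
  cc_e <- multilayer_clustering(unit_triangle(), matrix(0, 3, 3), 0.5)
  expect_equal(unname(cc_e$values_alpha), rep(-1, 3))

  # identical layers: the two replica sides coincide
  set.seed(305)
  m <- random_layer_matrix(8, 0.6)
  for (s in c(0.2, 0.7)) {
    ge <- multilayer_global_efficiency(m, m, s)
    expect_equal(ge$values_alpha, ge$values_beta)
    expect_equal(mean(ge$values_alpha), ge$network)
    cc <- multilayer_clustering(m, m, s)
    expect_equal(cc$values_alpha, cc$values_beta)
  }
})

test_that("the sigma-and-density sweep is tidy and monotone in sigma", {
  set.seed(306)
  w <- random_signed_matrix(21, p_edge = 1)
  grid <- default_density_grid()
  sg <- default_sigma_grid()
  ml <- multilayer_sweep(w, grid, sg)
  expect_equal(nrow(ml), 2 * length(sg))  # 20 sigmas x 2 measures
  expect_setequal(unique(ml$measure), c("ML-Ge", "ML-CC"))
  ge <- ml$value[ml$measure == "ML-Ge"][order(ml$sigma[ml$measure == "ML-Ge"])]
  expect_true(all(diff(ge) >= -1e-12))

  # cross-check one (density, sigma) cell against the direct computation
  layers <- split_signed_layers(w)
  p <- proportional_threshold(layers$positive$weights, 0.06)
  q <- proportional_threshold(layers$negative$weights, 0.06)
  direct_ge <- multilayer_global_efficiency(p, q, 0.2)$network
  curve <- vapply(grid, function(d) {
    pp <- proportional_threshold(layers$positive$weights, d)
    qq <- proportional_threshold(layers$negative$weights, d)
    multilayer_global_efficiency(pp, qq, 0.2)$network
  }, numeric(1))
  expect_equal(curve[1], direct_ge)
  expect_equal(ml$value[ml$measure == "ML-Ge" & ml$sigma == 0.2],
               measure_auc(grid, curve))
})

test_that("a layer below the density floor produces a constant AUC", {
  # negative layer with 12 edges (6% of 210): identical at every density
  set.seed(307)
  w <- matrix(0, 21, 21)
  up <- which(upper.tri(w))
  pos_sel <- sample(up, 150)
  w[pos_sel] <- runif(150, 0.1, 0.9)
  neg_sel <- sample(setdiff(up, pos_sel), 12)
  w[neg_sel] <- -runif(12, 0.1, 0.9)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  ml <- multilayer_sweep(w)
  expect_equal(nrow(ml), 40)
  expect_true(all(is.finite(ml$value)))
})
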