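test_that("pooled regression is exact on perfectly allometric data", {
  k <- 6
  base <- base_skull_shape(3, 3)
  v <- allometric_direction(base$partition)
  gs <- simulate_growth_series(base$coords, v, slope = 0.2,
                               size_range = c(10, 100), n = 8,
                               noise_sd = 0, seed = 1)
  fit <- pooled_regression(gs$shapes, gs$log_cs)
  expect_equal(fit$slope_scalar, 0.2, tolerance = 1e-9)
  expect_lt(fit$p, 0.01)
  # residual shape variance is zero: scores collinear with log size
  expect_equal(abs(cor(fit$scores, gs$log_cs)), 1, tolerance = 1e-12)
  expect_error(pooled_regression(gs$shapes, rep(1, 8)), "constant")
})

test_that("pooled-regression p is calibrated when shape ignores size", {
  set.seed(2)
  ps <- replicate(200, {
    X <- matrix(rnorm(12 * 10), 12, 10)
    pooled_regression(X, log_cs = runif(12, 1, 3),
                      n_permutations = 199)$p
  })
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.09)
})

test_that("regression score is a projection onto the allometric axis", {
  base <- base_skull_shape(4, 4)
  v <- allometric_direction(base$partition)
  gs <- simulate_growth_series(base$coords, v, slope = 0.3,
                               size_range = c(20, 200), n = 10,
                               noise_sd = 0.01, seed = 3)
  fit <- pooled_regression(gs$shapes, gs$log_cs)
  # fitted value at the mean size scores at the mean score
  fitted_mean <- fit$intercept + fit$b * mean(gs$log_cs)
  expect_equal(regression_score(fit, fitted_mean), mean(fit$scores),
               tolerance = 1e-9)
  # adding a vector orthogonal to b leaves the score unchanged
  u <- fit$b / sqrt(sum(fit$b^2))
  w <- rnorm(length(u)); w <- w - sum(w * u) * u
  s0 <- regression_score(fit, gs$shapes[1, ])
  expect_equal(regression_score(fit, gs$shapes[1, ] + w), s0,
               tolerance = 1e-9)
  # score differences across the series recover the generating slope
  slope_hat <- coef(lm(regression_score(fit, gs$shapes) ~ gs$log_cs))[2]
  expect_equal(unname(slope_hat), 0.3, tolerance = 0.05)
})

test_that("ontogenetic vectors connect smallest and largest specimens", {
  lcs <- c(a = 1.2, b = 3.1)
  sc <- c(a = 0.1, b = 0.6)
  v <- ontogenetic_vector(lcs, sc, label = "sp")
  expect_equal(unname(v$juvenile), c(1.2, 0.1))
  expect_equal(unname(v$adult), c(3.1, 0.6))
  expect_error(ontogenetic_vector(lcs[1], sc[1]), ">= 2")
  lcs3 <- c(a = 2, b = 2, c = 5)
  expect_warning(v3 <- ontogenetic_vector(lcs3, c(a = 1, b = 2, c = 3)),
                 "tie")
  expect_equal(unname(v3$juvenile["score"]), 1)  # id-order tie break
})

test_that("ancestral vectors reconstruct endpoints by SQCP per coordinate", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  va <- ontogenetic_vector(c(j = 1, a = 2), c(j = 0.1, a = 0.5), "A")
  vb <- ontogenetic_vector(c(j = 1, a = 2), c(j = 0.1, a = 0.5), "B")
  anc <- ancestral_vectors(tr, list(A = va, B = vb))
  expect_length(anc, 1L)
  expect_equal(anc[[1]]$juvenile, va$juvenile, tolerance = 1e-10)
  expect_equal(anc[[1]]$adult, va$adult, tolerance = 1e-10)
  expect_true(anc[[1]]$reconstructed)
  # unequal vectors on equal branches: ancestor is the arithmetic mean
  vb2 <- ontogenetic_vector(c(j = 2, a = 4), c(j = 0.3, a = 0.9), "B")
  anc2 <- ancestral_vectors(tr, list(A = va, B = vb2))
  expect_equal(unname(anc2[[1]]$adult), c((2 + 4) / 2, (0.5 + 0.9) / 2),
               tolerance = 1e-10)
  # component-wise consistency with direct sqcp_ancestral calls
  tr4 <- random_tree(4, seed = 9)
  tips <- lapply(tr4$tip.label, function(tp) {
    set.seed(match(tp, tr4$tip.label) * 13)
    ontogenetic_vector(setNames(sort(runif(2, 1, 4)), c("j", "a")),
                       setNames(runif(2), c("j", "a")), tp)
  })
  names(tips) <- tr4$tip.label
  anc4 <- ancestral_vectors(tr4, tips)
  adult_scores <- setNames(
    vapply(tr4$tip.label, function(tp) tips[[tp]]$adult[["score"]],
           numeric(1)), tr4$tip.label)
  direct <- sqcp_ancestral(tr4, adult_scores)
  for (nd in names(direct))
    expect_equal(anc4[[nd]]$adult[["score"]], direct[[nd]],
                 tolerance = 1e-10)
})

test_that("shift classification follows the 1.5 x CI criterion", {
  tr <- random_tree(6, seed = 10)
  nodes <- as.character(7:11)
  # equal scores everywhere: all deltas zero, nothing classified
  sc <- setNames(rep(0.4, 6 + 5), c(tr$tip.label, nodes))
  tab <- shift_table(tr, sc)
  expect_true(all(tab$classification == "none"))
  # one branch with a delta 10x the others is flagged peramorphic
  set.seed(11)
  sc2 <- setNames(rnorm(11, sd = 0.01), c(tr$tip.label, nodes))
  anc_of_t1 <- tr$edge[tr$edge[, 2] == 1, 1]
  sc2[tr$tip.label[1]] <- sc2[as.character(anc_of_t1)] + 0.5
  tab2 <- shift_table(tr, sc2)
  row <- tab2[tab2$descendant == tr$tip.label[1], ]
  expect_equal(row$classification, "peramorphosis")
  expect_gt(row$delta_score, row$threshold)
  # homogeneity: doubling branch lengths halves rates, classes unchanged
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  tab3 <- shift_table(tr2, sc2)
  m <- match(paste(tab2$ancestor, tab2$descendant),
             paste(tab3$ancestor, tab3$descendant))
  expect_equal(tab3$rate[m], tab2$rate / 2, tolerance = 1e-12)
  expect_equal(tab3$classification[m], tab2$classification)
  # additive constant on all scores changes nothing
  tab4 <- shift_table(tr, sc2 + 5)
  m4 <- match(paste(tab2$ancestor, tab2$descendant),
              paste(tab4$ancestor, tab4$descendant))
  expect_equal(tab4$delta_score[m4], tab2$delta_score, tolerance = 1e-12)
  expect_equal(tab4$classification[m4], tab2$classification)
})

test_that("vector angles are exact on canonical cases and clamped", {
  expect_equal(vector_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(vector_angle(c(1, 1), c(2, 2)), 0)
  expect_equal(vector_angle(c(1, 1), c(-1, -1)), 180)
  # near-parallel floating point must not leave [0, 180] or error
  u <- c(1, 1e-8)
  expect_gte(vector_angle(u, u * (1 + 1e-13)), 0)
  expect_error(vector_angle(c(0, 0), c(1, 1)), "zero-length")
})

test_that("angle randomization test is deterministic and bounded", {
  vs <- list(
    ontogenetic_vector(c(j = 1, a = 2), c(j = 0, a = 0.1), "n1"),
    ontogenetic_vector(c(j = 1, a = 2.5), c(j = 0, a = 0.9), "n2"),
    ontogenetic_vector(c(j = 1.2, a = 2.2), c(j = 0.1, a = 0.4), "n3"))
  r1 <- angle_randomization_test(vs, n_vectors = 200, seed = 5)
  r2 <- angle_randomization_test(vs, n_vectors = 200, seed = 5)
  expect_identical(r1$null_angles, r2$null_angles)
  expect_length(r1$null_angles, 100)
  expect_true(all(r1$null_angles >= 0 & r1$null_angles <= 180))
  expect_true(all(r1$percentile >= 0 & r1$percentile <= 1))
  same <- list(vs[[1]], vs[[1]])
  expect_error(angle_randomization_test(same), "degenerate")
})

test_that("heterochrony modes follow the classification rules", {
  anc <- ontogenetic_vector(c(j = 1, a = 2), c(j = 0.1, a = 0.3), "anc")
  expect_equal(classify_modes(anc, anc, angle_percentile = 0), "none")
  # same line, extended adult endpoint: hypermorphosis
  hyper <- ontogenetic_vector(c(j = 1, a = 2.5), c(j = 0.1, a = 0.4), "d")
  expect_equal(classify_modes(anc, hyper, angle_percentile = 0.2),
               "hypermorphosis")
  # steeper descendant over the same size range: acceleration
  acc <- ontogenetic_vector(c(j = 1, a = 2), c(j = 0.1, a = 0.8), "d")
  expect_equal(classify_modes(anc, acc, angle_percentile = 0.95),
               "acceleration")
  shallow <- ontogenetic_vector(c(j = 1, a = 2), c(j = 0.1, a = 0.15), "d")
  expect_equal(classify_modes(anc, shallow, angle_percentile = 0.95),
               "deceleration")
  pre <- ontogenetic_vector(c(j = 0.5, a = 1.5), c(j = 0.0, a = 0.2), "d")
  expect_equal(classify_modes(anc, pre, angle_percentile = 0.1),
               "predisplacement")
})
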