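test_that("Newick reading preserves topology and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  writeLines("(A,B,C);", f)
  expect_equal(read_newick(f)$Nnode, 1L)  # root trifurcation preserved
  writeLines("((A,B),A);", f)
  expect_error(read_newick(f), "duplicate")
})

test_that("equal-method time-scaling reproduces the two-tip arithmetic", {
  tr <- ape::read.tree(text = "(A,B);")
  ages <- data.frame(species = c("A", "B"), FAD_Ma = c(80, 75),
                     LAD_Ma = c(79, 74))
  tt <- timescale(tr, ages, method = "equal", root_extension = 5)
  expect_equal(tt$root_age, 85)
  bl <- setNames(tt$tree$edge.length,
                 tt$tree$tip.label[tt$tree$edge[, 2]])
  expect_equal(bl[["A"]], 5)
  expect_equal(bl[["B"]], 10)
})

test_that("time-scaled trees keep tip ages consistent with path lengths", {
  for (method in c("equal", "punctuated")) {
    tt <- toy_time_tree(method = method)
    expect_true(all(tt$tree$edge.length > 0))
    depths <- ape::node.depth.edgelength(tt$tree)
    n_tip <- length(tt$tree$tip.label)
    fad <- toy_ages()$FAD_Ma[match(tt$tree$tip.label, toy_ages()$species)]
    expect_equal(tt$root_age - depths[seq_len(n_tip)], fad,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(timescale(toy_tree(), toy_ages()[1:3, ]), "missing")
})

test_that("punctuated scaling adds exactly 1 Ma to ghost-free branches", {
  # B's FAD (85) is the oldest: under minimum-age dating its terminal
  # branch and the chain above it are zero-length
  tr <- ape::read.tree(text = "((A,B),C);")
  ages <- data.frame(species = c("A", "B", "C"),
                     FAD_Ma = c(70, 85, 60), LAD_Ma = c(69, 84, 59))
  tt <- timescale(tr, ages, method = "punctuated")
  b_edge <- which(tt$tree$edge[, 2] == which(tt$tree$tip.label == "B"))
  expect_equal(tt$tree$edge.length[b_edge], 1.0)
  # its parent chain also gained 1 Ma each
  expect_equal(tt$root_age, 87)
})

test_that("polytomies are resolved deterministically before dating", {
  tr <- ape::read.tree(text = "(A,B,C,D);")
  ages <- data.frame(species = LETTERS[1:4], FAD_Ma = c(80, 70, 60, 50),
                     LAD_Ma = c(79, 69, 59, 49))
  t1 <- timescale(tr, ages, method = "equal")
  t2 <- timescale(tr, ages, method = "equal")
  expect_true(ape::is.binary(t1$tree))
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_true(all(t1$tree$edge.length > 0))
})

test_that("tree covariance equals shared root-to-MRCA path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  C <- vcv_matrix(tr)
  expect_equal(C["A", "B"], 2)
  expect_equal(C["A", "A"], 3)
  expect_equal(C["A", "C"], 0)
  # brute-force double-loop oracle on random trees
  for (seed in 1:3) {
    tr <- random_tree(8, seed = seed)
    C <- vcv_matrix(tr)
    Cb <- full_node_vcv(tr)[1:8, 1:8]
    dimnames(Cb) <- dimnames(C)
    expect_equal(C, Cb, tolerance = 1e-10)
  }
})

test_that("independent contrasts match the closed form and the GLS slope", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(abs(as.numeric(
    pic_contrasts(tr, c(A = 0, B = 2)))), 2 / sqrt(2), tolerance = 1e-9)
  tr8 <- random_tree(8, seed = 4)
  const <- setNames(rep(3.3, 8), tr8$tip.label)
  expect_equal(max(abs(pic_contrasts(tr8, const))), 0, tolerance = 1e-12)
  # PIC through-origin slope == GLS slope with tree covariance
  x <- sim_bm_trait(tr8, seed = 8)
  y <- sim_bm_trait(tr8, seed = 9)
  fit <- pic_regression(tr8, x, y)
  C <- ape::vcv(tr8)
  Ci <- solve(C)
  one <- rep(1, 8)
  P <- Ci - Ci %*% one %*% t(one) %*% Ci / as.numeric(t(one) %*% Ci %*% one)
  gls_slope <- as.numeric((t(x[tr8$tip.label]) %*% P %*% y[tr8$tip.label]) /
                            (t(x[tr8$tip.label]) %*% P %*% x[tr8$tip.label]))
  expect_equal(fit$slope, gls_slope, tolerance = 1e-8)
  expect_equal(fit$df2, 6L)
})

test_that("PIC regression finds exact dependence and calibrates under null", {
  tr <- random_tree(12, seed = 5)
  x <- sim_bm_trait(tr, seed = 10)
  fit <- pic_regression(tr, x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_lt(fit$p, 1e-10)
  # type-I error under independent BM traits
  rej <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    xs <- sim_bm_trait(tr, seed = 1000 + 2 * r)
    ys <- sim_bm_trait(tr, seed = 1001 + 2 * r)
    if (pic_regression(tr, xs, ys)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.03)
  expect_lt(rej / n_rep, 0.07)
})

test_that("squared-change parsimony equals the GLS Brownian oracle", {
  tr2 <- ape::read.tree(text = "(A:2,B:1);")
  anc <- sqcp_ancestral(tr2, c(A = 1, B = 4))
  expect_equal(as.numeric(anc), (1 / 2 + 4 / 1) / (1 / 2 + 1 / 1),
               tolerance = 1e-12)
  tr <- random_tree(6, seed = 6)
  const <- setNames(rep(-1.5, 6), tr$tip.label)
  expect_equal(as.numeric(sqcp_ancestral(tr, const)), rep(-1.5, tr$Nnode),
               tolerance = 1e-10)
  for (seed in 1:4) {
    n <- 5 + seed
    tr <- random_tree(n, seed = 60 + seed)
    x <- sim_bm_trait(tr, seed = 70 + seed)
    mine <- sqcp_ancestral(tr, x)
    oracle <- gls_ancestral_oracle(tr, x)
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-8)
  }
})

test_that("squared-change parsimony agrees with an independent ML routine", {
  skip_if_not_installed("phytools")
  tr <- random_tree(10, seed = 77)
  x <- sim_bm_trait(tr, seed = 78)
  mine <- sqcp_ancestral(tr, x)
  ref <- phytools::fastAnc(tr, x)
  expect_equal(as.numeric(mine[names(ref)]), as.numeric(ref),
               tolerance = 1e-6)
})

test_that("scaling-parameter fits reduce to plain BM at parameter 1", {
  tt <- simulate_fossil_tree(10, seed = 3)
  x <- sim_bm_trait(tt$tree, seed = 30)
  bm <- fit_bm_model(tt, x, "BM")
  for (m in c("lambda", "kappa", "delta")) {
    f1 <- fit_bm_model(tt, x, m, fixed_value = 1)
    expect_equal(f1$loglik, bm$loglik, tolerance = 1e-8)
  }
  # lambda = 0 reduces to independent normals with variances sigma2*diag(C)
  f0 <- fit_bm_model(tt, x, "lambda", fixed_value = 0)
  C <- ape::vcv(tt$tree)
  xo <- x[tt$tree$tip.label]
  star_ll <- function(mu, s2) sum(stats::dnorm(xo, mu, sqrt(s2 * diag(C)),
                                               log = TRUE))
  expect_equal(f0$loglik, star_ll(f0$root_state, f0$sigma2),
               tolerance = 1e-8)
  # directional model needs a non-ultrametric tree and estimates a trend
  depths <- diag(C)
  xd <- xo + 0.8 * depths
  names(xd) <- names(xo)
  fd <- fit_bm_model(tt, xd, "directional")
  expect_gt(fd$loglik, fit_bm_model(tt, xd, "BM")$loglik - 1e-8)
})

test_that("model table sorts by AICc and reports LR against BM", {
  tt <- simulate_fossil_tree(12, seed = 4)
  x <- sim_bm_trait(tt$tree, seed = 44)
  bm <- fit_bm_model(tt, x, "BM")
  expect_equal(model_table(list(bm))$delta_aicc, 0)
  lam <- fit_bm_model(tt, x, "lambda", fixed_value = 1)
  tab <- model_table(list(bm, lam))
  expect_equal(tab$lr_vs_bm[tab$model == "lambda"], 0, tolerance = 1e-8)
  expect_equal(tab$aicc, sort(tab$aicc))
  small <- fit_bm_model(simulate_fossil_tree(6, seed = 5),
                        sim_bm_trait(simulate_fossil_tree(6, seed = 5)$tree,
                                     seed = 55), "BM")
  expect_error(model_table(list(bm, small)), "identical data")
})

test_that("lambda is recovered from Brownian simulations", {
  tt <- simulate_fossil_tree(25, seed = 9)
  lam <- numeric(60)
  for (r in seq_along(lam)) {
    x <- sim_bm_trait(tt$tree, seed = 900 + r)
    lam[r] <- fit_bm_model(tt, x, "lambda")$parameter
  }
  expect_gte(median(lam), 0.8)
})
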