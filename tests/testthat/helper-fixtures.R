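# Fixture builders shared across the test files. Everything is generated in
# code; no binary data.

square_config <- function(id = "sq", scale = NULL) {
  landmark_config(rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1)),
                  specimen_id = id, scale = scale)
}

# skull-ish asymmetric test configuration with midline + paired points
bilateral_config <- function(id = "bi") {
  coords <- rbind(
    c(0, 2),      # 1 midline (rostral)
    c(0, -2),     # 2 midline (caudal)
    c(-1.5, 1),   # 3 left
    c(1.5, 1),    # 4 right
    c(-1, -1),    # 5 left
    c(1, -1))     # 6 right
  landmark_config(coords, specimen_id = id,
                  midline_ids = c(1L, 2L),
                  pair_map = rbind(c(3L, 4L), c(5L, 6L)))
}

# random non-degenerate k-point configuration
random_config <- function(k = 10, seed = 1, id = paste0("r", seed)) {
  set.seed(seed)
  landmark_config(matrix(rnorm(2 * k, sd = 2), ncol = 2), specimen_id = id)
}

apply_similarity <- function(coords, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * coords %*% t(R), 2, shift, `+`)
}

# small fixed fossil tree: ((A,B),(C,D)); with staggered ages
toy_tree <- function() {
  ape::read.tree(text = "((A,B),(C,D));")
}

toy_ages <- function() {
  data.frame(species = c("A", "B", "C", "D"),
             FAD_Ma = c(80, 75, 70, 85),
             LAD_Ma = c(78, 72, 69, 82))
}

toy_time_tree <- function(method = "equal") {
  timescale(toy_tree(), toy_ages(), method = method, root_extension = 5)
}

# random binary tree with positive branch lengths, deterministic per seed
random_tree <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# simulate one Brownian-motion trait on a tree
sim_bm_trait <- function(tree, seed = 1, sigma = 1) {
  set.seed(seed)
  C <- ape::vcv(tree)
  x <- as.numeric(t(chol(C)) %*% rnorm(nrow(C), sd = sigma))
  names(x) <- rownames(C)
  x
}

# GLS oracle for BM ancestral states: for each internal node, the ML state
# is the GLS prediction E[x_node | tips] under joint Brownian motion.
gls_ancestral_oracle <- function(tree, trait) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  Cfull <- full_node_vcv(tree)
  tips <- seq_len(n_tip)
  ints <- n_tip + seq_len(n_node)
  C <- Cfull[tips, tips]
  Ci <- solve(C)
  one <- rep(1, n_tip)
  x <- trait[tree$tip.label]
  mu <- as.numeric(crossprod(one, Ci %*% x) / crossprod(one, Ci %*% one))
  vals <- vapply(ints, function(nd) {
    cvec <- Cfull[nd, tips]
    mu + as.numeric(cvec %*% Ci %*% (x - mu))
  }, numeric(1))
  names(vals) <- as.character(ints)
  vals
}

# shared path lengths between ALL nodes (tips + internal), brute force
full_node_vcv <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  parent <- rep(NA_integer_, n_all)
  plen <- rep(0, n_all)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(nd) {
    out <- integer(0)
    while (!is.na(nd)) { out <- c(out, nd); nd <- parent[nd] }
    out
  }
  depth <- function(nd) {
    d <- 0
    while (!is.na(parent[nd])) { d <- d + plen[nd]; nd <- parent[nd] }
    d
  }
  C <- matrix(0, n_all, n_all)
  for (i in seq_len(n_all)) for (j in seq_len(i)) {
    pi_ <- path_to_root(i); pj <- path_to_root(j)
    mrca <- pi_[pi_ %in% pj][1L]
    C[i, j] <- C[j, i] <- depth(mrca)
  }
  C
}

# iid multivariate-normal specimens with a block trait covariance; used for
# the modularity calibration tests (no tree structure)
sim_block_specimens <- function(n, k1, k2, rho_w, rho_b, seed = 1) {
  set.seed(seed)
  part <- c(rep("m1", k1), rep("m2", k2))
  col_module <- rep(part, each = 2)
  G <- ifelse(outer(col_module, col_module, `==`), rho_w, rho_b)
  diag(G) <- 1
  X <- matrix(rnorm(n * 2 * (k1 + k2)), n) %*% chol(G)
  list(X = X, partition = part)
}
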