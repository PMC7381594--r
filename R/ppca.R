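#' Phylogenetic principal components analysis
#'
#' PCA of per-species shape (or any multivariate trait) data under a
#' Brownian-motion model of evolution: the mean is the generalized
#' least-squares (phylogenetic) mean, the decomposed matrix is the
#' evolutionary covariance R = (X - 1a)' C^-1 (X - 1a) / (n - 1) with C the
#' tree covariance, and scores are projections of the GLS-centered data on
#' the eigenvectors. With a star tree of equal branch lengths this reduces
#' exactly to ordinary PCA.
#'
#' Axis signs are fixed by making each axis's largest-magnitude loading
#' positive, so results are deterministic.
#'
#' @param shapes species x 2k matrix, row names = species matching the tips.
#' @param tree `time_tree` or `phylo` with branch lengths covering exactly
#'   those species.
#' @param mode `"covariance"` (default) or `"correlation"` (decompose the
#'   correlation rescaling of R).
#' @return object of class `ppca_result`: list with `eigenvalues`,
#'   `percent_variance`, `loadings` (2k x axes), `scores` (species x axes),
#'   `phylo_mean` (2k vector), `mode`.
#' @export
phylo_pca <- function(shapes, tree, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  phy <- as_phylo(tree)
  shapes <- as.matrix(shapes)
  if (is.null(rownames(shapes)))
    stop("shapes must have species row names")
  extra <- setdiff(rownames(shapes), phy$tip.label)
  missing <- setdiff(phy$tip.label, rownames(shapes))
  if (length(extra) || length(missing))
    stop("species/tip mismatch; not in tree: ",
         paste(extra, collapse = ", "), "; not in data: ",
         paste(missing, collapse = ", "))
  X <- shapes[phy$tip.label, , drop = FALSE]
  C <- ape::vcv(phy)
  n <- nrow(X)
  Ci <- solve(C)
  one <- matrix(1, n, 1L)
  a <- as.numeric(solve(t(one) %*% Ci %*% one, t(one) %*% Ci %*% X))
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, Ci %*% Xc) / (n - 1)
  if (mode == "correlation") {
    s <- sqrt(diag(R))
    if (any(s <= 0))
      stop("correlation mode undefined: zero-variance coordinate(s)")
    R <- R / tcrossprod(s)
  }
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  V <- eig$vectors
  # deterministic axis signs
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  pct <- 100 * vals / sum(vals)
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(ncol(V)))
  rownames(scores) <- rownames(X)
  structure(list(eigenvalues = vals, percent_variance = pct,
                 loadings = V, scores = scores, phylo_mean = a,
                 mode = mode),
            class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat("Phylogenetic PCA (", x$mode, " mode): ", nrow(x$scores),
      " species, ", length(x$eigenvalues), " axes\n", sep = "")
  nshow <- min(5L, length(x$percent_variance))
  cat("  % variance:",
      paste0(sprintf("PC%d=%.1f", seq_len(nshow),
                     x$percent_variance[seq_len(nshow)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Species at the extremes of a pPC axis
#'
#' Identifies the species with the minimum and maximum score on an axis and
#' returns their shape deformations (difference from the phylogenetic mean),
#' reshaped to landmark coordinates. Ties are broken by species-name order
#' with a warning.
#'
#' @param result a `ppca_result`.
#' @param axis axis index.
#' @return list with `negative` and `positive`, each a list of `species`,
#'   `shape` (k x 2) and `deformation` (k x 2).
#' @export
axis_extremes <- function(result, axis = 1L) {
  sc <- result$scores[, axis]
  if (axis < 1L || axis > ncol(result$scores)) stop("axis out of range")
  ord <- order(sc, rownames(result$scores))
  lo <- ord[1L]
  hi <- ord[length(ord)]
  if (sum(sc == sc[lo]) > 1L || sum(sc == sc[hi]) > 1L)
    warning("tie for an axis extreme; first species by name order chosen")
  mk <- function(i) {
    list(species = rownames(result$scores)[i],
         shape = shape_to_coords(result$phylo_mean +
                                   as.numeric(result$loadings %*%
                                                result$scores[i, ])),
         deformation = shape_to_coords(as.numeric(
           result$loadings %*% result$scores[i, ])))
  }
  list(negative = mk(lo), positive = mk(hi))
}
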