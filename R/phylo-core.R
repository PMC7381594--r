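#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that validates tip-name uniqueness.
#' Polytomies are preserved.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

# node ages (time before present) from root age and edge lengths
node_ages <- function(tree, root_age) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  root_age - depth
}

ages_to_edge_lengths <- function(tree, ages) {
  ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
}

#' Time-scale a fossil phylogeny from appearance dates
#'
#' Calibrates node ages against per-tip first (FAD) and last (LAD)
#' appearance dates in Ma. Each tip is placed at its FAD; each internal node
#' is initially as old as its oldest descendant tip. Two rules then remove
#' the zero-length branches this "minimum-age" dating creates:
#'
#' * `method = "equal"`: time from the nearest strictly older ancestor is
#'   shared out equally along each chain of equal-aged nodes, so every
#'   branch gains positive duration while tip ages stay fixed.
#' * `method = "punctuated"`: exactly 1 Ma is added to each initially
#'   zero-length branch (those leading toward the oldest tip of a clade,
#'   i.e. lineages with no implied ghost duration), shifting ancestral node
#'   ages deeper while keeping all descendant ages fixed.
#'
#' Polytomies are first resolved to zero-length branches deterministically
#' (alphabetically by subtended tip names); the dating rules then give those
#' branches positive length.
#'
#' @param tree rooted `phylo` tree (branch lengths, if any, are ignored).
#' @param tip_ages data frame with columns `species`, `FAD_Ma`, `LAD_Ma`.
#' @param method `"equal"` or `"punctuated"`.
#' @param root_extension Ma added to the root age above the oldest FAD
#'   (default 1; guarantees the root branch has positive duration).
#' @return object of class `time_tree`: list with `tree` (a `phylo` with
#'   branch lengths in Ma), `tip_ages`, `root_age`, `node_age` (ages of all
#'   nodes, tips first), and `method`.
#' @export
timescale <- function(tree, tip_ages, method = c("equal", "punctuated"),
                      root_extension = 1) {
  method <- match.arg(method)
  missing_tips <- setdiff(tree$tip.label, tip_ages$species)
  if (length(missing_tips))
    stop("tips missing from the age table: ",
         paste(missing_tips, collapse = ", "))
  fad <- tip_ages$FAD_Ma[match(tree$tip.label, tip_ages$species)]
  lad <- tip_ages$LAD_Ma[match(tree$tip.label, tip_ages$species)]
  if (any(fad < lad)) stop("FAD must be >= LAD for every tip")
  if (any(fad <= 0)) stop("FADs must be positive")
  if (!ape::is.binary(tree))
    tree <- resolve_polytomies(tree)
  tree$edge.length <- NULL
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  ages <- numeric(n_node)
  ages[seq_len(n_tip)] <- fad
  # postorder (children before parents): node age = oldest descendant FAD
  for (nd in postorder_nodes(tree)) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    ages[nd] <- max(ages[ch])
  }
  ages[root] <- ages[root] + root_extension
  if (method == "equal") {
    ages <- equal_redistribute(tree, ages, root)
  } else {
    ages <- punctuate_ages(tree, ages, root, add = 1.0)
  }
  tree$edge.length <- ages_to_edge_lengths(tree, ages)
  if (any(tree$edge.length <= 0))
    stop("internal error: non-positive branch length after calibration")
  structure(list(tree = tree, tip_ages = tip_ages, root_age = ages[root],
                 node_age = ages, method = method),
            class = "time_tree")
}

# Deterministic resolution of polytomies: children ordered alphabetically by
# the name of their alphabetically first subtended tip, then combined into a
# ladder with zero-length internal branches.
resolve_polytomies <- function(tree) {
  tr <- ape::multi2di(tree, random = FALSE)
  tr$edge.length <- NULL
  tr
}

postorder_nodes <- function(tree) {
  # internal nodes ordered parents-before-children (preorder); reverse for
  # postorder use
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    stack <- c(stack, ch[ch > n_tip])
  }
  rev(out)  # children before parents
}

parent_of <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p)) p else NA_integer_
}

# "equal" rule: for every zero-length branch, walk up to the nearest strictly
# older ancestor and space the intervening equal-aged node ages evenly
# between that ancestor's age and the branch's child age.
equal_redistribute <- function(tree, ages, root) {
  repeat {
    el <- ages_to_edge_lengths(tree, ages)
    zero <- which(el <= 1e-12)
    if (!length(zero)) return(ages)
    e <- zero[1L]
    child <- tree$edge[e, 2]
    chain <- tree$edge[e, 1]  # ancestors with age == age[child]
    a <- parent_of(tree, chain[1L])
    while (!is.na(a) && ages[a] <= ages[child] + 1e-12) {
      chain <- c(chain, a)
      a <- parent_of(tree, a)
    }
    if (is.na(a))
      stop("root has no slack to redistribute; increase root_extension")
    # chain is ordered child-side -> root-side; space ages evenly
    m <- length(chain)
    new_ages <- ages[child] + seq_len(m) * (ages[a] - ages[child]) / (m + 1)
    ages[chain] <- new_ages
  }
}

# "punctuated" rule: postorder pass; each initially zero-length branch gets
# 1 Ma by pushing its parent deeper (descendant ages stay fixed); branches
# with positive initial duration keep at least that duration.
punctuate_ages <- function(tree, ages, root, add = 1.0) {
  init_len <- ages_to_edge_lengths(tree, ages)
  for (nd in postorder_nodes(tree)) {
    ch_edges <- which(tree$edge[, 1] == nd)
    req <- vapply(ch_edges, function(e) {
      child <- tree$edge[e, 2]
      len <- if (init_len[e] <= 1e-12) add else init_len[e]
      ages[child] + len
    }, numeric(1))
    ages[nd] <- max(ages[nd], req)
  }
  ages
}

#' @export
print.time_tree <- function(x, ...) {
  cat("Time-calibrated tree (", x$method, " method): ",
      length(x$tree$tip.label), " tips, root age ",
      format(x$root_age, digits = 6), " Ma\n", sep = "")
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "time_tree")) tree$tree else tree
}

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip path lengths. This is the covariance structure
#' of a trait evolving by Brownian motion on the tree.
#'
#' @param tree a `time_tree` or `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix with tip-name dimnames.
#' @export
vcv_matrix <- function(tree) {
  ape::vcv(as_phylo(tree))
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's standardized contrasts: at each internal node the
#' difference of daughter values divided by the square root of the summed
#' (pruning-adjusted) branch lengths; n - 1 contrasts for n tips.
#'
#' @param tree `time_tree` or binary `phylo` with positive branch lengths.
#' @param trait named per-tip numeric vector (names = tip labels).
#' @return numeric vector of n - 1 standardized contrasts.
#' @export
pic_contrasts <- function(tree, trait) {
  phy <- as_phylo(tree)
  if (!ape::is.binary(phy))
    stop("PIC requires a binary tree; time-scale after resolving polytomies")
  if (!all(phy$tip.label %in% names(trait)))
    stop("trait values missing for: ",
         paste(setdiff(phy$tip.label, names(trait)), collapse = ", "))
  ape::pic(trait[phy$tip.label], phy)
}

#' Through-origin regression of independent contrasts
#'
#' Regresses the contrasts of `y` on the contrasts of `x` through the
#' origin — the phylogenetically corrected regression of y on x. The F test
#' uses n - 2 denominator degrees of freedom (n tips, n - 1 contrasts, one
#' slope).
#'
#' @param tree `time_tree` or binary `phylo`.
#' @param x,y named per-tip numeric vectors.
#' @return list with `slope`, `F`, `p`, `df1`, `df2`, and the contrast
#'   vectors `cx`, `cy`.
#' @export
pic_regression <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)
  cy <- pic_contrasts(tree, y)
  if (sum(cx^2) <= 0) stop("zero variance in x contrasts")
  slope <- sum(cx * cy) / sum(cx^2)
  rss <- sum((cy - slope * cx)^2)
  df2 <- length(cx) - 1L
  ssr <- slope^2 * sum(cx^2)
  Fstat <- if (rss > 0) (ssr / 1) / (rss / df2) else Inf
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  list(slope = slope, F = Fstat, p = p, df1 = 1L, df2 = df2,
       cx = cx, cy = cy)
}

#' Squared-change parsimony ancestral states
#'
#' Internal-node values minimizing the sum over branches of
#' (child - parent)^2 / branch length. With branch-length weighting this is
#' the unique solution of a sparse linear system and coincides with the
#' maximum-likelihood Brownian-motion ancestral states.
#'
#' @param tree `time_tree` or `phylo` with positive branch lengths.
#' @param trait named per-tip numeric vector.
#' @return named numeric vector of internal-node states (names = node
#'   numbers, root first in `ape` numbering n_tip + 1, ...).
#' @export
sqcp_ancestral <- function(tree, trait) {
  phy <- as_phylo(tree)
  if (any(phy$edge.length <= 0)) stop("branch lengths must be positive")
  n_tip <- length(phy$tip.label)
  if (!all(phy$tip.label %in% names(trait)))
    stop("trait values missing for: ",
         paste(setdiff(phy$tip.label, names(trait)), collapse = ", "))
  x <- trait[phy$tip.label]
  n_int <- phy$Nnode
  # minimize sum over edges w_e (v_child - v_parent)^2, w = 1/length;
  # unknowns are the internal-node values
  A <- matrix(0, n_int, n_int)
  b <- numeric(n_int)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1] - n_tip
    ch <- phy$edge[e, 2]
    w <- 1 / phy$edge.length[e]
    A[p, p] <- A[p, p] + w
    if (ch > n_tip) {
      ci <- ch - n_tip
      A[ci, ci] <- A[ci, ci] + w
      A[p, ci] <- A[p, ci] - w
      A[ci, p] <- A[ci, p] - w
    } else {
      b[p] <- b[p] + w * x[ch]
    }
  }
  v <- solve(A, b)
  names(v) <- as.character(n_tip + seq_len(n_int))
  v
}

# log-likelihood of a multivariate-normal BM model given covariance C and
# design matrix X for the mean; sigma2 and mean coefficients profiled out.
bm_profile_loglik <- function(trait, C, X) {
  n <- length(trait)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  Ci_x <- backsolve(ch, forwardsolve(t(ch), trait))
  Ci_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtCiX <- crossprod(X, Ci_X)
  beta <- tryCatch(solve(XtCiX, crossprod(X, Ci_x)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  resid <- trait - X %*% beta
  Ci_r <- backsolve(ch, forwardsolve(t(ch), resid))
  sigma2 <- as.numeric(crossprod(resid, Ci_r)) / n
  if (sigma2 <= 0) return(NULL)
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(loglik = ll, sigma2 = sigma2, beta = as.numeric(beta))
}

transform_vcv <- function(tree, model, theta, C0 = NULL) {
  phy <- as_phylo(tree)
  if (is.null(C0)) C0 <- ape::vcv(phy)
  switch(model,
    lambda = {
      Cl <- C0 * theta
      diag(Cl) <- diag(C0)
      Cl
    },
    kappa = {
      phy$edge.length <- phy$edge.length^theta
      ape::vcv(phy)
    },
    delta = C0^theta,
    C0)
}

#' Fit a Brownian-motion model with optional tree transformation
#'
#' Maximum-likelihood fit of a univariate trait under Brownian motion on the
#' tree, with the mean either constant (root state) or trending with
#' root-to-tip path length (`directional`, identifiable only on
#' non-ultrametric trees), and the covariance optionally transformed by one
#' of Pagel's scaling parameters: `lambda` multiplies off-diagonal
#' covariances (phylogenetic signal), `kappa` raises each branch length to a
#' power (rate vs branch length), `delta` raises node depths to a power
#' (early vs late burst). The rate sigma^2 and mean parameters are profiled
#' analytically; the scaling parameter is optimized numerically within
#' lambda in [0, 1], kappa in [0, 3], delta in (0, 3].
#'
#' @param tree `time_tree` or `phylo` with branch lengths.
#' @param trait named per-tip numeric vector.
#' @param model one of `"BM"`, `"directional"`, `"lambda"`, `"kappa"`,
#'   `"delta"`.
#' @param fixed_value optional fixed value of the scaling parameter.
#' @return object of class `evo_model_fit`: list with `model`, `parameter`,
#'   `sigma2`, `root_state`, `beta` (directional trend, else NA), `loglik`,
#'   `aicc`, `k` (free parameters), `n`.
#' @export
fit_bm_model <- function(tree, trait,
                         model = c("BM", "directional", "lambda", "kappa",
                                   "delta"),
                         fixed_value = NULL) {
  model <- match.arg(model)
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  if (n < 4L) stop("need >= 4 tips")
  if (!all(phy$tip.label %in% names(trait)))
    stop("trait values missing for: ",
         paste(setdiff(phy$tip.label, names(trait)), collapse = ", "))
  x <- as.numeric(trait[phy$tip.label])
  X <- matrix(1, n, 1L)
  if (model == "directional") {
    depths <- diag(ape::vcv(phy))
    if (stats::sd(depths) < 1e-10)
      stop("directional model is unidentifiable on an ultrametric tree")
    X <- cbind(X, depths)
  }
  C0 <- ape::vcv(phy)
  obj <- function(theta) {
    C <- transform_vcv(tree, model, theta, C0 = C0)
    fit <- bm_profile_loglik(x, C, X)
    if (is.null(fit)) return(-1e10)
    fit$loglik
  }
  bounds <- switch(model, lambda = c(0, 1), kappa = c(0, 3),
                   delta = c(1e-6, 3), NULL)
  theta <- NA_real_
  n_theta <- 0L
  if (model %in% c("lambda", "kappa", "delta")) {
    if (!is.null(fixed_value)) {
      theta <- fixed_value
    } else {
      opt <- stats::optimize(obj, interval = bounds, maximum = TRUE,
                             tol = 1e-8)
      # the optimum can sit on a boundary; compare against both ends
      cand <- c(opt$maximum, bounds)
      vals <- vapply(cand, obj, numeric(1))
      theta <- cand[which.max(vals)]
      n_theta <- 1L
    }
  }
  C <- transform_vcv(tree, model, theta, C0 = C0)
  fit <- bm_profile_loglik(x, C, X)
  if (is.null(fit))
    stop("non-positive-definite transformed covariance at theta = ", theta)
  k <- 2L + n_theta + (model == "directional")
  aic <- -2 * fit$loglik + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  structure(
    list(model = model, parameter = theta, sigma2 = fit$sigma2,
         root_state = fit$beta[1],
         beta = if (model == "directional") fit$beta[2] else NA_real_,
         loglik = fit$loglik, aicc = aicc, k = k, n = n),
    class = "evo_model_fit")
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat("Evolutionary model fit: ", x$model, "\n", sep = "")
  if (!is.na(x$parameter))
    cat("  scaling parameter: ", format(x$parameter, digits = 5), "\n",
        sep = "")
  cat("  sigma2 = ", format(x$sigma2, digits = 5),
      ", root state = ", format(x$root_state, digits = 5), "\n", sep = "")
  cat("  logLik = ", format(x$loglik, digits = 7),
      ", AICc = ", format(x$aicc, digits = 7), " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Model-comparison table
#'
#' Sorts fits by AICc and adds delta-AICc and the likelihood-ratio statistic
#' of each model against plain Brownian motion.
#'
#' @param fits list of `evo_model_fit` objects on the same data.
#' @return data frame with columns model, parameter, loglik, aicc,
#'   delta_aicc, lr_vs_bm.
#' @export
model_table <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits are not on identical data (tip counts differ)")
  bm_ll <- NA_real_
  bm <- Filter(function(f) f$model == "BM", fits)
  if (length(bm)) bm_ll <- bm[[1L]]$loglik
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    parameter = vapply(fits, `[[`, numeric(1), "parameter"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$lr_vs_bm <- if (is.na(bm_ll)) NA_real_ else 2 * (tab$loglik - bm_ll)
  tab[order(tab$aicc), , drop = FALSE]
}
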