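#' Pooled multivariate regression of shape on log centroid size
#'
#' Per-coordinate least-squares regression of the aligned shape coordinates
#' on log centroid size across all specimens. The stacked slope vector `b`
#' is the multivariate allometric direction; the scalar slope and F
#' statistic come from the univariate regression of the regression score
#' (projection onto b/||b||) on log centroid size.
#'
#' Because the projection direction b is itself estimated from the data,
#' the parametric F-test p-value of the score regression is strongly
#' anti-conservative; the reported p-value therefore comes from a
#' permutation test that reshuffles log centroid size and refits the whole
#' multivariate regression each time.
#'
#' @param aligned_shapes specimens x 2k matrix (or `aligned_sample`).
#' @param log_cs per-specimen log centroid sizes (taken from the
#'   `aligned_sample` when omitted).
#' @param n_permutations size permutations for the p-value (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `allometric_model`: list with `b`, `intercept`,
#'   `slope_scalar`, `F`, `p`, `n`, `mean_shape`, `mean_log_cs`, `scores`,
#'   `log_cs`.
#' @export
pooled_regression <- function(aligned_shapes, log_cs = NULL,
                              n_permutations = 999L, seed = 1L) {
  X <- if (inherits(aligned_shapes, "aligned_sample")) aligned_shapes$shapes
       else as.matrix(aligned_shapes)
  if (is.null(log_cs) && inherits(aligned_shapes, "aligned_sample"))
    log_cs <- log(aligned_shapes$centroid_sizes)
  if (is.null(log_cs)) stop("log_cs must be supplied")
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 specimens")
  if (stats::sd(log_cs) <= 0) stop("log centroid size is constant")
  xc <- log_cs - mean(log_cs)
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  b <- as.numeric(crossprod(Xc, xc)) / sum(xc^2)
  intercept <- mean_shape - b * mean(log_cs)
  if (sqrt(sum(b^2)) <= 0) stop("zero allometric vector")
  u <- b / sqrt(sum(b^2))
  scores <- as.numeric(Xc %*% u)
  slope <- sum(scores * xc) / sum(xc^2)
  sse <- sum((scores - mean(scores) - slope * xc)^2)
  ssr <- slope^2 * sum(xc^2)
  Fstat <- if (sse > 0) ssr / (sse / (n - 2L)) else Inf
  # statistic for the permutation test: norm of the multivariate slope
  # (equals the score slope by construction)
  rng <- local_rng(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    xp <- xc[rng$sample_int(n)]
    bp <- as.numeric(crossprod(Xc, xp)) / sum(xp^2)
    if (sqrt(sum(bp^2)) >= slope) exceed <- exceed + 1L
  }
  p <- (1L + exceed) / (1L + n_permutations)
  structure(list(b = b, intercept = intercept, slope_scalar = slope,
                 F = Fstat, p = p, n = n,
                 mean_shape = mean_shape, mean_log_cs = mean(log_cs),
                 scores = stats::setNames(scores, rownames(X)),
                 log_cs = log_cs),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat("Pooled allometric regression (n = ", x$n, ")\n", sep = "")
  cat("  regression-score slope on log CS = ",
      format(x$slope_scalar, digits = 4), ", F = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Regression score of a shape
#'
#' Projection of the (sample-mean-centered) shape onto the normalized
#' allometric vector b/||b||; the scalar shape variable used in the
#' allometric and heterochrony plots.
#'
#' @param model an `allometric_model`.
#' @param shape 2k vector (or matrix of shapes in rows).
#' @return numeric scalar (or vector).
#' @export
regression_score <- function(model, shape) {
  u <- model$b / sqrt(sum(model$b^2))
  if (is.matrix(shape)) {
    if (ncol(shape) != length(u)) stop("shape dimension mismatch")
    as.numeric(sweep(shape, 2, model$mean_shape) %*% u)
  } else {
    if (length(shape) != length(u)) stop("shape dimension mismatch")
    sum((shape - model$mean_shape) * u)
  }
}

#' Ontogenetic vector of one species
#'
#' Connects the smallest and largest sampled specimens of a species in the
#' (log centroid size, regression score) plane. Ties on size are broken by
#' specimen-id order with a warning.
#'
#' @param log_cs named per-specimen log centroid sizes (>= 2 specimens).
#' @param scores named per-specimen regression scores (same specimens).
#' @param label species (or node) name.
#' @param reconstructed flag marking reconstructed ancestral vectors.
#' @return object of class `onto_vector`: list with `label`, `juvenile` and
#'   `adult` (each c(log_cs, score)), `reconstructed`.
#' @export
ontogenetic_vector <- function(log_cs, scores, label = "species",
                               reconstructed = FALSE) {
  if (length(log_cs) < 2L) stop("need >= 2 specimens")
  ids <- names(log_cs)
  if (is.null(ids)) ids <- as.character(seq_along(log_cs))
  ord <- order(log_cs, ids)
  lo <- ord[1L]; hi <- ord[length(ord)]
  if (sum(log_cs == log_cs[lo]) > 1L || sum(log_cs == log_cs[hi]) > 1L)
    warning("tie on centroid size; endpoint chosen by specimen-id order")
  structure(list(label = label,
                 juvenile = c(log_cs = unname(log_cs[lo]),
                              score = unname(scores[lo])),
                 adult = c(log_cs = unname(log_cs[hi]),
                           score = unname(scores[hi])),
                 reconstructed = reconstructed),
            class = "onto_vector")
}

onto_displacement <- function(v) {
  unname(c(v$adult[1] - v$juvenile[1], v$adult[2] - v$juvenile[2]))
}

#' Reconstruct ancestral ontogenetic vectors
#'
#' Reconstructs each of the four endpoint coordinates (juvenile log centroid
#' size, juvenile score, adult log centroid size, adult score) independently
#' at every internal node by branch-length-weighted squared-change parsimony
#' on the time-scaled tree.
#'
#' @param tree a `time_tree` (or `phylo` with positive branch lengths).
#' @param tip_vectors named list of `onto_vector` objects, one per tip.
#' @param node_labels optional named character vector mapping internal node
#'   numbers (as character) to clade names.
#' @return named list of reconstructed `onto_vector` objects, one per
#'   internal node.
#' @export
ancestral_vectors <- function(tree, tip_vectors, node_labels = NULL) {
  phy <- as_phylo(tree)
  missing <- setdiff(phy$tip.label, names(tip_vectors))
  if (length(missing))
    stop("tip vectors missing for: ", paste(missing, collapse = ", "))
  comp <- function(get) {
    stats::setNames(vapply(phy$tip.label,
                           function(tp) get(tip_vectors[[tp]]), numeric(1)),
                    phy$tip.label)
  }
  anc <- list(
    jl = sqcp_ancestral(tree, comp(function(v) v$juvenile[1])),
    js = sqcp_ancestral(tree, comp(function(v) v$juvenile[2])),
    al = sqcp_ancestral(tree, comp(function(v) v$adult[1])),
    as = sqcp_ancestral(tree, comp(function(v) v$adult[2])))
  nodes <- names(anc$jl)
  out <- lapply(nodes, function(nd) {
    lbl <- if (!is.null(node_labels) && nd %in% names(node_labels))
      node_labels[[nd]] else paste0("node_", nd)
    structure(list(label = lbl,
                   juvenile = c(log_cs = anc$jl[[nd]], score = anc$js[[nd]]),
                   adult = c(log_cs = anc$al[[nd]], score = anc$as[[nd]]),
                   reconstructed = TRUE),
              class = "onto_vector")
  })
  stats::setNames(out, nodes)
}

#' Allometric-shift table over all branches
#'
#' For every ancestor-to-descendant branch of the tree, computes the
#' difference in adult regression score (descendant minus ancestor), flags
#' it as a significant shift when its magnitude exceeds 1.5 times the 95%
#' t-based confidence-interval half-width of the mean of all branch
#' differences, classifies significant positive shifts as peramorphosis and
#' negative ones as paedomorphosis, and divides each difference by the
#' branch duration (Ma) to give a rate. Records are sorted by |rate| and
#' labeled with rate quartiles.
#'
#' @param tree a `time_tree` (or `phylo` with branch lengths in Ma).
#' @param adult_scores named numeric vector of adult regression scores for
#'   every tip (by tip label) and every internal node (by node number as
#'   character, as returned by [sqcp_ancestral()]).
#' @param node_labels optional named character vector mapping node numbers
#'   to clade names for reporting.
#' @param ci_level confidence level of the interval (default 0.95).
#' @param ci_factor multiplier of the CI half-width (default 1.5).
#' @return data frame of class `shift_table` with columns ancestor,
#'   descendant, delta_score, threshold, classification, branch_ma, rate,
#'   rate_quartile.
#' @export
shift_table <- function(tree, adult_scores, node_labels = NULL,
                        ci_level = 0.95, ci_factor = 1.5) {
  phy <- as_phylo(tree)
  n_tip <- length(phy$tip.label)
  node_name <- function(nd) {
    key <- as.character(nd)
    if (nd <= n_tip) return(phy$tip.label[nd])
    if (!is.null(node_labels) && key %in% names(node_labels))
      node_labels[[key]] else paste0("node_", key)
  }
  score_of <- function(nd) {
    key <- if (nd <= n_tip) phy$tip.label[nd] else as.character(nd)
    if (!key %in% names(adult_scores))
      stop("adult score missing for ", key)
    adult_scores[[key]]
  }
  deltas <- vapply(seq_len(nrow(phy$edge)), function(e)
    score_of(phy$edge[e, 2]) - score_of(phy$edge[e, 1]), numeric(1))
  m <- length(deltas)
  half_width <- stats::qt(1 - (1 - ci_level) / 2, df = m - 1L) *
    stats::sd(deltas) / sqrt(m)
  threshold <- ci_factor * half_width
  classification <- ifelse(deltas > threshold, "peramorphosis",
                           ifelse(deltas < -threshold, "paedomorphosis",
                                  "none"))
  bl <- phy$edge.length
  rate <- ifelse(bl > 0, deltas / bl, NA_real_)
  tab <- data.frame(
    ancestor = vapply(phy$edge[, 1], node_name, character(1)),
    descendant = vapply(phy$edge[, 2], node_name, character(1)),
    delta_score = deltas, threshold = threshold,
    classification = classification, branch_ma = bl, rate = rate,
    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$rate)), , drop = FALSE]
  # rank-based quartile labels are robust to tied rates
  rk <- rank(abs(tab$rate), ties.method = "average", na.last = "keep")
  quart <- pmin(pmax(ceiling(4 * rk / sum(!is.na(rk))), 1L), 4L)
  tab$rate_quartile <- factor(paste0("Q", quart),
                              levels = paste0("Q", 1:4))
  rownames(tab) <- NULL
  class(tab) <- c("shift_table", "data.frame")
  tab
}

#' Angle between two ontogenetic vectors
#'
#' Angle in degrees between the displacement vectors (adult minus juvenile
#' endpoint) in the (log centroid size, regression score) plane: the
#' arccosine of the dot product over the product of lengths, with the
#' argument clamped to [-1, 1] so parallel and antiparallel vectors give
#' exactly 0 and 180.
#'
#' @param u,v `onto_vector` objects or length-2 displacement vectors.
#' @return angle in degrees, in [0, 180].
#' @export
vector_angle <- function(u, v) {
  du <- if (inherits(u, "onto_vector")) onto_displacement(u) else as.numeric(u)
  dv <- if (inherits(v, "onto_vector")) onto_displacement(v) else as.numeric(v)
  nu <- sqrt(sum(du^2)); nv <- sqrt(sum(dv^2))
  if (nu <= 0 || nv <= 0) stop("zero-length ontogenetic vector")
  # atan2 form: exactly 0/180 for (anti)parallel vectors, no domain error
  cross <- du[1] * dv[2] - du[2] * dv[1]
  atan2(abs(cross), sum(du * dv)) * 180 / pi
}

#' Randomization test for ontogenetic-vector angles
#'
#' Draws random displacement vectors uniformly within the component-wise
#' bounds (per-axis min and max) of the observed displacements, measures the
#' angles between disjoint successive pairs (vectors 1-2, 3-4, ...), and
#' reports each observed angle's percentile within that null distribution.
#'
#' @param observed_vectors list of `onto_vector` objects (>= 2).
#' @param observed_angles optional named numeric vector of angles (degrees)
#'   to score against the null; defaults to angles between consecutive
#'   observed vectors.
#' @param n_vectors number of random vectors (default 200, giving
#'   n_vectors/2 null angles).
#' @param seed integer seed.
#' @return list with `null_angles`, `percentile` (named, fraction of null
#'   angles strictly below each observed angle), `seed`.
#' @export
angle_randomization_test <- function(observed_vectors,
                                     observed_angles = NULL,
                                     n_vectors = 200L, seed = 1L) {
  if (length(observed_vectors) < 2L) stop("need >= 2 observed vectors")
  disp <- t(vapply(observed_vectors, function(v)
    if (inherits(v, "onto_vector")) onto_displacement(v) else as.numeric(v),
    numeric(2)))
  lo <- apply(disp, 2, min)
  hi <- apply(disp, 2, max)
  if (all(hi - lo <= 0))
    stop("degenerate bounds: observed displacements are all identical")
  rng <- local_rng(seed)
  rand <- cbind(rng$runif(n_vectors, lo[1], hi[1]),
                rng$runif(n_vectors, lo[2], hi[2]))
  pair_idx <- seq(1L, n_vectors - 1L, by = 2L)
  null_angles <- vapply(pair_idx, function(i)
    vector_angle(rand[i, ], rand[i + 1L, ]), numeric(1))
  if (is.null(observed_angles)) {
    nm <- vapply(observed_vectors, function(v)
      if (inherits(v, "onto_vector")) v$label else "vector", character(1))
    observed_angles <- vapply(seq_len(length(observed_vectors) - 1L),
                              function(i) vector_angle(observed_vectors[[i]],
                                                       observed_vectors[[i + 1L]]),
                              numeric(1))
    names(observed_angles) <- paste(nm[-length(nm)], nm[-1L], sep = "->")
  }
  pct <- vapply(observed_angles, function(a) mean(null_angles < a),
                numeric(1))
  list(null_angles = null_angles, percentile = pct, seed = as.integer(seed))
}

#' Narrative heterochrony labels per branch
#'
#' Combines the allometric-shift classification with the vector-angle
#' evidence into the classical heterochrony vocabulary: a substantial angle
#' change means the descendant's ontogenetic allometry became steeper
#' (acceleration) or shallower (deceleration); near-parallel vectors whose
#' endpoints both moved toward smaller size and score indicate
#' predisplacement, away from the origin postdisplacement; a parallel vector
#' extended to larger adult size and score is consistent with
#' hypermorphosis.
#'
#' @param ancestor,descendant `onto_vector` objects for one branch.
#' @param angle_percentile the branch's angle percentile from
#'   [angle_randomization_test()].
#' @param shift_class the branch's classification from [shift_table()].
#' @param angle_cutoff percentile above which an angle counts as a
#'   substantial slope change (default 0.85).
#' @return character label.
#' @export
classify_modes <- function(ancestor, descendant, angle_percentile,
                           shift_class = "none", angle_cutoff = 0.85) {
  da <- onto_displacement(ancestor)
  dd <- onto_displacement(descendant)
  if (identical(unname(ancestor$juvenile), unname(descendant$juvenile)) &&
      identical(unname(ancestor$adult), unname(descendant$adult)))
    return("none")
  slope_of <- function(d) if (abs(d[1]) > 0) d[2] / d[1] else Inf
  if (angle_percentile >= angle_cutoff) {
    return(if (abs(slope_of(dd)) > abs(slope_of(da))) "acceleration"
           else "deceleration")
  }
  juv_shift <- descendant$juvenile - ancestor$juvenile
  adult_shift <- descendant$adult - ancestor$adult
  if (all(adult_shift > 0) && all(abs(juv_shift) <= abs(adult_shift)))
    return("hypermorphosis")
  if (all(juv_shift < 0) && all(adult_shift < 0))
    return("predisplacement")
  if (all(juv_shift > 0) && all(adult_shift > 0))
    return("postdisplacement")
  if (shift_class != "none") return(shift_class)
  "indeterminate"
}
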