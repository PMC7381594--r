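#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid; the standard size variable of landmark morphometrics and the
#' independent variable of the allometric analyses.
#'
#' @param config a [landmark_config] or a k x 2 coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  coords <- if (inherits(config, "landmark_config")) config$coords
            else as.matrix(config)
  ctr <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2, ctr)^2))
  if (cs <= 0) stop("all points coincident; centroid size undefined")
  cs
}

center_scale <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  coords / sqrt(sum(coords^2))
}

# Optimal proper rotation (2D) of centered X onto centered Y, both assumed
# comparable scale. Returns the angle minimizing ||R X' - Y'||^2.
optimal_angle <- function(x, y) {
  num <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])
  den <- sum(x[, 1] * y[, 1] + x[, 2] * y[, 2])
  atan2(num, den)
}

# rotation placing the point farthest from the centroid on the +x axis
canonical_rotation <- function(coords) {
  i <- which.max(rowSums(coords^2))
  -atan2(coords[i, 2], coords[i, 1])
}

rotate2d <- function(coords, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  coords %*% t(R)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Centers both configurations, scales both to unit centroid size, and
#' rotates the target by the proper rotation (no reflection) minimizing the
#' summed squared distance to the reference.
#'
#' @param target k x 2 matrix or [landmark_config] to align.
#' @param reference k x 2 matrix or [landmark_config] to align onto.
#' @return list with `aligned` (k x 2), `angle` (radians, the rotation
#'   applied to the target), and `rss` (minimized residual sum of squares).
#' @export
opa_align <- function(target, reference) {
  tx <- if (inherits(target, "landmark_config")) target$coords else as.matrix(target)
  rx <- if (inherits(reference, "landmark_config")) reference$coords else as.matrix(reference)
  if (nrow(tx) != nrow(rx))
    stop("point-count mismatch: ", nrow(tx), " vs ", nrow(rx))
  tx <- center_scale(tx)
  rx <- center_scale(rx)
  theta <- optimal_angle(tx, rx)
  aligned <- rotate2d(tx, theta)
  list(aligned = aligned, angle = theta, rss = sum((aligned - rx)^2))
}

#' Generalized Procrustes analysis
#'
#' Iteratively translates, scales and rotates all configurations into a
#' common coordinate frame: each shape is centered and scaled to unit
#' centroid size, rotated onto a provisional consensus, and the consensus is
#' recomputed until it stabilizes. This is partial Procrustes superimposition
#' (unit centroid size, no cos-rho rescaling); centroid sizes are carried
#' separately for the allometric analyses. Semilandmarks are treated as fixed
#' points (no sliding).
#'
#' @param configs list of >= 2 [landmark_config] objects with identical point
#'   counts, or a list of k x 2 matrices.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of iterations.
#' @param tangent project aligned shapes orthogonally onto the tangent space
#'   at the consensus (default TRUE; standard before PCA/regression).
#' @return object of class `aligned_sample`: list with `shapes` (specimens x
#'   2k matrix, rows named by specimen id), `centroid_sizes`, `consensus`
#'   (k x 2), `converged`, `iterations`, `tangent_projected`, and the
#'   carried-over `roles`/`specimen_ids`/`species`/`groups`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100L, tangent = TRUE) {
  if (length(configs) < 2L) stop("need >= 2 configurations")
  mats <- lapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$coords else as.matrix(cf))
  ks <- vapply(mats, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("mixed point counts: ", paste(unique(ks), collapse = ", "))
  is_cfg <- vapply(configs, inherits, logical(1), "landmark_config")
  if (all(is_cfg)) {
    role_sets <- unique(lapply(configs, `[[`, "roles"))
    if (length(role_sets) != 1L)
      stop("configurations have differing role tables")
  }
  n <- length(mats)
  cs <- vapply(mats, centroid_size, numeric(1))
  scaled <- lapply(mats, center_scale)
  ids0 <- if (all(is_cfg))
    vapply(configs, `[[`, character(1), "specimen_id")
  else paste0("specimen_", seq_len(n))
  # start from the lexicographically first specimen so the result does not
  # depend on input order
  consensus <- scaled[[order(ids0)[1L]]]
  prev_obj <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    scaled <- lapply(scaled, function(x)
      rotate2d(x, optimal_angle(x, consensus)))
    # consensus = plain arithmetic mean of the aligned shapes (not
    # renormalized); rotations onto it are invariant to its scale
    new_consensus <- Reduce(`+`, scaled) / n
    obj <- sum(vapply(scaled, function(x) sum((x - new_consensus)^2),
                      numeric(1)))
    if (obj > prev_obj + 1e-12)
      stop("GPA objective increased between iterations; numerical failure")
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    prev_obj <- obj
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge in ", max_iter, " iterations (last rms ",
         "consensus change above tol)")
  # canonical frame: rotate so the consensus point farthest from the
  # centroid lies on the positive x-axis; makes the output invariant to
  # rigid motions of the inputs
  theta_c <- canonical_rotation(consensus)
  scaled <- lapply(scaled, rotate2d, theta = theta_c)
  consensus <- rotate2d(consensus, theta_c)
  shapes <- t(vapply(scaled, function(x) as.vector(t(x)), numeric(2L * ks[1])))
  ids <- if (all(is_cfg))
    vapply(configs, `[[`, character(1), "specimen_id")
  else paste0("specimen_", seq_len(n))
  rownames(shapes) <- ids
  if (tangent) {
    cvec <- as.vector(t(consensus))
    cvec <- cvec / sqrt(sum(cvec^2))
    # orthogonal projection onto the tangent hyperplane at the consensus
    proj <- shapes %*% (diag(length(cvec)) - tcrossprod(cvec))
    shapes <- sweep(proj, 2, cvec, `+`)
  }
  structure(
    list(shapes = shapes, centroid_sizes = stats::setNames(cs, ids),
         consensus = consensus, converged = converged, iterations = iter,
         tangent_projected = tangent,
         roles = if (all(is_cfg)) configs[[1L]]$roles else NULL,
         specimen_ids = ids,
         species = if (all(is_cfg))
           vapply(configs, `[[`, character(1), "species") else ids,
         groups = if (all(is_cfg))
           vapply(configs, `[[`, character(1), "group") else NULL),
    class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("Procrustes-aligned sample: ", nrow(x$shapes), " specimens, ",
      ncol(x$shapes) / 2L, " landmarks\n", sep = "")
  cat("  converged in ", x$iterations, " iteration(s); tangent projection ",
      if (x$tangent_projected) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Mean shape of a subset of aligned specimens
#'
#' @param sample an `aligned_sample` from [gpa()].
#' @param subset specimen ids to average (default: all).
#' @return k x 2 matrix of mean coordinates.
#' @export
mean_shape <- function(sample, subset = NULL) {
  if (is.null(subset)) subset <- rownames(sample$shapes)
  if (!length(subset)) stop("subset must be nonempty")
  unknown <- setdiff(subset, rownames(sample$shapes))
  if (length(unknown))
    stop("unknown specimen id(s): ", paste(unknown, collapse = ", "))
  m <- colMeans(sample$shapes[subset, , drop = FALSE])
  shape_to_coords(m)
}
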