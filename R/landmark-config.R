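#' Landmark configuration for one specimen
#'
#' Bundles the ordered 2D landmark/semilandmark coordinates of a single
#' specimen together with the metadata the downstream analyses need: which
#' points are discrete homologous landmarks versus evenly spaced
#' semilandmarks, which points lie on the sagittal midline, and which points
#' form bilateral left/right pairs.
#'
#' Coordinates follow the TPS convention: x increases rightward, y increases
#' upward. All point indices are 1-based, matching both the file format and
#' R's indexing.
#'
#' @param coords numeric matrix (k x 2) of landmark coordinates.
#' @param specimen_id character scalar identifying the specimen.
#' @param species species name (defaults to the specimen id).
#' @param group taxonomic group label (e.g. "Centrosaurinae"); free text.
#' @param roles character vector of length k with entries `"fixed"` or
#'   `"semilandmark"`; defaults to all fixed.
#' @param midline_ids integer indices of points on the sagittal midline.
#' @param pair_map two-column integer matrix of (left, right) bilateral
#'   pairs; may have zero rows.
#' @param scale physical units per image unit, or `NULL` when unknown.
#'
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id = "specimen",
                            species = specimen_id, group = "other",
                            roles = NULL, midline_ids = integer(),
                            pair_map = NULL, scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be a k x 2 matrix")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  k <- nrow(coords)
  if (is.null(roles)) roles <- rep("fixed", k)
  if (length(roles) != k)
    stop("roles length (", length(roles), ") != number of points (", k, ")")
  if (!all(roles %in% c("fixed", "semilandmark")))
    stop("roles must be 'fixed' or 'semilandmark'")
  midline_ids <- as.integer(midline_ids)
  if (is.null(pair_map)) pair_map <- matrix(integer(), ncol = 2L)
  pair_map <- matrix(as.integer(pair_map), ncol = 2L)
  idx <- c(midline_ids, as.vector(pair_map))
  if (length(idx) && (any(idx < 1L) || any(idx > k)))
    stop("midline_ids/pair_map contain invalid point indices")
  if (length(intersect(midline_ids, as.vector(pair_map))))
    stop("a point cannot be both on the midline and in a bilateral pair")
  structure(
    list(specimen_id = as.character(specimen_id),
         species = as.character(species), group = as.character(group),
         coords = unname(coords), roles = roles,
         midline_ids = midline_ids, pair_map = pair_map,
         scale = if (is.null(scale)) NULL else as.numeric(scale)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "' (", x$species, ", ",
      x$group, ")\n", sep = "")
  cat("  ", nrow(x$coords), " points: ", sum(x$roles == "fixed"),
      " fixed, ", sum(x$roles == "semilandmark"), " semilandmarks\n",
      sep = "")
  if (length(x$midline_ids))
    cat("  midline points:", paste(x$midline_ids, collapse = ", "), "\n")
  if (nrow(x$pair_map))
    cat("  bilateral pairs:", nrow(x$pair_map), "\n")
  invisible(x)
}

n_landmarks <- function(config) nrow(config$coords)

#' Flatten configurations to a specimen-by-coordinate matrix
#'
#' Stacks configurations row-wise as (x1, y1, x2, y2, ...) vectors, the
#' layout used by the multivariate analyses.
#'
#' @param configs list of `landmark_config` objects with equal point counts.
#' @return numeric matrix (specimens x 2k), row names = specimen ids.
#' @export
configs_to_matrix <- function(configs) {
  ks <- vapply(configs, n_landmarks, integer(1))
  if (length(unique(ks)) != 1L)
    stop("configurations have mixed point counts: ",
         paste(unique(ks), collapse = ", "))
  out <- t(vapply(configs, function(cf) as.vector(t(cf$coords)),
                  numeric(2L * ks[1])))
  rownames(out) <- vapply(configs, `[[`, character(1), "specimen_id")
  out
}

#' Reshape a flat (x1, y1, ...) shape vector to a k x 2 matrix
#' @param v numeric vector of length 2k.
#' @return k x 2 coordinate matrix.
#' @export
shape_to_coords <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE)
}
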