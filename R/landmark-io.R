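#' Read landmark configurations from a TPS file
#'
#' Parses the TPS format produced by tpsDig/tpsUtil: per specimen a
#' `LM=<count>` line, that many `x y` coordinate lines, then `ID=` and
#' optionally `SCALE=` and `IMAGE=` lines. Coordinates are multiplied by
#' SCALE when present, so returned coordinates are in physical units.
#'
#' Point roles (fixed vs semilandmark), midline membership and bilateral
#' pairing are not representable in bare TPS; they are supplied through an
#' optional sidecar role table (see [read_role_table()]) applied uniformly
#' to every record.
#'
#' @param path TPS file path.
#' @param roles optional sidecar data frame from [read_role_table()].
#' @param metadata optional data frame with columns `specimen_id`,
#'   `species`, `group` (and possibly more) used to annotate records.
#' @return list of [landmark_config] objects in file order.
#' @export
read_tps <- function(path, roles = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  configs <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("expected 'LM=' at line ", i, ", got: ", lines[i])
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L) stop("malformed LM= count at line ", i)
    if (i + k > n_lines)
      stop("record starting at line ", i, " declares LM=", k,
           " but the file ends early")
    coord_lines <- lines[(i + 1L):(i + k)]
    if (any(grepl("=", coord_lines, fixed = TRUE)))
      stop("record starting at line ", i, ": LM=", k,
           " does not match the number of coordinate lines")
    coords <- matrix(NA_real_, nrow = k, ncol = 2L)
    for (j in seq_len(k)) {
      parts <- suppressWarnings(as.numeric(strsplit(coord_lines[j],
                                                    "\\s+")[[1]]))
      if (length(parts) != 2L || any(is.na(parts)))
        stop("non-numeric coordinate at line ", i + j, ": ", coord_lines[j])
      coords[j, ] <- parts
    }
    i <- i + k + 1L
    id <- NA_character_; scale <- NULL
    while (i <= n_lines && nzchar(lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                         ignore.case = TRUE)))
        if (is.na(scale)) stop("non-numeric SCALE= at line ", i)
      }
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("specimen_", length(configs) + 1L)
    if (!is.null(scale)) coords <- coords * scale
    cfg_roles <- NULL; midline <- integer(); pairs <- NULL
    if (!is.null(roles)) {
      rl <- roles[roles$index >= 1L & roles$index <= k, , drop = FALSE]
      cfg_roles <- rep("fixed", k)
      cfg_roles[rl$index] <- rl$role
      midline <- rl$index[rl$side == "midline"]
      lefts  <- rl[rl$side == "left",  , drop = FALSE]
      rights <- rl[rl$side == "right", , drop = FALSE]
      if (nrow(lefts) && nrow(lefts) == nrow(rights))
        pairs <- cbind(lefts$index, rights$index)
    }
    species <- id; group <- "other"
    if (!is.null(metadata)) {
      m <- metadata[metadata$specimen_id == id, , drop = FALSE]
      if (nrow(m) == 1L) {
        species <- m$species
        if ("group" %in% names(m)) group <- m$group
      }
    }
    configs[[length(configs) + 1L]] <- landmark_config(
      coords, specimen_id = id, species = species, group = group,
      roles = cfg_roles, midline_ids = midline, pair_map = pairs,
      scale = scale)
  }
  if (!length(configs)) stop("no TPS records found in ", path)
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are divided by each configuration's
#' scale (when set) so that a read/write round trip is the identity.
#'
#' @param configs nonempty list of [landmark_config] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (!length(configs)) stop("cannot write an empty configuration set")
  out <- character()
  for (cf in configs) {
    coords <- cf$coords
    if (!is.null(cf$scale) && cf$scale != 1) coords <- coords / cf$scale
    out <- c(out,
             paste0("LM=", nrow(coords)),
             paste(format(coords[, 1], trim = TRUE, digits = 17),
                   format(coords[, 2], trim = TRUE, digits = 17)),
             paste0("ID=", cf$specimen_id))
    if (!is.null(cf$scale))
      out <- c(out, paste0("SCALE=", format(cf$scale, digits = 17)))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a sidecar role table
#'
#' CSV with header `index,role,curve,side`: 1-based point index, role
#' (`fixed`/`semilandmark`), curve id for semilandmark curves (empty for
#' fixed points), and side (`left`/`right`/`midline`). Left and right rows
#' are paired in order of appearance.
#'
#' @param path CSV path.
#' @return data frame with those four columns.
#' @export
read_role_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "role", "curve", "side")
  if (!all(need %in% names(tab)))
    stop("role table must have columns: ", paste(need, collapse = ", "))
  tab$index <- as.integer(tab$index)
  tab
}

#' Resample a polyline into evenly spaced semilandmarks
#'
#' Places `n` points along the polyline so that consecutive output points
#' are separated by equal arc length; the endpoints are preserved. This is
#' how evenly spaced semilandmarks are generated from a digitized curve.
#'
#' @param points m x 2 matrix of ordered polyline vertices (m >= 2).
#' @param n number of output points (n >= 2).
#' @return n x 2 matrix of resampled points.
#' @export
resample_curve <- function(points, n) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 polyline points")
  if (n < 2L) stop("n must be >= 2")
  seg <- sqrt(rowSums(diff(points)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate polyline of total length 0")
  cum <- c(0, cumsum(seg))
  targets <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, nrow = n, ncol = 2L)
  out[1, ] <- points[1, ]
  out[n, ] <- points[nrow(points), ]
  for (i in seq(2L, n - 1L)) {
    s <- targets[i]
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(j, length(seg))
    frac <- if (seg[j] > 0) (s - cum[j]) / seg[j] else 0
    out[i, ] <- points[j, ] + frac * (points[j + 1L, ] - points[j, ])
  }
  out
}

# Total-least-squares line through points: returns a point on the line and a
# unit direction vector (first principal axis of the centered scatter).
fit_axis <- function(points) {
  ctr <- colMeans(points)
  dev <- sweep(points, 2, ctr)
  if (max(abs(dev)) < 1e-12)
    stop("midline points are coincident; the sagittal axis is undefined")
  sv <- svd(dev)
  list(point = ctr, dir = sv$v[, 1])
}

reflect_across <- function(p, axis) {
  v <- p - axis$point
  along <- sum(v * axis$dir) * axis$dir
  axis$point + 2 * along - v
}

project_onto <- function(p, axis) {
  v <- p - axis$point
  axis$point + sum(v * axis$dir) * axis$dir
}

#' Mirror the better-preserved side across the sagittal axis
#'
#' Fossil skulls are frequently better preserved on one side. This fits the
#' sagittal axis as the total-least-squares line through the midline points,
#' replaces each point on the discarded side with the reflection of its
#' bilateral partner from the kept side, and projects midline points exactly
#' onto the axis so the output is perfectly bilaterally symmetric.
#'
#' @param config a [landmark_config] with midline points and bilateral pairs.
#' @param use_side which side to keep: `"left"` or `"right"` (columns 1 and 2
#'   of `pair_map` respectively).
#' @return a new `landmark_config` with symmetric coordinates.
#' @export
mirror_fill <- function(config, use_side = c("left", "right")) {
  use_side <- match.arg(use_side)
  if (length(config$midline_ids) < 2L)
    stop("need >= 2 midline points to define the sagittal axis")
  if (!nrow(config$pair_map)) stop("pair_map is empty; nothing to mirror")
  axis <- fit_axis(config$coords[config$midline_ids, , drop = FALSE])
  coords <- config$coords
  keep_col <- if (use_side == "left") 1L else 2L
  fill_col <- 3L - keep_col
  for (r in seq_len(nrow(config$pair_map))) {
    kept <- config$pair_map[r, keep_col]
    fill <- config$pair_map[r, fill_col]
    coords[fill, ] <- reflect_across(coords[kept, ], axis)
  }
  for (m in config$midline_ids)
    coords[m, ] <- project_onto(coords[m, ], axis)
  out <- config
  out$coords <- coords
  out
}

#' Subset a landmark configuration
#'
#' Restricts a configuration to the given points, reindexing roles, midline
#' ids and bilateral pairs. Used e.g. to exclude the parietal-fenestra
#' landmarks so that taxa lacking fenestrae fit the same configuration.
#'
#' @param config a [landmark_config].
#' @param keep_ids integer indices of the points to keep (original 1-based
#'   indices; relative order is preserved).
#' @return a reindexed `landmark_config`. Bilateral pairs split by the
#'   subset are dropped with a warning.
#' @export
subset_landmarks <- function(config, keep_ids) {
  keep_ids <- sort(unique(as.integer(keep_ids)))
  k <- n_landmarks(config)
  if (!length(keep_ids)) stop("keep_ids must be nonempty")
  if (any(keep_ids < 1L) || any(keep_ids > k))
    stop("keep_ids out of range 1..", k)
  new_index <- match(seq_len(k), keep_ids)  # old -> new, NA if dropped
  pm <- config$pair_map
  if (nrow(pm)) {
    keep_pair <- !is.na(new_index[pm[, 1]]) & !is.na(new_index[pm[, 2]])
    split_pair <- xor(is.na(new_index[pm[, 1]]), is.na(new_index[pm[, 2]]))
    if (any(split_pair))
      warning(sum(split_pair),
              " bilateral pair(s) split by the subset were dropped")
    pm <- cbind(new_index[pm[keep_pair, 1]], new_index[pm[keep_pair, 2]])
  }
  landmark_config(
    config$coords[keep_ids, , drop = FALSE],
    specimen_id = config$specimen_id, species = config$species,
    group = config$group, roles = config$roles[keep_ids],
    midline_ids = stats::na.omit(new_index[config$midline_ids]),
    pair_map = pm, scale = config$scale)
}

#' Read a specimen metadata table
#'
#' CSV with header
#' `specimen_id,species,group,stage,basal_skull_length_mm`; stage is one of
#' juvenile/subadult/adult/unknown.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_specimen_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "species") %in% names(tab)))
    stop("metadata must have at least specimen_id and species columns")
  if ("basal_skull_length_mm" %in% names(tab)) {
    bad <- !is.na(tab$basal_skull_length_mm) & tab$basal_skull_length_mm <= 0
    if (any(bad)) stop("basal_skull_length_mm must be positive when present")
  }
  tab
}
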