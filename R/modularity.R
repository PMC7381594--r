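#' Covariance ratio between landmark modules
#'
#' The CR statistic of landmark modularity: with the coordinate covariance
#' matrix S partitioned by module into within blocks S11, S22 and the
#' between block S12,
#' \deqn{CR = \sqrt{ tr(S_{12} S_{21}) / \sqrt{ tr(\tilde S_{11}
#' \tilde S_{11}) \, tr(\tilde S_{22} \tilde S_{22}) } }}
#' where the tilde marks a within block with its diagonal zeroed. Values
#' below one indicate stronger covariation within modules than between
#' them, i.e. modularity. Both coordinates of a landmark always belong to
#' that landmark's module. Generalized to m modules as the average of all
#' pairwise two-module CRs.
#'
#' @param aligned_shapes specimens x 2k matrix of Procrustes-aligned
#'   coordinates (or an `aligned_sample`).
#' @param partition per-landmark module labels, length k (>= 2 landmarks per
#'   module).
#' @return nonnegative scalar.
#' @export
cr <- function(aligned_shapes, partition) {
  X <- if (inherits(aligned_shapes, "aligned_sample")) aligned_shapes$shapes
       else as.matrix(aligned_shapes)
  k <- ncol(X) / 2L
  if (length(partition) != k)
    stop("partition length (", length(partition),
         ") != number of landmarks (", k, ")")
  if (nrow(X) < 3L) stop("need >= 3 specimens")
  mods <- unique(partition)
  if (length(mods) < 2L) stop("need >= 2 modules")
  if (any(table(partition) < 2L)) stop("every module needs >= 2 landmarks")
  S <- stats::cov(X)
  col_module <- rep(partition, each = 2L)
  pair_cr <- function(m1, m2) {
    i1 <- which(col_module == m1)
    i2 <- which(col_module == m2)
    S12 <- S[i1, i2, drop = FALSE]
    S11 <- S[i1, i1, drop = FALSE]; diag(S11) <- 0
    S22 <- S[i2, i2, drop = FALSE]; diag(S22) <- 0
    denom <- sqrt(sum(S11 * S11) * sum(S22 * S22))
    if (denom <= 0)
      stop("a module has zero off-diagonal covariance; CR undefined")
    sqrt(sum(S12 * S12) / denom)
  }
  prs <- utils::combn(mods, 2L)
  mean(vapply(seq_len(ncol(prs)),
              function(j) pair_cr(prs[1, j], prs[2, j]), numeric(1)))
}

#' Random-partition permutation test of the CR statistic
#'
#' Compares the observed CR of the hypothesized partition against CR values
#' for random reassignments of whole landmarks (x and y kept together) to
#' modules of the same sizes. Low CR relative to the null indicates
#' modularity, so the p-value is left-tailed:
#' p = (1 + number of null CR <= observed) / (1 + n_permutations).
#'
#' @inheritParams cr
#' @param n_permutations number of random partitions (paper-scale default
#'   10000).
#' @param seed integer seed for the partition randomization.
#' @return object of class `cr_result`: list with `cr_observed`,
#'   `null_distribution`, `n_permutations`, `p_value`, `seed`.
#' @export
cr_test <- function(aligned_shapes, partition, n_permutations = 10000L,
                    seed = 1L) {
  X <- if (inherits(aligned_shapes, "aligned_sample")) aligned_shapes$shapes
       else as.matrix(aligned_shapes)
  observed <- cr(X, partition)
  k <- length(partition)
  rng <- local_rng(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    perm <- partition[rng$sample_int(k)]
    cr(X, perm)
  }, numeric(1))
  p <- (1 + sum(null <= observed)) / (1 + n_permutations)
  structure(list(cr_observed = observed, null_distribution = null,
                 n_permutations = as.integer(n_permutations),
                 p_value = p, seed = as.integer(seed)),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat("Covariance-ratio modularity test\n")
  cat("  observed CR = ", format(x$cr_observed, digits = 4),
      ", p = ", format(x$p_value, digits = 4), " (",
      x$n_permutations, " random partitions, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Semilandmark-removal sensitivity analysis for the CR test
#'
#' Because semilandmarks can outnumber fixed landmarks, a modularity signal
#' might be an artifact of their density. This re-runs the CR test with
#' randomly chosen semilandmarks removed (stratified proportionally across
#' modules), for several removal counts and replicates.
#'
#' @inheritParams cr_test
#' @param roles per-landmark role vector (`"fixed"`/`"semilandmark"`),
#'   length k; taken from the `aligned_sample` when omitted.
#' @param remove_counts numbers of semilandmarks to remove.
#' @param replicates random removals per count.
#' @param n_permutations random partitions per CR test.
#' @return data frame with columns remove_count, replicate, cr, p.
#' @export
semilandmark_sensitivity <- function(aligned_shapes, partition, roles = NULL,
                                     remove_counts = c(10L, 20L, 28L),
                                     replicates = 100L,
                                     n_permutations = 1000L, seed = 1L) {
  X <- if (inherits(aligned_shapes, "aligned_sample")) aligned_shapes$shapes
       else as.matrix(aligned_shapes)
  if (is.null(roles) && inherits(aligned_shapes, "aligned_sample"))
    roles <- aligned_shapes$roles
  if (is.null(roles)) stop("roles must be supplied")
  k <- length(partition)
  if (length(roles) != k) stop("roles length != number of landmarks")
  semis <- which(roles == "semilandmark")
  if (any(remove_counts >= length(semis)) && any(remove_counts > 0))
    if (max(remove_counts) >= length(semis))
      stop("remove_count must be below the number of semilandmarks (",
           length(semis), ")")
  rng <- local_rng(seed)
  rows <- list()
  for (rc in remove_counts) {
    reps <- if (rc == 0L) 1L else replicates
    for (rep_i in seq_len(reps)) {
      if (rc == 0L) {
        keep <- seq_len(k)
      } else {
        # stratify removals proportionally over modules
        drop_ids <- integer(0)
        mods <- unique(partition)
        per_mod <- vapply(mods, function(m) sum(partition[semis] == m),
                          numeric(1))
        quota <- round(rc * per_mod / sum(per_mod))
        # fix rounding so the total matches
        while (sum(quota) > rc) quota[which.max(quota)] <- quota[which.max(quota)] - 1L
        while (sum(quota) < rc) {
          room <- per_mod - quota
          quota[which.max(room)] <- quota[which.max(room)] + 1L
        }
        for (mi in seq_along(mods)) {
          pool <- semis[partition[semis] == mods[mi]]
          take <- min(quota[mi], length(pool))
          if (take > 0)
            drop_ids <- c(drop_ids, pool[rng$sample_int(length(pool))[seq_len(take)]])
        }
        keep <- setdiff(seq_len(k), drop_ids)
      }
      cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
      res <- cr_test(X[, cols, drop = FALSE], partition[keep],
                     n_permutations = n_permutations,
                     seed = rng$sample_int(2^30, size = 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        remove_count = rc, replicate = rep_i,
        cr = res$cr_observed, p = res$p_value)
    }
  }
  do.call(rbind, rows)
}
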