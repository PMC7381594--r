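#' Pairwise permutational ANOVAs along an ordination axis
#'
#' For each requested pair of groups, computes the classical one-way ANOVA
#' F statistic for the axis scores and a permutation p-value obtained by
#' reshuffling the group labels within the pair. Following common practice
#' in the morphometric literature the raw permutation p is reported as the
#' plain proportion of permuted F >= observed (so p = 0 is possible); the
#' (1+b)/(1+m) corrected estimate is also returned.
#'
#' @param scores named per-species scores on one axis.
#' @param groups named group labels for the same species.
#' @param pairs two-column character matrix (or data frame) of group pairs
#'   to test; default: all pairs of observed groups.
#' @param n_permutations label permutations per pair (default 1000).
#' @param seed integer seed.
#' @param axis axis index recorded in the output.
#' @return data frame with columns axis, group1, group2, F, df1, df2, p,
#'   p_corrected, n_permutations, seed.
#' @export
pairwise_perm_anova <- function(scores, groups, pairs = NULL,
                                n_permutations = 1000L, seed = 1L,
                                axis = 1L) {
  if (is.null(names(scores))) names(scores) <- names(groups)
  groups <- groups[names(scores)]
  if (is.null(pairs)) {
    gl <- sort(unique(groups))
    pairs <- t(utils::combn(gl, 2L))
  }
  pairs <- as.matrix(pairs)
  rng <- local_rng(seed)
  anova_f <- function(y, g) {
    n1 <- sum(g); n2 <- sum(!g)
    m1 <- mean(y[g]); m2 <- mean(y[!g]); m <- mean(y)
    ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
    ssw <- sum((y[g] - m1)^2) + sum((y[!g] - m2)^2)
    df2 <- n1 + n2 - 2L
    if (ssw <= 0) return(c(Inf, df2))
    c((ssb / 1) / (ssw / df2), df2)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    sel <- groups %in% c(g1, g2)
    y <- scores[sel]
    lab <- groups[sel] == g1
    if (sum(lab) < 2L || sum(!lab) < 2L)
      stop("group with < 2 members in pair ", g1, " vs ", g2)
    obs <- anova_f(y, lab)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- lab[rng$sample_int(length(lab))]
      if (anova_f(y, perm)[1] >= obs[1]) exceed <- exceed + 1L
    }
    data.frame(axis = axis, group1 = g1, group2 = g2, F = obs[1],
               df1 = 1L, df2 = as.integer(obs[2]),
               p = exceed / n_permutations,
               p_corrected = (1L + exceed) / (1L + n_permutations),
               n_permutations = as.integer(n_permutations),
               seed = as.integer(seed), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
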