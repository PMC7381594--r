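#' Simulation configuration
#'
#' Bundles the parameters of the synthetic landmark-data generator. The
#' generator emulates the statistical structure the analyses assume:
#' per-species mean shapes evolving by Brownian motion on a time-scaled
#' fossil tree with a block-structured (modular) trait covariance,
#' per-species linear ontogenetic allometry in log centroid size, and
#' isotropic digitization noise.
#'
#' @param seed master integer seed; every stage derives its own stream.
#' @param n_landmarks_module1 landmarks in the focal ("frill") module.
#' @param n_landmarks_module2 landmarks in the rest-of-skull module.
#' @param n_tips tip count of the generated fossil tree.
#' @param age_span (youngest FAD, oldest FAD) in Ma for the staggered tips.
#' @param bm_rate Brownian-motion shape variance per Ma.
#' @param within_module_corr correlation of coordinates within a module.
#' @param between_module_corr correlation of coordinates across modules
#'   (must not exceed `within_module_corr`).
#' @param slope regression-score allometric slope shared by species (a
#'   named vector overrides per species).
#' @param size_range (min, max) centroid size of each growth series.
#' @param n_specimens_per_species growth-series length per species.
#' @param noise_sd isotropic digitization noise in shape units.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_landmarks_module1 = 8L,
                       n_landmarks_module2 = 12L, n_tips = 8L,
                       age_span = c(5, 25), bm_rate = 1e-4,
                       within_module_corr = 0.7,
                       between_module_corr = 0.1, slope = 0.15,
                       size_range = c(50, 400),
                       n_specimens_per_species = 6L, noise_sd = 0.005) {
  if (between_module_corr > within_module_corr)
    stop("between-module correlation must not exceed within-module")
  if (within_module_corr > 1 || between_module_corr < 0)
    stop("correlations must satisfy 0 <= rho_b <= rho_w <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Base skull-like landmark template
#'
#' A fixed template configuration: the focal module's landmarks sample the
#' caudal arc (the frill outline), the second module the rostral arc of an
#' ellipse. Purely geometric; carries no digitization noise.
#'
#' @param n1,n2 landmarks in module 1 (frill) and module 2 (rest).
#' @return list with `coords` (k x 2), `partition` (length-k labels) and
#'   `roles` (alternating fixed/semilandmark within each module).
#' @export
base_skull_shape <- function(n1 = 8L, n2 = 12L) {
  th1 <- seq(pi * 0.15, pi * 0.85, length.out = n1)        # caudal arc
  th2 <- seq(pi * 1.05, pi * 1.95, length.out = n2)        # rostral arc
  coords <- rbind(cbind(1.2 * cos(th1), 0.8 * sin(th1)),
                  cbind(cos(th2), 0.6 * sin(th2)))
  roles <- c(rep(c("fixed", "semilandmark"), length.out = n1),
             rep(c("fixed", "semilandmark"), length.out = n2))
  list(coords = coords,
       partition = c(rep("frill", n1), rep("rest", n2)),
       roles = roles)
}

#' Simulate a fossil time-scaled tree
#'
#' Random rooted binary topology with staggered (non-ultrametric) tip ages:
#' first-appearance dates are drawn uniformly over `age_span` and the tree
#' is calibrated with [timescale()].
#'
#' @param n_tips number of tips.
#' @param age_span (youngest, oldest) FAD bounds in Ma.
#' @param seed integer seed.
#' @param method passed to [timescale()].
#' @return a `time_tree`.
#' @export
simulate_fossil_tree <- function(n_tips = 8L, age_span = c(5, 25),
                                 seed = 1L, method = "equal") {
  tree <- with_seed(seed, function() ape::rtree(n_tips, br = NULL))
  tree$tip.label <- paste0("sp", seq_len(n_tips))
  rng <- local_rng(seed + 1L)
  fad <- sort(rng$runif(n_tips, age_span[1], age_span[2]),
              decreasing = TRUE)
  ages <- data.frame(species = tree$tip.label, FAD_Ma = fad,
                     LAD_Ma = pmax(fad - 2, 0.1))
  timescale(tree, ages, method = method, root_extension = 2)
}

# block-structured trait covariance over 2k coordinates
block_trait_cov <- function(partition, rho_w, rho_b, rate) {
  col_module <- rep(partition, each = 2L)
  same <- outer(col_module, col_module, `==`)
  G <- ifelse(same, rho_w, rho_b)
  diag(G) <- 1
  G * rate
}

#' Simulate per-species mean shapes on a tree
#'
#' Species mean shapes are the base template plus matrix-normal deviations
#' with row (species) covariance C from the tree and column (trait)
#' covariance with within-module correlation rho_w and between-module
#' correlation rho_b, i.e. Brownian motion of a modular trait vector.
#'
#' @param tree a `time_tree` or `phylo` with branch lengths.
#' @param config a `sim_config`.
#' @return list with `shapes` (species x 2k matrix of mean shape vectors),
#'   `partition`, `roles`, `base` (2k template vector), `trait_cov`.
#' @export
simulate_tip_shapes <- function(tree, config = sim_config()) {
  phy <- as_phylo(tree)
  base <- base_skull_shape(config$n_landmarks_module1,
                           config$n_landmarks_module2)
  G <- block_trait_cov(base$partition, config$within_module_corr,
                       config$between_module_corr, config$bm_rate)
  C <- ape::vcv(phy)
  n <- nrow(C); p <- nrow(G)
  if (config$bm_rate == 0) {
    dev <- matrix(0, n, p)
  } else {
    eG <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(eG) <= 0)
      stop("trait covariance not positive definite (smallest eigenvalue ",
           format(min(eG)), ")")
    Lc <- t(chol(C))
    Lg <- chol(G)
    rng <- local_rng(config$seed + 2L)
    Z <- matrix(rng$rnorm(n * p), n, p)
    dev <- Lc %*% Z %*% Lg
  }
  base_vec <- as.vector(t(base$coords))
  shapes <- sweep(dev, 2, base_vec, `+`)
  rownames(shapes) <- rownames(C)
  list(shapes = shapes, partition = base$partition, roles = base$roles,
       base = base_vec, trait_cov = G)
}

#' Simulate an ontogenetic growth series for one species
#'
#' Log centroid sizes are evenly spaced over the log size range; each
#' specimen's shape is the species mean displaced along the allometric
#' direction proportionally to its centered log size, plus isotropic
#' digitization noise. Specimen configurations are rescaled so the realized
#' centroid size equals the prescribed one.
#'
#' @param mean_shape 2k vector (or k x 2 matrix) of the species mean shape.
#' @param allometric_vector 2k direction of allometric shape change
#'   (normalized internally).
#' @param slope regression-score change per unit log centroid size.
#' @param size_range (min, max) centroid size.
#' @param n specimens (>= 2).
#' @param noise_sd isotropic noise sd in shape units.
#' @param seed integer seed.
#' @param species species name for specimen ids.
#' @param center log centroid size at which the shape equals `mean_shape`;
#'   defaults to the series' own mean log size. Supplying a common value
#'   across species yields one coherent cross-species allometry.
#' @return list with `shapes` (n x 2k shape-space matrix, before size
#'   rescaling), `log_cs` (named), `configs` (list of [landmark_config]
#'   rescaled to the prescribed centroid sizes), `slope`.
#' @export
simulate_growth_series <- function(mean_shape, allometric_vector, slope,
                                   size_range = c(50, 400), n = 6L,
                                   noise_sd = 0, seed = 1L,
                                   species = "sp", center = NULL) {
  if (n < 2L) stop("need n >= 2 specimens")
  if (size_range[1] <= 0 || size_range[2] <= size_range[1])
    stop("invalid size_range")
  v <- as.numeric(allometric_vector)
  nv <- sqrt(sum(v^2))
  if (nv <= 0 && slope != 0)
    stop("zero allometric vector with nonzero slope")
  if (nv > 0) v <- v / nv
  mu <- if (is.matrix(mean_shape)) as.vector(t(mean_shape)) else
    as.numeric(mean_shape)
  log_cs <- seq(log(size_range[1]), log(size_range[2]), length.out = n)
  if (is.null(center)) center <- mean(log_cs)
  rng <- local_rng(seed)
  shapes <- t(vapply(seq_len(n), function(i) {
    mu + slope * (log_cs[i] - center) * v +
      rng$rnorm(length(mu), sd = noise_sd)
  }, numeric(length(mu))))
  ids <- sprintf("%s_%02d", species, seq_len(n))
  rownames(shapes) <- ids
  names(log_cs) <- ids
  configs <- lapply(seq_len(n), function(i) {
    coords <- shape_to_coords(shapes[i, ])
    coords <- sweep(coords, 2, colMeans(coords))
    coords <- coords * exp(log_cs[i]) / sqrt(sum(coords^2))
    landmark_config(coords, specimen_id = ids[i], species = species)
  })
  list(shapes = shapes, log_cs = log_cs, configs = configs, slope = slope)
}

#' Write a complete synthetic fixture set to disk
#'
#' Simulates a tree, species mean shapes and per-species growth series from
#' one configuration and writes everything in the package's interchange
#' formats: a TPS file of all specimens, the sidecar role table, specimen
#' metadata, the tip-age table, the Newick tree, and a manifest JSON
#' recording the seed and all true generating parameters (so recovery tests
#' can assert against ground truth).
#'
#' @param config a `sim_config`.
#' @param out_dir writable output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
make_fixture_set <- function(config = sim_config(), out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  tt <- simulate_fossil_tree(config$n_tips, config$age_span,
                             seed = config$seed)
  tips <- simulate_tip_shapes(tt, config)
  slopes <- config$slope
  if (length(slopes) == 1L)
    slopes <- stats::setNames(rep(slopes, config$n_tips),
                              rownames(tips$shapes))
  v <- allometric_direction(tips$partition)
  all_configs <- list(); meta <- list()
  for (sp in rownames(tips$shapes)) {
    gs <- simulate_growth_series(
      tips$shapes[sp, ], v, slopes[[sp]], config$size_range,
      config$n_specimens_per_species, config$noise_sd,
      seed = config$seed + 100L + match(sp, rownames(tips$shapes)),
      species = sp)
    all_configs <- c(all_configs, gs$configs)
    stage <- rep("subadult", length(gs$configs))
    stage[1L] <- "juvenile"
    stage[length(stage)] <- "adult"
    meta[[sp]] <- data.frame(
      specimen_id = names(gs$log_cs), species = sp, group = "other",
      stage = stage,
      basal_skull_length_mm = round(exp(gs$log_cs), 1))
  }
  files <- c(
    tps = file.path(out_dir, "specimens.tps"),
    roles = file.path(out_dir, "roles.csv"),
    metadata = file.path(out_dir, "metadata.csv"),
    ages = file.path(out_dir, "tip_ages.csv"),
    tree = file.path(out_dir, "tree.nwk"),
    manifest = file.path(out_dir, "manifest.json"))
  write_tps(all_configs, files[["tps"]])
  k <- config$n_landmarks_module1 + config$n_landmarks_module2
  utils::write.csv(
    data.frame(index = seq_len(k), role = tips$roles,
               curve = ifelse(tips$roles == "semilandmark",
                              tips$partition, ""),
               side = "midline"),
    files[["roles"]], row.names = FALSE)
  utils::write.csv(do.call(rbind, meta), files[["metadata"]],
                   row.names = FALSE)
  utils::write.csv(tt$tip_ages, files[["ages"]], row.names = FALSE)
  ape::write.tree(tt$tree, files[["tree"]])
  manifest <- list(
    seed = config$seed,
    n_landmarks_module1 = config$n_landmarks_module1,
    n_landmarks_module2 = config$n_landmarks_module2,
    n_tips = config$n_tips, bm_rate = config$bm_rate,
    within_module_corr = config$within_module_corr,
    between_module_corr = config$between_module_corr,
    slope = as.list(slopes), size_range = config$size_range,
    n_specimens_per_species = config$n_specimens_per_species,
    noise_sd = config$noise_sd, root_age = tt$root_age)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

#' Allometric direction used by the generator
#'
#' Unit 2k vector displacing the focal module's landmarks outward along y
#' (frill elongation) while leaving the rest module fixed — the kind of
#' localized allometry the frill analyses target.
#'
#' @param partition per-landmark module labels; the first label is focal.
#' @return unit numeric vector of length 2k.
#' @export
allometric_direction <- function(partition) {
  v <- numeric(2L * length(partition))
  focal <- partition == partition[1L]
  v[2L * which(focal)] <- 1       # y coordinates of the focal module
  v / sqrt(sum(v^2))
}

#' Simulate and analyze a complete heterochrony study
#'
#' End-to-end driver for recovery experiments: simulates species mean shapes
#' on the tree, generates a growth series per species with its own
#' allometric slope, pools all specimens into the allometric regression,
#' builds observed ontogenetic vectors, reconstructs ancestral vectors by
#' squared-change parsimony, and produces the allometric-shift table. With
#' one species given a slope 1.5x its relatives', the corresponding terminal
#' branch should be flagged as peramorphic.
#'
#' @param tree a `time_tree` (or `phylo` with positive branch lengths in Ma).
#' @param slopes named per-species regression-score slopes (one per tip).
#' @param config a [sim_config()]; its seed drives all randomness here.
#' @param regression_permutations permutations for the pooled regression p.
#' @param size_factors optional named per-species multipliers of the size
#'   range (e.g. exp of a Brownian trait), introducing cross-species size
#'   variation; allometry is then centered on the global mean log size so
#'   that larger species carry higher adult regression scores.
#' @return list with `model` (allometric fit), `vectors` (per-species
#'   ontogenetic vectors), `ancestors` (reconstructed vectors), `shifts`
#'   (the [shift_table()]), and `adult_scores`.
#' @export
simulate_heterochrony_study <- function(tree, slopes,
                                        config = sim_config(),
                                        regression_permutations = 99L,
                                        size_factors = NULL) {
  phy <- as_phylo(tree)
  missing <- setdiff(phy$tip.label, names(slopes))
  if (length(missing))
    stop("slopes missing for: ", paste(missing, collapse = ", "))
  tips <- simulate_tip_shapes(tree, config)
  v <- allometric_direction(tips$partition)
  ranges <- lapply(phy$tip.label, function(sp) {
    f <- if (is.null(size_factors)) 1 else size_factors[[sp]]
    config$size_range * f
  })
  names(ranges) <- phy$tip.label
  center <- if (is.null(size_factors)) NULL else
    mean(vapply(ranges, function(r) mean(log(r)), numeric(1)))
  shapes <- NULL; log_cs <- numeric(0); vectors <- list()
  for (sp in phy$tip.label) {
    gs <- simulate_growth_series(
      tips$shapes[sp, ], v, slopes[[sp]], ranges[[sp]],
      config$n_specimens_per_species, config$noise_sd,
      seed = config$seed + 1000L + match(sp, phy$tip.label), species = sp,
      center = center)
    shapes <- rbind(shapes, gs$shapes)
    log_cs <- c(log_cs, gs$log_cs)
  }
  fit <- pooled_regression(shapes, log_cs,
                           n_permutations = regression_permutations,
                           seed = config$seed)
  for (sp in phy$tip.label) {
    sel <- startsWith(names(log_cs), paste0(sp, "_"))
    vectors[[sp]] <- ontogenetic_vector(log_cs[sel], fit$scores[sel],
                                        label = sp)
  }
  ancestors <- ancestral_vectors(tree, vectors)
  adult_scores <- c(
    vapply(vectors, function(vv) vv$adult[["score"]], numeric(1)),
    vapply(ancestors, function(vv) vv$adult[["score"]], numeric(1)))
  names(adult_scores) <- c(names(vectors), names(ancestors))
  shifts <- shift_table(tree, adult_scores)
  list(model = fit, vectors = vectors, ancestors = ancestors,
       shifts = shifts, adult_scores = adult_scores)
}
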