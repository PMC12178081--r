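#' Synthetic outline dataset with group structure and allometry
#'
#' Deterministic generator emulating a group-structured sample of closed
#' outlines described by elliptic Fourier coefficients — several congeneric
#' species whose shells differ chiefly in outline elongation, sampled over
#' a time interval, with coefficient drift linked to (log) size
#' (allometry) and iid measurement noise. Group mean offsets are nearly
#' collinear (dominant elongation contrast on the first-harmonic d
#' coefficient plus a small orthogonal perturbation per species), the
#' structure typical of closely related bivalve species.
#'
#' @param n_per_group specimens per species; the default sums to 137 in 4
#'   species, mirroring a classic fossil-bivalve sampling design.
#' @param h harmonics (default 7).
#' @param group_spread half-range of the between-species elongation
#'   contrast, in coefficient units.
#' @param ortho_sd scale of the small species-specific off-axis offsets.
#' @param allometry_slope coefficient drift per unit log size along a fixed
#'   unit direction (0 disables allometry).
#' @param noise_sd iid coefficient noise (0 gives noise-free data).
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return list with `coeffs` (an [outline_coeffs]), `covariates`
#'   (data frame: `id`, `species`, `size`, `age`) and `truth` (the injected
#'   allometric vector, slope, and per-species mean coefficient offsets).
#' @export
make_outline_dataset <- function(n_per_group = c(35L, 34L, 34L, 34L),
                                 h = 7L, group_spread = 0.09,
                                 ortho_sd = 0.008,
                                 allometry_slope = 0.04, noise_sd = 0.01,
                                 seed = 1L) {
  set.seed(seed)
  g <- length(n_per_group)
  n <- sum(n_per_group)
  p <- 4L * h
  species <- factor(rep(paste0("sp", seq_len(g)), n_per_group))
  base <- numeric(p)                     # a1..d1, a2..d2, ...
  base[1L] <- 1; base[4L] <- 0.55        # a1, d1: elongate base ellipse
  # species offsets: elongation contrast on d1 + small orthogonal wiggle
  elong <- seq(-group_spread, group_spread, length.out = g)
  offsets <- matrix(0, g, p)
  offsets[, 4L] <- elong
  if (g >= 1L && ortho_sd > 0) {
    wig <- matrix(stats::rnorm(g * 2L, sd = ortho_sd), g, 2L)
    offsets[, 7L] <- wig[, 1L]           # c2
    offsets[, 9L] <- wig[, 2L]           # a3
  }
  # fixed unit allometric direction over mid harmonics
  v <- numeric(p); v[c(5L, 8L, 10L)] <- c(0.8, -0.5, 0.33)
  v <- v / sqrt(sum(v^2))
  size <- stats::rlnorm(n, meanlog = 3, sdlog = 0.35)
  lsc <- log(size) - mean(log(size))
  X <- matrix(base, n, p, byrow = TRUE) +
    offsets[as.integer(species), , drop = FALSE] +
    outer(lsc * allometry_slope, v) +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  # species occupy overlapping sub-intervals of a 5-unit time window
  breaks <- seq(0, 5, length.out = g + 2L)
  age <- stats::runif(n, breaks[as.integer(species)],
                      breaks[as.integer(species) + 2L])
  ids <- paste0("out", seq_len(n))
  sm <- shape_matrix(X, kind = "fourier", h = h, ids = ids)
  list(coeffs = unflatten_shapes(sm, ids = ids),
       covariates = data.frame(id = ids, species = species, size = size,
                               age = age),
       truth = list(allometry_vector = v, allometry_slope = allometry_slope,
                    offsets = offsets, base = base))
}

# a 9-landmark template: points around an ellipse, unit centroid size
default_template <- function(k = 9L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cfg <- cbind(1.4 * cos(th), 0.8 * sin(th))
  cfg <- sweep(cfg, 2L, colMeans(cfg))
  cfg / sqrt(sum(cfg^2))
}

#' Synthetic landmark dataset with groups, allometry and nuisance factors
#'
#' Deterministic generator emulating two common landmark sampling designs:
#' a longitudinal design (several individuals per species, each measured
#' repeatedly at increasing sizes — the structure of ontogenetic series)
#' and, with `n_meas_per_ind = 1`, a cross-sectional multi-species design.
#' Shape effects are additive in the flattened coordinate space: species
#' mean offsets, a fixed allometric deformation direction scaled by
#' centred log size, individual and locality/age nuisance shifts, and iid
#' coordinate noise. When `transform = TRUE` each configuration is finally
#' hit with a random rotation, scale and translation so that Procrustes
#' alignment is actually exercised.
#'
#' @param n_groups number of species.
#' @param n_ind_per_group individuals per species.
#' @param n_meas_per_ind repeated measures per individual (sizes increase
#'   within an individual).
#' @param k landmarks (2D).
#' @param group_disp scale of the species mean offsets (Procrustes-ish
#'   units; 0 disables).
#' @param allometry_slope deformation per unit log size (0 disables).
#' @param ind_sd individual-effect scale (0 disables).
#' @param locality_disp,age_disp nuisance shifts for a 3-level locality
#'   factor and a continuous age covariate.
#' @param noise_sd iid coordinate noise.
#' @param transform apply random similarity transforms to the output?
#' @param seed RNG seed.
#' @return list with `landmarks` (a [landmark_set] of raw configurations),
#'   `covariates` (data frame: `id`, `individual`, `species`, `locality`,
#'   `age`, `size`) and `truth` (template, allometric direction and slope,
#'   species offsets).
#' @export
make_landmark_dataset <- function(n_groups = 7L, n_ind_per_group = 10L,
                                  n_meas_per_ind = 4L, k = 9L,
                                  group_disp = 0.05,
                                  allometry_slope = 0.08, ind_sd = 0.02,
                                  locality_disp = 0.03, age_disp = 0.02,
                                  noise_sd = 0.01, transform = TRUE,
                                  seed = 1L) {
  set.seed(seed)
  tmpl <- default_template(k)
  p <- 2L * k
  n_ind <- n_groups * n_ind_per_group
  n <- n_ind * n_meas_per_ind
  species <- factor(rep(paste0("sp", seq_len(n_groups)),
                        each = n_ind_per_group * n_meas_per_ind))
  individual <- factor(rep(paste0("ind", seq_len(n_ind)),
                           each = n_meas_per_ind))
  # mean-zero random directions per species
  goff <- matrix(stats::rnorm(n_groups * p), n_groups, p)
  goff <- goff / sqrt(rowSums(goff^2)) * group_disp
  # allometric direction: smooth elongation-like deformation (x-stretch
  # with a dorsoventral compensation), unit norm
  v <- flatten_config(cbind(tmpl[, 1L], -0.5 * tmpl[, 2L]))
  v <- v / sqrt(sum(v^2))
  ioff <- matrix(stats::rnorm(n_ind * p, sd = ind_sd), n_ind, p)
  locality <- factor(sample(paste0("loc", 1:3), n, replace = TRUE))
  loff <- matrix(stats::rnorm(3L * p), 3L, p)
  loff <- loff / sqrt(rowSums(loff^2)) * locality_disp
  age <- stats::runif(n, 0, 1)
  aoff <- stats::rnorm(p); aoff <- aoff / sqrt(sum(aoff^2)) * age_disp
  # sizes increase within an individual (ontogenetic series)
  base_size <- stats::rlnorm(n_ind, meanlog = 2.5, sdlog = 0.3)
  growth <- if (n_meas_per_ind > 1L)
    seq(1, 2.8, length.out = n_meas_per_ind) else 1
  size <- as.vector(t(outer(base_size, growth)))
  lsc <- log(size) - mean(log(size))
  X <- matrix(flatten_config(tmpl), n, p, byrow = TRUE) +
    goff[as.integer(species), , drop = FALSE] +
    ioff[as.integer(individual), , drop = FALSE] +
    loff[as.integer(locality), , drop = FALSE] +
    outer(age - mean(age), aoff) +
    outer(lsc * allometry_slope, v) +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  ids <- paste0("lm", seq_len(n))
  arr <- array(NA_real_, c(n, k, 2L))
  for (i in seq_len(n)) {
    cfg <- unflatten_config(X[i, ], 2L)
    if (transform) {
      th <- stats::runif(1L, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      cfg <- cfg %*% R * size[i]
      cfg <- sweep(cfg, 2L, stats::rnorm(2L, sd = 5), `+`)
    }
    arr[i, , ] <- cfg
  }
  list(landmarks = landmark_set(arr, ids = ids),
       covariates = data.frame(id = ids, individual = individual,
                               species = species, locality = locality,
                               age = age, size = size),
       truth = list(template = tmpl, allometry_vector = v,
                    allometry_slope = allometry_slope,
                    group_offsets = goff, flat = X))
}

#' Multivariate Brownian-motion tip data on a tree
#'
#' Simulates `p` independent traits evolving by Brownian motion with a
#' common rate along a rooted tree with branch lengths: tip values are
#' `root + sqrt(rate) * L' z` per trait, with `L'L` the phylogenetic
#' covariance and `z` standard normal.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param rate BM rate (variance per unit branch length); 0 returns the
#'   root state at every tip.
#' @param p number of traits.
#' @param seed RNG seed.
#' @param root root state (scalar or length-`p`).
#' @return a plain `s x p` matrix of tip values with tip labels as
#'   rownames (wrap in [shape_matrix()] for the ordination functions).
#' @export
make_bm_tips <- function(tree, rate = 1, p = 1L, seed = 1L, root = 0) {
  check_tree(tree)
  set.seed(seed)
  C <- phylo_covariance(tree)
  s <- nrow(C)
  root <- rep_len(root, p)
  if (rate == 0)
    return(matrix(root, s, p, byrow = TRUE,
                  dimnames = list(rownames(C), NULL)))
  L <- chol(C)
  X <- matrix(root, s, p, byrow = TRUE) +
    sqrt(rate) * crossprod(L, matrix(stats::rnorm(s * p), s, p))
  rownames(X) <- rownames(C)
  X
}

#' A reproducible random tree for the comparative fixture
#'
#' A pure birth (Yule-like) coalescent-shaped tree from `ape::rcoal` seeded
#' deterministically, scaled to unit height — 13 tips by default, the size
#' of a small bird genus.
#'
#' @param s tips.
#' @param seed RNG seed.
#' @return an ultrametric `phylo` of height 1.
#' @export
make_fixture_tree <- function(s = 13L, seed = 1L) {
  set.seed(seed)
  tree <- ape::rcoal(s, tip.label = paste0("sp", seq_len(s)))
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree))
  tree
}

#' Write the three demo fixture bundles to disk
#'
#' Generates the outline, longitudinal-landmark and comparative (Brownian
#' motion on a tree) fixture datasets and writes them in the formats the
#' readers of this package consume: coefficient CSV + covariate CSV,
#' TPS + covariate CSV, and wide CSV + Newick.
#'
#' @param dir destination directory.
#' @param seed RNG seed shared by the three generators.
#' @return character vector of written files, invisibly.
#' @export
write_demo_bundles <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  od <- make_outline_dataset(seed = seed)
  write_coeffs_csv(od$coeffs, file.path(dir, "outlines_coeffs.csv"))
  utils::write.csv(od$covariates, file.path(dir, "outlines_covariates.csv"),
                   row.names = FALSE)
  ld <- make_landmark_dataset(seed = seed)
  write_tps(ld$landmarks, file.path(dir, "landmarks.tps"))
  utils::write.csv(ld$covariates, file.path(dir, "landmarks_covariates.csv"),
                   row.names = FALSE)
  tree <- make_fixture_tree(seed = seed)
  tips <- make_bm_tips(tree, rate = 0.05, p = 18L, seed = seed)
  sm <- shape_matrix(tips, kind = "landmarks2d", k = 9L,
                     ids = rownames(tips))
  write_wide_csv(sm, file.path(dir, "bm_tip_shapes.csv"))
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  invisible(list.files(dir, full.names = TRUE))
}
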