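# Seeded synthetic-data generators.  Every generator returns the planted
# ground truth alongside the data, so downstream stages can be tested by
# parameter recovery, and every generator is bit-reproducible under a fixed
# seed.

#' Toy protein specification for the two-state loop generator
#'
#' A bead model (one C-alpha-like bead per residue): a rigid core ball, a
#' copper-like site bead at its surface, and a mobile loop whose centre of
#' mass sits at one of two characteristic distances from the site.  The
#' default geometry is calibrated so that an equal open/closed mixture has
#' loop-to-site distance moments of 18.4 +/- 3.5 Angstrom, matching the
#' printed statistics of a realistic Met-loop conformer pool.
#'
#' @param n_core_residues rigid-core bead count
#' @param loop_residue_count loop bead count
#' @param site_position site bead position (Angstrom)
#' @param closed_distance,open_distance loop-COM-to-site distances of the
#'   two states (Angstrom), `open > closed > 0`
#' @param jitter_sd Gaussian jitter of the loop-to-site distance (Angstrom)
#' @param core_radius radius of the core ball (Angstrom)
#' @return list of class `"toy_protein_spec"`
#' @export
toy_protein_spec <- function(n_core_residues = 40L, loop_residue_count = 8L,
                             site_position = c(10.5, 0, 0),
                             closed_distance = 15.34,
                             open_distance = 21.46,
                             jitter_sd = 1.7, core_radius = 10) {
  stopifnot(n_core_residues >= 1L, loop_residue_count >= 1L,
            length(site_position) == 3L, jitter_sd >= 0, core_radius > 0)
  if (!(open_distance > closed_distance && closed_distance > 0)) {
    stop("need open_distance > closed_distance > 0", call. = FALSE)
  }
  structure(list(n_core_residues = as.integer(n_core_residues),
                 loop_residue_count = as.integer(loop_residue_count),
                 site_position = as.numeric(site_position),
                 closed_distance = closed_distance,
                 open_distance = open_distance,
                 jitter_sd = jitter_sd, core_radius = core_radius),
            class = "toy_protein_spec")
}

# Deterministic bead positions filling a ball (spiral lattice).
.core_beads <- function(n, radius) {
  pts <- .sphere_points(n)
  r <- radius * (seq_len(n) / n)^(1 / 3)
  pts * r
}

# A short arc of beads (3.8 A spacing) centred on the origin.
.loop_shape <- function(n) {
  t <- seq_len(n) - (n + 1) / 2
  arc <- cbind(3.8 * t, 1.5 * cos(t), 1.5 * sin(t))
  sweep(arc, 2, colMeans(arc))
}

.toy_atom_table <- function(spec) {
  n_core <- spec$n_core_residues
  n_loop <- spec$loop_residue_count
  data.frame(
    elety = c(rep("CA", n_core + n_loop), "CU"),
    resid = c(rep("GLY", n_core), rep("MET", n_loop), "CU"),
    chain = "A",
    resno = c(seq_len(n_core + n_loop), 999L),
    icode = "",
    element = c(rep("C", n_core + n_loop), "CU"),
    het = c(rep(FALSE, n_core + n_loop), TRUE),
    occ = 1, b = 0, stringsAsFactors = FALSE)
}

#' Generate a two-state (open/closed) loop conformer pool
#'
#' The rigid core and the site bead are identical across models; the loop
#' arc is rigidly placed so that its centre of mass lies at a distance
#' `d ~ Normal(state distance, jitter_sd)` (truncated positive) from the
#' site, in a random direction.  Exactly `round(f_closed * n_models)`
#' models are closed; the state assignment order is shuffled.
#'
#' @param n_models pool size (>= 1)
#' @param f_closed closed-state fraction in [0, 1]
#' @param spec a [toy_protein_spec()]
#' @param seed integer RNG seed (mandatory)
#' @return list: `ensemble` (a `confens`), `labels` (character
#'   "closed"/"open" ground truth), `distances` (planted loop-to-site
#'   distances), `spec`
#' @export
make_two_state_ensemble <- function(n_models, f_closed,
                                    spec = toy_protein_spec(), seed) {
  stopifnot(n_models >= 1L, f_closed >= 0, f_closed <= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_closed <- round(f_closed * n_models)
  labels <- sample(c(rep("closed", n_closed),
                     rep("open", n_models - n_closed)))
  core <- .core_beads(spec$n_core_residues, spec$core_radius)
  shape <- .loop_shape(spec$loop_residue_count)
  site <- spec$site_position
  out_dir <- site / sqrt(sum(site^2))
  xyz <- matrix(NA_real_, n_models,
                3L * (spec$n_core_residues + spec$loop_residue_count + 1L))
  dists <- numeric(n_models)
  for (m in seq_len(n_models)) {
    mode <- if (labels[m] == "closed") spec$closed_distance else
      spec$open_distance
    d <- -1
    while (d <= 0) d <- rnorm(1, mode, spec$jitter_sd)
    # random direction biased away from the core so open/closed differ
    # radially, not by burying the loop
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    u <- u + 2 * out_dir
    u <- u / sqrt(sum(u^2))
    com <- site + d * u
    loop <- sweep(shape, 2, com, "+")
    coords <- rbind(core, loop, site)
    xyz[m, ] <- as.vector(t(coords))
    dists[m] <- d
  }
  list(ensemble = new_confens(.toy_atom_table(spec), xyz),
       labels = labels, distances = dists, spec = spec)
}

#' Noise model for simulated SAXS profiles
#'
#' `sigma(s) = relative_sd * I(s) + floor`, emulating the
#' intensity-proportional uncertainty of SEC-SAXS data.
#'
#' @param relative_sd relative standard deviation (fraction >= 0)
#' @param floor additive uncertainty floor (intensity units, >= 0)
#' @return list of class `"noise_model"`
#' @export
noise_model <- function(relative_sd = 0.02, floor = 0) {
  stopifnot(relative_sd >= 0, floor >= 0)
  structure(list(relative_sd = relative_sd, floor = floor),
            class = "noise_model")
}

#' Simulate an experimental SAXS profile from an ensemble
#'
#' Forward-computes the weighted Debye average of the pool, attaches
#' `sigma(s)` from the noise model and perturbs the intensities with
#' seeded Gaussian noise of that sigma.  With a zero noise model the
#' profile equals the forward curve exactly (a tiny positive sigma is
#' still attached, since a profile's uncertainties must be positive).
#'
#' @param ens a `confens`, or a precomputed list of `saxs_curve`s
#' @param s_grid momentum-transfer grid (inverse Angstrom)
#' @param weights simplex weights over models (uniform when `NULL`)
#' @param noise a [noise_model()]
#' @param seed integer RNG seed (mandatory)
#' @return a `saxs_profile`, with the noiseless generating curve attached
#'   as attribute `truth`
#' @export
simulate_saxs_profile <- function(ens, s_grid, weights = NULL,
                                  noise = noise_model(), seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  curves <- if (inherits(ens, "confens")) {
    pool_debye_curves(ens, s_grid)
  } else {
    ens
  }
  if (!is.null(weights) && all(weights == 0)) {
    stop("weights are all zero", call. = FALSE)
  }
  truth <- ensemble_average_curve(curves, weights)
  sig <- noise$relative_sd * truth$intensity + noise$floor
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  inten <- truth$intensity + rnorm(length(sig), 0, sig)
  sig_out <- pmax(sig, 1e-10 * max(abs(truth$intensity)))
  out <- new_saxs_profile(truth$s, inten, sig_out)
  attr(out, "truth") <- truth
  out
}

#' Simulate a trajectory with planted block covariance
#'
#' Per-frame C-alpha displacements are drawn from a zero-mean multivariate
#' normal whose residue-residue correlation is `rho` within each declared
#' block and 0 elsewhere, applied identically and independently to the x,
#' y and z axes so the scalar dynamic cross-correlation of residues i, j
#' equals the planted `rho`.  A non-positive-semidefinite requested
#' correlation is repaired by eigenvalue clipping (logged).
#'
#' @param base a single-model `confens` supplying topology and mean
#'   coordinates (HETATM beads stay static)
#' @param block_spec list of blocks `list(residues = <resno vector>,
#'   rho = <correlation>)`; blocks must be disjoint
#' @param n_frames number of frames (>= 10)
#' @param amplitude_sd per-axis displacement standard deviation (Angstrom)
#' @param seed integer RNG seed (mandatory)
#' @param frame_interval metadata: ns between stored frames
#' @return list: `trajectory` (a `confens`), `correlation` (planted R x R
#'   matrix), `blocks`
#' @export
simulate_correlated_trajectory <- function(base, block_spec = list(),
                                           n_frames, amplitude_sd = 0.5,
                                           seed, frame_interval = NA_real_) {
  stopifnot(inherits(base, "confens"), n_frames >= 10L, amplitude_sd > 0)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  ca_idx <- which(base$atoms$elety == "CA" & !base$atoms$het)
  resnos <- base$atoms$resno[ca_idx]
  nres <- length(resnos)
  corr <- diag(nres)
  seen <- integer(0)
  for (b in block_spec) {
    stopifnot(abs(b$rho) <= 1)
    members <- match(b$residues, resnos)
    if (anyNA(members)) stop("block residues not in structure",
                             call. = FALSE)
    if (any(members %in% seen)) stop("blocks must be disjoint",
                                     call. = FALSE)
    seen <- c(seen, members)
    corr[members, members] <- b$rho
    diag(corr)[members] <- 1
  }
  eg <- eigen(corr, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    message("requested correlation not PSD: clipping negative eigenvalues")
  }
  vals <- pmax(eg$values, 0)
  root <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base_xyz <- conf_coords(base, 1L)
  xyz <- matrix(rep(as.vector(t(base_xyz)), each = n_frames), n_frames)
  cols_for <- function(axis) (ca_idx - 1L) * 3L + axis
  for (axis in 1:3) {
    z <- matrix(rnorm(n_frames * nres), n_frames)
    disp <- amplitude_sd * z %*% t(root)
    xyz[, cols_for(axis)] <- xyz[, cols_for(axis)] + disp
  }
  traj <- new_confens(base$atoms, xyz)
  attr(traj, "frame_interval") <- frame_interval
  list(trajectory = traj, correlation = corr, blocks = block_spec)
}

#' Simulate a docking pose set with a known distance distribution
#'
#' Single-atom ligands are placed at distances drawn from a Gaussian
#' mixture around the site (uniform random directions; negative draws are
#' rejected and redrawn).  Scores follow a distance-correlated linear
#' model with Gaussian noise, so closer poses score better.
#'
#' @param n_poses number of poses (0 allowed)
#' @param distance_mixture list of components `c(mode, sd, weight)`
#'   (Angstrom, Angstrom, simplex weight)
#' @param site site coordinates (length 3)
#' @param seed integer RNG seed (mandatory)
#' @param score_slope,score_intercept,score_sd linear score model
#'   (kcal/mol): `score = intercept + slope * distance + noise`
#' @return list: `pose_set` (a `"pose_set"`), `distances` (planted),
#'   `component` (mixture component per pose)
#' @export
simulate_pose_set <- function(n_poses,
                              distance_mixture = list(c(9, 0.5, 0.5),
                                                      c(12.5, 0.5, 0.5)),
                              site = c(0, 0, 0), seed,
                              score_slope = 0.35, score_intercept = -9,
                              score_sd = 0.4) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  comp <- do.call(rbind, lapply(distance_mixture, as.numeric))
  stopifnot(ncol(comp) == 3L, all(comp[, 1] > 0), all(comp[, 2] >= 0))
  if (abs(sum(comp[, 3]) - 1) > 1e-9) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  site <- as.numeric(site)
  poses <- list()
  dists <- numeric(n_poses)
  which_comp <- integer(n_poses)
  rejected <- 0L
  if (n_poses > 0L) {
    for (k in seq_len(n_poses)) {
      ci <- sample.int(nrow(comp), 1L, prob = comp[, 3])
      d <- rnorm(1, comp[ci, 1], comp[ci, 2])
      while (d <= 0) {
        rejected <- rejected + 1L
        d <- rnorm(1, comp[ci, 1], comp[ci, 2])
      }
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      poses[[k]] <- list(id = sprintf("pose_%04d", k),
                         coords = rbind(site + d * u), elements = "C")
      dists[k] <- d
      which_comp[k] <- ci
    }
  }
  if (rejected > 0L) {
    message(sprintf("rejected and redrew %d negative distance draw(s)",
                    rejected))
  }
  scores <- data.frame(
    pose_id = vapply(poses, `[[`, character(1), "id"),
    score_kcal_mol = score_intercept + score_slope * dists +
      rnorm(n_poses, 0, score_sd),
    stringsAsFactors = FALSE)
  if (n_poses == 0L) {
    scores <- data.frame(pose_id = character(0),
                         score_kcal_mol = numeric(0))
  }
  list(pose_set = new_pose_set(poses, scores), distances = dists,
       component = which_comp)
}

#' Write a pose set to the on-disk layout read by [read_pose_set()]
#'
#' @param pose_set a `"pose_set"`
#' @param pose_dir output directory for per-pose PDB files (created)
#' @param score_file output CSV path
#' @return `pose_dir`, invisibly
#' @export
write_pose_set <- function(pose_set, pose_dir, score_file) {
  dir.create(pose_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pose_set$poses) {
    atoms <- data.frame(elety = paste0("C", seq_len(nrow(p$coords))),
                        resid = "LIG", chain = "X", resno = 1L, icode = "",
                        element = p$elements, het = TRUE, occ = 1, b = 0,
                        stringsAsFactors = FALSE)
    ens <- new_confens(atoms, matrix(as.vector(t(p$coords)), 1L))
    write_pdb_models(ens, file.path(pose_dir, paste0(p$id, ".pdb")))
  }
  utils::write.csv(pose_set$scores, score_file, row.names = FALSE,
                   quote = FALSE)
  invisible(pose_dir)
}
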