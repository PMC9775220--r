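# Loop-state inference: loop-to-site distances, open/closed classification,
# genetic subensemble selection against an experimental SAXS curve, and the
# two-state population scan.

#' Loop centre-of-mass to site-atom distance, per conformer
#'
#' The gating metric: the Euclidean distance from the mass-weighted centre
#' of mass of a loop segment to a reference site atom (e.g. the T1 copper),
#' evaluated in every conformer of the pool.
#'
#' @param ens a `confens`
#' @param loop_range residue range `c(first, last)` of the loop
#' @param site site-atom address `list(chain =, resno =, elety =)`
#' @param chain chain holding the loop (default the site chain)
#' @return numeric vector of distances (Angstrom), one per conformer
#' @export
loop_site_distance <- function(ens, loop_range, site, chain = site$chain) {
  loop <- select_subset(ens, chain = chain, residue_range = loop_range)
  vapply(seq_len(n_models(ens)), function(m) {
    com <- center_of_mass(conf_coords(loop, m), loop$atoms$element,
                          mass_weighted = TRUE)
    site_xyz <- atom_coords(ens, site$chain, site$resno, site$elety,
                            icode = if (is.null(site$icode)) "" else
                              site$icode, model = m)
    sqrt(sum((com - site_xyz)^2))
  }, numeric(1))
}

#' Summed accessible surface area of the residue patch around a site
#'
#' The "ASA near the site" metric: total accessible area of every residue
#' with at least one heavy atom within `radius` of the site atom.  The
#' patch membership is decided per conformer.
#'
#' @inheritParams loop_site_distance
#' @param radius patch radius (Angstrom), default 12
#' @param probe_radius,n_points passed to [shrake_rupley_asa()]
#' @return numeric vector (Angstrom^2), one value per conformer
#' @export
site_patch_asa <- function(ens, site, radius = 12, probe_radius = 1.4,
                           n_points = 240L) {
  vapply(seq_len(n_models(ens)), function(m) {
    xyz <- conf_coords(ens, m)
    site_xyz <- atom_coords(ens, site$chain, site$resno, site$elety,
                            model = m)
    d <- sqrt(colSums((t(xyz) - site_xyz)^2))
    heavy <- ens$atoms$element != "H"
    near <- unique(atom_keys(ens$atoms)[heavy & d <= radius])
    tab <- shrake_rupley_asa(ens, model = m, probe_radius = probe_radius,
                             n_points = n_points)
    sum(tab$asa[paste(tab$chain, tab$resno, tab$icode, sep = "|") %in% near])
  }, numeric(1))
}

#' Classify conformers as open or closed
#'
#' Closed means the loop sits at or below a distance boundary.  The
#' boundary is either given explicitly (`method = "threshold"`) or found by
#' a deterministic one-dimensional 2-means split (`method = "split"`, means
#' initialised at the minimum and maximum) with the boundary at the
#' midpoint of the two cluster means.  Degenerate inputs (a single
#' conformer, or a collapsed cluster) fall back to a median threshold with
#' a warning.
#'
#' @param distances per-conformer loop-to-site distances (Angstrom)
#' @param patch_asa optional per-conformer site-patch ASA, carried through
#' @param method `"split"` (default) or `"threshold"`
#' @param threshold explicit boundary (Angstrom), required for
#'   `method = "threshold"`
#' @return list of class `"state_labels"`: `labels` (character
#'   "open"/"closed"), `boundary`, `d_loop_site`, `patch_asa`
#' @export
classify_states <- function(distances, patch_asa = NULL,
                            method = c("split", "threshold"),
                            threshold = NULL) {
  method <- match.arg(method)
  d <- as.numeric(distances)
  stopifnot(length(d) >= 1L, all(d >= 0))
  if (method == "threshold") {
    if (is.null(threshold)) stop("threshold method needs a threshold",
                                 call. = FALSE)
    boundary <- threshold
  } else {
    boundary <- .two_means_boundary(d)
  }
  labels <- ifelse(d <= boundary, "closed", "open")
  structure(list(labels = labels, boundary = boundary, d_loop_site = d,
                 patch_asa = patch_asa),
            class = "state_labels")
}

.two_means_boundary <- function(d) {
  fallback <- function(why) {
    warning("two-component split degenerate (", why,
            "): falling back to median threshold")
    median(d)
  }
  if (length(d) < 2L || diff(range(d)) == 0) {
    return(fallback("fewer than 2 distinct values"))
  }
  mu <- range(d)
  for (iter in 1:100) {
    assign1 <- abs(d - mu[1]) <= abs(d - mu[2])
    if (all(assign1) || !any(assign1)) return(fallback("empty cluster"))
    mu_new <- c(mean(d[assign1]), mean(d[!assign1]))
    if (max(abs(mu_new - mu)) < 1e-12) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mean(mu)
}

#' @export
print.state_labels <- function(x, ...) {
  cat(sprintf("<state_labels> %d conformers: %d closed / %d open (boundary %.2f A)\n",
              length(x$labels), sum(x$labels == "closed"),
              sum(x$labels == "open"), x$boundary))
  invisible(x)
}

#' Per-model theoretical curves for a conformer pool
#'
#' Convenience wrapper computing one Debye curve per conformer on a common
#' grid, the input expected by [select_subensemble()].
#'
#' @param ens a `confens`
#' @param s_grid momentum-transfer grid (inverse Angstrom)
#' @param ... passed to [debye_curve()]
#' @return list of `saxs_curve` objects, one per model
#' @export
pool_debye_curves <- function(ens, s_grid, ...) {
  lapply(seq_len(n_models(ens)), function(m) {
    debye_curve(ens, s_grid, model = m, ...)
  })
}

.curve_matrix <- function(curves) {
  s <- curves[[1]]$s
  for (cv in curves) {
    if (length(cv$s) != length(s) || max(abs(cv$s - s)) > 1e-9) {
      stop("pool curves are not on a common s grid", call. = FALSE)
    }
  }
  list(s = s, m = vapply(curves, function(cv) cv$intensity,
                         numeric(length(s))))
}

#' Genetic selection of a subensemble that fits a SAXS profile
#'
#' Searches size-`n_se` multisets of pool members whose uniformly averaged
#' theoretical curve minimises the chi-square discrepancy (with analytic
#' scale factor) against the experimental profile.  Plain generational GA:
#' tournament selection, single-point crossover, per-gene mutation to a
#' random pool index, elitism of the best individual, random immigrants
#' (5% per generation) against premature convergence, and greedy seeding
#' of the initial population with the best-fitting single models.  A seed
#' is mandatory so selections are reproducible.
#'
#' @param pool_curves list of `saxs_curve` objects (one per pool model)
#' @param exp_profile a `saxs_profile` on the same grid
#' @param n_se subensemble size (>= 1)
#' @param seed integer RNG seed (mandatory)
#' @param pop_size GA population size
#' @param generations number of generations
#' @param mutation_rate per-gene mutation probability
#' @param allow_repeats permit repeated pool members (multiset, default)
#' @return list of class `"subensemble_selection"`: `member_indices`
#'   (sorted), `size`, `chi2`, `scale`, `history` (best chi2 per
#'   generation), `pool_chi2` (chi2 of the uniform full-pool average)
#' @export
select_subensemble <- function(pool_curves, exp_profile, n_se, seed,
                               pop_size = 100L, generations = 200L,
                               mutation_rate = 0.1, allow_repeats = TRUE) {
  if (n_se < 1L) stop("n_se must be >= 1", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  cm <- .curve_matrix(pool_curves)
  p <- ncol(cm$m)
  if (!allow_repeats && n_se > p) {
    stop("n_se exceeds pool size with allow_repeats = FALSE", call. = FALSE)
  }
  score <- function(idx) {
    avg <- new_saxs_curve(cm$s, rowMeans(cm$m[, idx, drop = FALSE]))
    chi2_discrepancy(exp_profile, avg)
  }
  pool_fit <- score(seq_len(p))
  if (p == 1L) {
    one <- score(1L)
    return(structure(list(member_indices = rep(1L, n_se), size = n_se,
                          chi2 = one$chi2, scale = one$scale,
                          history = one$chi2, pool_chi2 = pool_fit$chi2),
                     class = "subensemble_selection"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function() sample.int(p, n_se, replace = allow_repeats)
  popn <- replicate(pop_size, draw(), simplify = FALSE)
  if (allow_repeats) {
    # greedy seeding: the best-fitting single models, replicated, join the
    # initial population
    single <- vapply(seq_len(p), function(i) score(rep(i, n_se))$chi2,
                     numeric(1))
    n_seed <- min(p, max(1L, pop_size %/% 4L))
    seeds_idx <- order(single)[seq_len(n_seed)]
    popn[seq_len(n_seed)] <- lapply(seeds_idx, rep, n_se)
  }
  fitness <- vapply(popn, function(idx) score(idx)$chi2, numeric(1))
  history <- numeric(generations)
  n_immigrant <- max(1L, pop_size %/% 20L)
  for (g in seq_len(generations)) {
    elite <- which.min(fitness)
    nxt <- list(popn[[elite]])
    # random immigrants keep the search from collapsing early
    for (im in seq_len(n_immigrant)) nxt[[length(nxt) + 1L]] <- draw()
    while (length(nxt) < pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, 2L)
        popn[[cand[which.min(fitness[cand])]]]
      }
      pa <- pick(); pb <- pick()
      cut <- sample.int(n_se, 1L)
      child <- c(head(pa, cut), tail(pb, n_se - cut))
      mut <- runif(n_se) < mutation_rate
      if (any(mut)) child[mut] <- sample.int(p, sum(mut), replace = TRUE)
      if (!allow_repeats) {
        while (anyDuplicated(child)) {
          dup <- which(duplicated(child))
          child[dup] <- sample.int(p, length(dup))
        }
      }
      nxt[[length(nxt) + 1L]] <- child
    }
    popn <- nxt
    fitness <- vapply(popn, function(idx) score(idx)$chi2, numeric(1))
    history[g] <- min(fitness)
  }
  best <- popn[[which.min(fitness)]]
  fit <- score(best)
  structure(list(member_indices = sort(best), size = n_se,
                 chi2 = fit$chi2, scale = fit$scale, history = history,
                 pool_chi2 = pool_fit$chi2),
            class = "subensemble_selection")
}

# Save/restore .Random.seed so seeded routines do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Scan subensemble sizes and keep the best fit
#'
#' @inheritParams select_subensemble
#' @param n_se_values candidate subensemble sizes
#' @return the best `"subensemble_selection"`, with an extra element
#'   `scan` (data frame n_se, chi2)
#' @export
select_subensemble_scan <- function(pool_curves, exp_profile,
                                    n_se_values = c(5L, 10L, 20L, 50L),
                                    seed, ...) {
  fits <- lapply(seq_along(n_se_values), function(k) {
    select_subensemble(pool_curves, exp_profile, n_se_values[k],
                       seed = seed + k - 1L, ...)
  })
  chi2s <- vapply(fits, `[[`, numeric(1), "chi2")
  best <- fits[[which.min(chi2s)]]
  best$scan <- data.frame(n_se = n_se_values, chi2 = chi2s)
  best
}

#' Two-state population scan against an experimental profile
#'
#' For each closed-state fraction `f` on a grid over [0, 1], scores the
#' mixed curve `f * closed + (1 - f) * open` against the experimental
#' profile (chi-square with fitted scale) and reports the best fraction.
#' Ties are broken toward the larger `f` (logged with a message).
#'
#' @param closed_curve,open_curve state-averaged `saxs_curve`s on the
#'   experimental grid
#' @param exp_profile a `saxs_profile`
#' @param f_step grid step in (0, 0.5]
#' @return list of class `"population_fit"`: `f_grid`, `chi2_of_f`,
#'   `best_f`, `best_chi2`
#' @export
population_scan <- function(closed_curve, open_curve, exp_profile,
                            f_step = 0.01) {
  stopifnot(f_step > 0, f_step <= 0.5)
  f_grid <- unique(c(seq(0, 1, by = f_step), 1))
  chi2s <- vapply(f_grid, function(f) {
    mix <- new_saxs_curve(closed_curve$s,
                          f * closed_curve$intensity +
                            (1 - f) * open_curve$intensity)
    chi2_discrepancy(exp_profile, mix)$chi2
  }, numeric(1))
  best_chi2 <- min(chi2s)
  hits <- which(chi2s <= best_chi2)
  if (length(hits) > 1L) {
    message(sprintf("population scan: %d tied minima, keeping largest f",
                    length(hits)))
  }
  best_f <- max(f_grid[hits])
  structure(list(f_grid = f_grid, chi2_of_f = chi2s, best_f = best_f,
                 best_chi2 = best_chi2),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> best closed fraction %.2f (chi2 = %.3f)\n",
              x$best_f, x$best_chi2))
  invisible(x)
}
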