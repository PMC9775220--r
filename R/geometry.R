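# Structural measurement primitives.

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Finds the rotation/translation minimising the (optionally weighted)
#' root-mean-square deviation between two paired coordinate sets.  The
#' returned transform maps `coords_b` onto `coords_a`:
#' `b_fit = b %*% rotation + rep(translation, each = N)`.
#'
#' @param coords_a,coords_b N x 3 matrices of paired positions (Angstrom)
#' @param weights optional non-negative length-N weights
#' @return a list with elements `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd` (Angstrom), of class `"superposition"`
#' @export
kabsch_superpose_rmsd <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  n <- nrow(a)
  if (n < 3L || nrow(b) != n || ncol(a) != 3L || ncol(b) != 3L) {
    stop("need two paired N x 3 coordinate sets with N >= 3", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  ca <- colSums(a * w)
  cb <- colSums(b * w)
  ac <- sweep(a, 2, ca)
  bc <- sweep(b, 2, cb)
  # Degenerate (collinear) sets leave the rotation about the common axis
  # undetermined.
  for (m in list(ac, bc)) {
    sv <- svd(m * sqrt(w))$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-300)) {
      stop("degenerate (collinear) coordinates: superposition undefined",
           call. = FALSE)
    }
  }
  h <- t(bc * w) %*% ac
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  bfit <- bc %*% rot
  rmsd <- sqrt(sum(w * rowSums((bfit - ac)^2)))
  structure(list(rotation = rot, translation = ca - as.vector(cb %*% rot),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Centre of mass of a set of atoms
#'
#' @param coords N x 3 coordinate matrix (Angstrom)
#' @param elements element symbols, required when `mass_weighted`
#' @param mass_weighted use standard atomic masses (default) or the
#'   unweighted centroid
#' @return length-3 numeric vector
#' @export
center_of_mass <- function(coords, elements = NULL, mass_weighted = TRUE) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty atom list", call. = FALSE)
  if (mass_weighted) {
    if (is.null(elements)) stop("elements required for mass weighting",
                                call. = FALSE)
    w <- atomic_masses(elements)
  } else {
    w <- rep(1, nrow(coords))
  }
  colSums(coords * w) / sum(w)
}

.scope_mask <- function(atoms, scope) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  switch(scope,
         "all" = rep(TRUE, nrow(atoms)),
         "heavy" = atoms$element != "H",
         "sidechain-heavy" = atoms$element != "H" &
           !(atoms$elety %in% backbone),
         stop("unknown atom scope: ", scope, call. = FALSE))
}

#' Minimum inter-residue distance
#'
#' Minimum pairwise Euclidean distance between the atoms of two residues,
#' over a configurable atom scope.  Crystal structures usually lack
#' hydrogens, so the default scope is heavy atoms.
#'
#' @param ens a `confens`
#' @param res_a,res_b residue addresses: `list(chain =, resno =, icode =)`
#' @param atom_scope `"heavy"` (default), `"all"` or `"sidechain-heavy"`
#' @param model model index
#' @return distance in Angstrom
#' @export
min_residue_distance <- function(ens, res_a, res_b,
                                 atom_scope = c("heavy", "all",
                                                "sidechain-heavy"),
                                 model = 1L) {
  atom_scope <- match.arg(atom_scope)
  pick <- function(res) {
    icode <- if (is.null(res$icode)) "" else res$icode
    idx <- which(ens$atoms$chain == res$chain & ens$atoms$resno == res$resno &
                   ens$atoms$icode == icode)
    if (length(idx) == 0L) {
      stop(sprintf("residue %s/%d not found", res$chain, res$resno),
           call. = FALSE)
    }
    idx <- idx[.scope_mask(ens$atoms[idx, , drop = FALSE], atom_scope)]
    if (length(idx) == 0L) {
      stop(sprintf("residue %s/%d has no atoms in scope '%s'",
                   res$chain, res$resno, atom_scope), call. = FALSE)
    }
    idx
  }
  xyz <- conf_coords(ens, model)
  xa <- xyz[pick(res_a), , drop = FALSE]
  xb <- xyz[pick(res_b), , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from a deterministic Fibonacci point lattice on
#' each solvent-expanded sphere, summed per residue.  Relative accessibility
#' is the residue total divided by a fixed per-residue-type reference
#' maximum (Tien et al. theoretical values); residue types absent from the
#' reference table get `NA` relative values.
#'
#' @param ens a `confens`
#' @param model model index
#' @param probe_radius solvent probe radius (Angstrom), default 1.4
#' @param n_points sampling points per atom, default 960
#' @param include_het include HETATM atoms as occluders and in the table
#' @return data frame (chain, resno, icode, resid, asa, rel) with one row
#'   per residue; `asa` in Angstrom^2, `rel` in percent
#' @export
shrake_rupley_asa <- function(ens, model = 1L, probe_radius = 1.4,
                              n_points = 960L, include_het = TRUE) {
  stopifnot(probe_radius > 0, n_points >= 100L)
  a <- ens$atoms
  keep <- if (include_het) rep(TRUE, nrow(a)) else !a$het
  a <- a[keep, , drop = FALSE]
  xyz <- conf_coords(ens, model)[keep, , drop = FALSE]
  rad <- vdw_radii(a$element) + probe_radius
  n <- nrow(a)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i] + rep(xyz[i, ], each = n_points)
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | dj < rad[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * rad[i]^2 * acc / n_points
  }
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  ord <- unique(key)
  res_area <- vapply(ord, function(k) sum(area[key == k]), numeric(1))
  first <- match(ord, key)
  ref <- .max_asa[a$resid[first]]
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resid = a$resid[first],
             asa = unname(res_area),
             rel = unname(100 * res_area / ref),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Radius of gyration from coordinates
#'
#' @param ens a `confens` (or an N x 3 matrix)
#' @param model model index (ignored for a matrix)
#' @param mass_weighted weight by atomic masses (default) or uniformly
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(ens, model = 1L, mass_weighted = TRUE) {
  if (inherits(ens, "confens")) {
    xyz <- conf_coords(ens, model)
    w <- if (mass_weighted) atomic_masses(ens$atoms$element)
         else rep(1, nrow(xyz))
  } else {
    xyz <- as.matrix(ens)
    w <- rep(1, nrow(xyz))
  }
  if (nrow(xyz) == 0L) stop("empty coordinate set", call. = FALSE)
  com <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / sum(w))
}

#' Matthews coefficient and solvent content
#'
#' `V_M = cell_volume / (molecules_per_cell * molecular_mass)`;
#' solvent fraction is `(1 - 1.23 / V_M) * 100` percent, with 1.23 A^3/Da
#' the reciprocal of the standard protein partial specific volume.
#'
#' @param cell_volume unit-cell volume (Angstrom^3)
#' @param molecules_per_cell number of protein molecules in the unit cell
#' @param molecular_mass molecular mass of one molecule (Da)
#' @return list with `vm` (Angstrom^3/Da) and `solvent_pct`
#' @export
matthews_solvent <- function(cell_volume, molecules_per_cell,
                             molecular_mass) {
  stopifnot(cell_volume > 0, molecules_per_cell > 0, molecular_mass > 0)
  vm <- cell_volume / (molecules_per_cell * molecular_mass)
  solv <- (1 - 1.23 / vm) * 100
  if (vm <= 1.23) {
    warning(sprintf("V_M = %.3f <= 1.23 A^3/Da implies negative solvent",
                    vm))
  }
  list(vm = vm, solvent_pct = solv)
}
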