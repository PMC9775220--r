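# Trajectory statistics (RMSF, covariance PCA, dynamic cross-correlation)
# and the correlation-weighted protein residue network with optimal and
# suboptimal communication paths.

.traj_ca_indices <- function(traj, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  idx <- if (selection == "calpha") {
    which(traj$atoms$elety == "CA" & !traj$atoms$het)
  } else {
    which(!traj$atoms$het)
  }
  if (length(idx) == 0L) stop("empty atom selection", call. = FALSE)
  idx
}

# Frames x (3n) coordinate matrix for a subset of atoms.
.traj_coord_matrix <- function(traj, idx) {
  cols <- as.vector(t(outer((idx - 1L) * 3L, 1:3, "+")))
  traj$xyz[, cols, drop = FALSE]
}

# Two-pass alignment onto the mean structure: mean, superpose every frame,
# recompute the mean, superpose again.  Removes rigid-body motion.
.align_frames <- function(mat) {
  nfr <- nrow(mat)
  as_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  flat <- function(m) as.vector(t(m))
  ref <- as_xyz(colMeans(mat))
  for (pass in 1:2) {
    for (f in seq_len(nfr)) {
      x <- as_xyz(mat[f, ])
      sp <- kabsch_superpose_rmsd(ref, x)
      mat[f, ] <- flat(x %*% sp$rotation +
                         rep(sp$translation, each = nrow(x)))
    }
    ref <- as_xyz(colMeans(mat))
  }
  mat
}

#' Root-mean-square fluctuation per residue
#'
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over frames, optionally after
#' removing rigid-body motion by two-pass Kabsch superposition of every
#' frame onto the mean structure.
#'
#' @param traj a multi-model `confens` (>= 2 frames)
#' @param selection `"calpha"` (default) or `"all"` non-HETATM atoms
#' @param align superpose frames onto the mean before measuring (default
#'   TRUE)
#' @return named numeric vector of RMSF values (Angstrom), one per residue
#' @export
rmsf <- function(traj, selection = c("calpha", "all"), align = TRUE) {
  stopifnot(inherits(traj, "confens"))
  if (n_models(traj) < 2L) stop("need at least 2 frames", call. = FALSE)
  idx <- .traj_ca_indices(traj, selection)
  mat <- .traj_coord_matrix(traj, idx)
  if (align) mat <- .align_frames(mat)
  dev2 <- sweep(mat, 2, colMeans(mat))^2
  per_atom <- sqrt(rowSums(matrix(colMeans(dev2), ncol = 3L, byrow = TRUE)))
  key <- atom_keys(traj$atoms[idx, , drop = FALSE])
  out <- vapply(split(per_atom, factor(key, levels = unique(key))),
                function(v) sqrt(mean(v^2)), numeric(1))
  out
}

#' Dynamic cross-correlation matrix of C-alpha displacements
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` over aligned
#' frames, with `dr = r - <r>` (scalar dot-product correlation of 3-D
#' displacement vectors, the standard DCC definition).  Residues with zero
#' positional variance get zero off-diagonal entries (diagonal 1) and a
#' message.
#'
#' @param traj a multi-model `confens`
#' @param stride keep every `stride`-th frame (>= 10 frames must remain)
#' @param align remove rigid-body motion first (default TRUE)
#' @return list of class `"dcc_matrix"`: `values` (R x R symmetric, unit
#'   diagonal), `residues` (residue keys)
#' @export
dcc_matrix <- function(traj, stride = 1L, align = TRUE) {
  stopifnot(inherits(traj, "confens"), stride >= 1L)
  frames <- seq(1L, n_models(traj), by = stride)
  if (length(frames) < 10L) {
    stop("fewer than 10 frames after stride", call. = FALSE)
  }
  idx <- .traj_ca_indices(traj, "calpha")
  mat <- .traj_coord_matrix(traj, idx)[frames, , drop = FALSE]
  if (align) mat <- .align_frames(mat)
  dev <- sweep(mat, 2, colMeans(mat))
  nres <- length(idx)
  dx <- dev[, seq(1L, 3L * nres, by = 3L), drop = FALSE]
  dy <- dev[, seq(2L, 3L * nres, by = 3L), drop = FALSE]
  dz <- dev[, seq(3L, 3L * nres, by = 3L), drop = FALSE]
  cross <- (t(dx) %*% dx + t(dy) %*% dy + t(dz) %*% dz) / length(frames)
  v <- diag(cross)
  zero <- v <= 0
  if (any(zero)) {
    message(sprintf("%d zero-variance residue(s): rows/columns set to 0",
                    sum(zero)))
    v[zero] <- 1
  }
  cmat <- cross / sqrt(outer(v, v))
  if (any(zero)) {
    cmat[zero, ] <- 0
    cmat[, zero] <- 0
  }
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  res_keys <- atom_keys(traj$atoms[idx, , drop = FALSE])
  dimnames(cmat) <- list(res_keys, res_keys)
  structure(list(values = cmat, residues = res_keys),
            class = "dcc_matrix")
}

#' Principal component analysis of the C-alpha positional covariance
#'
#' Eigendecomposition of the 3R x 3R covariance matrix of aligned C-alpha
#' coordinates.  Rank deficiency (more coordinates than frames) is allowed;
#' trailing eigenvalues are clipped at zero.
#'
#' @inheritParams dcc_matrix
#' @return list of class `"pca_result"`: `eigenvalues` (descending,
#'   Angstrom^2), `components` (orthonormal columns), `projections`
#'   (frames x modes), `variance_explained`
#' @export
covariance_pca <- function(traj, stride = 1L, align = TRUE) {
  stopifnot(inherits(traj, "confens"), stride >= 1L)
  frames <- seq(1L, n_models(traj), by = stride)
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  idx <- .traj_ca_indices(traj, "calpha")
  mat <- .traj_coord_matrix(traj, idx)[frames, , drop = FALSE]
  if (align) mat <- .align_frames(mat)
  centered <- sweep(mat, 2, colMeans(mat))
  cv <- crossprod(centered) / (nrow(centered) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  tot <- sum(vals)
  structure(list(eigenvalues = vals, components = eg$vectors,
                 projections = centered %*% eg$vectors,
                 variance_explained = if (tot > 0) vals / tot else vals),
            class = "pca_result")
}

#' Correlation-weighted protein residue network
#'
#' Nodes are residue mass-weighted centres of mass in the mean structure;
#' an edge joins residues whose centres lie within `cutoff` (4.5 Angstrom
#' by default, the centre-of-mass contact criterion) and whose correlation
#' is non-zero.  The edge length is `-ln|C_ij|` (WISP convention: the
#' stronger the correlation, the shorter the edge) or `1 - |C_ij|`.
#'
#' @param mean_structure a single-model `confens` (e.g. the trajectory
#'   mean)
#' @param dcc a `"dcc_matrix"` whose residues match the structure
#' @param cutoff centre-of-mass contact cutoff (Angstrom), > 0
#' @param weighting `"neglog"` (default) or `"one-minus"`
#' @return list of class `"residue_network"`: `graph` (igraph), `nodes`
#'   (data frame id, x, y, z), `cutoff`, `weighting`
#' @export
build_network <- function(mean_structure, dcc, cutoff = 4.5,
                          weighting = c("neglog", "one-minus")) {
  weighting <- match.arg(weighting)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  stopifnot(inherits(dcc, "dcc_matrix"))
  a <- mean_structure$atoms
  keys <- atom_keys(a)
  res_keys <- unique(keys[!a$het])
  if (!identical(res_keys, dcc$residues)) {
    stop("DCC residues do not match the structure's residues",
         call. = FALSE)
  }
  xyz <- conf_coords(mean_structure, 1L)
  coms <- t(vapply(res_keys, function(k) {
    sel <- which(keys == k & !a$het)
    center_of_mass(xyz[sel, , drop = FALSE], a$element[sel])
  }, numeric(3)))
  nres <- length(res_keys)
  d2 <- outer(rowSums(coms^2), rowSums(coms^2), "+") - 2 * coms %*% t(coms)
  absc <- abs(dcc$values)
  pair <- which(upper.tri(d2) & d2 <= cutoff^2 & absc > 0, arr.ind = TRUE)
  w <- if (weighting == "neglog") -log(absc[pair]) else 1 - absc[pair]
  g <- igraph::graph_from_data_frame(
    data.frame(from = res_keys[pair[, 1]], to = res_keys[pair[, 2]],
               abs_c = absc[pair], weight = w),
    directed = FALSE,
    vertices = data.frame(name = res_keys, x = coms[, 1], y = coms[, 2],
                          z = coms[, 3]))
  structure(list(graph = g,
                 nodes = data.frame(id = res_keys, x = coms[, 1],
                                    y = coms[, 2], z = coms[, 3],
                                    row.names = NULL),
                 cutoff = cutoff, weighting = weighting),
            class = "residue_network")
}

#' Optimal and suboptimal paths between two residues
#'
#' Path 1 is the Dijkstra optimum; paths 2..k are loopless k-shortest
#' (Yen) paths.  Lengths are non-decreasing.  A disconnected pair yields an
#' empty path set with `reachable = FALSE`.
#'
#' @param net a `"residue_network"`
#' @param source,target residue ids (node names)
#' @param k maximum number of paths (<= 15 by convention)
#' @return list of class `"path_set"`: `source`, `target`, `paths` (list of
#'   node-id vectors), `lengths`, `reachable`
#' @export
shortest_paths_k <- function(net, source, target, k = 15L) {
  g <- net$graph
  vn <- igraph::V(g)$name
  if (!(source %in% vn) || !(target %in% vn)) {
    stop("source/target not in network", call. = FALSE)
  }
  dist <- igraph::distances(g, v = source, to = target)[1, 1]
  if (!is.finite(dist)) {
    return(structure(list(source = source, target = target,
                          paths = list(), lengths = numeric(0),
                          reachable = FALSE),
                     class = "path_set"))
  }
  ksp <- igraph::k_shortest_paths(g, from = source, to = target, k = k)
  paths <- lapply(ksp$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
  lens <- vapply(ksp$epaths, function(ep) {
    sum(igraph::E(g)$weight[as.integer(ep)])
  }, numeric(1))
  ord <- order(lens)
  structure(list(source = source, target = target, paths = paths[ord],
                 lengths = lens[ord], reachable = TRUE),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %s -> %s: %d path(s)%s\n", x$source, x$target,
              length(x$paths),
              if (x$reachable) sprintf(", optimal length %.3f",
                                       x$lengths[1]) else " (unreachable)"))
  invisible(x)
}

#' Rank residue pairs by the change in optimal path length between two
#' networks
#'
#' For each pair, `delta = length in net_b - length in net_a` (negative
#' means communication shortened in B).  The table is sorted by `delta`
#' ascending; relative deltas are emitted alongside.  Per-residue
#' participation counts over the optimal paths of the 5 most-shortened
#' pairs are attached for mapping onto the structure.
#'
#' @param net_a,net_b two `"residue_network"`s sharing the requested nodes
#' @param pairs data frame with columns `source`, `target`
#' @param n_top number of most-shortened pairs used for participation
#' @return data frame (source, target, len_a, len_b, delta, delta_rel,
#'   reachable) sorted by delta, with attribute `participation` (data frame
#'   residue, count_a, count_b)
#' @export
path_delta_ranking <- function(net_a, net_b, pairs, n_top = 5L) {
  stopifnot(all(c("source", "target") %in% names(pairs)))
  one <- function(net, s, t) {
    vn <- igraph::V(net$graph)$name
    if (!(s %in% vn) || !(t %in% vn)) {
      stop(sprintf("node %s or %s missing from network", s, t),
           call. = FALSE)
    }
    igraph::distances(net$graph, v = s, to = t)[1, 1]
  }
  la <- mapply(one, list(net_a), pairs$source, pairs$target)
  lb <- mapply(one, list(net_b), pairs$source, pairs$target)
  reachable <- is.finite(la) & is.finite(lb)
  delta <- ifelse(reachable, lb - la, NA_real_)
  out <- data.frame(source = pairs$source, target = pairs$target,
                    len_a = la, len_b = lb, delta = delta,
                    delta_rel = ifelse(reachable & la > 0, delta / la,
                                       NA_real_),
                    reachable = reachable, stringsAsFactors = FALSE)
  out <- out[order(out$delta, !out$reachable), , drop = FALSE]
  rownames(out) <- NULL
  top <- head(out[out$reachable, , drop = FALSE], n_top)
  count_nodes <- function(net) {
    tab <- table(unlist(lapply(seq_len(nrow(top)), function(i) {
      sp <- shortest_paths_k(net, top$source[i], top$target[i], k = 1L)
      if (sp$reachable) sp$paths[[1]] else character(0)
    })))
    tab
  }
  ca <- count_nodes(net_a)
  cb <- count_nodes(net_b)
  residues <- sort(unique(c(names(ca), names(cb))))
  attr(out, "participation") <- data.frame(
    residue = residues,
    count_a = as.integer(ifelse(residues %in% names(ca), ca[residues], 0)),
    count_b = as.integer(ifelse(residues %in% names(cb), cb[residues], 0)),
    row.names = NULL)
  out
}

#' Export a residue network as an edge-list text table
#'
#' @param net a `"residue_network"`
#' @param path output path (TSV: node_i, node_j, abs_c, weight)
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  utils::write.table(ed[, c("from", "to", "abs_c", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
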