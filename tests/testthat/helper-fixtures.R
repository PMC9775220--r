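# Fixtures built in code and independent oracles used across the suite.

# Build a confens directly from an N x 3 coordinate matrix (or an
# nmodels x 3N matrix for multi-model ensembles), one single-atom residue
# per bead.
bead_ensemble <- function(coords, element = "C", elety = "CA",
                          het = FALSE, chain = "A", resno = NULL) {
  if (is.null(dim(coords)) || ncol(coords) == 3L) {
    coords <- rbind(coords)
    xyz <- matrix(as.vector(t(coords)), 1L)
    n <- nrow(coords)
  } else {
    xyz <- coords
    n <- ncol(coords) / 3L
  }
  atoms <- data.frame(
    elety = rep_len(elety, n), resid = "GLY", chain = chain,
    resno = if (is.null(resno)) seq_len(n) else resno, icode = "",
    element = rep_len(element, n), het = rep_len(het, n), occ = 1, b = 0,
    stringsAsFactors = FALSE)
  loopdyn:::new_confens(atoms, xyz)
}

# A small all-atom-style PDB text fixture: n_res three-atom residues.
toy_pdb_lines <- function(n_res = 3L, chain = "A", resno0 = 1L,
                          model_ids = NULL, shift = 0) {
  body <- function(dz) {
    unlist(lapply(seq_len(n_res), function(r) {
      base <- c(3.8 * r, 0, dz)
      sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        (r - 1L) * 3L + 1:3, c("N", "CA", "C"), "ALA", chain,
        resno0 + r - 1L, base[1] + c(0, 1.2, 2.1), base[2] + c(0, 1.0, 0.4),
        base[3], 1, 10, c("N", "C", "C"))
    }))
  }
  if (is.null(model_ids)) {
    c(body(shift), "END")
  } else {
    c(unlist(lapply(model_ids, function(m) {
      c(sprintf("MODEL     %4d", m), body(shift + (m - 1) * 0.5), "ENDMDL")
    })), "END")
  }
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# O(N^2) reference Debye sum, deliberately naive.
brute_debye <- function(coords, s_grid, f = rep(1, nrow(coords))) {
  n <- nrow(coords)
  vapply(s_grid, function(s) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) {
          acc <- acc + f[i]^2
        } else {
          r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
          acc <- acc + f[i] * f[j] * sin(s * r) / (s * r)
        }
      }
    }
    acc
  }, numeric(1))
}

# Dense grid search over the scale factor, refined around the best cell.
grid_search_mu_chi2 <- function(exp_profile, theo, normalization = "K-1") {
  k <- nrow(exp_profile)
  denom <- if (normalization == "K-1") k - 1L else k
  chi2_at <- function(mu) {
    sum(((exp_profile$intensity - mu * theo$intensity) /
           exp_profile$sigma)^2) / denom
  }
  mus <- seq(1e-3, 20, length.out = 4001)
  c1 <- vapply(mus, chi2_at, numeric(1))
  best <- mus[which.min(c1)]
  for (width in c(0.01, 1e-5)) {
    mus <- seq(best - width, best + width, length.out = 4001)
    cc <- vapply(mus, chi2_at, numeric(1))
    best <- mus[which.min(cc)]
  }
  list(mu = best, chi2 = chi2_at(best))
}

# Rotation-space minimisation oracle for RMSD: coarse Euler-angle grid
# followed by Nelder-Mead refinement from the best grid cells.  Independent
# of the Kabsch solution.
rmsd_rotation_oracle <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((bc %*% t(rotmat(ang)) - ac)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  cells <- expand.grid(grid, grid, grid)
  vals <- apply(cells, 1L, obj)
  best <- Inf
  for (idx in order(vals)[1:5]) {
    op <- stats::optim(as.numeric(cells[idx, ]), obj,
                       control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, op$value)
  }
  best
}

# Exhaustive loopless k-shortest-path oracle via full simple-path
# enumeration.
enumerate_k_paths <- function(graph, from, to, k) {
  ap <- igraph::all_simple_paths(graph, from = from, to = to)
  if (length(ap) == 0L) return(list(paths = list(), lengths = numeric(0)))
  lens <- vapply(ap, function(p) {
    v <- as.integer(p)
    sum(vapply(seq_len(length(v) - 1L), function(i) {
      e <- igraph::get_edge_ids(graph, c(v[i], v[i + 1L]))
      igraph::E(graph)$weight[e]
    }, numeric(1)))
  }, numeric(1))
  ord <- order(lens)[seq_len(min(k, length(lens)))]
  list(paths = lapply(ap[ord], function(p) igraph::V(graph)$name[as.integer(p)]),
       lengths = lens[ord])
}

# Random connected weighted graph on n nodes wrapped as a residue network.
random_test_network <- function(n = 8L, p = 0.45, seed = 1L) {
  set.seed(seed)
  repeat {
    adj <- matrix(runif(n * n) < p, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj + t(adj), mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("R", seq_len(n))
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 2)
  igraph::E(g)$abs_c <- exp(-igraph::E(g)$weight)
  structure(list(graph = g, nodes = data.frame(id = igraph::V(g)$name),
                 cutoff = Inf, weighting = "neglog"),
            class = "residue_network")
}

toy_site <- list(chain = "A", resno = 999L, elety = "CU")

toy_loop_range <- function(spec) {
  c(spec$n_core_residues + 1L,
    spec$n_core_residues + spec$loop_residue_count)
}
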