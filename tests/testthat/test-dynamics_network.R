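static_traj <- function(n_res = 6L, n_frames = 12L, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(n_res * 3, sd = 6), ncol = 3)
  bead_ensemble(matrix(rep(as.vector(t(base)), each = n_frames), n_frames))
}

test_that("RMSF is zero for static and rigidly rotating trajectories", {
  traj <- static_traj()
  expect_equal(unname(rmsf(traj)), rep(0, 6))

  # whole-body rotation about z, alignment removes it
  set.seed(2)
  base <- matrix(rnorm(18, sd = 6), ncol = 3)
  frames <- t(vapply(seq(0, 1.5, length.out = 15), function(th) {
    r <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
    as.vector(t(base %*% t(r) + th * 5))
  }, numeric(18)))
  expect_lt(max(rmsf(bead_ensemble(frames), align = TRUE)), 1e-6)
})

test_that("RMSF of isotropic Gaussian jitter matches sqrt(3) sigma", {
  set.seed(7)
  n_frames <- 5000L
  base <- matrix(rnorm(24, sd = 8), ncol = 3)
  frames <- matrix(rep(as.vector(t(base)), each = n_frames), n_frames)
  sigma <- 0.5
  frames[, 10:12] <- frames[, 10:12] +
    matrix(rnorm(3 * n_frames, 0, sigma), n_frames)
  v <- rmsf(bead_ensemble(frames), align = FALSE)
  expect_lt(abs(v[4] - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.03)
  expect_lt(max(v[-4]), 1e-9)
})

test_that("DCC hits the exact values for identical and negated motions", {
  set.seed(11)
  n <- 60L
  amp <- rnorm(n)
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), ncol = 3, byrow = TRUE)
  frames <- matrix(rep(as.vector(t(base)), each = n), n)
  frames[, 1] <- frames[, 1] + amp          # residue 1 x
  frames[, 4] <- frames[, 4] + amp          # residue 2 x: identical series
  frames[, 7] <- frames[, 7] - amp          # residue 3 x: negated
  dcc <- dcc_matrix(bead_ensemble(frames), align = FALSE)
  expect_equal(unname(diag(dcc$values)), rep(1, 3))
  expect_equal(dcc$values[1, 2], 1, tolerance = 1e-12)
  expect_equal(dcc$values[1, 3], -1, tolerance = 1e-12)
  expect_identical(dcc$values, t(dcc$values))
})

test_that("independent residues decorrelate and rigid motion is removed", {
  base <- bead_ensemble(6 * loopdyn:::.sphere_points(8L))
  sim <- simulate_correlated_trajectory(base, list(), n_frames = 2000L,
                                        amplitude_sd = 0.4, seed = 5)
  dcc <- dcc_matrix(sim$trajectory, align = FALSE)
  off <- dcc$values[upper.tri(dcc$values)]
  expect_lt(max(abs(off)), 0.1)

  # a global rigid rotation applied to all frames leaves aligned DCC
  # unchanged
  dcc_al <- dcc_matrix(sim$trajectory, align = TRUE)
  th <- 0.7
  r <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  rot_xyz <- t(apply(sim$trajectory$xyz, 1L, function(row) {
    as.vector(t(matrix(row, ncol = 3, byrow = TRUE) %*% t(r)))
  }))
  traj_rot <- loopdyn:::new_confens(sim$trajectory$atoms, rot_xyz)
  dcc_rot <- dcc_matrix(traj_rot, align = TRUE)
  expect_equal(dcc_rot$values, dcc_al$values, tolerance = 1e-6)
})

test_that("planted block correlations are recovered within tolerance", {
  base <- bead_ensemble(8 * loopdyn:::.sphere_points(10L))
  blocks <- list(list(residues = 1:3, rho = 0.8),
                 list(residues = 4:5, rho = -0.6))
  sim <- simulate_correlated_trajectory(base, blocks, n_frames = 2000L,
                                        amplitude_sd = 0.5, seed = 6)
  dcc <- dcc_matrix(sim$trajectory, align = FALSE)
  err <- abs(unname(dcc$values) - sim$correlation)
  expect_lt(max(err), 0.08)
})

test_that("zero-variance residues are flagged and neutralised", {
  set.seed(3)
  n <- 40L
  base <- matrix(c(0, 0, 0, 9, 0, 0), ncol = 3, byrow = TRUE)
  frames <- matrix(rep(as.vector(t(base)), each = n), n)
  frames[, 1] <- frames[, 1] + rnorm(n)
  expect_message(dcc <- dcc_matrix(bead_ensemble(frames), align = FALSE),
                 "zero-variance")
  expect_equal(unname(dcc$values[1, 2]), 0)
  expect_equal(unname(diag(dcc$values)), rep(1, 2))
})

test_that("covariance PCA finds a planted collective mode", {
  set.seed(9)
  n_res <- 10L
  base <- 7 * loopdyn:::.sphere_points(n_res)
  mode_dir <- matrix(rnorm(n_res * 3), ncol = 3)
  mode_dir <- mode_dir / sqrt(sum(mode_dir^2))
  n <- 300L
  amp <- rnorm(n, sd = 2)
  frames <- t(vapply(seq_len(n), function(t) {
    as.vector(t(base + amp[t] * mode_dir +
                  matrix(rnorm(n_res * 3, sd = 0.05), ncol = 3)))
  }, numeric(n_res * 3)))
  pca <- covariance_pca(bead_ensemble(frames), align = FALSE)
  expect_gte(pca$variance_explained[1], 0.95)
  expect_equal(sum(pca$eigenvalues),
               sum(diag(cov(sweep(frames, 2, colMeans(frames))))),
               tolerance = 1e-6)
  # modes orthonormal
  k <- 5L
  expect_equal(crossprod(pca$components[, 1:k]), diag(k), tolerance = 1e-9)

  static <- static_traj()
  expect_lt(max(covariance_pca(static)$eigenvalues), 1e-12)
})

test_that("network edges follow the contact cutoff and weight law", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0))
  mean_structure <- bead_ensemble(coords)
  cmat <- matrix(c(1, 1, exp(-1), 1, 1, 0.5, exp(-1), 0.5, 1), 3)
  keys <- loopdyn:::atom_keys(mean_structure$atoms)
  dimnames(cmat) <- list(keys, keys)
  dcc <- structure(list(values = cmat, residues = keys),
                   class = "dcc_matrix")
  net <- build_network(mean_structure, dcc, cutoff = 4.5)
  ed <- igraph::as_data_frame(net$graph)
  expect_equal(nrow(ed), 1L)          # only the 3 A pair is in contact
  expect_equal(ed$weight, 0)          # |C| = 1 -> zero length
  net2 <- build_network(mean_structure, dcc, cutoff = 25)
  ed2 <- igraph::as_data_frame(net2$graph)
  # |C| of 1, 0.5, e^-1 map to lengths 0, ln 2, 1
  expect_equal(sort(ed2$weight), c(0, log(2), 1), tolerance = 1e-12)
  expect_error(build_network(mean_structure, dcc, cutoff = 0), "positive")
  expect_false(igraph::any_loop(net2$graph))
})

test_that("optimal paths beat detours and k = 1 is plain Dijkstra", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "c"), to = c("b", "c", "b"),
               weight = c(1, 1.5, 1.5), abs_c = 0.5), directed = FALSE)
  net <- structure(list(graph = g, nodes = NULL, cutoff = Inf,
                        weighting = "neglog"), class = "residue_network")
  ps <- shortest_paths_k(net, "a", "b", k = 3L)
  expect_equal(ps$paths[[1]], c("a", "b"))
  expect_equal(ps$lengths[1], 1)
  expect_equal(ps$lengths, sort(ps$lengths))
  ps1 <- shortest_paths_k(net, "a", "b", k = 1L)
  expect_equal(length(ps1$paths), 1L)
  expect_equal(ps1$lengths, 1)
})

test_that("suboptimal paths match exhaustive enumeration on random graphs", {
  for (seed in 1:10) {
    net <- random_test_network(8L, seed = seed)
    vs <- igraph::V(net$graph)$name
    ps <- shortest_paths_k(net, vs[1], vs[8], k = 15L)
    oracle <- enumerate_k_paths(net$graph, vs[1], vs[8], 15L)
    expect_equal(ps$lengths, oracle$lengths, tolerance = 1e-12)
    expect_identical(ps$paths, oracle$paths)
  }
})

test_that("disconnected pairs yield an empty, flagged path set", {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("a", "b"))
  net <- structure(list(graph = g, nodes = NULL, cutoff = Inf,
                        weighting = "neglog"), class = "residue_network")
  ps <- shortest_paths_k(net, "a", "b")
  expect_false(ps$reachable)
  expect_equal(length(ps$paths), 0L)
})

test_that("path lengths satisfy the triangle property", {
  net <- random_test_network(8L, seed = 42)
  d <- igraph::distances(net$graph)
  for (a in 1:8) for (b in 1:8) for (c in 1:8) {
    expect_lte(d[a, c], d[a, b] + d[b, c] + 1e-12)
  }
})

test_that("path-delta ranking is zero on identical networks and signed right", {
  net <- random_test_network(8L, seed = 3)
  vs <- igraph::V(net$graph)$name
  pairs <- data.frame(source = vs[c(1, 2)], target = vs[c(8, 7)])
  tab0 <- path_delta_ranking(net, net, pairs)
  expect_true(all(tab0$delta == 0))

  # halve one edge on the optimal route of pair 1 in network B
  netb <- net
  sp <- shortest_paths_k(net, vs[1], vs[8], k = 1L)$paths[[1]]
  eid <- igraph::get_edge_ids(netb$graph, c(sp[1], sp[2]))
  igraph::E(netb$graph)$weight[eid] <-
    igraph::E(netb$graph)$weight[eid] / 2
  tab <- path_delta_ranking(net, netb, pairs)
  expect_lt(min(tab$delta), 0)
  expect_equal(tab$delta, sort(tab$delta))
  part <- attr(tab, "participation")
  expect_true(all(c("residue", "count_a", "count_b") %in% names(part)))
})

test_that("a strengthened residue chain dominates the shortened pairs", {
  base <- bead_ensemble(3.5 * loopdyn:::.sphere_points(12L))
  chain_res <- c(1L, 4L, 7L, 10L)
  weak <- simulate_correlated_trajectory(base, list(), n_frames = 800L,
                                         amplitude_sd = 0.4, seed = 21)
  strong <- simulate_correlated_trajectory(
    base, list(list(residues = chain_res, rho = 0.9)), n_frames = 800L,
    amplitude_sd = 0.4, seed = 22)
  make_net <- function(sim) {
    build_network(base, dcc_matrix(sim$trajectory, align = FALSE),
                  cutoff = 12)
  }
  neta <- make_net(weak)
  netb <- make_net(strong)
  keys <- loopdyn:::atom_keys(base$atoms)
  pairs <- expand.grid(source = keys, target = keys,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source < pairs$target, ]
  tab <- path_delta_ranking(neta, netb, pairs)
  top5 <- head(tab, 5L)
  in_chain <- keys[chain_res]
  frac_chain <- mean(top5$source %in% in_chain & top5$target %in% in_chain)
  expect_gte(frac_chain, 0.8)
  part <- attr(tab, "participation")
  expect_true(all(in_chain %in% part$residue))
  expect_gte(min(part$count_b[part$residue %in% in_chain]), 2L)
})
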