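test_that("loop-to-site distance reduces to simple geometry", {
  # single-atom loop 7 A from the site bead
  atoms <- data.frame(
    elety = c("CA", "CU"), resid = c("MET", "CU"), chain = "A",
    resno = c(10L, 999L), icode = "", element = c("C", "CU"),
    het = c(FALSE, TRUE), occ = 1, b = 0, stringsAsFactors = FALSE)
  xyz <- matrix(c(7, 0, 0, 0, 0, 0), 1L, byrow = TRUE)
  ens <- loopdyn:::new_confens(atoms, xyz)
  expect_equal(loop_site_distance(ens, c(10L, 10L), toy_site), 7)
  xyz0 <- matrix(c(0, 0, 0, 0, 0, 0), 1L)
  expect_equal(loop_site_distance(loopdyn:::new_confens(atoms, xyz0),
                                  c(10L, 10L), toy_site), 0)
  expect_error(loop_site_distance(ens, c(50L, 60L), toy_site), "empty")
})

test_that("generated pools reproduce the calibrated distance moments", {
  gen <- make_two_state_ensemble(2500, 0.5, seed = 101)
  d <- loop_site_distance(gen$ensemble, toy_loop_range(gen$spec), toy_site)
  expect_equal(d, gen$distances, tolerance = 1e-9)
  expect_lt(abs(mean(d) - 18.4) / 18.4, 0.02)
  expect_lt(abs(sd(d) - 3.5) / 3.5, 0.02)
})

test_that("state classification splits a planted bimodal pool", {
  set.seed(33)
  d <- c(rnorm(120, 12, 1), rnorm(80, 24, 1))
  truth <- rep(c("closed", "open"), c(120, 80))
  st <- classify_states(d)
  expect_gte(mean(st$labels == truth), 0.99)
  expect_gt(st$boundary, 14)
  expect_lt(st$boundary, 22)
  # permutation invariance
  perm <- sample(length(d))
  st2 <- classify_states(d[perm])
  expect_identical(st2$labels, st$labels[perm])
  expect_equal(st2$boundary, st$boundary)
})

test_that("explicit thresholds and degenerate splits behave as documented", {
  st <- classify_states(c(1, 2, 3), method = "threshold", threshold = 10)
  expect_true(all(st$labels == "closed"))
  expect_error(classify_states(c(1, 2), method = "threshold"), "threshold")
  expect_warning(st1 <- classify_states(5, method = "split"), "degenerate")
  expect_equal(st1$labels, "closed")
  expect_warning(classify_states(rep(4, 10)), "degenerate")
})

test_that("subensemble selection degenerates gracefully on a pool of one", {
  s <- seq(0.01, 0.3, length.out = 40)
  ens <- bead_ensemble(matrix(rnorm(30, sd = 6), ncol = 3))
  cv <- pool_debye_curves(ens, s)
  prof <- simulate_saxs_profile(cv, s, noise = noise_model(0.02), seed = 2)
  sel <- select_subensemble(cv, prof, n_se = 5L, seed = 1)
  expect_equal(sel$member_indices, rep(1L, 5L))
  expect_equal(sel$chi2, chi2_discrepancy(prof, cv[[1]])$chi2)
})

test_that("selection concentrates on a planted generating model", {
  set.seed(8)
  s <- seq(0.01, 0.35, length.out = 60)
  pool <- lapply(1:12, function(k) {
    debye_curve(bead_ensemble(matrix(rnorm(36, sd = 5 + k / 4), ncol = 3)), s)
  })
  truth_idx <- 7L
  prof <- loopdyn:::new_saxs_profile(s, pool[[truth_idx]]$intensity,
                                     0.01 * pool[[truth_idx]]$intensity)
  sel <- select_subensemble(pool, prof, n_se = 4L, seed = 5,
                            pop_size = 60L, generations = 60L)
  expect_lt(sel$chi2, 1e-6)
  expect_true(all(sel$member_indices == truth_idx))
  expect_lte(sel$chi2, sel$pool_chi2)
})

test_that("selection against a closed-state profile picks closed members", {
  gen <- make_two_state_ensemble(
    60, 0.5, toy_protein_spec(closed_distance = 12, open_distance = 24,
                              jitter_sd = 1), seed = 44)
  s <- seq(0.01, 0.35, length.out = 60)
  cv <- pool_debye_curves(gen$ensemble, s)
  closed_avg <- ensemble_average_curve(cv[gen$labels == "closed"])
  prof <- simulate_saxs_profile(list(closed_avg), s,
                                noise = noise_model(0.005), seed = 3)
  sel <- select_subensemble(cv, prof, n_se = 10L, seed = 6,
                            pop_size = 80L, generations = 80L)
  picked <- gen$labels[sel$member_indices]
  expect_gte(mean(picked == "closed"), 0.9)
  expect_lte(sel$chi2, sel$pool_chi2)
  # reproducible under the same seed
  sel2 <- select_subensemble(cv, prof, n_se = 10L, seed = 6,
                             pop_size = 80L, generations = 80L)
  expect_identical(sel$member_indices, sel2$member_indices)
  expect_equal(sel$chi2, sel2$chi2)
})

test_that("subensemble size scan returns the best of the scanned sizes", {
  s <- seq(0.01, 0.3, length.out = 40)
  ens <- make_two_state_ensemble(20, 0.5, seed = 9)$ensemble
  cv <- pool_debye_curves(ens, s)
  prof <- simulate_saxs_profile(cv, s, noise = noise_model(0.02), seed = 4)
  sc <- select_subensemble_scan(cv, prof, n_se_values = c(2L, 5L), seed = 1,
                                pop_size = 30L, generations = 30L)
  expect_equal(sc$chi2, min(sc$scan$chi2))
  expect_true(sc$size %in% c(2L, 5L))
})

test_that("population scan recovers pure states exactly", {
  s <- seq(0.01, 0.35, length.out = 80)
  gen <- make_two_state_ensemble(100, 0.5, seed = 13)
  cv <- pool_debye_curves(gen$ensemble, s)
  closed <- ensemble_average_curve(cv[gen$labels == "closed"])
  open <- ensemble_average_curve(cv[gen$labels == "open"])
  pure_closed <- loopdyn:::new_saxs_profile(s, closed$intensity,
                                            0.01 * closed$intensity)
  expect_equal(population_scan(closed, open, pure_closed)$best_f, 1.0)
  pure_open <- loopdyn:::new_saxs_profile(s, open$intensity,
                                          0.01 * open$intensity)
  expect_equal(population_scan(closed, open, pure_open)$best_f, 0.0)
})

test_that("population recovery error shrinks as noise vanishes", {
  s <- seq(0.01, 0.4, length.out = 200)
  gen <- make_two_state_ensemble(200, 0.5, seed = 14)
  cv <- pool_debye_curves(gen$ensemble, s)
  closed <- ensemble_average_curve(cv[gen$labels == "closed"])
  open <- ensemble_average_curve(cv[gen$labels == "open"])
  f_true <- 0.7
  errs <- vapply(c(0.04, 0.02, 0.002), function(noise) {
    est <- vapply(1:6, function(k) {
      prof <- simulate_saxs_profile(list(closed, open), s,
                                    weights = c(f_true, 1 - f_true),
                                    noise = noise_model(noise),
                                    seed = 500 + k)
      population_scan(closed, open, prof)$best_f
    }, numeric(1))
    mean(abs(est - f_true))
  }, numeric(1))
  expect_lte(errs[2], errs[1] + 0.01)
  expect_lte(errs[3], errs[2])
  expect_lt(errs[3], 0.011)
})

test_that("full pipeline recovers planted closed fractions", {
  s <- seq(0.01, 0.4, length.out = 400)
  spec <- toy_protein_spec(closed_distance = 12, open_distance = 24,
                           jitter_sd = 1)
  for (f in c(0.1, 0.5, 0.9)) {
    g <- make_two_state_ensemble(400, f, spec, seed = 300 + round(100 * f))
    cv <- pool_debye_curves(g$ensemble, s)
    prof <- simulate_saxs_profile(cv, s, noise = noise_model(0.02),
                                  seed = 17 + round(100 * f))
    d <- loop_site_distance(g$ensemble, toy_loop_range(spec), toy_site)
    st <- classify_states(d)
    fit <- population_scan(
      ensemble_average_curve(cv[st$labels == "closed"]),
      ensemble_average_curve(cv[st$labels == "open"]), prof)
    expect_lte(abs(fit$best_f - f), 0.05)
  }
})
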