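test_that("Debye curve matches closed forms for 1 and 2 scatterers", {
  one <- bead_ensemble(rbind(c(0, 0, 0)))
  expect_equal(debye_curve(one, c(0.01, 0.1, 1))$intensity, rep(1, 3))

  d <- 4
  two <- bead_ensemble(rbind(c(0, 0, 0), c(d, 0, 0)))
  s_pi <- pi / d
  cv <- debye_curve(two, c(1e-6, s_pi))
  expect_equal(cv$intensity[2], 2, tolerance = 1e-12)   # sin(pi)/pi = 0
  expect_equal(cv$intensity[1], 4, tolerance = 1e-6)    # (sum f)^2 limit
  expect_error(debye_curve(two, c(0, 0.1)), "positive")
})

test_that("Debye curve equals the naive double sum and binning stays accurate", {
  set.seed(12)
  xyz <- matrix(rnorm(90, sd = 8), ncol = 3)
  s <- seq(0.01, 0.45, length.out = 25)
  exact <- debye_curve(bead_ensemble(xyz), s)
  oracle <- brute_debye(xyz, s)
  expect_lt(max(abs(exact$intensity - oracle) / oracle), 1e-10)

  binned <- debye_curve(bead_ensemble(xyz), s, bin_threshold = 10L)
  expect_lt(max(abs(binned$intensity - exact$intensity) /
                  abs(exact$intensity)), 1e-3)

  heavy <- debye_curve(bead_ensemble(xyz, element = "O"), s,
                       form_factor = "per-element")
  expect_equal(heavy$intensity, 64 * exact$intensity, tolerance = 1e-10)
})

test_that("forward intensity dominates wide angle for compact clusters", {
  for (seed in 1:5) {
    set.seed(seed)
    xyz <- matrix(rnorm(45, sd = 6), ncol = 3)
    cv <- debye_curve(bead_ensemble(xyz), c(0.005, 0.5))
    expect_gt(cv$intensity[1], cv$intensity[2])
  }
})

test_that("chi-square discrepancy has exact scale behaviour", {
  s <- seq(0.01, 0.2, length.out = 30)
  i <- 100 * exp(-(s * 15)^2 / 3)
  p <- loopdyn:::new_saxs_profile(s, i, 0.02 * i)
  same <- chi2_discrepancy(p, loopdyn:::new_saxs_curve(s, i))
  expect_equal(same$chi2, 0, tolerance = 1e-20)
  expect_equal(same$scale, 1, tolerance = 1e-12)

  fifth <- chi2_discrepancy(p, loopdyn:::new_saxs_curve(s, i / 5))
  expect_equal(fifth$chi2, 0, tolerance = 1e-20)
  expect_equal(fifth$scale, 5, tolerance = 1e-12)

  # scale invariance of chi2 under positive rescaling of the theory
  set.seed(3)
  theo <- loopdyn:::new_saxs_curve(s, i * (1 + rnorm(30, sd = 0.05)))
  c1 <- chi2_discrepancy(p, theo)$chi2
  c2 <- chi2_discrepancy(p, loopdyn:::new_saxs_curve(s, 7.3 * theo$intensity))$chi2
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("analytic scale factor agrees with dense grid search", {
  p <- loopdyn:::new_saxs_profile(c(0.01, 0.05, 0.1, 0.2),
                                  c(10, 7, 4, 2), c(0.5, 0.4, 0.3, 0.2))
  theo <- loopdyn:::new_saxs_curve(p$s, c(3.2, 2.4, 1.2, 0.8))
  fit <- chi2_discrepancy(p, theo)
  oracle <- grid_search_mu_chi2(p, theo)
  expect_equal(fit$scale, oracle$mu, tolerance = 1e-6)
  expect_equal(fit$chi2, oracle$chi2, tolerance = 1e-6)
  # fixed scale and alternative normalisation
  expect_equal(chi2_discrepancy(p, theo, fit_scale = FALSE)$scale, 1)
  expect_equal(chi2_discrepancy(p, theo, normalization = "K")$chi2,
               fit$chi2 * 3 / 4, tolerance = 1e-12)
})

test_that("chi-square rejects mismatched grids and single points", {
  p <- loopdyn:::new_saxs_profile(c(0.01, 0.02), c(1, 1), c(0.1, 0.1))
  expect_error(chi2_discrepancy(p, loopdyn:::new_saxs_curve(c(0.01, 0.03),
                                                            c(1, 1))),
               "grids")
  p1 <- loopdyn:::new_saxs_profile(0.01, 1, 0.1)
  expect_error(chi2_discrepancy(p1, loopdyn:::new_saxs_curve(0.01, 1)),
               "2 points")
})

test_that("ensemble averaging is a weighted pointwise mean and linear", {
  s <- c(0.01, 0.05, 0.1)
  c1 <- loopdyn:::new_saxs_curve(s, c(1, 2, 3))
  c2 <- loopdyn:::new_saxs_curve(s, c(4, 5, 6))
  c3 <- loopdyn:::new_saxs_curve(s, c(7, 8, 9))
  expect_equal(ensemble_average_curve(list(c1, c1, c1))$intensity,
               c1$intensity)
  expect_equal(ensemble_average_curve(list(c1, c2), c(1, 0))$intensity,
               c1$intensity)
  w <- c(0.2, 0.3, 0.5)
  expect_equal(ensemble_average_curve(list(c1, c2, c3), w)$intensity,
               0.2 * c(1, 2, 3) + 0.3 * c(4, 5, 6) + 0.5 * c(7, 8, 9))
  scaled <- lapply(list(c1, c2, c3), function(cv) {
    loopdyn:::new_saxs_curve(s, 3 * cv$intensity)
  })
  expect_equal(ensemble_average_curve(scaled, w)$intensity,
               3 * ensemble_average_curve(list(c1, c2, c3), w)$intensity)
  expect_error(ensemble_average_curve(list(c1, c2), c(0.7, 0.7)),
               "sum to 1")
  expect_error(ensemble_average_curve(list()), "empty")
})

test_that("Guinier fit recovers Rg exactly on noiseless model data", {
  rg <- 20
  s <- seq(0.005, 0.06, length.out = 40)
  i0 <- 250
  p <- loopdyn:::new_saxs_profile(s, i0 * exp(-(s * rg)^2 / 3),
                                  0.01 * i0 * exp(-(s * rg)^2 / 3))
  fit <- guinier_rg(p)
  expect_equal(fit$rg, rg, tolerance = 1e-6)
  expect_equal(fit$i0, i0, tolerance = 1e-6)
})

test_that("Guinier fit tolerates 1% noise and matches the sphere relation", {
  rg <- 20
  s <- seq(0.005, 0.1, length.out = 60)
  truth <- 100 * exp(-(s * rg)^2 / 3)
  set.seed(21)
  p <- loopdyn:::new_saxs_profile(s, truth + rnorm(60, 0, 0.01 * truth),
                                  0.01 * truth)
  expect_lt(abs(guinier_rg(p)$rg - rg) / rg, 0.02)

  # homogeneous sphere: Rg = sqrt(3/5) R
  r_sph <- 25
  s2 <- seq(0.002, 1.2 / (sqrt(3 / 5) * r_sph), length.out = 80)
  x <- s2 * r_sph
  isph <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  psph <- loopdyn:::new_saxs_profile(s2, isph,
                                     rep(0.01 * isph[1], length(s2)))
  expect_lt(abs(guinier_rg(psph, srg_max = 1.0)$rg -
                  sqrt(3 / 5) * r_sph) / (sqrt(3 / 5) * r_sph), 0.01)
})

test_that("Guinier fit refuses profiles without a decaying region", {
  s <- seq(0.01, 0.1, length.out = 20)
  p <- loopdyn:::new_saxs_profile(s, exp((s * 10)^2), rep(0.1, 20))
  expect_error(guinier_rg(p), "Guinier")
})

test_that("P(r) inversion recovers a planted two-distance structure", {
  # P(r) concentrated at r0 on the grid: I(s) = sinc(s r0)
  dmax <- 50
  n_r <- 49L
  dr <- dmax / (n_r + 1)
  r0 <- 20 * dr  # exactly on the grid
  s <- seq(0.02, 0.6, length.out = 120)
  i <- sin(s * r0) / (s * r0)
  p <- loopdyn:::new_saxs_profile(s, i, rep(0.001, length(s)))
  out <- pofr_transform(p, dmax, n_r = n_r, lambda = 1e-10)
  expect_equal(out$r[which.max(out$p)], r0, tolerance = dr / 2)
  expect_lt(attr(out, "forward_chi2"), 1.5)
})

test_that("P(r) support ends at the sphere diameter and zeros stay zero", {
  r_sph <- 15
  s <- seq(0.01, 0.5, length.out = 150)
  x <- s * r_sph
  i <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  p <- loopdyn:::new_saxs_profile(s, i, pmax(0.005 * i, 1e-7))
  out <- pofr_transform(p, dmax = 40, n_r = 60L)
  dr <- 40 / 61
  support_end <- max(out$r[out$p > 0.01 * max(out$p)])
  expect_lt(abs(support_end - 2 * r_sph), 2 * dr + 1e-9)
  expect_true(all(out$p >= 0))
  expect_equal(out$p[1], 0)
  expect_equal(out$p[length(out$p)], 0)

  pz <- loopdyn:::new_saxs_profile(s, rep(0, length(s)), rep(1, length(s)))
  outz <- pofr_transform(pz, dmax = 40, n_r = 30L, lambda = 1e-6)
  expect_equal(max(abs(outz$p)), 0)
})
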