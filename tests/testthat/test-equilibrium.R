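mouse_g <- growth_params("simeoni", lambda0 = 0.25, lambda1 = 0.4603, phi = 20)
mouse_m <- mortality_params(0.25 / 4032.3)

test_that("geometric factor evaluates partial geometric sums with a p = 1 branch", {
  expect_identical(geometric_factor(1, 4), 4)
  expect_equal(geometric_factor(0.5, 4), 1.875)
  expect_identical(geometric_factor(0, 7), 1)
  expect_equal(geometric_factor(1 - 1e-14, 5), 5)  # no catastrophic division
})

test_that("Simeoni equilibria follow the threshold dichotomy", {
  thr <- infusion_threshold(mouse_g, mouse_m)
  expect_equal(thr, 4032.3, tolerance = 1e-12)
  tcm <- tcm_params(4, 0.2859, 0.44268)
  above <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar = thr * 1.5)
  expect_equal(above$regime, "zero-only")
  expect_length(above$points, 1)
  below <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar = thr / 2)
  expect_equal(below$regime, "zero-plus-nonzero")
  at <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar = thr)
  expect_equal(at$regime, "continuum")
})

test_that("the nonzero Simeoni equilibrium matches its closed forms", {
  thr <- 4032.3
  Cbar <- thr / 2
  eC <- mouse_m$eta * Cbar
  for (p in c(0, 0.5, 1)) {
    tcm <- tcm_params(4, 0.2859, p)
    nz <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar)$points[[2]]
    # the chain is in exact balance
    d <- coxian_tcm_rhs(nz$u, nz$y, Cbar, mouse_g, mouse_m, tcm)
    expect_lt(max(abs(c(d$du, d$dy))), 1e-12)
    # y_i = (eta Cbar u / k1) p^(i-1)
    expect_equal(nz$y, (eC * nz$u / 0.2859) * p^(0:3), tolerance = 1e-12)
    # sharp-switch limit: w = lambda1/(eta Cbar), here indistinguishable
    expect_equal(nz$w, 0.4603 / eC, tolerance = 1e-6)
    if (p == 1) {
      expect_equal(nz$w, (1 + 4 * Cbar * mouse_m$eta / 0.2859) * nz$u,
                   tolerance = 1e-12)
    }
  }
})

test_that("equilibrium proliferating mass decreases strictly in p", {
  Cbar <- 4032.3 / 2
  ub <- vapply(seq(0, 1, by = 0.1), function(p) {
    equilibria_simeoni(mouse_g, mouse_m, tcm_params(4, 0.2859, p), Cbar)$points[[2]]$u
  }, numeric(1))
  expect_true(all(diff(ub) < 0))
})

test_that("logistic equilibria: eradication at or above threshold, else direct solve", {
  g <- growth_params("logistic", lambda0 = 0.12, umax = 0.0066)
  m <- mortality_params(0.0035)
  tcm <- tcm_params(5, 0.1682, 0.9)
  thr <- infusion_threshold(g, m)
  expect_equal(equilibria_logistic(g, m, tcm, thr)$regime, "zero-only")
  expect_equal(equilibria_logistic(g, m, tcm, thr + 1)$regime, "zero-only")
  # no drug: carrying capacity, empty chain
  eq0 <- equilibria_logistic(g, m, tcm, 0)
  expect_equal(eq0$points[[2]]$u, 0.0066)
  expect_true(all(eq0$points[[2]]$y == 0))
  # below threshold the algebraic solve is an exact steady state
  nz <- equilibria_logistic(g, m, tcm, 10)$points[[2]]
  d <- coxian_tcm_rhs(nz$u, nz$y, 10, g, m, tcm)
  expect_lt(max(abs(c(d$du, d$dy))), 1e-15)
  expect_equal(nz$w, 0.0066 * (1 - 0.0035 * 10 / 0.12), tolerance = 1e-12)
})

test_that("zero-equilibrium stability flips across the infusion threshold", {
  tcm <- tcm_params(4, 0.2859, 0.44268)
  zero <- list(u = 0, y = rep(0, 4))
  lo <- stability_classify(zero, mouse_g, mouse_m, tcm, Cbar = 4032.2)
  hi <- stability_classify(zero, mouse_g, mouse_m, tcm, Cbar = 4032.4)
  expect_equal(lo$verdict, "unstable")
  expect_gt(max(Re(lo$eigenvalues)), 0)
  expect_equal(hi$verdict, "stable")
  expect_lt(max(Re(hi$eigenvalues)), 0)
})

test_that("nonzero equilibria are locally stable for n = 2, 3, 4", {
  Cbar <- 4032.3 / 2
  for (n in 2:4) {
    tcm <- tcm_params(n, 0.2859, 0.5)
    eq <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar)
    st <- stability_classify(eq$points[[2]], mouse_g, mouse_m, tcm, Cbar)
    expect_equal(st$verdict, "stable")
  }
})

test_that("classification is refused on the equilibrium continuum", {
  tcm <- tcm_params(4, 0.2859, 0.44268)
  eq <- equilibria_simeoni(mouse_g, mouse_m, tcm, Cbar = 4032.3)
  expect_error(stability_classify(eq, mouse_g, mouse_m, tcm, 4032.3), "continuum")
})
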