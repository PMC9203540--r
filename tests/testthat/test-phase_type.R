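test_that("Erlang density matches its closed form and the gamma density", {
  # f_1(0) = k1
  expect_equal(erlang_density(0, erlang_spec(1, 0.2859)), 0.2859)
  # hand evaluation: n = 2, k1 = 1, a = 1 -> e^-1
  expect_equal(erlang_density(1, erlang_spec(2, 1)), exp(-1), tolerance = 1e-12)
  # against the gamma density with integer shape, on a grid
  sp <- erlang_spec(4, 0.2859)
  a <- seq(0, 80, by = 0.5)
  expect_equal(erlang_density(a, sp), dgamma(a, shape = 4, rate = 0.2859),
               tolerance = 1e-12)
  expect_error(erlang_density(-0.1, sp), "nonnegative")
})

test_that("Erlang density integrates to one", {
  sp <- erlang_spec(4, 0.2859)
  I <- integrate(function(a) erlang_density(a, sp), 0, Inf, rel.tol = 1e-10)
  expect_lt(abs(I$value - 1), 1e-8)
})

test_that("Coxian generator has the stated structure and reduces correctly", {
  # all p_i = 1 (i < n), equal rates -> Erlang generator
  ph <- coxian_generator(coxian_spec(3, k = 0.7, p = c(1, 1, 0)))
  S_erl <- diag(-0.7, 3); S_erl[cbind(1:2, 2:3)] <- 0.7
  expect_equal(ph$S, S_erl)
  expect_equal(ph$alpha, c(1, 0, 0))
  # n = 1 -> exponential
  ph1 <- coxian_generator(coxian_spec(1, k = 2.5, p = 0))
  expect_equal(ph1$S, matrix(-2.5, 1, 1))
  # conservation S 1 + S0 = 0 for random specs
  for (seed in 1:10) {
    ph <- coxian_generator(random_coxian(seed))
    expect_equal(drop(ph$S %*% rep(1, ph$n)) + ph$S0, rep(0, ph$n))
  }
  expect_error(coxian_spec(3, k = 1, p = c(0.5, 0.5, 0.5)), "p_n = 0")
})

test_that("matrix-exponential density agrees with the Erlang closed form", {
  sp <- erlang_spec(4, 0.2859)
  tg <- seq(0, 10 * phase_moments(sp), length.out = 60)
  expect_lt(max(abs(phase_density(sp, tg) - erlang_density(tg, sp))), 1e-10)
})

test_that("phase-type density starts at the phase-1 exit rate and normalizes", {
  cx <- coxian_spec(3, k = c(0.8, 0.5, 0.9), p = c(0.3, 0.6, 0))
  # f(0) = alpha S0 = (1 - p_1) k_1
  expect_equal(phase_density(cx, 0), (1 - 0.3) * 0.8, tolerance = 1e-12)
  expect_equal(phase_density(erlang_spec(4, 0.2859), 0), 0)
  for (seed in 1:3) {
    spec <- random_coxian(seed)
    I <- integrate(function(t) phase_density(spec, t), 0, Inf, rel.tol = 1e-10)
    expect_lt(abs(I$value - 1), 1e-8)
    # CDF -> 1 at 50x mean
    expect_lt(abs(phase_cdf(spec, 50 * phase_moments(spec)) - 1), 1e-6)
  }
})

test_that("Coxian reduces to Erlang pointwise at p = 1 with equal rates", {
  for (n in c(2, 4, 6)) {
    cx <- coxian_spec(n, k = 0.4, p = c(rep(1, n - 1), 0))
    erl <- erlang_spec(n, 0.4)
    tg <- seq(0, 10 * n / 0.4, length.out = 50)
    expect_lt(max(abs(phase_density(cx, tg) - erlang_density(tg, erl))), 1e-10)
  }
})

test_that("density components satisfy df/dt = f S", {
  spec <- random_coxian(42)
  ph <- as_phase_type(spec)
  f_vec <- function(t) drop(ph$alpha %*% as.matrix(Matrix::expm(ph$S * t)))
  h <- 1e-6
  for (t in c(0.5, 2, 5)) {
    fd <- (f_vec(t + h) - f_vec(t - h)) / (2 * h)
    expect_equal(fd, drop(f_vec(t) %*% ph$S), tolerance = 1e-6)
  }
})

test_that("mean residence time matches analytic forms", {
  expect_equal(phase_moments(erlang_spec(4, 0.2859)), 4 / 0.2859, tolerance = 1e-12)
  expect_equal(phase_moments(coxian_spec(1, k = 2, p = 0)), 0.5, tolerance = 1e-12)
  # Coxian(2, k = (1, 1), p = (0.5, 0)): mean = 1 + 0.5 * 1 = 1.5
  expect_equal(phase_moments(coxian_spec(2, k = 1, p = c(0.5, 0))), 1.5,
               tolerance = 1e-12)
})

test_that("invalid phase-type specifications are rejected", {
  expect_error(phase_type_spec(c(0.5, 0.4), diag(-1, 2)), "sum")
  expect_error(phase_type_spec(c(1, 0), matrix(c(1, 0, 0, -1), 2)), "negative")
  expect_error(erlang_spec(0, 1), "integer")
  expect_error(erlang_spec(2, -1), "k1")
})
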