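test_that("range-normalized RMSE matches the defining formula", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # RMSE 1 over range 2
  expect_equal(nrmse(c(0, 2), c(1, 1)), 0.5)
  # invariant to common positive rescaling
  obs <- c(0.1, 0.5, 1.2, 0.9); pred <- c(0.2, 0.4, 1.0, 1.1)
  expect_equal(nrmse(obs * 37, pred * 37), nrmse(obs, pred))
  expect_error(nrmse(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("continuation probability is recovered exactly from noise-free data", {
  sc <- mouse150_scenario()  # truth p = 0.44268
  ds <- generate_xenograft_dataset(sc)
  fit <- fit_least_squares(sc, ds, start = c(p = 0.8), lower = c(p = 0),
                           upper = c(p = 1), n_starts = 1, seed = 1)
  expect_lt(abs(fit$par[["p"]] - 0.44268) / 0.44268, 1e-3)
  expect_true(fit$converged)
  # stored n-RMSE is recomputable from the stored residuals
  rec <- sqrt(mean(fit$residuals[[1]]^2)) / (max(ds$value) - min(ds$value))
  expect_equal(fit$nrmse[1], rec, tolerance = 1e-12)
})

test_that("fit guards: bounds, identifiability warning", {
  sc <- mouse150_scenario()
  ds <- generate_xenograft_dataset(sc)
  expect_error(fit_least_squares(sc, ds, start = c(p = 1.5), lower = c(p = 0),
                                 upper = c(p = 1)), "outside bounds")
  expect_error(fit_least_squares(sc, ds, start = c(p = 0.5), lower = c(p = 0),
                                 upper = c(p = Inf)), "finite")
  w <- capture_warnings(
    fit_least_squares(sc, ds, start = c(p = 0.5, k1 = 0.3),
                      lower = c(p = 0, k1 = 0.01), upper = c(p = 1, k1 = 2),
                      n_starts = 1,
                      control = minpack.lm::nls.lm.control(maxiter = 1)))
  expect_match(w, "identifiable", all = FALSE)
})

test_that("staged spheroid protocol recovers the generating truths", {
  control <- spheroid_series("erlang", 4, 1, conc = 0)
  treated <- lapply(c(5, 10), function(cc) spheroid_series("erlang", 4, 1, cc))
  treated_cox <- lapply(c(5, 10), function(cc) spheroid_series("coxian", 5, 0.9, cc))
  sf <- staged_spheroid_fit(
    control, treated,
    growth = growth_params("logistic", lambda0 = 0.1, umax = max(control$value)),
    w0 = spheroid_truth$w0, treated_coxian = treated_cox, seed = 1)
  truth <- unlist(spheroid_truth[c("lambda0", "umax", "k1", "eta", "p")])
  expect_lt(max(abs(sf$estimates - truth) / truth), 1e-3)

  # joint refit from the staged solution must not increase the stage loss
  g3 <- growth_params("logistic", lambda0 = sf$estimates[["lambda0"]],
                      umax = sf$estimates[["umax"]])
  sc3 <- tcm_scenario("coxian", g3, mortality_params(sf$estimates[["eta"]]),
                      tcm_params(5, sf$estimates[["k1"]], sf$estimates[["p"]]),
                      0, spheroid_truth$w0)
  joint <- fit_least_squares(
    sc3, treated_cox,
    start = sf$estimates[c("k1", "eta", "p")],
    lower = c(k1 = 1e-4, eta = 1e-7, p = 0), upper = c(k1 = 10, eta = 1, p = 1),
    n_starts = 1, control = minpack.lm::nls.lm.control(maxiter = 30))
  expect_lte(joint$loss, sf$stages$coxian$loss + 1e-12)
})

test_that("stage 3 on Erlang-generated data drives p to one and reproduces the Erlang fit", {
  control <- spheroid_series("erlang", 4, 1, conc = 0)
  treated <- lapply(c(5, 10), function(cc) spheroid_series("erlang", 4, 1, cc))
  sf <- staged_spheroid_fit(
    control, treated,
    growth = growth_params("logistic", lambda0 = 0.1, umax = max(control$value)),
    w0 = spheroid_truth$w0, n_coxian = 4, seed = 1)
  expect_gt(sf$estimates[["p"]], 1 - 1e-4)
  expect_lt(abs(sf$stages$coxian$loss - sf$stages$erlang$loss), 1e-10)
})

test_that("missing control series is an error", {
  expect_error(staged_spheroid_fit(NULL, list(),
                                   growth = growth_params("logistic", 0.1, umax = 1),
                                   w0 = 1e-3), "control")
})
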