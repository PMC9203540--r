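# shared fixture builders; everything is generated in code, no stored data

mouse150_pk <- function(horizon = 40) {
  list(params = pk_params(k01 = 1.6, k21 = 0.2353, k12 = 0.1699, V = 1028),
       schedule = dose_schedule(13:22, 4.5e7, horizon = horizon))
}

# noise-free spheroid series generated from the model each stage of the
# staged protocol fits (control logistic; Erlang n=4; Coxian n=5 p=0.9)
spheroid_truth <- list(lambda0 = 0.12, umax = 0.0066, k1 = 0.1682,
                       eta = 0.0035, p = 0.9, w0 = 5e-4)

spheroid_series <- function(model, n, p, conc,
                            times = c(0, 1, 2, 3, 6, 24, 48, 72),
                            truth = spheroid_truth) {
  g <- growth_params("logistic", lambda0 = truth$lambda0, umax = truth$umax)
  sc <- tcm_scenario(model, g, mortality_params(truth$eta),
                     tcm_params(n, truth$k1, p), conc, truth$w0)
  observation_series(times, simulate_scenario(sc, times)$w,
                     group = if (conc == 0) "control" else paste0(conc, "uM"),
                     exposure = conc)
}

random_coxian <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  coxian_spec(n, k = stats::runif(n, 0.2, 2), p = c(stats::runif(n - 1), 0))
}
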