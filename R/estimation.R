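#' Observation series
#'
#' A time series of tumor burden measurements (xenograft weight in g or
#' spheroid volume in mm^3). A constant drug concentration for the series
#' (spheroid assay) or a full exposure object may be attached; it overrides
#' the scenario exposure during fitting.
#'
#' @param time Non-decreasing observation times.
#' @param value Nonnegative measurements; at least two distinct values are
#'   required for the range-normalized RMSE.
#' @param group Optional label (e.g. `"control"`, `"5uM"`).
#' @param exposure Optional exposure for this series (constant concentration
#'   or [pk_exposure()]).
#' @return A data.frame of class `observation_series`.
#' @export
observation_series <- function(time, value, group = NULL, exposure = NULL) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value)) stop("`time` and `value` lengths differ", call. = FALSE)
  if (any(diff(time) < 0)) stop("`time` must be non-decreasing", call. = FALSE)
  if (any(value < 0)) stop("`value` must be nonnegative", call. = FALSE)
  out <- data.frame(time = time, value = value)
  if (!is.null(group)) out$group <- group
  class(out) <- c("observation_series", "data.frame")
  attr(out, "exposure") <- exposure
  out
}

#' Range-normalized root-mean-square error
#'
#' `nrmse = sqrt(sum((y - yhat)^2) / n) / (y_max - y_min)`, with the range
#' taken from the observed values. Dimensionless and invariant to a common
#' positive rescaling of both series.
#'
#' @param observed Observed values or an [observation_series()].
#' @param predicted Model predictions, same length.
#' @return The normalized RMSE.
#' @examples
#' nrmse(c(0, 2), c(1, 1))  # 0.5
#' @export
nrmse <- function(observed, predicted) {
  if (inherits(observed, "observation_series")) observed <- observed$value
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  rng <- max(observed) - min(observed)
  if (rng <= 0) stop("observed series is constant: normalization undefined", call. = FALSE)
  sqrt(mean((observed - predicted)^2)) / rng
}

#' Model scenario
#'
#' Bundles everything needed to simulate a TCM: model variant, growth, kill
#' and transit-chain parameters, exposure and the initial (all-proliferating)
#' tumor mass. This is the object the estimation routines perturb.
#'
#' @param model `"coxian"` or `"erlang"`.
#' @param growth,mortality,tcm Parameter objects.
#' @param exposure As in [simulate_tcm()].
#' @param w0 Initial tumor mass.
#' @return An object of class `tcm_scenario`.
#' @export
tcm_scenario <- function(model, growth, mortality, tcm, exposure, w0) {
  stopifnot(inherits(growth, "growth_params"), inherits(mortality, "mortality_params"),
            inherits(tcm, "tcm_params"))
  structure(list(model = model, growth = growth, mortality = mortality,
                 tcm = tcm, exposure = exposure, w0 = w0),
            class = "tcm_scenario")
}

#' Simulate a scenario at given times
#'
#' @param scenario A [tcm_scenario()].
#' @param times Output times (0 is prepended internally if absent).
#' @param ... Passed to [simulate_tcm()].
#' @return The `tcm_trajectory` restricted to `times`.
#' @export
simulate_scenario <- function(scenario, times, ...) {
  tt <- sort(unique(c(0, times)))
  tr <- simulate_tcm(scenario$model, scenario$growth, scenario$mortality,
                     scenario$tcm, scenario$exposure, scenario$w0, tt, ...)
  tr[tr$time %in% times, , drop = FALSE]
}

fittable_params <- c("lambda0", "lambda1", "phi", "umax", "eta", "k1", "p", "w0")

set_scenario_param <- function(scenario, name, value) {
  switch(name,
    lambda0 = , lambda1 = , phi = , umax = {
      g <- unclass(scenario$growth)
      g[[name]] <- value
      scenario$growth <- do.call(growth_params, c(list(variant = g$variant),
        g[intersect(names(g), c("lambda0", "lambda1", "phi", "umax", "logistic_bracket"))]))
    },
    eta = scenario$mortality <- mortality_params(value),
    k1 = scenario$tcm <- tcm_params(scenario$tcm$n, value, scenario$tcm$p),
    p = scenario$tcm <- tcm_params(scenario$tcm$n, scenario$tcm$k1, value),
    w0 = scenario$w0 <- value,
    stop("unknown fittable parameter: ", name, call. = FALSE)
  )
  scenario
}

apply_params <- function(scenario, par) {
  for (nm in names(par)) scenario <- set_scenario_param(scenario, nm, par[[nm]])
  scenario
}

#' Nonlinear least-squares parameter estimation
#'
#' Fits free parameters of a scenario to one or more observation series by
#' bounded Levenberg-Marquardt least squares on the stacked (unweighted)
#' residuals of total mass `w`, the natural-scale analogue of `lsqnonlin`
#' fitting. Multiple Latin-hypercube starting points guard against local
#' minima; the best final loss wins. Deterministic for a given `seed`.
#'
#' @param scenario A [tcm_scenario()] holding all fixed parameters.
#' @param data An [observation_series()] or a list of them. A series-level
#'   `exposure` attribute (e.g. its constant assay concentration) overrides
#'   the scenario exposure for that series.
#' @param start Named vector of initial values for the free parameters
#'   (their names define the free set).
#' @param lower,upper Named bounds, finite and ordered, same names as
#'   `start`.
#' @param n_starts Number of multistart points (>= 1); the first is `start`,
#'   the rest Latin-hypercube samples of the box.
#' @param seed Integer seed for the multistart design.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `tcm_fit`: `par` (estimates), `loss`,
#'   `nrmse` (per series), `residuals`, `predicted`, `observed`,
#'   `converged`, `message`, `starts`, `seed`.
#' @export
fit_least_squares <- function(scenario, data, start, lower, upper,
                              n_starts = 5, seed = 1,
                              control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(scenario, "tcm_scenario"))
  if (inherits(data, "observation_series")) data <- list(data)
  free <- names(start)
  if (is.null(free) || any(!nzchar(free))) stop("`start` must be a named vector", call. = FALSE)
  if (!all(free %in% fittable_params)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, fittable_params), collapse = ", "), call. = FALSE)
  }
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper for every free parameter", call. = FALSE)
  }
  if (any(start < lower) || any(start > upper)) {
    stop("initial guess outside bounds", call. = FALSE)
  }
  if (all(c("p", "k1") %in% free) && length(data) == 1L) {
    warning("fitting `p` and `k1` jointly from a single series is weakly identifiable; ",
            "delay parameters trade off (consider the staged protocol)", call. = FALSE)
  }

  residual_fun <- function(par) {
    par <- stats::setNames(as.numeric(par), free)
    unlist(lapply(data, function(series) {
      sc <- apply_params(scenario, as.list(par))
      ex <- attr(series, "exposure")
      if (!is.null(ex)) sc$exposure <- ex
      pred <- tryCatch(simulate_scenario(sc, series$time)$w,
                       error = function(e) rep(1e6, nrow(series)))
      series$value - pred
    }), use.names = FALSE)
  }

  starts <- matrix(start, nrow = 1, dimnames = list(NULL, free))
  if (n_starts > 1) {
    d <- length(free)
    uni <- with_preserved_seed(seed, lhs::randomLHS(n_starts - 1L, d))
    extra <- sweep(sweep(uni, 2, upper - lower, `*`), 2, lower, `+`)
    colnames(extra) <- free
    starts <- rbind(starts, extra)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = residual_fun, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss) best <- list(fit = fit, loss = loss)
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  fit <- best$fit
  est <- stats::setNames(as.numeric(fit$par), free)
  preds <- lapply(data, function(series) {
    sc <- apply_params(scenario, as.list(est))
    ex <- attr(series, "exposure")
    if (!is.null(ex)) sc$exposure <- ex
    simulate_scenario(sc, series$time)$w
  })
  scores <- mapply(function(series, pred) nrmse(series$value, pred),
                   data, preds)
  structure(list(
    par = est, loss = best$loss,
    nrmse = as.numeric(scores),
    residuals = lapply(seq_along(data), function(i) data[[i]]$value - preds[[i]]),
    predicted = preds,
    observed = lapply(data, function(s) s$value),
    converged = fit$info %in% 1:4,
    message = fit$message,
    starts = starts, seed = seed
  ), class = "tcm_fit")
}

# run `expr` under a given seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Staged spheroid fitting protocol
#'
#' Three-stage constant-concentration workflow:
#' \enumerate{
#'   \item `lambda0` and `umax` fitted to the drug-free control series with
#'     pure logistic growth;
#'   \item `k1` and `eta` fitted to the treated series with the Erlang
#'     (`p = 1`) logistic TCM of `n_erlang` compartments, stage-1 values
#'     fixed;
#'   \item `p` fitted to the treated series with the Coxian logistic TCM of
#'     `n_coxian` compartments, everything else fixed.
#' }
#' Each treated series must carry its assay concentration in its `exposure`
#' attribute. `treated_coxian` allows stage 3 to use its own series (e.g.
#' when benchmarking recovery of a Coxian-generated dataset); it defaults to
#' `treated`.
#'
#' @param control Drug-free [observation_series()].
#' @param treated List of treated [observation_series()] at constant
#'   concentrations.
#' @param growth Logistic [growth_params()] providing starting structure
#'   (its `lambda0`/`umax` serve as stage-1 initial values).
#' @param w0 Initial mass (fixed, known from the assay seeding).
#' @param n_erlang,n_coxian Damaged-chain lengths for the two variants.
#' @param treated_coxian Optional stage-3 series list.
#' @param start,lower,upper Optional named overrides for initial values and
#'   bounds of `lambda0`, `umax`, `k1`, `eta`, `p`.
#' @param seed Multistart seed.
#' @return A list of class `tcm_staged_fit` with elements `estimates`
#'   (named vector of the five parameters), `stages` (the three `tcm_fit`
#'   objects) and `nrmse` (per treated series, Erlang and Coxian).
#' @export
staged_spheroid_fit <- function(control, treated, growth, w0,
                                n_erlang = 4, n_coxian = 5,
                                treated_coxian = treated,
                                start = NULL, lower = NULL, upper = NULL,
                                seed = 1) {
  if (is.null(control)) stop("a drug-free control series is required", call. = FALSE)
  stopifnot(inherits(growth, "growth_params"), growth$variant == "logistic")
  if (inherits(treated, "observation_series")) treated <- list(treated)
  if (inherits(treated_coxian, "observation_series")) treated_coxian <- list(treated_coxian)

  dft <- function(user, default) {
    out <- default
    if (!is.null(user)) out[names(user)] <- user
    out
  }
  s0 <- dft(start, c(lambda0 = growth$lambda0, umax = growth$umax,
                     k1 = 0.1, eta = 0.001, p = 0.5))
  lo <- dft(lower, c(lambda0 = 1e-4, umax = 1e-6, k1 = 1e-4, eta = 1e-7, p = 0))
  hi <- dft(upper, c(lambda0 = 10, umax = 1, k1 = 10, eta = 1, p = 1))

  # stage 1: control, pure logistic growth (chain inert at C = 0)
  sc1 <- tcm_scenario("erlang", growth, mortality_params(0),
                      tcm_params(n_erlang, s0[["k1"]]), exposure = 0, w0 = w0)
  fit1 <- fit_least_squares(sc1, control,
                            start = s0[c("lambda0", "umax")],
                            lower = lo[c("lambda0", "umax")],
                            upper = hi[c("lambda0", "umax")], seed = seed)
  g1 <- growth_params("logistic", lambda0 = fit1$par[["lambda0"]],
                      umax = fit1$par[["umax"]],
                      logistic_bracket = growth$logistic_bracket)

  # stage 2: treated, Erlang logistic TCM, fit (k1, eta)
  sc2 <- tcm_scenario("erlang", g1, mortality_params(s0[["eta"]]),
                      tcm_params(n_erlang, s0[["k1"]]), exposure = 0, w0 = w0)
  fit2 <- fit_least_squares(sc2, treated,
                            start = s0[c("k1", "eta")],
                            lower = lo[c("k1", "eta")],
                            upper = hi[c("k1", "eta")], seed = seed)

  # stage 3: treated, Coxian logistic TCM, fit p only
  sc3 <- tcm_scenario("coxian", g1, mortality_params(fit2$par[["eta"]]),
                      tcm_params(n_coxian, fit2$par[["k1"]], p = s0[["p"]]),
                      exposure = 0, w0 = w0)
  fit3 <- fit_least_squares(sc3, treated_coxian,
                            start = s0["p"], lower = lo["p"], upper = hi["p"],
                            seed = seed)

  structure(list(
    estimates = c(lambda0 = fit1$par[["lambda0"]], umax = fit1$par[["umax"]],
                  k1 = fit2$par[["k1"]], eta = fit2$par[["eta"]],
                  p = fit3$par[["p"]]),
    stages = list(control = fit1, erlang = fit2, coxian = fit3),
    nrmse = list(control = fit1$nrmse, erlang = fit2$nrmse, coxian = fit3$nrmse)
  ), class = "tcm_staged_fit")
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat("TCM least-squares fit\n")
  cat("  estimates:", paste(sprintf("%s = %.6g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  loss = %.6g, converged = %s\n", x$loss, x$converged))
  cat("  n-RMSE per series:", paste(sprintf("%.4f", x$nrmse), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tcm_staged_fit <- function(x, ...) {
  cat("Staged spheroid fit\n")
  cat("  estimates:", paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
                            collapse = ", "), "\n")
  cat("  Erlang n-RMSE:", paste(sprintf("%.4f", x$nrmse$erlang), collapse = ", "), "\n")
  cat("  Coxian n-RMSE:", paste(sprintf("%.4f", x$nrmse$coxian), collapse = ", "), "\n")
  invisible(x)
}
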