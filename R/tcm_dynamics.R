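#' Tumor growth-law parameters
#'
#' Two proliferation laws are supported:
#' \itemize{
#'   \item `"simeoni"`: `k_in(u, w) = lambda0 u / (1 + ((lambda0/lambda1) w)^phi)^(1/phi)`,
#'     approximately exponential (`lambda0 u`) below the threshold weight
#'     `w_th = lambda1 / lambda0` and linear (`lambda1 u / w`) above it; `phi`
#'     controls the sharpness of the switch.
#'   \item `"logistic"`: `k_in = lambda0 (1 - w/umax) u` with carrying capacity
#'     `umax`. By default the saturation bracket uses the TOTAL mass
#'     `w = u + sum(y)`; `logistic_bracket = "proliferating"` uses `u` instead.
#' }
#'
#' @param variant `"simeoni"` or `"logistic"`.
#' @param lambda0 First-phase exponential rate (time^-1), > 0.
#' @param lambda1 Linear-phase rate (mass time^-1), required for simeoni.
#' @param phi Transition sharpness (dimensionless, >= 1), simeoni only.
#' @param umax Carrying capacity (mass or volume), logistic only.
#' @param logistic_bracket `"total"` (default) or `"proliferating"`.
#' @return An object of class `growth_params`; for simeoni it exposes the
#'   threshold `w_th = lambda1 / lambda0`.
#' @examples
#' growth_params("simeoni", lambda0 = 0.25, lambda1 = 0.4603, phi = 20)
#' growth_params("logistic", lambda0 = 0.12, umax = 0.0066)
#' @export
growth_params <- function(variant = c("simeoni", "logistic"), lambda0,
                          lambda1 = NULL, phi = 20, umax = NULL,
                          logistic_bracket = c("total", "proliferating")) {
  variant <- match.arg(variant)
  logistic_bracket <- match.arg(logistic_bracket)
  if (!is.finite(lambda0) || lambda0 <= 0) stop("`lambda0` must be > 0", call. = FALSE)
  if (variant == "simeoni") {
    if (is.null(lambda1) || !is.finite(lambda1) || lambda1 <= 0) {
      stop("simeoni growth requires `lambda1` > 0", call. = FALSE)
    }
    if (!is.finite(phi) || phi < 1) stop("`phi` must be >= 1", call. = FALSE)
    out <- list(variant = variant, lambda0 = lambda0, lambda1 = lambda1,
                phi = phi, w_th = lambda1 / lambda0)
  } else {
    if (is.null(umax) || !is.finite(umax) || umax <= 0) {
      stop("logistic growth requires `umax` > 0", call. = FALSE)
    }
    out <- list(variant = variant, lambda0 = lambda0, umax = umax,
                logistic_bracket = logistic_bracket)
  }
  structure(out, class = "growth_params")
}

#' Drug-kill (mortality) parameters
#'
#' The kill term is `k_out(C, u) = eta * C * u`: mass moves from the
#' proliferating pool to the first damaged compartment at a rate proportional
#' to drug concentration.
#'
#' @param eta Drug potency (concentration^-1 time^-1), >= 0.
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(eta) {
  if (!is.finite(eta) || eta < 0) stop("`eta` must be >= 0", call. = FALSE)
  structure(list(eta = eta), class = "mortality_params")
}

#' Transit-chain parameters
#'
#' `n` damaged-cell compartments with common transit rate `k1` and mean
#' continuation probability `p`: at each transition a damaged cell continues
#' down the chain with probability `p` and dies immediately with probability
#' `1 - p`. `p = 1` recovers the Erlang (Simeoni) chain.
#'
#' @param n Integer number of damaged compartments, >= 1.
#' @param k1 Transit rate (time^-1), > 0.
#' @param p Mean continuation probability in `[0, 1]` (default 1).
#' @return An object of class `tcm_params`.
#' @export
tcm_params <- function(n, k1, p = 1) {
  if (!is.finite(n) || n < 1 || n != round(n)) stop("`n` must be an integer >= 1", call. = FALSE)
  if (!is.finite(k1) || k1 <= 0) stop("`k1` must be > 0", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), k1 = k1, p = p), class = "tcm_params")
}

#' Tumor growth rate k_in
#'
#' Evaluates the growth law of [growth_params()]. The simeoni form is
#' computed in log-domain so that `((lambda0/lambda1) w)^phi` cannot
#' overflow at large `phi`.
#'
#' @param u Proliferating mass (>= 0, vectorized).
#' @param w Total mass `u + sum(y)` (>= 0, vectorized).
#' @param params A [growth_params()].
#' @return Growth rate(s) (mass time^-1).
#' @export
growth_rate <- function(u, w, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(u < 0) || any(w < 0)) stop("states must be nonnegative", call. = FALSE)
  if (params$variant == "simeoni") {
    out <- params$lambda0 * u
    pos <- w > 0
    if (any(pos)) {
      z <- params$phi * (log(w[pos]) - log(params$w_th))
      # log(1 + e^z)^(1/phi), overflow-safe
      log_denom <- (pmax(z, 0) + log1p(exp(-abs(z)))) / params$phi
      out[pos] <- params$lambda0 * u[pos] * exp(-log_denom)
    }
    out
  } else {
    sat <- if (params$logistic_bracket == "total") w else u
    params$lambda0 * (1 - sat / params$umax) * u
  }
}

#' Drug-kill rate k_out
#'
#' @param C Drug concentration (>= 0, vectorized).
#' @param u Proliferating mass (>= 0, vectorized).
#' @param params A [mortality_params()].
#' @return Kill rate(s) `eta * C * u` (mass time^-1).
#' @export
mortality_rate <- function(C, u, params) {
  stopifnot(inherits(params, "mortality_params"))
  if (any(C < 0) || any(u < 0)) stop("`C` and `u` must be nonnegative", call. = FALSE)
  params$eta * C * u
}

#' Right-hand sides of the transit compartment models
#'
#' `coxian_tcm_rhs` implements
#' \deqn{du/dt = k_{in} - k_{out},\quad dy_1/dt = k_{out} - k_1 y_1,\quad
#'       dy_i/dt = p k_1 y_{i-1} - k_1 y_i \ (i \ge 2),}
#' and `erlang_tcm_rhs` is the `p = 1` special case (the classical chain
#' `dy_i/dt = k_1 (y_{i-1} - y_i)`); any `p` carried by `tcm` is ignored
#' there.
#'
#' @param u Proliferating mass.
#' @param y Numeric vector of damaged-compartment masses, length `tcm$n`.
#' @param C Drug concentration at the evaluation time.
#' @param growth A [growth_params()].
#' @param mortality A [mortality_params()].
#' @param tcm A [tcm_params()].
#' @return A list with elements `du` (scalar) and `dy` (length `n`).
#' @export
coxian_tcm_rhs <- function(u, y, C, growth, mortality, tcm) {
  if (length(y) != tcm$n) stop("length(y) must equal tcm$n", call. = FALSE)
  w <- u + sum(y)
  kin <- growth_rate(u, w, growth)
  kout <- mortality_rate(C, u, mortality)
  k1 <- tcm$k1; p <- tcm$p
  dy <- numeric(tcm$n)
  dy[1] <- kout - k1 * y[1]
  if (tcm$n >= 2L) dy[-1] <- p * k1 * y[-tcm$n] - k1 * y[-1]
  list(du = kin - kout, dy = dy)
}

#' @rdname coxian_tcm_rhs
#' @export
erlang_tcm_rhs <- function(u, y, C, growth, mortality, tcm) {
  coxian_tcm_rhs(u, y, C, growth, mortality,
                 tcm_params(tcm$n, tcm$k1, p = 1))
}

#' Simulate a transit compartment tumor model
#'
#' Integrates the Erlang or Coxian TCM driven by a drug exposure. When the
#' exposure is a [pk_exposure()] the two PK amounts are co-integrated with
#' the tumor states and bolus doses are applied as solver events, so the
#' integrator restarts at every discontinuity. Initial damaged compartments
#' are exactly zero: before treatment the whole tumor is proliferating.
#'
#' @param model `"coxian"` or `"erlang"` (`"erlang"` forces `p = 1`).
#' @param growth A [growth_params()].
#' @param mortality A [mortality_params()].
#' @param tcm A [tcm_params()].
#' @param exposure A nonnegative number (constant concentration), a
#'   [constant_infusion_concentration()], a [pk_exposure()], or a function
#'   `C(t)`.
#' @param w0 Initial tumor mass (all proliferating), > 0.
#' @param times Strictly increasing output grid.
#' @param rtol,atol Solver tolerances (defaults 1e-8 / 1e-10).
#' @param method `deSolve` method; the default `"lsoda"` switches to a stiff
#'   integrator when the kill rate `eta * C` is large.
#' @return A data.frame of class `tcm_trajectory` with columns `time`, `u`,
#'   `y1..yn`, `w`, `C`; parameters and solver settings are kept in
#'   attributes. Any state below `-1e-9` aborts with an error (no clipping).
#' @examples
#' g <- growth_params("logistic", lambda0 = 0.12, umax = 0.0066)
#' tr <- simulate_tcm("erlang", g, mortality_params(0.0035),
#'                    tcm_params(4, 0.1682), exposure = 5,
#'                    w0 = 5e-4, times = seq(0, 72, by = 1))
#' head(tr)
#' @export
simulate_tcm <- function(model = c("coxian", "erlang"), growth, mortality, tcm,
                         exposure, w0, times, rtol = 1e-8, atol = 1e-10,
                         method = "lsoda") {
  model <- match.arg(model)
  stopifnot(inherits(growth, "growth_params"), inherits(mortality, "mortality_params"),
            inherits(tcm, "tcm_params"))
  if (!is.finite(w0) || w0 < 0) stop("`w0` must be nonnegative", call. = FALSE)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (model == "erlang") tcm <- tcm_params(tcm$n, tcm$k1, p = 1)
  n <- tcm$n
  ynames <- paste0("y", seq_len(n))

  if (is.numeric(exposure) && length(exposure) == 1L) {
    exposure <- constant_infusion_concentration(exposure)
  }

  if (inherits(exposure, "pk_exposure")) {
    params <- exposure$params
    A <- pk_matrix(params)
    state <- c(q1 = 0, q2 = 0, u = w0, stats::setNames(rep(0, n), ynames))
    rhs <- function(t, s, parms) {
      C <- s[1] / params$V
      d <- coxian_tcm_rhs(s[3], s[4:(3 + n)], max(C, 0), growth, mortality, tcm)
      list(c(A %*% s[1:2], d$du, d$dy))
    }
    sched <- exposure$schedule
    bol <- sched$route == "bolus"
    if (any(!bol)) stop("simulate_tcm supports bolus-only PK schedules; use a concentration function for infusions", call. = FALSE)
    evt <- data.frame(var = "q1", time = sched$times,
                      value = sched$amounts,
                      method = if (exposure$bolus_mode == "add") "add" else "rep")
    tt <- sort(unique(c(times, sched$times[sched$times <= max(times)])))
    sol <- deSolve::ode(y = state, times = tt, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        events = list(data = evt))
    sol <- as.data.frame(sol)
    sol$C <- sol$q1 / params$V
  } else {
    cfun <- if (is.function(exposure)) exposure else {
      Cbar <- exposure$Cbar
      function(t) Cbar
    }
    state <- c(u = w0, stats::setNames(rep(0, n), ynames))
    rhs <- function(t, s, parms) {
      C <- cfun(t)
      d <- coxian_tcm_rhs(s[1], s[2:(1 + n)], max(C, 0), growth, mortality, tcm)
      list(c(d$du, d$dy))
    }
    sol <- deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    sol <- as.data.frame(sol)
    sol$C <- vapply(sol$time, cfun, numeric(1))
  }

  if (any(!is.finite(as.matrix(sol[c("u", ynames)])))) {
    stop("solver produced non-finite states; last good time = ",
         max(sol$time[stats::complete.cases(sol)]), call. = FALSE)
  }
  mn <- min(as.matrix(sol[c("u", ynames)]))
  if (mn < -1e-9) {
    stop(sprintf("state became negative (min = %.3e) beyond solver tolerance", mn),
         call. = FALSE)
  }
  out <- sol[sol$time %in% times, c("time", "u", ynames), drop = FALSE]
  out$w <- out$u + rowSums(out[, ynames, drop = FALSE])
  out$C <- sol$C[sol$time %in% times]
  rownames(out) <- NULL
  class(out) <- c("tcm_trajectory", "data.frame")
  attr(out, "model") <- model
  attr(out, "growth") <- growth
  attr(out, "mortality") <- mortality
  attr(out, "tcm") <- tcm
  attr(out, "w0") <- w0
  attr(out, "solver") <- list(method = method, rtol = rtol, atol = atol)
  out
}

#' Distributed-delay master-equation oracle
#'
#' Integrates the convolution form of the perturbed tumor model,
#' \deqn{du/dt = k_{in}(u,w) - k_{out}(C,u), \qquad
#'       dy/dt = k_{out}(C,u) - (k_{out} * f)(t),}
#' where `f` is the residence-time density of the damaged-cell cascade and
#' `*` is convolution over age. The solution uses a fixed uniform grid with a
#' Heun (trapezoidal predictor-corrector) step and a trapezoidal quadrature
#' of the convolution that honours one-sided limits of `k_out` at bolus
#' times, so the scheme stays second-order accurate between events. For an
#' Erlang kernel this equals the total damaged mass of the equivalent ODE
#' chain (the linear chain trick); it is the independent oracle for
#' [simulate_tcm()].
#'
#' @param growth,mortality As in [simulate_tcm()].
#' @param kernel An [erlang_spec()], [coxian_spec()] or [phase_type_spec()]
#'   giving the age density `f`.
#' @param exposure A constant concentration, [constant_infusion_concentration()],
#'   function `C(t)`, or a bolus-only [pk_exposure()] (evaluated exactly via
#'   the matrix-exponential PK solution, with left/right limits at doses).
#' @param w0 Initial (all proliferating) tumor mass.
#' @param t_end End of integration.
#' @param dt Fixed step; must divide every dose time. Default 0.005.
#' @param check_refinement If `TRUE`, re-runs at `2 * dt` and warns when the
#'   Richardson estimate suggests the grid is too coarse.
#' @return A data.frame with columns `time`, `u`, `y` (total damaged mass)
#'   and `w`.
#' @export
convolution_oracle <- function(growth, mortality, kernel, exposure, w0, t_end,
                               dt = 0.005, check_refinement = FALSE) {
  stopifnot(inherits(growth, "growth_params"), inherits(mortality, "mortality_params"))
  run <- function(dt) {
    m <- round(t_end / dt)
    if (abs(m * dt - t_end) > 1e-9) stop("`dt` must divide `t_end`", call. = FALSE)
    tg <- seq(0, t_end, length.out = m + 1L)
    cf <- pk_conc_fun(exposure)
    CL <- cf(tg, side = "left")
    CR <- cf(tg, side = "right")
    f <- if (inherits(kernel, "erlang_spec")) erlang_density(tg, kernel) else phase_density(kernel, tg)
    eta <- mortality$eta
    u <- numeric(m + 1L); y <- numeric(m + 1L)
    koutL <- numeric(m + 1L); koutR <- numeric(m + 1L)
    u[1] <- w0
    koutL[1] <- eta * CL[1] * u[1]; koutR[1] <- eta * CR[1] * u[1]
    conv_at <- function(j, kL, kR) {
      # trapezoid of a -> kout(t_j - a) f(a) over [0, t_j], split at dose
      # discontinuities: age-cell left endpoints see the left limit in time,
      # right endpoints the right limit.
      if (j == 1L) return(0)
      idx <- seq_len(j - 1L)
      0.5 * dt * (sum(f[idx] * kL[j + 1L - idx]) + sum(f[idx + 1L] * kR[j - idx]))
    }
    for (j in seq_len(m)) {
      uj <- u[j]; yj <- y[j]
      conv_j <- conv_at(j, koutL, koutR)
      s1u <- growth_rate(uj, max(uj + yj, 0), growth) - koutR[j]
      s1y <- koutR[j] - conv_j
      us <- max(uj + dt * s1u, 0); ys <- yj + dt * s1y
      koutL[j + 1L] <- eta * CL[j + 1L] * us
      conv_n <- conv_at(j + 1L, koutL, koutR)
      s2u <- growth_rate(us, max(us + ys, 0), growth) - koutL[j + 1L]
      s2y <- koutL[j + 1L] - conv_n
      u[j + 1L] <- max(uj + dt / 2 * (s1u + s2u), 0)
      y[j + 1L] <- yj + dt / 2 * (s1y + s2y)
      koutL[j + 1L] <- eta * CL[j + 1L] * u[j + 1L]
      koutR[j + 1L] <- eta * CR[j + 1L] * u[j + 1L]
    }
    data.frame(time = tg, u = u, y = y, w = u + y)
  }
  res <- run(dt)
  if (check_refinement) {
    coarse <- run(2 * dt)
    sub <- res[match(coarse$time, res$time), ]
    gap <- max(abs(sub$y - coarse$y)) / max(abs(res$y), .Machine$double.eps)
    if (gap > 1e-3) {
      warning(sprintf("convolution grid may be too coarse (Richardson gap %.2e)", gap),
              call. = FALSE)
    }
    attr(res, "richardson_gap") <- gap
  }
  res
}

#' @export
print.tcm_trajectory <- function(x, ...) {
  tcm <- attr(x, "tcm")
  cat(sprintf("TCM trajectory (%s, n = %d, k1 = %g, p = %g): %d time points on [%g, %g]\n",
              attr(x, "model"), tcm$n, tcm$k1, tcm$p, nrow(x), min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
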