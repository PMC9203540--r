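#' Two-compartment pharmacokinetic parameters
#'
#' Central (plasma) and peripheral compartments with first-order elimination
#' from the central compartment:
#' \deqn{dq1/dt = -k01 q1 - k21 q1 + k12 q2 + v(t), \quad
#'       dq2/dt = k21 q1 - k12 q2, \quad C(t) = q1(t) / V.}
#'
#' @param k01 Elimination rate from plasma (day^-1).
#' @param k21 Plasma-to-peripheral rate (day^-1).
#' @param k12 Peripheral-to-plasma rate (day^-1).
#' @param V Central volume of distribution (ml).
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(k01 = 1.6, k21 = 0.2353, k12 = 0.1699, V = 1028)
#' @export
pk_params <- function(k01, k21, k12, V) {
  vals <- c(k01 = k01, k21 = k21, k12 = k12)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("PK rates must be >= 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("`V` must be > 0", call. = FALSE)
  structure(list(k01 = k01, k21 = k21, k12 = k12, V = V), class = "pk_params")
}

#' Dosing schedule
#'
#' A list of dosing events. Bolus events add `amount` (ng kg^-1) to the
#' central compartment instantaneously; infusion events set a constant
#' zero-order input rate (amount per unit time) that persists until the next
#' infusion event (rate 0 switches it off) or the horizon.
#'
#' @param times Strictly increasing event times within `[0, horizon]`.
#' @param amounts Nonnegative dose amounts (bolus) or rates (infusion),
#'   recycled to `length(times)`.
#' @param route `"bolus"` or `"infusion"`, recycled.
#' @param horizon End of the simulation window (defaults to the last event
#'   time plus one unit).
#' @return An object of class `dose_schedule`.
#' @examples
#' # ten daily boluses from day 13 (mouse xenograft regimen)
#' dose_schedule(times = 13:22, amounts = 4.5e7, horizon = 40)
#' @export
dose_schedule <- function(times, amounts, route = "bolus", horizon = NULL) {
  times <- as.numeric(times)
  amounts <- rep_len(as.numeric(amounts), length(times))
  route <- rep_len(as.character(route), length(times))
  if (is.null(horizon)) horizon <- if (length(times)) max(times) + 1 else 1
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("event times must be strictly increasing", call. = FALSE)
    if (any(times < 0) || any(times > horizon)) {
      stop("event times must lie within [0, horizon]", call. = FALSE)
    }
    if (any(amounts < 0)) stop("dose amounts must be nonnegative", call. = FALSE)
    if (!all(route %in% c("bolus", "infusion"))) {
      stop("`route` must be 'bolus' or 'infusion'", call. = FALSE)
    }
  }
  structure(list(times = times, amounts = amounts, route = route, horizon = horizon),
            class = "dose_schedule")
}

pk_matrix <- function(params) {
  matrix(c(-params$k01 - params$k21, params$k12,
           params$k21, -params$k12),
         nrow = 2, byrow = TRUE)
}

#' Eigenvalues of the two-compartment system
#'
#' Both eigenvalues of the disposition matrix are real and negative when
#' `k01 > 0`; the slow one sets the terminal log-linear slope of the
#' bi-exponential concentration decay, the fast one the distribution phase.
#'
#' @param params A [pk_params()].
#' @return Numeric vector of the two eigenvalues, slow (closest to zero) first.
#' @export
pk_eigenvalues <- function(params) {
  ev <- eigen(pk_matrix(params), only.values = TRUE)$values
  ev <- sort(Re(ev), decreasing = TRUE)
  ev
}

#' Simulate the two-compartment PK model
#'
#' Integrates the plasma/peripheral amounts with `deSolve`, restarting the
#' integrator at every dose event so no discontinuity is stepped across.
#' Bolus events add the dose amount to `q1` (standard superposition
#' convention); `bolus_mode = "reset"` instead resets `q1` to the amount,
#' mirroring a literal reading of "q1(t_in) = dose".
#'
#' @param params A [pk_params()].
#' @param schedule A [dose_schedule()].
#' @param times Output time grid within `[0, horizon]`.
#' @param bolus_mode `"add"` (default) or `"reset"`.
#' @param rtol,atol Solver tolerances.
#' @param method `deSolve` integration method (default `"lsoda"`).
#' @return A data.frame of class `pk_profile` with columns `time`, `q1`,
#'   `q2`, `C`.
#' @export
pk_simulate <- function(params, schedule, times,
                        bolus_mode = c("add", "reset"),
                        rtol = 1e-10, atol = 1e-6, method = "lsoda") {
  stopifnot(inherits(params, "pk_params"), inherits(schedule, "dose_schedule"))
  bolus_mode <- match.arg(bolus_mode)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > schedule$horizon)) {
    stop("output grid must lie within [0, horizon]", call. = FALSE)
  }
  A <- pk_matrix(params)
  rhs <- function(t, y, parms) {
    list(c(A %*% y[1:2] + c(parms$rate, 0)))
  }
  ev_t <- schedule$times
  grid <- sort(unique(c(times, ev_t)))
  segs <- c(0, ev_t[ev_t > 0], schedule$horizon)
  segs <- sort(unique(segs))
  state <- c(q1 = 0, q2 = 0)
  rate <- 0
  out_t <- numeric(0); out_q <- NULL
  for (s in seq_len(length(segs) - 1L)) {
    t0 <- segs[s]; t1 <- segs[s + 1L]
    # apply any event at t0
    iev <- which(ev_t == t0)
    if (length(iev)) {
      for (j in iev) {
        if (schedule$route[j] == "bolus") {
          state["q1"] <- if (bolus_mode == "add") state["q1"] + schedule$amounts[j] else schedule$amounts[j]
        } else {
          rate <- schedule$amounts[j]
        }
      }
    }
    tt <- grid[grid >= t0 & grid <= t1]
    tt <- sort(unique(c(t0, tt, t1)))
    sol <- deSolve::ode(y = state, times = tt, func = rhs, parms = list(rate = rate),
                        method = method, rtol = rtol, atol = atol)
    keep <- sol[, "time"] < t1 | t1 == schedule$horizon
    out_t <- c(out_t, sol[keep, "time"])
    out_q <- rbind(out_q, sol[keep, c("q1", "q2"), drop = FALSE])
    state <- c(q1 = as.numeric(sol[nrow(sol), "q1"]),
               q2 = as.numeric(sol[nrow(sol), "q2"]))
  }
  prof <- data.frame(time = out_t, q1 = out_q[, 1], q2 = out_q[, 2])
  prof <- prof[!duplicated(prof$time) & prof$time %in% times, , drop = FALSE]
  prof$C <- prof$q1 / params$V
  rownames(prof) <- NULL
  class(prof) <- c("pk_profile", "data.frame")
  attr(prof, "params") <- params
  attr(prof, "schedule") <- schedule
  prof
}

#' Exact matrix-exponential PK solution (bolus-only oracle)
#'
#' For a bolus-only schedule the linear system has the exact impulse
#' superposition solution
#' `q(t) = sum_{t_d <= t} expm(A (t - t_d)) e1 D_d`, evaluated here through
#' the eigendecomposition of the 2x2 disposition matrix. Serves as an
#' independent oracle for [pk_simulate()].
#'
#' @inheritParams pk_simulate
#' @param side `"right"` includes a dose given exactly at an output time
#'   (post-dose value), `"left"` excludes it (pre-dose value).
#' @return A data.frame of class `pk_profile`.
#' @export
pk_matrix_exponential_solution <- function(params, schedule, times, side = c("right", "left")) {
  stopifnot(inherits(params, "pk_params"), inherits(schedule, "dose_schedule"))
  side <- match.arg(side)
  if (any(schedule$route != "bolus")) {
    stop("matrix-exponential solution supports bolus-only schedules", call. = FALSE)
  }
  A <- pk_matrix(params)
  ed <- eigen(A)
  Vm <- ed$vectors; Vi <- solve(Vm); lam <- ed$values
  q_at <- function(t) {
    if (side == "right") sel <- schedule$times <= t else sel <- schedule$times < t
    td <- schedule$times[sel]; D <- schedule$amounts[sel]
    if (!length(td)) return(c(0, 0))
    # expm(A dt) e1 = V diag(exp(lam dt)) V^-1 e1
    w <- Vi[, 1]
    acc <- c(0 + 0i, 0 + 0i)
    for (j in seq_along(td)) {
      acc <- acc + D[j] * (Vm %*% (exp(lam * (t - td[j])) * w))[, 1]
    }
    Re(acc)
  }
  qs <- t(vapply(times, q_at, numeric(2)))
  prof <- data.frame(time = times, q1 = qs[, 1], q2 = qs[, 2], C = qs[, 1] / params$V)
  class(prof) <- c("pk_profile", "data.frame")
  attr(prof, "params") <- params
  attr(prof, "schedule") <- schedule
  prof
}

#' Constant-infusion (steady-state) concentration profile
#'
#' Represents drug administered by infusion at steady state, i.e. a constant
#' plasma concentration `Cbar` driving the tumor model; this is the exposure
#' object used by the equilibrium analysis.
#'
#' @param Cbar Nonnegative constant concentration (ng ml^-1).
#' @return An exposure object of class `constant_exposure`; calling it is not
#'   needed — [simulate_tcm()] accepts it (or a bare nonnegative number)
#'   directly.
#' @examples
#' constant_infusion_concentration(4032.2)
#' @export
constant_infusion_concentration <- function(Cbar) {
  if (!is.finite(Cbar) || Cbar < 0) stop("`Cbar` must be a nonnegative number", call. = FALSE)
  structure(list(Cbar = as.numeric(Cbar)), class = "constant_exposure")
}

#' Pharmacokinetic exposure driver for the tumor model
#'
#' Bundles PK parameters and a dosing schedule so the tumor simulation can
#' co-integrate drug amounts exactly (with bolus jumps as solver events)
#' instead of interpolating a precomputed profile.
#'
#' @inheritParams pk_simulate
#' @return An object of class `pk_exposure`.
#' @export
pk_exposure <- function(params, schedule, bolus_mode = c("add", "reset")) {
  stopifnot(inherits(params, "pk_params"), inherits(schedule, "dose_schedule"))
  bolus_mode <- match.arg(bolus_mode)
  structure(list(params = params, schedule = schedule, bolus_mode = bolus_mode),
            class = "pk_exposure")
}

# Exact concentration with one-sided limits at dose times (bolus-only),
# used by the convolution oracle. Returns a function(t, side).
pk_conc_fun <- function(exposure) {
  if (inherits(exposure, "constant_exposure")) {
    Cbar <- exposure$Cbar
    return(function(t, side = "right") rep(Cbar, length(t)))
  }
  if (is.numeric(exposure) && length(exposure) == 1L) {
    Cbar <- exposure
    return(function(t, side = "right") rep(Cbar, length(t)))
  }
  if (is.function(exposure)) {
    return(function(t, side = "right") exposure(t))
  }
  stopifnot(inherits(exposure, "pk_exposure"))
  params <- exposure$params; schedule <- exposure$schedule
  function(t, side = "right") {
    pk_matrix_exponential_solution(params, schedule, t, side = side)$C
  }
}
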