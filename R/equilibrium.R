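#' Geometric continuation-probability factor
#'
#' The dimensionless sum `1 + p + ... + p^(n-1)` that multiplies the damaged
#' compartments at equilibrium; equal to `(1 - p^n) / (1 - p)` for `p < 1`
#' and exactly `n` at `p = 1` (explicit branch, no division).
#'
#' @param p Continuation probability in `[0, 1]`.
#' @param n Integer chain length, >= 1.
#' @return The partial geometric sum.
#' @examples
#' geometric_factor(0.5, 4)  # 1.875
#' geometric_factor(1, 4)    # 4
#' @export
geometric_factor <- function(p, n) {
  if (!is.finite(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(n) || n < 1 || n != round(n)) stop("`n` must be an integer >= 1", call. = FALSE)
  if (abs(1 - p) < 1e-12) return(as.numeric(n))
  (1 - p^n) / (1 - p)
}

#' Critical infusion concentration
#'
#' The constant-infusion threshold `lambda0 / eta`: below it the tumor
#' persists at a nonzero equilibrium, above it the zero equilibrium is the
#' only one and the tumor is eradicated.
#'
#' @param growth A [growth_params()].
#' @param mortality A [mortality_params()].
#' @return Threshold concentration (same unit as `C`).
#' @export
infusion_threshold <- function(growth, mortality) {
  if (mortality$eta == 0) return(Inf)
  growth$lambda0 / mortality$eta
}

# shared chain equilibrium: ybar_i = (eta Cbar ubar / k1) p^(i-1)
chain_equilibrium <- function(ubar, eta, Cbar, tcm) {
  (eta * Cbar * ubar / tcm$k1) * tcm$p^(seq_len(tcm$n) - 1L)
}

new_equilibrium_result <- function(regime, threshold, Cbar, points, printed = NULL) {
  structure(list(regime = regime, threshold = threshold, Cbar = Cbar,
                 points = points, printed = printed),
            class = "tcm_equilibria")
}

#' Equilibria of the Simeoni-growth TCM under constant infusion
#'
#' For constant concentration `Cbar` the regimes are set solely by the sign
#' of `Cbar - lambda0/eta`:
#' above the threshold only the zero equilibrium exists; below it the zero
#' equilibrium is joined by a nonzero one; exactly at the threshold a
#' continuum of equilibria appears. The nonzero point is obtained by a
#' direct steady-state solve of the full growth law: balancing
#' `k_in = eta Cbar u` gives
#' `wbar = w_th ((lambda0/(eta Cbar))^phi - 1)^(1/phi)` (evaluated in
#' log-domain), `ubar = wbar / (1 + (eta Cbar / k1) g(p, n))` with
#' `g = ` [geometric_factor()], and `ybar_i = (eta Cbar ubar / k1) p^(i-1)`.
#' In the sharp-switch limit (`phi` large) `wbar` tends to
#' `lambda1 / (eta Cbar)`, independent of `p` and `n`; that limiting form
#' (`ubar = lambda1 / (eta Cbar + (eta Cbar)^2 g / k1)`) is reported in
#' `$printed` for comparison.
#'
#' @param growth A simeoni [growth_params()].
#' @param mortality A [mortality_params()].
#' @param tcm A [tcm_params()].
#' @param Cbar Constant infusion concentration, >= 0.
#' @param tol_rel Relative tolerance for detecting the threshold collision.
#' @return A `tcm_equilibria` object: `regime` (`"zero-only"`,
#'   `"zero-plus-nonzero"` or `"continuum"`), `threshold`, and `points`, a
#'   list of equilibria each with `u`, `y`, `w`, `type`.
#' @export
equilibria_simeoni <- function(growth, mortality, tcm, Cbar, tol_rel = 1e-12) {
  stopifnot(inherits(growth, "growth_params"), growth$variant == "simeoni",
            inherits(mortality, "mortality_params"), inherits(tcm, "tcm_params"))
  if (!is.finite(Cbar) || Cbar < 0) stop("`Cbar` must be >= 0", call. = FALSE)
  thr <- infusion_threshold(growth, mortality)
  eta <- mortality$eta
  zero_pt <- list(u = 0, y = rep(0, tcm$n), w = 0, type = "zero")
  if (is.finite(thr) && abs(Cbar - thr) <= tol_rel * thr) {
    return(new_equilibrium_result("continuum", thr, Cbar, list(zero_pt)))
  }
  if (Cbar > thr) {
    return(new_equilibrium_result("zero-only", thr, Cbar, list(zero_pt)))
  }
  g <- geometric_factor(tcm$p, tcm$n)
  if (Cbar == 0 || eta == 0) {
    # unbounded growth, no finite nonzero equilibrium for the simeoni law
    return(new_equilibrium_result("zero-only", thr, Cbar, list(zero_pt)))
  }
  # direct solve: (1 + (w/w_th)^phi)^(1/phi) = lambda0 / (eta Cbar) = r
  r <- growth$lambda0 / (eta * Cbar)
  L <- growth$phi * log(r)
  wbar <- if (L > 700) growth$w_th * r else growth$w_th * exp(log(expm1(L)) / growth$phi)
  ubar <- wbar / (1 + (eta * Cbar / tcm$k1) * g)
  ybar <- chain_equilibrium(ubar, eta, Cbar, tcm)
  nz <- list(u = ubar, y = ybar, w = ubar + sum(ybar), type = "nonzero")
  ubar_lim <- growth$lambda1 / (eta * Cbar + (eta * Cbar)^2 / tcm$k1 * g)
  printed <- list(ubar = ubar_lim,
                  wbar = growth$lambda1 / (eta * Cbar),
                  note = "sharp-switch (large phi) limiting forms")
  new_equilibrium_result("zero-plus-nonzero", thr, Cbar, list(zero_pt, nz), printed)
}

#' Equilibria of the logistic-growth TCM under constant infusion
#'
#' Direct steady-state solve of the logistic chain. With the total-mass
#' bracket, `lambda0 (1 - wbar/umax) = eta Cbar` gives
#' `wbar = umax (1 - eta Cbar / lambda0)` and
#' `ubar = wbar / (1 + (eta Cbar / k1) g(p, n))`; with the
#' proliferating-mass bracket the same closed form applies to `ubar`
#' directly, and `wbar = ubar (1 + (eta Cbar / k1) g)`. At or above the
#' threshold only zero remains. A commonly quoted alternative closed form
#' (with the last damaged compartment lacking its `p^(n-1)` attenuation) is
#' reported in `$printed` for comparison but is not a steady state of the
#' chain and is never asserted.
#'
#' @inheritParams equilibria_simeoni
#' @param growth A logistic [growth_params()].
#' @return A `tcm_equilibria` object (see [equilibria_simeoni()]).
#' @export
equilibria_logistic <- function(growth, mortality, tcm, Cbar, tol_rel = 1e-12) {
  stopifnot(inherits(growth, "growth_params"), growth$variant == "logistic",
            inherits(mortality, "mortality_params"), inherits(tcm, "tcm_params"))
  if (!is.finite(Cbar) || Cbar < 0) stop("`Cbar` must be >= 0", call. = FALSE)
  thr <- infusion_threshold(growth, mortality)
  eta <- mortality$eta
  zero_pt <- list(u = 0, y = rep(0, tcm$n), w = 0, type = "zero")
  if (Cbar >= thr) {
    # at or above the threshold zero is the unique equilibrium
    return(new_equilibrium_result("zero-only", thr, Cbar, list(zero_pt)))
  }
  g <- geometric_factor(tcm$p, tcm$n)
  fac <- 1 + (eta * Cbar / tcm$k1) * g
  if (growth$logistic_bracket == "total") {
    wbar <- growth$umax * (1 - eta * Cbar / growth$lambda0)
    ubar <- wbar / fac
  } else {
    ubar <- growth$umax * (1 - eta * Cbar / growth$lambda0)
    wbar <- ubar * fac
  }
  ybar <- chain_equilibrium(ubar, eta, Cbar, tcm)
  nz <- list(u = ubar, y = ybar, w = ubar + sum(ybar), type = "nonzero")
  printed <- list(
    ubar = growth$umax * (growth$lambda0 - eta * Cbar) / growth$lambda0,
    yn_no_attenuation = eta * Cbar / tcm$k1 * ubar,
    note = "alternative printed closed form; not a steady state of the chain")
  new_equilibrium_result("zero-plus-nonzero", thr, Cbar, list(zero_pt, nz), printed)
}

#' Local stability of a constant-infusion equilibrium
#'
#' Builds the autonomous right-hand side at constant `Cbar`, evaluates a
#' numerical Jacobian at the equilibrium (central differences) and
#' classifies by the eigenvalue real parts: `"stable"` if all are below
#' `-tol`, `"unstable"` if any exceeds `tol`, `"marginal"` otherwise.
#' Classification is refused for a continuum regime, where the Jacobian is
#' structurally singular along the equilibrium manifold.
#'
#' @param eq Either a `tcm_equilibria` object (classifies every point) or a
#'   list with elements `u` and `y`.
#' @param growth,mortality,tcm,Cbar Model and infusion as in
#'   [equilibria_simeoni()].
#' @param tol Eigenvalue tolerance on the real part (default 1e-10).
#' @return For a single point, a list with `verdict`, `eigenvalues`,
#'   `jacobian`; for a `tcm_equilibria`, the same object with a `stability`
#'   entry added to each point.
#' @export
stability_classify <- function(eq, growth, mortality, tcm, Cbar, tol = 1e-10) {
  if (inherits(eq, "tcm_equilibria")) {
    if (identical(eq$regime, "continuum")) {
      stop("continuum regime: equilibria form a manifold, spectral classification refused",
           call. = FALSE)
    }
    eq$points <- lapply(eq$points, function(pt) {
      pt$stability <- stability_classify(pt, growth, mortality, tcm, Cbar, tol)
      pt
    })
    return(eq)
  }
  state <- c(eq$u, eq$y)
  # smooth extension of the rhs so central differences at a boundary
  # equilibrium (u = y = 0) do not cross a domain restriction
  kin_smooth <- function(u, w) {
    if (growth$variant == "simeoni") {
      if (w <= 0) return(growth$lambda0 * u)  # (w/w_th)^phi and its slope vanish at 0 for phi > 1
      z <- growth$phi * (log(w) - log(growth$w_th))
      growth$lambda0 * u * exp(-(pmax(z, 0) + log1p(exp(-abs(z)))) / growth$phi)
    } else {
      sat <- if (growth$logistic_bracket == "total") w else u
      growth$lambda0 * (1 - sat / growth$umax) * u
    }
  }
  f <- function(s) {
    u <- s[1]; y <- s[-1]
    w <- u + sum(y)
    kout <- mortality$eta * Cbar * u
    dy <- numeric(tcm$n)
    dy[1] <- kout - tcm$k1 * y[1]
    if (tcm$n >= 2L) dy[-1] <- tcm$p * tcm$k1 * y[-tcm$n] - tcm$k1 * y[-1]
    c(kin_smooth(u, w) - kout, dy)
  }
  J <- pracma::jacobian(f, state)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  verdict <- if (all(re < -tol)) "stable" else if (any(re > tol)) "unstable" else "marginal"
  list(verdict = verdict, eigenvalues = ev, jacobian = J)
}

#' @export
print.tcm_equilibria <- function(x, ...) {
  cat(sprintf("Constant-infusion equilibria: Cbar = %g, threshold lambda0/eta = %g\n",
              x$Cbar, x$threshold))
  cat("  regime:", x$regime, "\n")
  for (pt in x$points) {
    lab <- if (!is.null(pt$stability)) paste0(" [", pt$stability$verdict, "]") else ""
    cat(sprintf("  %s equilibrium: u = %g, w = %g%s\n", pt$type, pt$u, pt$w, lab))
  }
  invisible(x)
}
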