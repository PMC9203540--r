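#' Erlang residence-time specification
#'
#' An Erlang distribution with `n` phases and common rate `k1` is the
#' residence-time law implied by a chain of `n` transit compartments with
#' identical mean residence time `1/k1` (total mean `n/k1`). It is the delay
#' kernel of the classical (Simeoni-type) transit compartment model.
#'
#' @param n Integer number of phases, `n >= 1`.
#' @param k1 Common transit rate (time^-1), `k1 > 0`.
#' @return An object of class `erlang_spec` with elements `n` and `k1`.
#' @examples
#' sp <- erlang_spec(4, 0.2859)
#' phase_moments(sp)  # 4 / 0.2859
#' @export
erlang_spec <- function(n, k1) {
  stopifnot(length(n) == 1L, length(k1) == 1L)
  if (!is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  if (!is.finite(k1) || k1 <= 0) stop("`k1` must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), k1 = as.numeric(k1)), class = "erlang_spec")
}

#' Coxian residence-time specification
#'
#' In a Coxian distribution a cell in phase `i` leaves at rate `k[i]`; with
#' probability `p[i]` it continues to phase `i + 1` and with probability
#' `1 - p[i]` it exits (dies) immediately. The last phase always exits
#' (`p[n] = 0`). With all `p[i] = 1` (i < n) and equal rates it reduces to the
#' Erlang distribution.
#'
#' @param n Integer number of phases.
#' @param k Vector of phase exit rates (time^-1), recycled to length `n`.
#' @param p Vector of continuation probabilities in `[0, 1]`, recycled to
#'   length `n`; the final entry must be 0 (it is forced to 0 when a scalar
#'   `p` is supplied).
#' @return An object of class `coxian_spec`.
#' @examples
#' coxian_spec(3, k = 0.3, p = 0.5)
#' @export
coxian_spec <- function(n, k, p) {
  if (!is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  scalar_p <- length(p) == 1L
  k <- rep_len(as.numeric(k), n)
  p <- rep_len(as.numeric(p), n)
  if (scalar_p) p[n] <- 0
  if (any(!is.finite(k)) || any(k <= 0)) stop("all rates `k` must be > 0", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("continuation probabilities `p` must lie in [0, 1]", call. = FALSE)
  }
  if (p[n] != 0) stop("the final continuation probability must be 0 (p_n = 0)", call. = FALSE)
  structure(list(n = n, k = k, p = p), class = "coxian_spec")
}

#' General phase-type specification
#'
#' A phase-type distribution is the absorption-time law of a finite
#' continuous-time Markov chain with initial distribution `alpha`,
#' sub-generator `S` (transient-state block) and exit-rate vector
#' `S0 = -S %*% 1`. Density: `f(t) = alpha %*% expm(S t) %*% S0`.
#'
#' @param alpha Probability row vector over starting phases (sums to 1).
#' @param S Square sub-generator matrix: strictly negative diagonal,
#'   nonnegative off-diagonal, nonpositive row sums.
#' @return An object of class `phase_type_spec` with elements `alpha`, `S`,
#'   `S0` and `n`.
#' @export
phase_type_spec <- function(alpha, S) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n) stop("`S` must be square", call. = FALSE)
  alpha <- as.numeric(alpha)
  if (length(alpha) != n) stop("`alpha` length must match nrow(S)", call. = FALSE)
  if (any(alpha < 0) || any(alpha > 1) || abs(sum(alpha) - 1) > 1e-12) {
    stop("`alpha` must be a probability vector summing to 1 (tol 1e-12)", call. = FALSE)
  }
  if (any(diag(S) >= 0)) stop("diagonal of `S` must be strictly negative", call. = FALSE)
  off <- S; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of `S` must be nonnegative", call. = FALSE)
  S0 <- as.numeric(-S %*% rep(1, n))
  if (any(S0 < -1e-12)) stop("exit rates S0 = -S %*% 1 must be nonnegative", call. = FALSE)
  S0[S0 < 0] <- 0
  structure(list(alpha = alpha, S = S, S0 = S0, n = n), class = "phase_type_spec")
}

#' Erlang density
#'
#' Evaluates `f_n(a) = k1 (k1 a)^(n-1) exp(-k1 a) / (n-1)!`, the Erlang
#' density, in log-domain for numerical safety.
#'
#' @param a Nonnegative ages (vectorized).
#' @param spec An [erlang_spec()].
#' @return Density values (time^-1).
#' @export
erlang_density <- function(a, spec) {
  stopifnot(inherits(spec, "erlang_spec"))
  if (any(a < 0)) stop("ages `a` must be nonnegative", call. = FALSE)
  n <- spec$n; k1 <- spec$k1
  out <- numeric(length(a))
  pos <- a > 0
  out[pos] <- exp(log(k1) + (n - 1) * (log(k1) + log(a[pos])) - k1 * a[pos] - lfactorial(n - 1))
  out[!pos] <- if (n == 1L) k1 else 0
  out
}

#' Coxian sub-generator construction
#'
#' Builds the phase-type representation of a Coxian distribution:
#' `alpha = (1, 0, ..., 0)`, `S` with diagonal `-k_i` and superdiagonal
#' `p_i k_i`, so the exit rates are `(1 - p_i) k_i` for `i < n` and `k_n` for
#' the last phase.
#'
#' @param spec A [coxian_spec()].
#' @return A [phase_type_spec()].
#' @examples
#' ph <- coxian_generator(coxian_spec(3, k = 1, p = c(1, 1, 0)))
#' ph$S  # Erlang generator with rate 1
#' @export
coxian_generator <- function(spec) {
  stopifnot(inherits(spec, "coxian_spec"))
  n <- spec$n
  S <- diag(-spec$k, n, n)
  if (n >= 2L) {
    S[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- spec$p[-n] * spec$k[-n]
  }
  alpha <- c(1, rep(0, n - 1L))
  phase_type_spec(alpha, S)
}

#' Coerce a specification to phase-type form
#'
#' @param spec An `erlang_spec`, `coxian_spec` or `phase_type_spec`.
#' @return A [phase_type_spec()].
#' @export
as_phase_type <- function(spec) {
  if (inherits(spec, "phase_type_spec")) return(spec)
  if (inherits(spec, "erlang_spec")) {
    return(coxian_generator(coxian_spec(spec$n, k = spec$k1, p = c(rep(1, spec$n - 1L), 0))))
  }
  if (inherits(spec, "coxian_spec")) return(coxian_generator(spec))
  stop("cannot coerce object of class ", paste(class(spec), collapse = "/"),
       " to phase_type_spec", call. = FALSE)
}

#' Phase-type density and distribution function
#'
#' `phase_density` evaluates `f(t) = alpha %*% expm(S t) %*% S0` and
#' `phase_cdf` evaluates `F(t) = 1 - alpha %*% expm(S t) %*% 1`, using a
#' scaling-and-squaring matrix exponential. No closed-form Coxian density is
#' attempted.
#'
#' @param spec A spec coercible via [as_phase_type()].
#' @param t Nonnegative times (vectorized).
#' @return Numeric vector of densities (resp. cumulative probabilities).
#' @export
phase_density <- function(spec, t) {
  ph <- as_phase_type(spec)
  if (any(t < 0)) stop("times `t` must be nonnegative", call. = FALSE)
  vapply(t, function(ti) {
    E <- as.matrix(Matrix::expm(ph$S * ti))
    val <- drop(ph$alpha %*% E %*% ph$S0)
    if (!is.finite(val)) {
      stop("matrix exponential produced non-finite density at t = ", ti, call. = FALSE)
    }
    val
  }, numeric(1))
}

#' @rdname phase_density
#' @export
phase_cdf <- function(spec, t) {
  ph <- as_phase_type(spec)
  if (any(t < 0)) stop("times `t` must be nonnegative", call. = FALSE)
  vapply(t, function(ti) {
    E <- as.matrix(Matrix::expm(ph$S * ti))
    val <- 1 - drop(ph$alpha %*% E %*% rep(1, ph$n))
    if (!is.finite(val)) {
      stop("matrix exponential produced non-finite CDF at t = ", ti, call. = FALSE)
    }
    val
  }, numeric(1))
}

#' Mean residence time of a phase-type law
#'
#' The mean absorption time is `-alpha %*% solve(S) %*% 1`; for an Erlang
#' chain this is the total mean residence time `n / k1`.
#'
#' @param spec A spec coercible via [as_phase_type()].
#' @return The mean residence time (same time unit as the rates).
#' @export
phase_moments <- function(spec) {
  ph <- as_phase_type(spec)
  mean_t <- tryCatch(
    -drop(ph$alpha %*% solve(ph$S, rep(1, ph$n))),
    error = function(e) stop("sub-generator `S` is singular: ", conditionMessage(e), call. = FALSE)
  )
  mean_t
}

#' Sample absorption times from a phase-type law
#'
#' Simulates the embedded jump chain: from phase `i` the dwell time is
#' exponential with rate `-S[i, i]`; the chain then exits with probability
#' `S0[i] / -S[i, i]` or moves to phase `j` with probability
#' `S[i, j] / -S[i, i]`.
#'
#' @param spec A spec coercible via [as_phase_type()].
#' @param n_draws Number of absorption times to draw.
#' @return Numeric vector of `n_draws` absorption times. Uses the current RNG
#'   state; seed externally for reproducibility.
#' @export
phase_sample <- function(spec, n_draws) {
  ph <- as_phase_type(spec)
  n <- ph$n
  rates <- -diag(ph$S)
  state <- sample.int(n, n_draws, replace = TRUE, prob = ph$alpha)
  times <- numeric(n_draws)
  alive <- rep(TRUE, n_draws)
  guard <- 0L
  while (any(alive)) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("phase_sample: jump chain failed to absorb", call. = FALSE)
    for (i in seq_len(n)) {
      idx <- which(alive & state == i)
      if (!length(idx)) next
      times[idx] <- times[idx] + stats::rexp(length(idx), rate = rates[i])
      # destination: 0 = absorbed, otherwise next transient phase
      probs <- c(ph$S0[i], pmax(ph$S[i, ], 0))
      probs[i + 1L] <- 0
      dest <- sample.int(n + 1L, length(idx), replace = TRUE, prob = probs) - 1L
      absorbed <- dest == 0L
      alive[idx[absorbed]] <- FALSE
      state[idx[!absorbed]] <- dest[!absorbed]
    }
  }
  times
}

#' @export
print.erlang_spec <- function(x, ...) {
  cat(sprintf("Erlang residence-time kernel: n = %d, k1 = %g (mean %g)\n",
              x$n, x$k1, x$n / x$k1))
  invisible(x)
}

#' @export
print.coxian_spec <- function(x, ...) {
  cat(sprintf("Coxian residence-time kernel: n = %d\n", x$n))
  cat("  k:", format(x$k, digits = 6), "\n")
  cat("  p:", format(x$p, digits = 6), "\n")
  invisible(x)
}

#' @export
print.phase_type_spec <- function(x, ...) {
  cat(sprintf("Phase-type distribution with %d transient phases\n", x$n))
  cat("  mean residence time:", format(phase_moments(x), digits = 6), "\n")
  invisible(x)
}
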