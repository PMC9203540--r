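#' Measurement-noise model
#'
#' The source study reports no noise model, so the generators expose a
#' documented choice: `"proportional"` multiplies each value by a lognormal
#' factor `exp(N(0, sigma^2))` (typical for tumor-burden measurements, and
#' the default with `sigma = 0.05`); `"additive"` adds `N(0, sigma^2)` and
#' truncates at zero; `"none"` returns the trajectory exactly.
#'
#' @param kind `"none"`, `"additive"` or `"proportional"`.
#' @param sigma Dispersion, >= 0.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "additive", "proportional"),
                        sigma = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise, stream = 0L) {
  if (noise$kind == "none" || noise$sigma == 0) return(values)
  with_preserved_seed(noise$seed + stream, {
    eps <- stats::rnorm(length(values), 0, noise$sigma)
    switch(noise$kind,
           additive = pmax(values + eps, 0),
           proportional = values * exp(eps))
  })
}

#' Generate a synthetic xenograft dataset
#'
#' Emulates the mouse xenograft design: tumor implanted at day 0 with mass
#' `w0 = 0.0121` g, ten daily intravenous boluses of `4.5e7` from day 13,
#' tumor weight sampled on a default of 10 occasions spread uniformly over
#' days 13-40 (the drug-effect window; the study does not print its actual
#' sampling days, so this design is synthetic by construction).
#'
#' @param scenario A [tcm_scenario()] holding the generating truth; defaults
#'   to the bundled mouse150 scenario (see [mouse150_scenario()]).
#' @param times Sampling times (default `seq(13, 40, by = 3)`, n = 10).
#' @param noise A [noise_model()].
#' @return An [observation_series()] with the truth scenario, noise model
#'   and noiseless trajectory stored in attributes (`truth`, `noise`,
#'   `clean`).
#' @export
generate_xenograft_dataset <- function(scenario = mouse150_scenario(),
                                       times = seq(13, 40, by = 3),
                                       noise = noise_model("none")) {
  stopifnot(inherits(scenario, "tcm_scenario"), inherits(noise, "noise_model"))
  if (inherits(scenario$exposure, "pk_exposure")) {
    horizon <- scenario$exposure$schedule$horizon
    if (any(times > horizon)) stop("sampling times beyond the schedule horizon", call. = FALSE)
  }
  clean <- simulate_scenario(scenario, times)$w
  series <- observation_series(times, apply_noise(clean, noise),
                               group = "xenograft", exposure = scenario$exposure)
  attr(series, "truth") <- scenario
  attr(series, "noise") <- noise
  attr(series, "clean") <- clean
  series
}

#' Generate a synthetic spheroid dataset
#'
#' Emulates the 3D spheroid assay: one series per drug concentration
#' (0 = control), each under a constant concentration (no drug elimination
#' over the 72 h assay), sampled at the eight assay times
#' 0, 1, 2, 3, 6, 24, 48 and 72 h, optionally with replicates.
#'
#' @param scenario A [tcm_scenario()] generating truth (logistic growth);
#'   defaults to the bundled spheroid scenario (see [spheroid_scenario()]).
#' @param concentrations Nonnegative concentrations, one series per value
#'   (default `c(0, 5, 10)` micromolar).
#' @param times Sampling times in hours (default the eight assay times).
#' @param replicates Replicates per group (default 1; the assay used 30).
#' @param noise A [noise_model()]; replicate r of group g uses an
#'   independent seeded stream.
#' @return A named list of [observation_series()] (one per concentration,
#'   replicates stacked with a `replicate` column), with attributes `truth`
#'   and `noise`.
#' @export
generate_spheroid_dataset <- function(scenario = spheroid_scenario(),
                                      concentrations = c(0, 5, 10),
                                      times = c(0, 1, 2, 3, 6, 24, 48, 72),
                                      replicates = 1,
                                      noise = noise_model("none")) {
  stopifnot(inherits(scenario, "tcm_scenario"), inherits(noise, "noise_model"))
  if (any(concentrations < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  out <- lapply(seq_along(concentrations), function(gi) {
    conc <- concentrations[gi]
    sc <- scenario
    sc$exposure <- conc
    clean <- simulate_scenario(sc, times)$w
    reps <- lapply(seq_len(replicates), function(r) {
      vals <- apply_noise(clean, noise, stream = 1000L * gi + r)
      data.frame(time = times, value = vals, replicate = r)
    })
    df <- do.call(rbind, reps)
    df <- df[order(df$time, df$replicate), , drop = FALSE]
    series <- observation_series(df$time, df$value,
                                 group = if (conc == 0) "control" else paste0(conc, "uM"),
                                 exposure = conc)
    series$replicate <- df$replicate
    attr(series, "clean") <- clean
    series
  })
  names(out) <- vapply(out, function(s) s$group[1], character(1))
  attr(out, "truth") <- scenario
  attr(out, "noise") <- noise
  out
}

#' Write / read the observation CSV dialect
#'
#' Comma-separated, header row, '.' decimal, UTF-8; a leading comment line
#' records the time unit and a hash of the generating configuration for
#' provenance.
#'
#' @param series An [observation_series()] (or plain data.frame with `time`,
#'   `value`).
#' @param path File path.
#' @param time_unit `"days"` or `"hours"`.
#' @return `write_observations_csv` returns `path` invisibly;
#'   `read_observations_csv` returns an [observation_series()].
#' @export
write_observations_csv <- function(series, path, time_unit = "days") {
  hash <- rlang::hash(list(series$time, series$value, time_unit))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# coxtcm observations; time_unit=%s; config_hash=%s",
                     time_unit, hash), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  series <- observation_series(df$time, df$value,
                               group = if ("group" %in% names(df)) df$group[1] else NULL)
  if ("replicate" %in% names(df)) series$replicate <- df$replicate
  series
}
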