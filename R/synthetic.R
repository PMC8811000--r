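# Synthetic microbalance recordings: forward model -> uptake mass -> inverse
# buoyancy map -> regular sampling + drift + i.i.d. Gaussian reading noise.
# Every downstream stage (correction, reduction, slope and permeability fits)
# is testable end-to-end without any experimental download.

#' Measurement-noise model for synthetic recordings
#'
#' Additive i.i.d. Gaussian noise on each mass reading plus an optional linear
#' baseline drift. The 5 mg default standard deviation is a plausible figure
#' for a microbalance carrying a ~100 g sample.
#'
#' @param sigma_mass Standard deviation of the reading noise (kg).
#' @param drift_rate Linear baseline drift (kg s\eqn{^{-1}}).
#' @param sampling_interval Sampling interval (s).
#' @return A `wi_noise_model`.
#' @export
noise_model <- function(sigma_mass = 5e-6, drift_rate = 0, sampling_interval = 10) {
  assert_scalar_number(sigma_mass, "sigma_mass")
  if (sigma_mass < 0) abort_invalid("sigma_mass: must be >= 0")
  assert_scalar_number(drift_rate, "drift_rate")
  assert_scalar_number(sampling_interval, "sampling_interval")
  if (sampling_interval <= 0) abort_invalid("sampling_interval: must be > 0")
  structure(list(sigma_mass = sigma_mass, drift_rate = drift_rate,
                 sampling_interval = sampling_interval),
            class = "wi_noise_model")
}

#' Study scenarios
#'
#' The four 1D simulation scenarios (oil in poplar vessels, oil in spruce
#' latewood, water in latewood, water in a generic fibre tissue) plus the 2D
#' dual-scale water-in-spruce case, wired to the built-in fluid/tissue presets
#' and the default sample geometry (100 mm length, 8e-4 m\eqn{^2} section,
#' 4 mm ring width).
#'
#' @return A tibble with one row per scenario: `label`, `model` ("1d"/"2d")
#'   and list-columns `fluid`, `tissue`, `cross_section`, `geometry`.
#' @export
#' @examples
#' scenario_presets()$label
scenario_presets <- function() {
  fl <- builtin_fluids()
  ts <- builtin_tissues()
  geo <- sample_geometry()
  tibble::tibble(
    label = c("oil_poplar_vessels", "oil_spruce_latewood", "water_latewood",
              "water_fibers", "water_spruce_2d"),
    model = c("1d", "1d", "1d", "1d", "2d"),
    fluid = list(fl$silicone_oil, fl$silicone_oil, fl$water, fl$water, fl$water),
    tissue = list(ts$vessels, ts$latewood, ts$latewood, ts$fibers, ts$latewood),
    cross_section = list(NULL, NULL, NULL, NULL, ts$cross_section),
    geometry = list(geo, geo, geo, geo, geo)
  )
}

as_scenario <- function(scenario) {
  if (is.character(scenario) && length(scenario) == 1L) {
    presets <- scenario_presets()
    if (!scenario %in% presets$label) {
      abort_invalid(sprintf("unknown scenario '%s' (available: %s)",
                            scenario, paste(presets$label, collapse = ", ")))
    }
    scenario <- presets[presets$label == scenario, ]
  }
  if (!is.data.frame(scenario) || nrow(scenario) != 1L) {
    abort_invalid("scenario: must be a label or a one-row scenario tibble")
  }
  list(label = scenario$label, model = scenario$model,
       fluid = scenario$fluid[[1]], tissue = scenario$tissue[[1]],
       cross_section = scenario$cross_section[[1]],
       geometry = scenario$geometry[[1]])
}

scenario_heq <- function(sc, times, settings = numerical_settings()) {
  if (identical(sc$model, "2d")) {
    res <- run_2d(sc$fluid, sc$tissue, sc$cross_section, sc$geometry, settings,
                  t_end = max(times))
    approx(res$curve$time_s, res$curve$h_eq_m, xout = times, rule = 2,
           ties = "ordered")$y
  } else {
    analytic_heq_at(times, sc$fluid, sc$tissue, sc$geometry, settings$gravity)
  }
}

#' Generate a synthetic microbalance recording
#'
#' Runs the scenario's forward model, converts the equivalent height to an
#' uptake mass `u(t) = rho S h_eq(t)`, applies the inverse buoyancy map
#' `m_raw = u A_c/(A_c - S)`, samples at the noise model's interval, and adds
#' drift and seeded Gaussian reading noise. Bit-identical for a given
#' (scenario, noise, `t_end`, seed).
#'
#' @param scenario A label from [scenario_presets()] or a one-row scenario.
#' @param noise A [noise_model()].
#' @param t_end Recording duration (s).
#' @param seed Integer seed for the reading noise.
#' @param container_ratio Container-to-sample cross-section ratio \eqn{A_c/S}.
#' @param settings A [numerical_settings()] forwarded to the forward model.
#' @return A [balance_series()].
#' @export
generate_balance_series <- function(scenario, noise = noise_model(), t_end, seed,
                                    container_ratio = 50,
                                    settings = numerical_settings()) {
  assert_scalar_number(t_end, "t_end")
  if (t_end <= 0) abort_invalid("t_end: must be > 0")
  assert_scalar_number(seed, "seed")
  sc <- as_scenario(scenario)
  S <- cross_section_area(sc$geometry)
  A_c <- container_ratio * S
  times <- seq(0, t_end, by = noise$sampling_interval)
  heq <- scenario_heq(sc, times, settings)
  u <- sc$fluid$density * S * heq
  m_raw <- u * if (is.infinite(A_c)) 1 else A_c / (A_c - S)
  m_raw <- m_raw + noise$drift_rate * times
  if (noise$sigma_mass > 0) {
    m_raw <- m_raw + withr::with_seed(as.integer(seed),
                                      rnorm(length(times), 0, noise$sigma_mass))
  }
  balance_series(times, m_raw, A_c, S, sc$fluid)
}

#' Permeability-recovery experiment
#'
#' For each replicate: generate a synthetic recording, reduce it to
#' equivalent-height kinetics, and refit the tissue permeability with
#' [fit_permeability()]. Reports the distribution of relative errors against
#' the generating value — the end-to-end accuracy of the whole pipeline under
#' the stated noise.
#'
#' @inheritParams generate_balance_series
#' @param n_replicates Number of replicates (\eqn{\ge 1}).
#' @param t_end Recording duration (s); defaults to 1.2 times the scenario's
#'   closed-form time to reach the sample top.
#' @return A `wi_recovery_table` tibble: `replicate`, `true_permeability`,
#'   `estimated_permeability`, `relative_error`.
#' @export
recovery_experiment <- function(scenario, noise = noise_model(), n_replicates, seed,
                                t_end = NULL, container_ratio = 50,
                                settings = numerical_settings()) {
  assert_scalar_number(n_replicates, "n_replicates")
  if (n_replicates < 1) abort("n_replicates must be >= 1", class = "wi_precondition")
  sc <- as_scenario(scenario)
  if (identical(sc$model, "2d")) {
    abort_invalid("recovery_experiment fits the 1D closed form; use a 1D scenario")
  }
  if (is.null(t_end)) {
    h_ref <- min(sc$geometry$length,
                 0.95 * max_height(sc$fluid, sc$tissue, settings$gravity))
    t_end <- 1.2 * analytic_time(h_ref, sc$fluid, sc$tissue, settings$gravity)
  }
  true_K <- sc$tissue$permeability
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    series <- generate_balance_series(scenario, noise, t_end,
                                      seed = as.integer(seed) + r - 1L,
                                      container_ratio = container_ratio,
                                      settings = settings)
    fit <- fit_permeability(reduce_kinetics(series), sc$fluid, sc$tissue,
                            sc$geometry, settings$gravity)
    tibble::tibble(replicate = r, true_permeability = true_K,
                   estimated_permeability = fit$permeability,
                   relative_error = abs(fit$permeability - true_K) / true_K)
  }) -> out
  class(out) <- c("wi_recovery_table", class(out))
  out
}
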