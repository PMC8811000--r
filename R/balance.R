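# Reduction of gravimetric microbalance recordings to equivalent-height
# kinetics. The balance reads the mass of liquid entering the hanging sample;
# as liquid leaves the container its level drops, reducing the buoyancy on the
# immersed sample mouth, so the raw reading overstates the uptake. With a
# container of cross-section A_c and a sample of cross-section S, a true
# uptake u drops the level by u/(rho (A_c - S)), changing the apparent mass by
# rho S * level drop, hence m_raw = u * A_c / (A_c - S) and the correction
# u = m_raw (A_c - S)/A_c. The corrected uptake converts to the equivalent
# height of rise h_eq = dm / (rho S).

#' Construct a microbalance series
#'
#' @param times Sampling times (s), strictly increasing.
#' @param mass_raw Raw recorded uptake (kg).
#' @param container_cross_section Container cross-section \eqn{A_c} (m\eqn{^2});
#'   may be `Inf` (no level drop). Must exceed the sample cross-section.
#' @param sample_cross_section Sample cross-section \eqn{S} (m\eqn{^2}).
#' @param fluid A [fluid()] object (its density converts mass to height).
#' @return A `wi_balance_series` tibble with columns `time_s`, `mass_raw_kg`
#'   and the metadata as attributes.
#' @export
balance_series <- function(times, mass_raw, container_cross_section,
                           sample_cross_section, fluid) {
  if (length(times) != length(mass_raw)) {
    abort_invalid("times and mass_raw must have equal length")
  }
  if (length(times) && any(diff(times) <= 0)) {
    abort_invalid("times: must be strictly increasing")
  }
  assert_scalar_number(sample_cross_section, "sample_cross_section")
  if (!(is.numeric(container_cross_section) && length(container_cross_section) == 1L)) {
    abort_invalid("container_cross_section: must be a single number")
  }
  if (sample_cross_section <= 0 || container_cross_section <= sample_cross_section) {
    abort_invalid("cross-sections must satisfy container > sample > 0")
  }
  assert_valid_fluid(fluid)
  out <- tibble::new_tibble(list(time_s = as.numeric(times),
                                 mass_raw_kg = as.numeric(mass_raw)),
                            class = "wi_balance_series")
  attr(out, "container_cross_section") <- container_cross_section
  attr(out, "sample_cross_section") <- sample_cross_section
  attr(out, "fluid") <- fluid
  out
}

series_meta <- function(series) {
  list(A_c = attr(series, "container_cross_section"),
       S = attr(series, "sample_cross_section"),
       fluid = attr(series, "fluid"))
}

#' Buoyancy-correct a microbalance series
#'
#' Applies the level-drop closure `u = m_raw (A_c - S)/A_c` (see the module
#' notes above): the correction is linear and contractive, approaching the
#' identity as the container grows.
#'
#' @param series A [balance_series()].
#' @return The series with a `mass_corr_kg` column added.
#' @export
buoyancy_correct <- function(series) {
  meta <- series_meta(series)
  if (is.null(meta$A_c)) abort_invalid("series: missing balance metadata; use balance_series()")
  if (meta$A_c <= meta$S) abort_invalid("container cross-section must exceed sample cross-section")
  factor <- if (is.infinite(meta$A_c)) 1 else (meta$A_c - meta$S) / meta$A_c
  dplyr::mutate(series, mass_corr_kg = .data$mass_raw_kg * factor)
}

#' Reduce a balance series to equivalent-height kinetics
#'
#' Buoyancy-corrects (if not already done) and converts the corrected uptake
#' to the equivalent height of rise \eqn{h_{eq} = \Delta m/(\rho S)}.
#'
#' @param series A [balance_series()], corrected or raw.
#' @return A `wi_reduced_kinetics` tibble with columns `time_s`, `sqrt_time`,
#'   `mass_corr_kg`, `h_eq_m`.
#' @export
#' @examples
#' w <- builtin_fluids()$water
#' s <- balance_series(c(10, 20, 30), c(1, 2, 3) * 1e-4, 0.04, 8e-4, w)
#' reduce_kinetics(s)
reduce_kinetics <- function(series) {
  meta <- series_meta(series)
  if (!"mass_corr_kg" %in% names(series)) series <- buoyancy_correct(series)
  out <- tibble::new_tibble(
    list(time_s = series$time_s,
         sqrt_time = sqrt(series$time_s),
         mass_corr_kg = series$mass_corr_kg,
         h_eq_m = series$mass_corr_kg / (meta$fluid$density * meta$S)),
    class = "wi_reduced_kinetics")
  attr(out, "container_cross_section") <- meta$A_c
  attr(out, "sample_cross_section") <- meta$S
  attr(out, "fluid") <- meta$fluid
  out
}

#' Square-root-of-time slope of reduced kinetics
#'
#' Ordinary least squares of `h_eq` on `sqrt(t)` within a time window; the
#' early Washburn regime plots as a straight line on this scale.
#'
#' @param kinetics A `wi_reduced_kinetics` tibble (or any tibble with
#'   `time_s`, `sqrt_time`, `h_eq_m`).
#' @param window Time interval `c(t0, t1)` (s) to fit within; defaults to the
#'   full range. At least 3 samples are required.
#' @return A `wi_sqrt_fit` object; see [tidy()] and [glance()] methods.
#' @export
sqrt_time_slope <- function(kinetics, window = range(kinetics$time_s)) {
  sub <- dplyr::filter(kinetics, .data$time_s >= window[1], .data$time_s <= window[2])
  if (nrow(sub) < 3L) {
    abort("need at least 3 samples inside the window", class = "wi_insufficient_data")
  }
  fit <- lm(h_eq_m ~ sqrt_time, data = sub)
  res <- stats::residuals(fit)
  structure(
    list(slope = unname(coef(fit)["sqrt_time"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         rms = sqrt(mean(res^2)),
         n = nrow(sub), window = window, model = fit),
    class = "wi_sqrt_fit"
  )
}

#' @export
print.wi_sqrt_fit <- function(x, ...) {
  cat(sprintf("<sqrt-time fit>  slope = %.4g m/sqrt(s), intercept = %.4g m, RMS = %.3g m (n = %d)\n",
              x$slope, x$intercept, x$rms, x$n))
  invisible(x)
}

#' Fit a longitudinal permeability to reduced kinetics
#'
#' One-parameter least squares of the closed-form Washburn curve against the
#' data: all parameters except the tissue permeability are held fixed and the
#' RMSE between model and measured equivalent heights is minimised over
#' `log10(K)` on a bracket of `[1e-20, 1e-8]` m\eqn{^2}.
#'
#' @param kinetics A `wi_reduced_kinetics` tibble.
#' @param fluid A [fluid()].
#' @param tissue A [tissue()] whose permeability plays the role of the unknown
#'   (its stored value is ignored).
#' @param geometry A [sample_geometry()] (length cap).
#' @param gravity Gravitational acceleration (m s\eqn{^{-2}}).
#' @param interval Permeability bracket (m\eqn{^2}).
#' @return A `wi_permeability_fit` with elements `permeability`, `rmse`, `n`.
#' @export
fit_permeability <- function(kinetics, fluid, tissue, geometry = sample_geometry(),
                             gravity = 9.81, interval = c(1e-20, 1e-8)) {
  if (!nrow(kinetics)) abort("kinetics is empty", class = "wi_degenerate_data")
  if (diff(range(kinetics$h_eq_m)) == 0) {
    abort("kinetics is constant; permeability is unidentifiable",
          class = "wi_degenerate_data")
  }
  objective <- function(log10K) {
    tis <- tissue
    tis$permeability <- 10^log10K
    pred <- analytic_heq_at(kinetics$time_s, fluid, tis, geometry, gravity)
    sqrt(mean((pred - kinetics$h_eq_m)^2))
  }
  opt <- optimize(objective, interval = log10(interval), tol = 1e-6)
  structure(
    list(permeability = 10^opt$minimum, rmse = opt$objective, n = nrow(kinetics),
         fluid = fluid$name, tissue = tissue$name),
    class = "wi_permeability_fit"
  )
}

#' @export
print.wi_permeability_fit <- function(x, ...) {
  cat(sprintf("<permeability fit>  K = %.4g m^2 (RMSE = %.3g m, n = %d, %s in %s)\n",
              x$permeability, x$rmse, x$n, x$fluid, x$tissue))
  invisible(x)
}

#' RMSE between a model curve and reduced kinetics
#'
#' Interpolates the model equivalent height (linearly in time) to the data
#' times and returns the root-mean-square difference. The model curve must
#' span the data window.
#'
#' @param curve An `imbibition_curve` (columns `time_s`, `h_eq_m`).
#' @param kinetics A `wi_reduced_kinetics` tibble.
#' @return RMSE (m).
#' @export
model_vs_data_rmse <- function(curve, kinetics) {
  tol <- 1e-9 * max(abs(kinetics$time_s), 1)
  if (min(kinetics$time_s) < min(curve$time_s) - tol ||
      max(kinetics$time_s) > max(curve$time_s) + tol) {
    abort("model curve does not span the data window", class = "wi_no_overlap")
  }
  pred <- approx(curve$time_s, curve$h_eq_m, xout = kinetics$time_s,
                 rule = 2, ties = "ordered")$y
  sqrt(mean((pred - kinetics$h_eq_m)^2))
}

#' Read a raw microbalance recording
#'
#' Delimited text with columns `time_s` and `mass_g` (raw uptake in grams).
#'
#' @param path File to read.
#' @inheritParams balance_series
#' @return A [balance_series()].
#' @export
read_balance_series <- function(path, fluid, sample_cross_section,
                                container_cross_section) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "mass_g") %in% names(df))) {
    abort_invalid("balance file: expected columns time_s, mass_g")
  }
  balance_series(df$time_s, df$mass_g * 1e-3, container_cross_section,
                 sample_cross_section, fluid)
}

#' Write reduced kinetics as delimited text
#'
#' Columns `time_s`, `sqrt_time`, `mass_corr_g`, `h_eq_m`.
#'
#' @param kinetics A `wi_reduced_kinetics` tibble.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_reduced_kinetics <- function(kinetics, path) {
  out <- tibble::tibble(time_s = kinetics$time_s, sqrt_time = kinetics$sqrt_time,
                        mass_corr_g = kinetics$mass_corr_kg * 1e3,
                        h_eq_m = kinetics$h_eq_m)
  readr::write_csv(out, path)
  invisible(path)
}
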