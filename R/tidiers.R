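# broom-style tidiers for the fitted objects and solver results.

#' @exportS3Method generics::tidy
tidy.wi_sqrt_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "sqrt_time_slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @exportS3Method generics::glance
glance.wi_sqrt_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = summary(x$model)$r.squared,
    rms_residual_m = x$rms,
    nobs = x$n,
    window_start_s = x$window[1],
    window_end_s = x$window[2]
  )
}

#' @exportS3Method generics::tidy
tidy.wi_permeability_fit <- function(x, ...) {
  tibble::tibble(term = "permeability", estimate = x$permeability)
}

#' @exportS3Method generics::glance
glance.wi_permeability_fit <- function(x, ...) {
  tibble::tibble(permeability_m2 = x$permeability, rmse_m = x$rmse, nobs = x$n,
                 fluid = x$fluid, tissue = x$tissue)
}

#' @exportS3Method generics::glance
glance.washburn2d_result <- function(x, ...) {
  cv <- x$curve
  t_cap <- if (any(cv$capped)) min(cv$time_s[cv$capped]) else NA_real_
  cons <- x$conservation
  ok <- cons$stored_m3 > 0
  max_err <- max(abs(cons$inflow_m3[ok] - cons$stored_m3[ok]) / cons$stored_m3[ok])
  tibble::tibble(
    t_final_s = x$state$time,
    h_lw_final_m = x$state$h_lw,
    h_eq_final_m = equivalent_height_2d(x$state, x$latewood, x$cross_section),
    capped = x$state$capped,
    time_to_cap_s = t_cap,
    max_conservation_error = max_err
  )
}

#' @exportS3Method generics::glance
glance.wi_recovery_table <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x),
    median_relative_error = stats::median(x$relative_error),
    max_relative_error = max(x$relative_error)
  )
}
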