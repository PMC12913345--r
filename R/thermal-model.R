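#' Per-temperature development rates for a life stage
#'
#' Computes the temperature-specific development rate of a stage as the
#' reciprocal of the mean development time in days (1/d) among the
#' individuals that completed the stage. Temperatures where no individual
#' completed the stage (e.g. lethal extremes) are excluded, which is why
#' different stages can span different temperature ranges.
#'
#' @param records Cohort tibble (see [simulate_cohort()]).
#' @param stage `"egg"`, `"larva"`, `"pupa"`, or `"egg_adult"` for the
#'   full egg-to-adult development of emerged individuals.
#' @param per_individual If `TRUE`, the rate is the mean of individual
#'   reciprocal durations instead of the reciprocal of the mean duration.
#' @return A tibble `temperature`, `rate` (1/day), `n`, `stage`.
#' @examples
#' cohort <- simulate_cohort(species_config("P_nasuta", 50), seed = 1)
#' development_rates(cohort, "egg")
#' @export
development_rates <- function(records, stage, per_individual = FALSE) {
  stage <- match.arg(stage, c(STAGES[1:3], "egg_adult"))
  if (stage == "egg_adult") {
    done <- is.na(records$died_in_stage)
    dur <- records$egg_d + records$larva_d + records$pupa_d
  } else {
    done <- completed_stage(records, stage)
    dur <- records[[paste0(stage, "_d")]]
  }
  d <- tibble(temperature = records$temperature_C,
              duration = dur)[done & !is.na(dur), ]
  if (nrow(d) == 0) {
    abort(paste0("stage '", stage, "' was never completed at any temperature"))
  }
  d %>%
    group_by(.data$temperature) %>%
    summarise(
      rate = if (per_individual) mean(1 / .data$duration)
             else 1 / mean(.data$duration),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(stage = stage)
}

#' Fit the linear development-rate model
#'
#' Ordinary least squares fit of `rate = a + b * T` to per-temperature
#' development rates: the classical degree-day model in which the rate of
#' development increases linearly with temperature over the favourable
#' range. The lower developmental threshold `t = -a/b` (the temperature
#' at which the fitted rate extrapolates to zero) and the thermal
#' constant `K = 1/b` (degree-days needed to complete the stage) are
#' derived from the coefficients when the slope is positive.
#'
#' @param points A tibble with columns `temperature` and `rate`, as from
#'   [development_rates()]; a `stage` column is carried through if present.
#' @return An object of class `thermal_fit` with elements `a`, `b`,
#'   `r_squared`, `t`, `K`, `stage`, `temperature_range`, `n_points`,
#'   `points`.
#' @examples
#' pts <- tibble::tibble(temperature = c(16, 22, 28),
#'                       rate = -0.1 + 0.01 * c(16, 22, 28))
#' fit <- fit_thermal(pts)
#' glance(fit)
#' @export
fit_thermal <- function(points) {
  stopifnot(all(c("temperature", "rate") %in% names(points)))
  if (nrow(points) < 2) abort("need at least 2 rate points")
  if (length(unique(points$temperature)) < 2) {
    abort("need at least 2 distinct temperatures")
  }
  m <- lm(rate ~ temperature, data = points)
  a <- unname(coef(m)[1])
  b <- unname(coef(m)[2])
  sse <- sum(stats::resid(m)^2)
  sst <- sum((points$rate - mean(points$rate))^2)
  r2 <- if (sse <= 1e-30) 1 else 1 - sse / sst
  structure(
    list(
      a = a,
      b = b,
      r_squared = r2,
      t = if (b > 0) -a / b else NA_real_,
      K = if (b > 0) 1 / b else NA_real_,
      stage = if ("stage" %in% names(points)) points$stage[1] else NA_character_,
      temperature_range = range(points$temperature),
      n_points = nrow(points),
      points = as_tibble(points[c("temperature", "rate")])
    ),
    class = "thermal_fit"
  )
}

#' Lower developmental threshold and thermal constant
#'
#' Derives the lower developmental threshold `t = -a/b` (degrees C) and
#' the thermal constant `K = 1/b` (degree-days) from a fitted linear
#' development-rate model or from its coefficients directly.
#'
#' @param object A `thermal_fit`, or the intercept `a` (1/day).
#' @param b Slope (1/(day * degree C)); only when `object` is numeric.
#' @return A one-row tibble `t`, `K`.
#' @examples
#' thermal_params(-0.0949, 0.0062)  # t = 15.3 at 1 dp
#' @export
thermal_params <- function(object, b = NULL) {
  if (inherits(object, "thermal_fit")) {
    a <- object$a
    b <- object$b
  } else {
    a <- object
    if (is.null(b)) abort("supply the slope b")
  }
  if (!is.finite(b) || b <= 0) {
    abort("slope must be positive for a biologically valid threshold")
  }
  tibble(t = -a / b, K = 1 / b)
}

#' Predicted stage duration at a temperature
#'
#' Inverts the fitted linear rate model: `duration = 1 / (a + b * T)`
#' days. Undefined at or below the lower threshold, where the predicted
#' rate is non-positive.
#'
#' @param fit A `thermal_fit`.
#' @param temperature Temperature(s) in degrees C.
#' @return Numeric vector of predicted durations (days).
#' @export
predict_duration <- function(fit, temperature) {
  stopifnot(inherits(fit, "thermal_fit"))
  r <- fit$a + fit$b * temperature
  if (any(r <= 1e-10)) {
    abort("temperature at or below the developmental threshold: infinite duration")
  }
  1 / r
}

#' Table of thermal parameters per stage
#'
#' Fits the linear development-rate model for each immature stage and for
#' total egg-to-adult development and tabulates coefficients, fit quality
#' and derived thermal parameters. With `rounded = TRUE` the table uses
#' the conventional reporting precision (coefficients 4 dp, threshold 1
#' dp, thermal constant whole degree-days); computation is always done
#' unrounded.
#'
#' @param records Cohort tibble.
#' @param species Optional species label for the output.
#' @param rounded Round for reporting (default `FALSE`).
#' @return A tibble `species`, `stage`, `T_min`, `T_max`, `a`, `b`, `R2`,
#'   `t`, `K`.
#' @export
thermal_table <- function(records, species = NA_character_, rounded = FALSE) {
  stages <- c(STAGES[1:3], "egg_adult")
  rows <- purrr::map(stages, function(s) {
    pts <- tryCatch(development_rates(records, s), error = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 2) return(NULL)
    fit <- fit_thermal(pts)
    tibble(
      species = species, stage = s,
      T_min = fit$temperature_range[1], T_max = fit$temperature_range[2],
      a = fit$a, b = fit$b, R2 = fit$r_squared, t = fit$t, K = fit$K
    )
  })
  out <- bind_rows(rows)
  if (rounded && nrow(out) > 0) {
    out <- out %>%
      mutate(a = round(.data$a, 4), b = round(.data$b, 4),
             R2 = round(.data$R2, 2), t = round(.data$t, 1),
             K = round(.data$K))
  }
  out
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat("Linear development-rate fit",
      if (!is.na(x$stage)) paste0("(", x$stage, ")"), "\n")
  cat(sprintf("  rate = %.4f + %.4f * T over %g-%g degrees C (%d points)\n",
              x$a, x$b, x$temperature_range[1], x$temperature_range[2],
              x$n_points))
  cat(sprintf("  R^2 = %.3f; threshold t = %.1f degrees C; K = %.0f DD\n",
              x$r_squared, x$t, x$K))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.thermal_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.thermal_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, t = x$t, K = x$K,
         n_points = x$n_points,
         T_min = x$temperature_range[1], T_max = x$temperature_range[2])
}

#' @describeIn fit_thermal Diagnostic plot: observed rate points, the
#'   fitted line and the lower developmental threshold.
#' @param object,x A `thermal_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.thermal_fit <- function(object, ...) {
  pts <- object$points
  xmax <- max(pts$temperature)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$temperature, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$a, slope = object$b,
                         linetype = 2) +
    ggplot2::geom_vline(xintercept = object$t, colour = "grey50") +
    ggplot2::annotate("text", x = object$t, y = max(pts$rate),
                      label = sprintf("t = %.1f", object$t), hjust = -0.1) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Development rate (1/day)",
      title = if (!is.na(object$stage)) {
        paste("Development rate:", object$stage)
      } else {
        "Development rate"
      },
      subtitle = sprintf("K = %.0f degree-days, R² = %.2f",
                         object$K, object$r_squared)
    ) +
    ggplot2::expand_limits(x = c(object$t, xmax), y = 0) +
    ggplot2::theme_minimal()
}
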