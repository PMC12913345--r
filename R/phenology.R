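#' Number of generations from accumulated degree-days
#'
#' The degree-day generation model: `NG = (Tm - t) * days / K`, the
#' number of generations completed in `days` days at mean temperature
#' `Tm` given a lower developmental threshold `t` and a thermal constant
#' `K` degree-days per generation. Accumulation below the threshold is
#' clamped to zero.
#'
#' @param Tm Mean temperature (degrees C); vectorized.
#' @param t Lower developmental threshold (degrees C).
#' @param K Thermal constant (degree-days); must be positive.
#' @param days Number of days (month length or 365 for a year).
#' @return Number of generations (dimensionless, >= 0).
#' @examples
#' generations(17, t = 11.5, K = 366, days = 31)   # 0.47 at 2 dp
#' generations(23, t = 14.9, K = 344, days = 365)  # 8.59 at 2 dp
#' @export
generations <- function(Tm, t, K, days) {
  if (any(K <= 0)) abort("thermal constant K must be positive")
  if (any(days < 1)) abort("days must be >= 1")
  pmax(0, (Tm - t) * days / K)
}

#' Temperature isotherms of the Colombian coffee region
#'
#' The four mean-temperature bands used to stratify the coffee-growing
#' region: at or below 17 degrees C, 17-20, 20-23, and above 23. Bounded
#' bands are evaluated at both boundary temperatures (`tm_low`,
#' `tm_high`), producing the range of generation numbers across the
#' band; the open bands use their single boundary as representative
#' temperature.
#'
#' @return A tibble `label`, `t_low`, `t_high` (band bounds, `NA` when
#'   open), `tm_low`, `tm_high` (representative temperatures).
#' @export
default_isotherms <- function() {
  tibble(
    label = c("<=17", ">17 and <=20", ">20 and <=23", ">23"),
    t_low = c(NA, 17, 20, 23),
    t_high = c(17, 20, 23, NA),
    tm_low = c(17, 17, 20, 23),
    tm_high = c(17, 20, 23, 23)
  )
}

#' Calendar used for monthly degree-day accumulation
#'
#' A 365-day civil year (February = 28 days).
#'
#' @return A tibble `month`, `days`.
#' @export
default_calendar <- function() {
  tibble(
    month = month.name,
    days = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  )
}

validate_isotherms <- function(isotherms) {
  iso <- as_tibble(isotherms)
  if (!"tm_low" %in% names(iso) && "representative_Tm" %in% names(iso)) {
    iso$tm_low <- iso$representative_Tm
    iso$tm_high <- iso$representative_Tm
  }
  req <- c("label", "t_low", "t_high", "tm_low", "tm_high")
  if (!all(req %in% names(iso))) {
    abort(paste("isotherms need columns:", paste(req, collapse = ", ")))
  }
  lo <- ifelse(is.na(iso$t_low), -Inf, iso$t_low)
  hi <- ifelse(is.na(iso$t_high), Inf, iso$t_high)
  if (any(lo >= hi)) abort("each isotherm needs t_low < t_high")
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (nrow(iso) > 1) {
    gaps <- hi[-length(hi)] != lo[-1]
    if (any(hi[-length(hi)] > lo[-1])) abort("isotherm ranges overlap")
    if (any(gaps)) abort("isotherm ranges leave gaps")
  }
  iso
}

#' Assign a temperature to its isotherm
#'
#' Bands are left-open and right-closed: a temperature on a boundary
#' belongs to the cooler band (`Tm = 17` falls in `<=17`).
#'
#' @param Tm Mean temperature(s), degrees C.
#' @param isotherms Isotherm table (see [default_isotherms()]).
#' @return Character vector of band labels.
#' @examples
#' classify_isotherm(c(17, 17.1, 25))
#' @export
classify_isotherm <- function(Tm, isotherms = default_isotherms()) {
  iso <- validate_isotherms(isotherms)
  lo <- ifelse(is.na(iso$t_low), -Inf, iso$t_low)
  hi <- ifelse(is.na(iso$t_high), Inf, iso$t_high)
  vapply(Tm, function(x) {
    hit <- which(x > lo & x <= hi)
    if (length(hit) != 1) abort(paste("no unique isotherm for Tm =", x))
    iso$label[hit]
  }, character(1))
}

#' Monthly and annual generation numbers per isotherm
#'
#' Evaluates the degree-day model for every (species, isotherm, month)
#' cell at the isotherm's representative temperatures, plus an annual row
#' computed over the full calendar from unrounded monthly inputs (so the
#' annual value equals the sum of the unrounded monthly values). Bounded
#' isotherms report the range (`ng_low`, `ng_high`) between their two
#' boundary temperatures; open isotherms report a single value in both
#' columns.
#'
#' @param params A tibble with columns `species`, `t` (lower threshold,
#'   degrees C) and `K` (thermal constant, degree-days), one row per
#'   species; [thermal_table()] output (egg-adult row) works directly.
#' @param isotherms Isotherm table (see [default_isotherms()]).
#' @param calendar Calendar table (see [default_calendar()]).
#' @param rounded Round the generation numbers to 2 decimals for display.
#' @return A tibble `species`, `isotherm`, `month` (month name or
#'   `"annual"`), `days`, `ng_low`, `ng_high`.
#' @examples
#' pars <- tibble::tibble(species = c("P_nasuta", "P_coffea"),
#'                        t = c(11.5, 14.9), K = c(366, 344))
#' gt <- generation_table(pars, rounded = TRUE)
#' dplyr::filter(gt, month == "annual")
#' @export
generation_table <- function(params, isotherms = default_isotherms(),
                             calendar = default_calendar(),
                             rounded = FALSE) {
  iso <- validate_isotherms(isotherms)
  stopifnot(all(c("species", "t", "K") %in% names(params)))
  cal <- bind_rows(as_tibble(calendar),
                   tibble(month = "annual", days = sum(calendar$days)))
  grid <- tidyr::crossing(
    params[c("species", "t", "K")],
    iso[c("label", "tm_low", "tm_high")],
    cal
  ) %>%
    mutate(
      ng_low = generations(.data$tm_low, .data$t, .data$K, .data$days),
      ng_high = generations(.data$tm_high, .data$t, .data$K, .data$days)
    ) %>%
    rename(isotherm = "label") %>%
    select("species", "isotherm", "month", "days", "ng_low", "ng_high")
  grid <- grid %>%
    mutate(month = factor(.data$month, levels = c(month.name, "annual"))) %>%
    arrange(.data$species, .data$month) %>%
    mutate(month = as.character(.data$month))
  if (rounded) {
    grid <- mutate(grid, ng_low = round(.data$ng_low, 2),
                   ng_high = round(.data$ng_high, 2))
  }
  grid
}

#' Plot monthly generation numbers per isotherm
#'
#' @param table Output of [generation_table()] (unrounded).
#' @return A ggplot object.
#' @export
plot_generations <- function(table) {
  monthly <- table %>%
    filter(.data$month != "annual") %>%
    mutate(month = factor(.data$month, levels = month.name))
  ggplot2::ggplot(monthly,
                  ggplot2::aes(x = .data$month, group = .data$isotherm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ng_low,
                                      ymax = .data$ng_high,
                                      fill = .data$isotherm), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ng_high,
                                    colour = .data$isotherm)) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "Generations per month",
                  fill = "Isotherm (°C)", colour = "Isotherm (°C)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
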