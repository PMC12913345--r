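#' Default cohort configurations for the two parasitoid species
#'
#' Builds the simulation configuration that reproduces the design of the
#' constant-temperature assays for *Prorops nasuta* (larval-pupal
#' ectoparasitoid of the coffee berry borer) or *Phymastichus coffea*
#' (adult endoparasitoid): eight constant temperatures (16--35 degrees C),
#' stage-specific survival, temperature-dependent sex ratio, adult
#' longevity and per-female fecundity.
#'
#' Anchor values are the published ones: female proportions per
#' temperature (e.g. 0.96 at 16 degrees C for *P. nasuta*, about 0.52 at
#' all viable temperatures for *P. coffea*), total development time at the
#' extreme viable temperatures (64.8 d at 16 degrees C and 19 d at 30
#' degrees C for *P. nasuta*; 87.35 d at 19 degrees C and 32.78 d at 28
#' degrees C for *P. coffea*), peak fecundity at 25 degrees C (27 and 38
#' eggs/female respectively) and failure to develop at 32/35 degrees C
#' (and beyond the egg stage at 16 degrees C for *P. coffea*), encoded as
#' a zero survival probability at the stage where development halts.
#' Stage-level means at the remaining temperatures follow the linear
#' development-rate models fitted for each stage (see
#' [fit_thermal()]), with per-stage shares of the total taken from the
#' stage-level regressions.
#'
#' @param species `"P_nasuta"` or `"P_coffea"`.
#' @param n_per_temperature Number of individuals started per temperature.
#'   Defaults: 200 for *P. nasuta*, 150 for *P. coffea*.
#'
#' @return An object of class `cohort_config`: a list with elements
#'   `species`, `n_per_temperature`, `fecundity_dispersion` (negative
#'   binomial size), `observation_interval` (days between egg-count
#'   censuses: 15 for *P. nasuta*, whose host beans were dissected every
#'   15 days, 1 for *P. coffea*), `stages` (tibble: `temperature`,
#'   `stage`, `duration_mean`, `duration_sd`, `survival_prob`) and
#'   `adults` (tibble: `temperature`, `female_proportion`,
#'   `longevity_mean`, `longevity_sd`, `fecundity_mean`).
#'
#' @examples
#' cfg <- species_config("P_nasuta")
#' cfg$adults
#' @export
species_config <- function(species = c("P_nasuta", "P_coffea"),
                           n_per_temperature = NULL) {
  species <- match.arg(species)
  temps <- c(16, 19, 22, 25, 28, 30, 32, 35)

  if (species == "P_nasuta") {
    rate_coefs <- list(
      egg   = c(a = -0.2856, b = 0.0220),
      larva = c(a = -0.0532, b = 0.0054),
      pupa  = c(a = -0.0925, b = 0.0076)
    )
    total_anchor <- c(`16` = 64.8, `30` = 19)
    # egg-to-adult survival; decomposed as the 4th root per stage
    total_survival <- c(`16` = 0.45, `19` = 0.65, `22` = 0.82,
                        `25` = 0.85, `28` = 0.45, `30` = 0.40)
    survival <- purrr::map(
      setNames(as.character(temps), temps),
      function(tt) {
        if (tt %in% names(total_survival)) {
          rep(unname(total_survival[tt])^0.25, 4)
        } else if (tt == "32") {
          c(0.50, 0, 0, 0)  # development halts after the egg stage
        } else {
          c(0, 0, 0, 0)     # 35 C: all die as eggs
        }
      }
    )
    female_prop <- c(`16` = 0.96, `19` = 0.83, `22` = 0.62, `25` = 0.59,
                     `28` = 0.36, `30` = 0.21, `32` = 0.5, `35` = 0.5)
    longevity <- c(`16` = 40, `19` = 41, `22` = 41, `25` = 42,
                   `28` = 15, `30` = 8, `32` = 1, `35` = 1)
    fecundity <- c(`16` = 8, `19` = 12, `22` = 20, `25` = 27,
                   `28` = 10, `30` = 3, `32` = 0, `35` = 0)
    obs_interval <- 15
    n_default <- 200
  } else {
    rate_coefs <- list(
      egg   = c(a = -0.5222, b = 0.0343),
      larva = c(a = -0.0949, b = 0.0062),
      pupa  = c(a = -0.0907, b = 0.0063)
    )
    total_anchor <- c(`19` = 87.35, `28` = 32.78)
    survival <- list(
      `16` = c(0.75, 0, 0, 0),     # eggs hatch, larvae do not develop
      `19` = c(0.85, 0.85, 0.85, 0.62),
      `22` = c(0.90, 0.90, 0.90, 0.80),
      `25` = c(0.92, 0.92, 0.92, 0.87),
      `28` = c(0.90, 0.88, 0.88, 0.75),
      `30` = c(0.85, 0.80, 0.82, 0.63),
      `32` = c(0.70, 0.41, 0, 0),  # no pupal survival at 32 C
      `35` = c(0, 0, 0, 0)
    )
    female_prop <- c(`16` = 0.5, `19` = 0.51, `22` = 0.52, `25` = 0.52,
                     `28` = 0.52, `30` = 0.52, `32` = 0.5, `35` = 0.5)
    longevity <- c(`16` = 1.12, `19` = 4, `22` = 3.5, `25` = 3.5,
                   `28` = 3, `30` = 2.5, `32` = 1, `35` = 1)
    fecundity <- c(`16` = 4, `19` = 4, `22` = 25, `25` = 38,
                   `28` = 30, `30` = 20, `32` = 0, `35` = 0)
    obs_interval <- 1
    n_default <- 150
  }

  stage_pred <- function(stage, temp) {
    cf <- rate_coefs[[stage]]
    r <- cf[["a"]] + cf[["b"]] * temp
    if (r <= 0) return(NA_real_)
    1 / r
  }

  stages <- purrr::map_dfr(temps, function(temp) {
    preds <- vapply(c("egg", "larva", "pupa"), stage_pred, numeric(1),
                    temp = temp)
    # fall back to the nearest temperature with a positive predicted rate
    # (only matters for stages no individual can reach)
    if (anyNA(preds)) {
      for (s in names(preds)[is.na(preds)]) {
        ok <- vapply(temps, stage_pred, numeric(1), stage = s)
        preds[s] <- ok[which.min(abs(temps - temp) + ifelse(is.na(ok), Inf, 0))]
        if (is.na(preds[s])) preds[s] <- 30
      }
    }
    key <- as.character(temp)
    scale <- if (key %in% names(total_anchor)) {
      unname(total_anchor[key]) / sum(preds)
    } else {
      1
    }
    means <- c(preds * scale, unname(longevity[key]))
    tibble(
      temperature = temp,
      stage = STAGES,
      duration_mean = unname(means),
      duration_sd = 0.1 * unname(means),
      survival_prob = survival[[key]]
    )
  })

  adults <- tibble(
    temperature = temps,
    female_proportion = unname(female_prop[as.character(temps)]),
    longevity_mean = unname(longevity[as.character(temps)]),
    longevity_sd = 0.3 * unname(longevity[as.character(temps)]),
    fecundity_mean = unname(fecundity[as.character(temps)])
  )

  new_cohort_config(
    species = species,
    n_per_temperature = n_per_temperature %||% n_default,
    fecundity_dispersion = 3,
    observation_interval = obs_interval,
    stages = stages,
    adults = adults
  )
}

#' Construct and validate a cohort configuration
#'
#' @param species Free-text species label.
#' @param n_per_temperature Individuals per temperature (>= 0).
#' @param fecundity_dispersion Negative binomial size parameter (> 0).
#' @param observation_interval Days between egg-count censuses (>= 1).
#' @param stages Tibble with columns `temperature`, `stage`,
#'   `duration_mean`, `duration_sd`, `survival_prob`, one row per
#'   (temperature, stage) for the ordered stages egg, larva, pupa, adult.
#' @param adults Tibble with columns `temperature`, `female_proportion`,
#'   `longevity_mean`, `longevity_sd`, `fecundity_mean`.
#' @return A `cohort_config` object.
#' @export
new_cohort_config <- function(species, n_per_temperature,
                              fecundity_dispersion, observation_interval,
                              stages, adults) {
  cfg <- structure(
    list(
      species = species,
      n_per_temperature = n_per_temperature,
      fecundity_dispersion = fecundity_dispersion,
      observation_interval = observation_interval,
      stages = as_tibble(stages),
      adults = as_tibble(adults)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_per_temperature < 0) abort("n_per_temperature must be >= 0")
  if (cfg$fecundity_dispersion <= 0) abort("fecundity_dispersion must be > 0")
  if (cfg$observation_interval < 1) abort("observation_interval must be >= 1")
  st <- cfg$stages
  if (!all(c("temperature", "stage", "duration_mean", "duration_sd",
             "survival_prob") %in% names(st))) {
    abort("stages table is missing required columns")
  }
  if (any(st$duration_mean <= 0)) abort("duration_mean must be > 0")
  if (any(st$duration_sd < 0)) abort("duration_sd must be >= 0")
  if (any(st$survival_prob < 0 | st$survival_prob > 1)) {
    abort("survival_prob must lie in [0, 1]")
  }
  bad_order <- st %>%
    group_by(.data$temperature) %>%
    summarise(ok = identical(.data$stage, STAGES), .groups = "drop")
  if (!all(bad_order$ok)) {
    abort("each temperature needs the ordered stages egg, larva, pupa, adult")
  }
  ad <- cfg$adults
  if (!setequal(ad$temperature, unique(st$temperature))) {
    abort("adults and stages tables must cover the same temperatures")
  }
  if (any(ad$female_proportion < 0 | ad$female_proportion > 1)) {
    abort("female_proportion must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$species, "\n")
  cat("  temperatures:", paste(x$adults$temperature, collapse = ", "),
      "degrees C\n")
  cat("  n per temperature:", x$n_per_temperature, "\n")
  cat("  observation interval:", x$observation_interval, "day(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
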