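#' Simulate an individual-level cohort under constant temperatures
#'
#' Draws one life history per individual under the configured study design:
#' stage durations in whole days from a discretized gamma distribution
#' (shape from the configured mean/SD, floored at 1 day), sequential
#' Bernoulli survival through egg, larva and pupa, a final emergence
#' Bernoulli (the adult-stage survival probability), sex assigned to
#' emerged adults with the temperature's female proportion, adult
#' longevity from a discretized gamma, and total eggs per female from a
#' negative binomial with the configured mean and dispersion. Eggs are
#' spread over the female's adult life along a symmetric triangular age
#' profile and then censused on the configured observation interval.
#'
#' A given `(config, seed)` pair always reproduces the same cohort.
#'
#' @param config A [cohort_config][new_cohort_config] object.
#' @param seed Integer random seed.
#'
#' @return A tibble with one row per individual: `id`, `temperature_C`,
#'   `egg_d`, `larva_d`, `pupa_d` (days; `NA` beyond the stage of death),
#'   `died_in_stage` (`"egg"`, `"larva"`, `"pupa"`, `"adult"` for death at
#'   emergence, or `NA` for individuals that emerged), `sex` (`"female"`/
#'   `"male"`, `NA` before adulthood), `adult_longevity_d` and
#'   `egg_counts` (list-column of integer egg counts, one per observation
#'   interval of adult life; empty for males and pre-adult deaths).
#'
#' @examples
#' cohort <- simulate_cohort(species_config("P_nasuta"), seed = 1)
#' dplyr::count(cohort, temperature_C, died_in_stage)
#' @export
simulate_cohort <- function(config, seed) {
  validate_cohort_config(config)
  if (missing(seed) || !is.numeric(seed)) abort("an integer seed is required")
  set.seed(as.integer(seed))

  temps <- config$adults$temperature
  out <- purrr::map(temps, function(temp) {
    simulate_temperature(config, temp)
  })
  records <- bind_rows(out)
  if (nrow(records) > 0) records$id <- seq_len(nrow(records))
  records
}

simulate_temperature <- function(config, temp) {
  n <- config$n_per_temperature
  if (n == 0) return(empty_cohort())
  st <- config$stages[config$stages$temperature == temp, ]
  ad <- config$adults[config$adults$temperature == temp, ]

  dur <- vapply(STAGES[1:3], function(s) {
    row <- st[st$stage == s, ]
    draw_duration(n, row$duration_mean, row$duration_sd)
  }, numeric(n))
  dur <- matrix(dur, nrow = n,
                dimnames = list(NULL, STAGES[1:3]))

  surv_p <- setNames(st$survival_prob, st$stage)
  alive_through <- matrix(FALSE, n, 4, dimnames = list(NULL, STAGES))
  alive <- rep(TRUE, n)
  for (s in STAGES) {
    pass <- runif(n) < surv_p[[s]]
    alive <- alive & pass
    alive_through[, s] <- alive
  }
  died_in <- apply(alive_through, 1, function(z) {
    i <- which(!z)[1]
    if (is.na(i)) NA_character_ else STAGES[i]
  })
  emerged <- is.na(died_in)

  stage_idx <- match(died_in, STAGES)       # NA for emerged adults
  keep <- function(s_i) is.na(stage_idx) | stage_idx >= s_i
  egg_d   <- ifelse(keep(1), dur[, "egg"], NA_real_)
  larva_d <- ifelse(keep(2), dur[, "larva"], NA_real_)
  pupa_d  <- ifelse(keep(3), dur[, "pupa"], NA_real_)

  sex <- rep(NA_character_, n)
  sex[emerged] <- ifelse(runif(sum(emerged)) < ad$female_proportion,
                         "female", "male")

  longevity <- rep(NA_real_, n)
  longevity[emerged] <- draw_duration(sum(emerged), ad$longevity_mean,
                                      ad$longevity_sd)

  egg_counts <- rep(list(integer(0)), n)
  is_f <- !is.na(sex) & sex == "female"
  if (any(is_f)) {
    totals <- rnbinom(sum(is_f), size = config$fecundity_dispersion,
                      mu = ad$fecundity_mean)
    egg_counts[is_f] <- purrr::map2(
      totals, longevity[is_f],
      ~ allocate_eggs(.x, .y, config$observation_interval)
    )
  }

  tibble(
    id = NA_integer_,
    temperature_C = temp,
    egg_d = egg_d,
    larva_d = larva_d,
    pupa_d = pupa_d,
    died_in_stage = died_in,
    sex = sex,
    adult_longevity_d = longevity,
    egg_counts = egg_counts
  )
}

# Whole-day positive durations; a zero SD returns the configured mean
# exactly (degenerate, noise-free draws).
draw_duration <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  x <- rgamma(n, shape = shape, rate = shape / mean)
  pmax(1, round(x))
}

# Spread `total` eggs over `longevity` days of adult life with a symmetric
# triangular weight profile, then sum into observation intervals.
allocate_eggs <- function(total, longevity, interval) {
  days <- max(1L, as.integer(longevity))
  n_int <- as.integer(ceiling(days / interval))
  if (total == 0) return(integer(n_int))
  d <- seq_len(days)
  w <- pmin(d, days + 1 - d)
  per_day <- as.integer(rmultinom(1, total, w))
  idx <- ceiling(d / interval)
  as.integer(tapply(per_day, idx, sum))
}

empty_cohort <- function() {
  tibble(
    id = integer(0),
    temperature_C = numeric(0),
    egg_d = numeric(0),
    larva_d = numeric(0),
    pupa_d = numeric(0),
    died_in_stage = character(0),
    sex = character(0),
    adult_longevity_d = numeric(0),
    egg_counts = list()
  )
}

# TRUE where the individual completed the given immature stage
# (i.e. survived past it), FALSE otherwise.
completed_stage <- function(records, stage) {
  s_i <- match(stage, STAGES)
  death_i <- match(records$died_in_stage, STAGES)  # NA for emerged adults
  is.na(death_i) | death_i > s_i
}
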