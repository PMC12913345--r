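# Shared fixtures: all cohorts are generated in code at test time.

# A minimal single-temperature configuration with uniform stage settings.
single_temp_config <- function(temperature = 25, n = 100,
                               duration_means = c(3, 5, 4),
                               duration_sd_frac = 0.1,
                               survival = c(1, 1, 1, 1),
                               female_proportion = 0.5,
                               longevity_mean = 10, longevity_sd = 2,
                               fecundity_mean = 20, dispersion = 3,
                               observation_interval = 1) {
  means <- c(duration_means, longevity_mean)
  new_cohort_config(
    species = "synthetic",
    n_per_temperature = n,
    fecundity_dispersion = dispersion,
    observation_interval = observation_interval,
    stages = tibble::tibble(
      temperature = temperature,
      stage = c("egg", "larva", "pupa", "adult"),
      duration_mean = means,
      duration_sd = duration_sd_frac * means,
      survival_prob = survival
    ),
    adults = tibble::tibble(
      temperature = temperature,
      female_proportion = female_proportion,
      longevity_mean = longevity_mean,
      longevity_sd = longevity_sd,
      fecundity_mean = fecundity_mean
    )
  )
}

# Restrict a species configuration to a subset of temperatures.
subset_config <- function(cfg, temps) {
  cfg$stages <- dplyr::filter(cfg$stages, temperature %in% temps)
  cfg$adults <- dplyr::filter(cfg$adults, temperature %in% temps)
  cfg
}

# Hand-built two-individual cohort: one death in the egg stage on day 3,
# one female completing every stage and laying daily-counted eggs.
tiny_cohort <- function() {
  tibble::tibble(
    id = 1:2,
    temperature_C = 25,
    egg_d = c(3, 2),
    larva_d = c(NA, 3),
    pupa_d = c(NA, 2),
    died_in_stage = c("egg", NA),
    sex = c(NA, "female"),
    adult_longevity_d = c(NA, 4),
    egg_counts = list(integer(0), c(1L, 2L, 1L, 0L))
  )
}

# Random survival/fecundity schedule for solver cross-checks.
random_schedule <- function(n_ages = 30) {
  lx <- cumprod(c(1, runif(n_ages - 1, 0.85, 1)))
  mx <- ifelse(seq_len(n_ages) > 5, rexp(n_ages, rate = 2), 0)
  tibble::tibble(x = seq_len(n_ages) - 1, lx = lx, mx = mx)
}
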