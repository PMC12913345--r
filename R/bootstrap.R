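# Per-individual egg-age matrix (n x A): eggs attributed to each age of
# life. All demographic parameters of a resampled cohort are functions of
# the column means of a row-resample of this matrix, which makes the
# bootstrap a cheap matrix operation.
egg_age_matrix <- function(records, observation_interval = NULL) {
  interval <- observation_interval %||% infer_interval(records)
  tl <- cohort_timelines(records, interval)
  tl$eggs
}

params_from_phi <- function(phi, need_r) {
  R0 <- sum(phi)
  if (!need_r) return(c(R0 = R0, r = NA, lambda = NA, T_gen = NA, Dt = NA))
  if (R0 == 0) {
    return(c(R0 = 0, r = NA, lambda = NA, T_gen = NA, Dt = NA))
  }
  r <- solve_euler_lotka(seq_along(phi) - 1, phi)
  c(R0 = R0, r = r, lambda = exp(r),
    T_gen = if (r != 0) log(R0) / r else NA,
    Dt = if (r > 0) log(2) / r else NA)
}

#' Percentile-bootstrap confidence intervals for life-table parameters
#'
#' Resamples individuals with replacement, recomputes the demographic
#' parameters on every replicate, and reports 95% percentile intervals.
#' The lower bound for `R0` is clamped at zero (a net reproductive rate
#' cannot be negative). Replicates in which no resampled female
#' reproduced (`R0 = 0`) have no Euler-Lotka root; they are excluded from
#' the percentiles of `r`, `lambda`, `T_gen` and `Dt` and their count is
#' reported in `n_excluded`.
#'
#' @param records Cohort tibble for one temperature.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; identical `(records, B, seed)` give
#'   identical intervals.
#' @param parameters Which parameters to bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @param observation_interval Passed to the schedule builder.
#' @return A tibble `parameter`, `estimate`, `ci_low`, `ci_high`, `B`,
#'   `seed`, `n_excluded`.
#' @examples
#' cohort <- simulate_cohort(species_config("P_coffea", 40), seed = 1)
#' at25 <- dplyr::filter(cohort, temperature_C == 25)
#' bootstrap_params(at25, B = 200, seed = 9, parameters = "R0")
#' @export
bootstrap_params <- function(records, B = 2000, seed,
                             parameters = c("R0", "r", "lambda",
                                            "T_gen", "Dt"),
                             conf_level = 0.95,
                             observation_interval = NULL) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (B < 100) abort("B must be at least 100")
  if (nrow(records) == 0) abort("empty cohort")
  if (missing(seed)) abort("a seed is required")
  set.seed(as.integer(seed))

  E <- egg_age_matrix(records, observation_interval)
  n <- nrow(E)
  need_r <- any(parameters != "R0")

  est <- params_from_phi(colMeans(E), need_r)
  reps <- matrix(NA_real_, B, 5,
                 dimnames = list(NULL, c("R0", "r", "lambda", "T_gen", "Dt")))
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), n)
    reps[b, ] <- params_from_phi(as.vector(w %*% E) / n, need_r)
  }

  alpha <- (1 - conf_level) / 2
  out <- purrr::map_dfr(parameters, function(p) {
    v <- reps[, p]
    v_ok <- v[!is.na(v)]
    if (length(v_ok) == 0) {
      warn(paste0("all bootstrap replicates degenerate for ", p,
                  "; confidence interval undefined"))
      ci <- c(NA_real_, NA_real_)
    } else {
      ci <- unname(quantile(v_ok, c(alpha, 1 - alpha)))
    }
    if (p == "R0" && !is.na(ci[1])) ci[1] <- max(0, ci[1])
    tibble(parameter = p, estimate = unname(est[p]),
           ci_low = ci[1], ci_high = ci[2],
           B = B, seed = as.integer(seed),
           n_excluded = sum(is.na(v)))
  })
  out
}

#' Paired-bootstrap comparison of two temperatures
#'
#' Resamples both cohorts in tandem and forms the replicate distribution
#' of the parameter difference (a - b). The two-sided bootstrap p-value
#' uses the small-sample correction
#' `p = 2 * min((c_le + 1)/(B + 1), (c_ge + 1)/(B + 1))`, capped at 1,
#' where `c_le`/`c_ge` count replicates with a difference at or below /
#' at or above zero. Replicates degenerate in either cohort are excluded
#' from the rate-based parameters as in [bootstrap_params()].
#'
#' @param records_a,records_b Cohort tibbles for the two temperatures.
#' @inheritParams bootstrap_params
#' @return A tibble `parameter`, `diff`, `ci_low`, `ci_high`, `p`, `B`,
#'   `seed`, `n_excluded`.
#' @export
compare_temperatures <- function(records_a, records_b, B = 2000, seed,
                                 parameters = c("R0", "r", "lambda",
                                                "T_gen", "Dt"),
                                 conf_level = 0.95,
                                 observation_interval = NULL) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (B < 100) abort("B must be at least 100")
  if (nrow(records_a) == 0 || nrow(records_b) == 0) abort("empty cohort")
  if (missing(seed)) abort("a seed is required")
  set.seed(as.integer(seed))

  Ea <- egg_age_matrix(records_a, observation_interval)
  Eb <- egg_age_matrix(records_b, observation_interval)
  na <- nrow(Ea); nb <- nrow(Eb)
  need_r <- any(parameters != "R0")

  est <- params_from_phi(colMeans(Ea), need_r) -
    params_from_phi(colMeans(Eb), need_r)
  diffs <- matrix(NA_real_, B, 5,
                  dimnames = list(NULL, c("R0", "r", "lambda", "T_gen", "Dt")))
  for (b in seq_len(B)) {
    wa <- tabulate(sample.int(na, na, replace = TRUE), na)
    wb <- tabulate(sample.int(nb, nb, replace = TRUE), nb)
    diffs[b, ] <- params_from_phi(as.vector(wa %*% Ea) / na, need_r) -
      params_from_phi(as.vector(wb %*% Eb) / nb, need_r)
  }

  alpha <- (1 - conf_level) / 2
  purrr::map_dfr(parameters, function(p) {
    v <- diffs[, p]
    v_ok <- v[!is.na(v)]
    if (length(v_ok) == 0) {
      warn(paste0("all bootstrap replicates degenerate for ", p))
      return(tibble(parameter = p, diff = unname(est[p]),
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    B = B, seed = as.integer(seed), n_excluded = B))
    }
    ci <- unname(quantile(v_ok, c(alpha, 1 - alpha)))
    Bk <- length(v_ok)
    p_val <- min(1, 2 * min((sum(v_ok <= 0) + 1) / (Bk + 1),
                            (sum(v_ok >= 0) + 1) / (Bk + 1)))
    tibble(parameter = p, diff = unname(est[p]),
           ci_low = ci[1], ci_high = ci[2], p = p_val,
           B = B, seed = as.integer(seed), n_excluded = sum(is.na(v)))
  })
}
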