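#' Age-stage schedules from a single-temperature cohort
#'
#' Builds the age-stage two-sex schedules from individual life histories:
#' `s_xj`, the probability that a newborn (age 0 = oviposition day) is
#' alive and in stage j at age x, estimated as the fraction of the
#' initial cohort; the age-specific survival rate `l_x = sum_j s_xj`; and
#' the age-specific fecundity `m_x`, the mean eggs laid at age x per
#' individual alive at x. Interval egg censuses are spread uniformly over
#' the days of each observation interval. Both sexes and pre-adult deaths
#' remain in the denominator, the two-sex convention that avoids the
#' female-only bias of classical life tables.
#'
#' @param records Cohort tibble for a single temperature.
#' @return An object of class `life_schedule`: list with `age_stage`
#'   (tibble `x`, `stage`, `s`), `schedule` (tibble `x`, `lx`, `mx`),
#'   `n0`, `temperature`.
#' @param observation_interval Days per egg-count interval used when the
#'   cohort was censused (1 = daily counts).
#' @examples
#' cohort <- simulate_cohort(species_config("P_coffea", 30), seed = 3)
#' sched <- build_schedules(dplyr::filter(cohort, temperature_C == 25))
#' head(tidy(sched))
#' @export
build_schedules <- function(records, observation_interval = NULL) {
  if (nrow(records) == 0) abort("empty cohort")
  if (length(unique(records$temperature_C)) != 1) {
    abort("all records must share one temperature")
  }
  interval <- observation_interval %||% infer_interval(records)
  tl <- cohort_timelines(records, interval)
  A <- max(tl$death_age)
  if (A == 0) abort("all individuals died at age 0; no schedule")
  n0 <- nrow(records)
  ages <- 0:(A - 1)

  occ <- vapply(STAGES, function(s) {
    delta <- numeric(A + 1)
    st <- tl$stage_start[, s]
    en <- tl$stage_end[, s]
    live <- !is.na(st) & en > st
    for (i in which(live)) {
      delta[st[i] + 1] <- delta[st[i] + 1] + 1
      delta[en[i] + 1] <- delta[en[i] + 1] - 1
    }
    cumsum(delta)[seq_len(A)]
  }, numeric(A))

  alive <- rowSums(occ)
  eggs_by_age <- colSums(tl$eggs[, seq_len(A), drop = FALSE])
  lx <- alive / n0
  mx <- ifelse(alive > 0, eggs_by_age / alive, 0)

  age_stage <- tibble(
    x = rep(ages, times = length(STAGES)),
    stage = rep(STAGES, each = length(ages)),
    s = as.vector(occ) / n0
  )
  structure(
    list(
      age_stage = age_stage,
      schedule = tibble(x = ages, lx = lx, mx = mx),
      n0 = n0,
      temperature = records$temperature_C[1]
    ),
    class = "life_schedule"
  )
}

# Per-individual integer-day timelines: stage start/end ages, death age,
# and a (n x A_max) matrix of eggs attributed to each age of life.
cohort_timelines <- function(records, interval) {
  n <- nrow(records)
  dm <- cbind(
    egg = records$egg_d,
    larva = records$larva_d,
    pupa = records$pupa_d,
    adult = ifelse(is.na(records$died_in_stage), records$adult_longevity_d, 0)
  )
  dm[is.na(dm)] <- 0
  ends <- t(apply(dm, 1, cumsum))
  starts <- cbind(0, ends[, 1:3, drop = FALSE])
  colnames(starts) <- STAGES
  death_age <- ends[, 4]

  A <- max(death_age)
  eggs <- matrix(0, n, A)
  is_f <- !is.na(records$sex) & records$sex == "female"
  for (i in which(is_f)) {
    counts <- records$egg_counts[[i]]
    if (length(counts) == 0 || sum(counts) == 0) next
    L <- dm[i, "adult"]
    adult_start <- starts[i, "adult"]
    for (k in seq_along(counts)) {
      d_from <- (k - 1) * interval + 1
      d_to <- min(k * interval, L)
      if (d_to < d_from) break
      span <- d_from:d_to
      eggs[i, adult_start + span] <-
        eggs[i, adult_start + span] + counts[k] / length(span)
    }
  }
  list(stage_start = starts, stage_end = ends[, STAGES, drop = FALSE],
       death_age = death_age, eggs = eggs)
}

# Heuristic: if any female has fewer egg-count intervals than adult days,
# the census must have pooled several days; recover the smallest interval
# consistent with every female's record.
infer_interval <- function(records) {
  is_f <- !is.na(records$sex) & records$sex == "female"
  if (!any(is_f)) return(1)
  L <- records$adult_longevity_d[is_f]
  k <- vapply(records$egg_counts[is_f], length, integer(1))
  ok <- k > 0 & !is.na(L)
  if (!any(ok)) return(1)
  max(1, max(ceiling(L[ok] / k[ok])))
}

as_schedule <- function(schedule) {
  if (inherits(schedule, "life_schedule")) return(schedule$schedule)
  stopifnot(all(c("x", "lx", "mx") %in% names(schedule)))
  as_tibble(schedule)
}

#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`: the expected lifetime offspring per newborn,
#' equivalently the cohort's total egg production divided by its initial
#' size.
#'
#' @param schedule A `life_schedule` or a tibble with columns `x`, `lx`,
#'   `mx`.
#' @return The net reproductive rate (offspring/newborn).
#' @export
net_reproductive_rate <- function(schedule) {
  s <- as_schedule(schedule)
  sum(s$lx * s$mx)
}

#' Intrinsic rate of increase (Euler-Lotka root)
#'
#' Solves `sum_x exp(-r (x + 1)) l_x m_x = 1` for the per-day intrinsic
#' rate of increase r, using the age-indexed-from-0 convention of
#' age-stage two-sex life tables (hence the `x + 1` exponent rather than
#' the classical `x`). The left side is strictly decreasing in r, so the
#' root is unique whenever `R0 > 0`; it is bracketed by doubling,
#' narrowed by bisection and polished with Newton steps to
#' `|sum - 1| < 1e-12`.
#'
#' @inheritParams net_reproductive_rate
#' @param method `"newton"` (bisection + Newton polish, default) or
#'   `"bisection"` (bisection only, to the same tolerance).
#' @param tol Convergence tolerance on `|sum - 1|`.
#' @return The intrinsic rate of increase (1/day).
#' @examples
#' # reproduction concentrated at a single age: closed form ln(2)/5
#' s <- tibble::tibble(x = 0:4, lx = 1, mx = c(0, 0, 0, 0, 2))
#' intrinsic_rate(s)
#' @export
intrinsic_rate <- function(schedule, method = c("newton", "bisection"),
                           tol = 1e-12) {
  method <- match.arg(method)
  s <- as_schedule(schedule)
  solve_euler_lotka(s$x, s$lx * s$mx, method = method, tol = tol)
}

solve_euler_lotka <- function(x, phi, method = "newton", tol = 1e-12) {
  keep <- phi > 0
  if (!any(keep)) abort("R0 = 0: the Euler-Lotka equation has no root")
  x <- x[keep]
  phi <- phi[keep]
  if (any(!is.finite(phi))) abort("non-finite schedule")
  w <- x + 1
  f <- function(r) sum(exp(-r * w) * phi) - 1
  R0 <- sum(phi)
  if (R0 == 1) return(0)

  # f is strictly decreasing; expand a bracket around 0
  lo <- -0.5; hi <- 0.5
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (method == "bisection") {
      if (abs(f(mid)) < tol || (hi - lo) < 1e-16) return(mid)
    } else if ((hi - lo) < 1e-6) {
      break
    }
  }
  r <- (lo + hi) / 2
  if (method == "bisection") return(r)
  for (it in 1:100) {
    fr <- f(r)
    if (abs(fr) < tol) break
    grad <- -sum(w * exp(-r * w) * phi)
    r_new <- r - fr / grad
    if (!is.finite(r_new)) break
    r <- r_new
  }
  r
}

#' Demographic parameters from R0 and r
#'
#' Assembles the standard parameter set: finite rate of increase
#' `lambda = exp(r)` (per day), mean generation time `T_gen = ln(R0)/r`
#' (days) and doubling time `Dt = ln(2)/r` (days). At `r = 0` the
#' generation and doubling times are undefined and reported as `NA`
#' (the population neither grows nor declines); `Dt` is likewise `NA`
#' for declining populations.
#'
#' @param R0 Net reproductive rate.
#' @param r Intrinsic rate of increase (1/day).
#' @return A one-row tibble `R0`, `r`, `lambda`, `T_gen`, `Dt`.
#' @export
derived_params <- function(R0, r) {
  if (!is.finite(r)) abort("r must be finite")
  tibble(
    R0 = R0,
    r = r,
    lambda = exp(r),
    T_gen = if (r != 0 && R0 > 0) log(R0) / r else NA_real_,
    Dt = if (r > 0) log(2) / r else NA_real_
  )
}

#' Full life-table analysis of a single-temperature cohort
#'
#' Builds the age-stage schedules and computes all demographic
#' parameters.
#'
#' @inheritParams build_schedules
#' @return An object of class `life_table`: list with `schedule` (the
#'   `life_schedule`), `params` (tibble from [derived_params()]), `n0`,
#'   `temperature`.
#' @examples
#' cohort <- simulate_cohort(species_config("P_nasuta", 100), seed = 1)
#' lt <- life_table(dplyr::filter(cohort, temperature_C == 25))
#' glance(lt)
#' @export
life_table <- function(records, observation_interval = NULL) {
  sched <- build_schedules(records, observation_interval)
  R0 <- net_reproductive_rate(sched)
  r <- if (R0 > 0) intrinsic_rate(sched) else NA_real_
  params <- if (is.na(r)) {
    tibble(R0 = R0, r = NA_real_, lambda = NA_real_,
           T_gen = NA_real_, Dt = NA_real_)
  } else {
    derived_params(R0, r)
  }
  structure(
    list(schedule = sched, params = params,
         n0 = sched$n0, temperature = sched$temperature),
    class = "life_table"
  )
}

#' @export
print.life_schedule <- function(x, ...) {
  cat("<life_schedule> n0 =", x$n0, "at", x$temperature, "degrees C,",
      nrow(x$schedule), "ages\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.life_schedule <- function(x, ...) x$schedule

#' @export
print.life_table <- function(x, ...) {
  cat("Life table at", x$temperature, "degrees C (n0 =", x$n0, ")\n")
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.life_table <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "parameter", values_to = "estimate")
}

#' @exportS3Method generics::glance
glance.life_table <- function(x, ...) {
  dplyr::bind_cols(x$params,
                   tibble(n0 = x$n0, temperature = x$temperature))
}

#' @describeIn life_table Survival (`l_x`) and fecundity (`m_x`) curves.
#' @param object,x A `life_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.life_table <- function(object, ...) {
  s <- object$schedule$schedule
  long <- tidyr::pivot_longer(s, c("lx", "mx"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(lx = "Age-specific survival l(x)",
                            mx = "Age-specific fecundity m(x)"))) +
    ggplot2::labs(x = "Age (days)", y = NULL,
                  title = paste0("Life-table schedules at ",
                                 object$temperature, " °C")) +
    ggplot2::theme_minimal()
}
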