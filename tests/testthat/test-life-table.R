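test_that("schedules count survivors and spread eggs by age", {
  sched <- build_schedules(tiny_cohort(), observation_interval = 1)
  s <- sched$schedule
  # the egg-stage death on day 3 halves survival at x = 3
  expect_equal(s$lx[s$x < 3], rep(1, 3))
  expect_equal(s$lx[s$x >= 3], rep(0.5, 8))
  # daily egg counts land on the adult ages 7..10 of the surviving female
  expect_equal(s$mx[s$x %in% 7:10], c(1, 2, 1, 0))
  expect_equal(sum(s$mx[!s$x %in% 7:10]), 0)
  # age-stage occupancies are cohort fractions
  expect_true(all(sched$age_stage$s %in% c(0, 0.5, 1)))
  # conservation: total eggs = n0 * sum(lx mx)
  expect_equal(sched$n0 * sum(s$lx * s$mx), 4)

  expect_error(build_schedules(tiny_cohort()[0, ]), "empty")
})

test_that("conservation holds on simulated cohorts for any census interval", {
  for (interval in c(1, 15)) {
    cfg <- single_temp_config(n = 150, survival = c(0.9, 0.9, 0.9, 0.9),
                              longevity_mean = 30, longevity_sd = 6,
                              observation_interval = interval)
    co <- simulate_cohort(cfg, seed = 100 + interval)
    sched <- build_schedules(co, observation_interval = interval)
    total_eggs <- sum(vapply(co$egg_counts, sum, numeric(1)))
    expect_equal(nrow(co) * net_reproductive_rate(sched), total_eggs,
                 tolerance = 1e-9)
  }
})

test_that("cohort survival at emergence matches the configured product", {
  surv <- c(0.9, 0.85, 0.9, 0.95)
  cfg <- single_temp_config(n = 2000, duration_means = c(3, 5, 4),
                            duration_sd_frac = 0, longevity_sd = 0,
                            survival = surv)
  co <- simulate_cohort(cfg, seed = 111)
  sched <- build_schedules(co, observation_interval = 1)
  p <- prod(surv)
  # identical durations: everyone alive at age 12 is an emerged adult
  l_at_emergence <- sched$schedule$lx[sched$schedule$x == 12]
  expect_lt(abs(l_at_emergence - p), 2 * sqrt(p * (1 - p) / 2000))
})

test_that("net reproductive rate is the lx-weighted fecundity sum", {
  expect_equal(net_reproductive_rate(
    tibble::tibble(x = 0:1, lx = c(1, 0.5), mx = c(0, 10))), 5)
  expect_equal(net_reproductive_rate(
    tibble::tibble(x = 0:3, lx = 1, mx = 0)), 0)
})

test_that("Euler-Lotka root matches closed forms and the bisection oracle", {
  # R0 = 1 has root r = 0
  expect_equal(intrinsic_rate(tibble::tibble(x = 0:1, lx = 1, mx = c(0, 1))),
               0)
  # reproduction concentrated at age 4 with lx mx = 2: exp(-5r) * 2 = 1
  one_term <- tibble::tibble(x = 0:4, lx = 1, mx = c(0, 0, 0, 0, 2))
  expect_equal(intrinsic_rate(one_term), log(2) / 5, tolerance = 1e-10)

  set.seed(121)
  for (i in 1:100) {
    s <- random_schedule()
    r_newton <- intrinsic_rate(s, method = "newton")
    r_bisect <- intrinsic_rate(s, method = "bisection")
    expect_equal(r_newton, r_bisect, tolerance = 1e-10)
    # the root satisfies the renewal identity
    expect_lt(abs(sum(exp(-r_newton * (s$x + 1)) * s$lx * s$mx) - 1), 1e-10)
    # sign coupling: r > 0 iff R0 > 1
    expect_equal(r_newton > 0, net_reproductive_rate(s) > 1)
  }
  expect_error(intrinsic_rate(tibble::tibble(x = 0:2, lx = 1, mx = 0)),
               "R0 = 0")
})

test_that("derived parameters follow their defining identities", {
  p <- derived_params(R0 = 16.6, r = 0.05)
  expect_equal(p$lambda, exp(0.05))
  expect_equal(round(p$lambda, 2), 1.05)
  expect_equal(p$T_gen, log(16.6) / 0.05)
  expect_equal(p$Dt, log(2) / 0.05)

  p0 <- derived_params(R0 = 1, r = 0)
  expect_equal(p0$lambda, 1)
  expect_true(is.na(p0$T_gen))
  expect_true(is.na(p0$Dt))

  expect_equal(derived_params(R0 = exp(1), r = 1)$T_gen, 1)
  expect_error(derived_params(R0 = 2, r = NaN), "finite")
})

test_that("life_table output keeps lambda = exp(r) to machine precision", {
  cfg <- single_temp_config(n = 200, survival = c(0.9, 0.9, 0.9, 0.9))
  co <- simulate_cohort(cfg, seed = 131)
  lt <- life_table(co, observation_interval = 1)
  expect_equal(lt$params$lambda, exp(lt$params$r), tolerance = 1e-15)
  expect_equal(lt$params$r > 0, lt$params$R0 > 1)
  expect_equal(glance(lt)$temperature, 25)
})

test_that("bootstrap intervals are deterministic and respect constraints", {
  cfg <- single_temp_config(n = 80, survival = c(0.8, 0.9, 0.9, 0.9))
  co <- simulate_cohort(cfg, seed = 141)
  b1 <- bootstrap_params(co, B = 200, seed = 5, observation_interval = 1)
  b2 <- bootstrap_params(co, B = 200, seed = 5, observation_interval = 1)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_low <= b1$estimate + 1e-12))
  expect_true(all(b1$ci_high >= b1$estimate - 1e-12))
  expect_gte(b1$ci_low[b1$parameter == "R0"], 0)

  # a cohort of identical individuals has zero resampling variance
  ident <- tiny_cohort()[rep(2, 10), ]
  ident$id <- 1:10
  bi <- bootstrap_params(ident, B = 100, seed = 6,
                         observation_interval = 1)
  expect_equal(bi$ci_low, bi$estimate)
  expect_equal(bi$ci_high, bi$estimate)

  # sparse reproduction: replicates losing the only mother are excluded
  # from the rate parameters and R0's lower bound is clamped at zero
  sparse <- dplyr::bind_rows(tiny_cohort()[c(2, 1), ],
                             tiny_cohort()[rep(1, 18), ])
  sparse$id <- 1:20
  # the cohort declines, so doubling time is undefined in every replicate
  expect_warning(
    bs <- bootstrap_params(sparse, B = 200, seed = 7,
                           observation_interval = 1),
    "degenerate for Dt"
  )
  expect_gte(bs$ci_low[bs$parameter == "R0"], 0)
  expect_gt(bs$n_excluded[bs$parameter == "r"], 0)
  expect_equal(bs$n_excluded[bs$parameter == "R0"], 0)
})

test_that("temperature comparisons detect real differences and not null ones", {
  cfg <- single_temp_config(n = 120, survival = c(0.9, 0.9, 0.9, 0.9),
                            fecundity_mean = 20)
  co_a <- simulate_cohort(cfg, seed = 151)
  # identical cohorts: difference straddles zero, p near 1
  same <- compare_temperatures(co_a, co_a, B = 200, seed = 8,
                               observation_interval = 1)
  expect_equal(same$diff, rep(0, 5))
  expect_true(all(same$p[!is.na(same$p)] > 0.5))
  expect_true(all(same$ci_low <= 0 & same$ci_high >= 0))

  # doubled fecundity: R0 difference significant at alpha = 0.05
  cfg2 <- single_temp_config(n = 120, survival = c(0.9, 0.9, 0.9, 0.9),
                             fecundity_mean = 40)
  co_b <- simulate_cohort(cfg2, seed = 152)
  diffd <- compare_temperatures(co_a, co_b, B = 400, seed = 9,
                                observation_interval = 1)
  expect_lt(diffd$p[diffd$parameter == "R0"], 0.05)
  expect_lt(diffd$diff[diffd$parameter == "R0"], 0)

  # swapping the cohorts negates the estimated difference
  swapped <- compare_temperatures(co_b, co_a, B = 400, seed = 9,
                                  observation_interval = 1)
  expect_equal(swapped$diff, -diffd$diff)
  expect_lt(swapped$p[swapped$parameter == "R0"], 0.05)
})
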