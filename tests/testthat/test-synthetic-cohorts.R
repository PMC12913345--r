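test_that("default configurations carry the published anchor values", {
  pn <- species_config("P_nasuta")
  fp <- setNames(pn$adults$female_proportion, pn$adults$temperature)
  expect_equal(unname(fp[c("16", "19", "22", "25", "28", "30")]),
               c(0.96, 0.83, 0.62, 0.59, 0.36, 0.21))
  fec <- setNames(pn$adults$fecundity_mean, pn$adults$temperature)
  expect_equal(unname(fec[c("25", "30")]), c(27, 3))
  # development halts past the egg stage at 32 C, at the egg stage at 35 C
  s32 <- pn$stages[pn$stages$temperature == 32, ]
  expect_gt(s32$survival_prob[s32$stage == "egg"], 0)
  expect_equal(s32$survival_prob[s32$stage == "larva"], 0)
  expect_equal(pn$stages$survival_prob[pn$stages$temperature == 35], rep(0, 4))
  # total development means anchored at the viability extremes
  tot <- pn$stages |>
    dplyr::filter(stage != "adult") |>
    dplyr::group_by(temperature) |>
    dplyr::summarise(total = sum(duration_mean))
  expect_equal(tot$total[tot$temperature == 16], 64.8)
  expect_equal(tot$total[tot$temperature == 30], 19)
  # egg-to-adult survival >= 0.80 in the optimal band
  surv <- pn$stages |>
    dplyr::group_by(temperature) |>
    dplyr::summarise(s = prod(survival_prob))
  expect_true(all(surv$s[surv$temperature %in% c(22, 25)] >= 0.80))

  pc <- species_config("P_coffea")
  fpc <- setNames(pc$adults$female_proportion, pc$adults$temperature)
  expect_true(all(fpc[c("19", "22", "25", "28", "30")] >= 0.51 &
                    fpc[c("19", "22", "25", "28", "30")] <= 0.52))
  fecc <- setNames(pc$adults$fecundity_mean, pc$adults$temperature)
  expect_equal(unname(fecc[c("16", "19", "25")]), c(4, 4, 38))
  s16 <- pc$stages[pc$stages$temperature == 16, ]
  expect_equal(s16$survival_prob[s16$stage == "egg"], 0.75)
  expect_equal(s16$survival_prob[s16$stage == "larva"], 0)
  s32c <- pc$stages[pc$stages$temperature == 32, ]
  expect_equal(s32c$survival_prob[s32c$stage == "larva"], 0.41)
  s25c <- pc$stages[pc$stages$temperature == 25, ]
  expect_equal(s25c$survival_prob[s25c$stage == "adult"], 0.87)
  totc <- pc$stages |>
    dplyr::filter(stage != "adult") |>
    dplyr::group_by(temperature) |>
    dplyr::summarise(total = sum(duration_mean))
  expect_equal(totc$total[totc$temperature == 19], 87.35)
  expect_equal(totc$total[totc$temperature == 28], 32.78)

  expect_error(species_config("P_unknown"))
})

test_that("simulation is deterministic and honours degenerate settings", {
  cfg <- single_temp_config(n = 50)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, seed = 12)))

  # byte-identical files from identical (config, seed)
  p1 <- tempfile(); p2 <- tempfile()
  write_cohort(a, p1); write_cohort(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- simulate_cohort(single_temp_config(n = 0), seed = 1)
  expect_equal(nrow(empty), 0)

  # zero SD and certain survival: durations equal the configured means
  det <- simulate_cohort(
    single_temp_config(n = 20, duration_means = c(3, 5, 4),
                       duration_sd_frac = 0, longevity_sd = 0),
    seed = 4
  )
  expect_true(all(det$egg_d == 3))
  expect_true(all(det$larva_d == 5))
  expect_true(all(det$pupa_d == 4))
  expect_true(all(is.na(det$died_in_stage)))
})

test_that("stage survival follows the configured Bernoulli probability", {
  cfg <- single_temp_config(n = 10000, survival = c(0.5, 1, 1, 1))
  co <- simulate_cohort(cfg, seed = 21)
  frac_surviving_egg <- mean(is.na(co$died_in_stage) |
                               co$died_in_stage != "egg")
  half_width <- qnorm(0.995) * sqrt(0.25 / 10000)
  expect_lt(abs(frac_surviving_egg - 0.5), half_width)
})

test_that("no individual carries data beyond its stage of death", {
  cfg <- single_temp_config(n = 400, survival = c(0.7, 0.7, 0.7, 0.7))
  co <- simulate_cohort(cfg, seed = 31)
  dead_egg <- co[!is.na(co$died_in_stage) & co$died_in_stage == "egg", ]
  expect_true(all(is.na(dead_egg$larva_d)))
  expect_true(all(is.na(dead_egg$pupa_d)))
  expect_true(all(is.na(dead_egg$sex)))
  expect_true(all(lengths(dead_egg$egg_counts) == 0))
  dead_larva <- co[!is.na(co$died_in_stage) & co$died_in_stage == "larva", ]
  expect_true(all(!is.na(dead_larva$egg_d)))
  expect_true(all(is.na(dead_larva$pupa_d)))
  pre_adult <- co[!is.na(co$died_in_stage), ]
  expect_true(all(is.na(pre_adult$adult_longevity_d)))
  males <- co[!is.na(co$sex) & co$sex == "male", ]
  expect_true(all(lengths(males$egg_counts) == 0))
})

test_that("realized fecundity converges to the configured mean", {
  cfg <- single_temp_config(n = 4000, female_proportion = 1,
                            fecundity_mean = 27, dispersion = 3)
  co <- simulate_cohort(cfg, seed = 41)
  eggs <- vapply(co$egg_counts[co$sex == "female"], sum, numeric(1))
  se <- sd(eggs) / sqrt(length(eggs))
  expect_lt(abs(mean(eggs) - 27), 2 * se)
  # every total is conserved across its interval allocation
  expect_true(all(eggs >= 0))
})

test_that("cohort files round-trip exactly", {
  # property: a 500-record random cohort survives write -> read unchanged
  cfg <- single_temp_config(n = 500, survival = c(0.8, 0.8, 0.9, 0.9),
                            observation_interval = 3)
  co <- simulate_cohort(cfg, seed = 51)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(read_cohort(path), co)

  # empty cohort -> header-only file -> empty cohort
  pe <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(single_temp_config(n = 0), 1), pe)
  expect_equal(length(readLines(pe)), 1)
  expect_equal(nrow(read_cohort(pe)), 0)

  # single record dead in the egg stage keeps its absent fields
  one <- tiny_cohort()[1, ]
  p1 <- tempfile(fileext = ".csv")
  write_cohort(one, p1)
  expect_equal(read_cohort(p1), one)
})

test_that("malformed cohort files are rejected with line numbers", {
  path <- tempfile(fileext = ".csv")
  write_cohort(tiny_cohort(), path)
  lines <- readLines(path)
  bad <- sub("^1,25,3", "1,25,-3", lines)
  writeLines(bad, path)
  expect_error(read_cohort(path), "line 2")

  writeLines(sub("1;2;1;0", "1;x;1", lines), path)
  expect_error(read_cohort(path), "egg_counts")
})
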