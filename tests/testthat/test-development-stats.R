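test_that("Kruskal-Wallis statistic matches hand-ranked computation", {
  # ranks 1..4, R1 = 3, R2 = 7: H = 12/(N(N+1)) * sum(R^2/n) - 3(N+1) = 2.4
  d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
  out <- kw_test(d, y, g)
  expect_equal(out$statistic, 2.4)
  expect_equal(out$df, 1L)

  # identical values in every group: H = 0, p = 1
  same <- data.frame(g = rep(1:2, each = 3), y = 5)
  out0 <- kw_test(same, y, g)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)

  expect_error(kw_test(data.frame(g = "a", y = 1), y, g), "2")
})

test_that("Kruskal-Wallis is tie-consistent and rank-invariant", {
  set.seed(71)
  d <- data.frame(g = rep(1:3, each = 8), y = rnorm(24))
  # invariance under a strictly monotone transform of the pooled values
  d2 <- transform(d, y = exp(y))
  expect_equal(kw_test(d, y, g)$statistic, kw_test(d2, y, g)$statistic)

  # no ties: the tie-corrected statistic equals the plain-H formula
  r <- rank(d$y)
  N <- length(r)
  Rsum <- tapply(r, d$g, sum)
  H_plain <- 12 / (N * (N + 1)) * sum(Rsum^2 / 8) - 3 * (N + 1)
  expect_equal(kw_test(d, y, g)$statistic, H_plain)
})

test_that("Dunn z statistics follow the tie-corrected formula", {
  # separated triples, ranks 1..9, no ties: var_core = N(N+1)/12 = 7.5
  d <- data.frame(g = rep(1:3, each = 3),
                  y = c(1, 2, 3, 10, 11, 12, 20, 21, 22))
  out <- dunn_test(d, y, g)
  expect_equal(out$z, c(-3, -6, -3) / sqrt(7.5 * (2 / 3)), tolerance = 1e-12)
  # only the extreme pair separates at alpha = 0.05 with 3 per group
  expect_equal(out$significant, c(FALSE, TRUE, FALSE))

  same <- data.frame(g = rep(1:2, each = 3), y = 5)
  out0 <- dunn_test(same, y, g)
  expect_equal(out0$z, 0)
  expect_equal(out0$p_value, 1)

  # antisymmetry: relabelling the two groups negates z, keeps p
  d2 <- data.frame(g = rep(c("hi", "lo"), each = 4),
                   y = c(9, 8, 7, 9, 1, 2, 1, 3))
  ab <- dunn_test(d2, y, g)
  d2$g <- ifelse(d2$g == "hi", "zlo", "ahi")  # reverses factor order
  ba <- dunn_test(d2, y, g)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("Dunn z for two groups squares to the tie-corrected H", {
  set.seed(72)
  for (i in 1:10) {
    d <- data.frame(g = rep(1:2, times = c(7, 9)),
                    y = sample(1:6, 16, replace = TRUE))  # heavy ties
    if (length(unique(d$y)) == 1) next
    z <- dunn_test(d, y, g)$z
    H <- kw_test(d, y, g)$statistic
    expect_equal(z^2, H, tolerance = 1e-10)
  }
})

test_that("compact letter display implements insert-and-absorb", {
  all_ns <- tibble::tibble(group_a = c("A", "A", "B"),
                           group_b = c("B", "C", "C"),
                           significant = FALSE)
  expect_equal(cld_letters(all_ns, c("A", "B", "C"))$letters,
               c("a", "a", "a"))

  all_sig <- dplyr::mutate(all_ns, significant = TRUE)
  expect_equal(cld_letters(all_sig, c("A", "B", "C"))$letters,
               c("a", "b", "c"))

  # only A != C: the middle group shares a letter with both
  mid <- dplyr::mutate(all_ns, significant = c(FALSE, TRUE, FALSE))
  expect_equal(cld_letters(mid, c("A", "B", "C"))$letters,
               c("a", "ab", "b"))

  expect_error(cld_letters(all_ns[1:2, ], c("A", "B", "C")), "all pairs")
})

test_that("letter table orders groups by descending median", {
  set.seed(73)
  d <- data.frame(g = rep(c(16, 25, 30), each = 20),
                  y = c(rnorm(20, 60, 2), rnorm(20, 30, 2), rnorm(20, 19, 2)))
  lt <- letter_table(d, y, g)
  expect_equal(lt$group, c("16", "25", "30"))
  expect_true(all(diff(lt$median) < 0))
  expect_equal(lt$letters, c("a", "b", "c"))
})

test_that("saturated logit survival model matches closed forms and glm", {
  d <- data.frame(t = rep(c("a", "b", "c"), each = 10),
                  alive = c(rep(1, 8), 0, 0,        # 8/10
                            rep(1, 10),             # 10/10 -> corrected
                            rep(c(1, 0), 5)))       # 5/10
  fit <- survival_glm(d, alive, t)
  ga <- fit$groups[fit$groups$group == "a", ]
  expect_equal(ga$proportion, 0.8)
  expect_equal(ga$logit, log(4))
  expect_equal(ga$se, sqrt(1 / 8 + 1 / 2))
  expect_false(ga$corrected)

  gb <- fit$groups[fit$groups$group == "b", ]
  expect_true(gb$corrected)
  expect_equal(gb$logit, log(10.5 / 0.5))

  # non-degenerate groups agree with the one-factor binomial GLM
  d2 <- d[d$t != "b", ]
  gm <- glm(alive ~ 0 + factor(t), binomial, data = d2)
  expect_equal(fit$groups$logit[c(1, 3)], unname(coef(gm)), tolerance = 1e-6)
  expect_equal(fit$groups$se[c(1, 3)],
               unname(summary(gm)$coefficients[, 2]), tolerance = 1e-6)

  # identical outcomes give a zero contrast
  d3 <- data.frame(t = rep(c("x", "y"), each = 10), alive = rep(c(1, 0), 10))
  f3 <- survival_glm(d3, alive, t)
  expect_equal(f3$contrasts$z, 0)

  expect_error(survival_glm(data.frame(t = "a", alive = 2), alive, t),
               "binary")
})
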