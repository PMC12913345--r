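#' Kruskal-Wallis test across temperature groups
#'
#' Tie-corrected Kruskal-Wallis rank sum test of a response across groups,
#' the omnibus test used for development time, longevity, fecundity and
#' sex-ratio comparisons across constant temperatures. The statistic is
#' the usual midrank H divided by `1 - sum(t^3 - t) / (N^3 - N)` and is
#' referred to a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param data A data frame.
#' @param response,group Column names (tidy-eval) holding the response
#'   values and the grouping labels.
#' @return A one-row tibble: `statistic` (H, reported as chi-square),
#'   `df`, `p_value`, `n_groups`, `n`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(1, 2, 3, 4))
#' kw_test(d, y, g)   # H = 2.4 on 1 df
#' @export
kw_test <- function(data, response, group) {
  y <- dplyr::pull(data, {{ response }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- factor(g[ok])
  if (nlevels(g) < 2) abort("kw_test needs at least 2 non-empty groups")
  if (length(unique(y)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n_groups = nlevels(g), n = length(y)))
  }
  kt <- kruskal.test(y, g)
  tibble(
    statistic = unname(kt$statistic),
    df = as.integer(unname(kt$parameter)),
    p_value = unname(kt$p.value),
    n_groups = nlevels(g),
    n = length(y)
  )
}

#' Dunn's post hoc pairwise comparisons
#'
#' All pairwise rank comparisons following a Kruskal-Wallis test, using
#' Dunn's z statistic with the pooled-midrank tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t) /
#' (12(N-1))) * (1/n_i + 1/n_j))`. Two-sided p-values come from the
#' standard normal; the default follows the original procedure with no
#' multiplicity adjustment, with Holm and Bonferroni available.
#'
#' @inheritParams kw_test
#' @param alpha Significance level for the `significant` flag.
#' @param adjust Multiplicity adjustment: `"none"`, `"holm"` or
#'   `"bonferroni"`.
#' @return A tibble with one row per unordered pair: `group_a`,
#'   `group_b`, `z`, `p_value`, `adjusted_p`, `significant`.
#' @examples
#' d <- data.frame(g = rep(1:3, each = 3),
#'                 y = c(1, 2, 3, 10, 11, 12, 20, 21, 22))
#' dunn_test(d, y, g)
#' @export
dunn_test <- function(data, response, group, alpha = 0.05,
                      adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  y <- dplyr::pull(data, {{ response }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- factor(g[ok])
  if (nlevels(g) < 2) abort("dunn_test needs at least 2 non-empty groups")

  N <- length(y)
  r <- rank(y)  # midranks
  rbar <- tapply(r, g, mean)
  ns <- tabulate(g)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    denom2 <- var_core * (1 / ns[i] + 1 / ns[j])
    z <- if (denom2 <= 0) 0 else (rbar[[i]] - rbar[[j]]) / sqrt(denom2)
    tibble(group_a = lev[i], group_b = lev[j], z = z,
           p_value = if (denom2 <= 0) 1 else 2 * pnorm(-abs(z)))
  })
  res$adjusted_p <- p.adjust(res$p_value, method = adjust)
  res$significant <- res$adjusted_p < alpha
  res
}

#' Compact letter display from pairwise comparisons
#'
#' Summarises a set of pairwise significance results as letter codes
#' (insert-and-absorb algorithm): groups that are not significantly
#' different share at least one letter; letters are assigned in the order
#' of `groups`, conventionally descending median, starting at `"a"`.
#' Non-transitive significance patterns are represented faithfully by
#' overlapping letter sets.
#'
#' @param comparisons A tibble with columns `group_a`, `group_b` and
#'   `significant` covering every pair (as from [dunn_test()]).
#' @param groups Character vector of all group labels, in display order.
#' @return A tibble `group`, `letters` in the order of `groups`.
#' @examples
#' cmp <- tibble::tibble(group_a = c("A", "A", "B"),
#'                       group_b = c("B", "C", "C"),
#'                       significant = c(FALSE, TRUE, FALSE))
#' cld_letters(cmp, c("A", "B", "C"))   # A "a", B "ab", C "b"
#' @export
cld_letters <- function(comparisons, groups) {
  groups <- as.character(groups)
  stopifnot(all(comparisons$group_a %in% groups),
            all(comparisons$group_b %in% groups))
  covered <- nrow(comparisons) >= choose(length(groups), 2)
  if (!covered) abort("comparisons must cover all pairs of groups")

  cols <- list(groups)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    for (k in seq_len(nrow(sig))) {
      a <- as.character(sig$group_a[k]); b <- as.character(sig$group_b[k])
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns contained in another column
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              !(length(new_cols[[i]]) == length(new_cols[[j]]) && i < j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  first_pos <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  lab <- letters[seq_along(cols)]
  lt <- vapply(groups, function(gp) {
    paste(lab[vapply(cols, function(col) gp %in% col, logical(1))],
          collapse = "")
  }, character(1))
  tibble(group = groups, letters = unname(lt))
}

#' Letter-annotated group summary for one response
#'
#' Convenience wrapper chaining [kw_test()], [dunn_test()] and
#' [cld_letters()]: the letter annotation used on figures, with groups
#' ordered by descending median. If the omnibus test is not significant
#' at `alpha`, every group receives the letter `"a"`.
#'
#' @inheritParams dunn_test
#' @return A tibble `group`, `median`, `n`, `letters`, ordered by
#'   descending median.
#' @export
letter_table <- function(data, response, group, alpha = 0.05,
                         adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  med <- data %>%
    filter(!is.na({{ response }}), !is.na({{ group }})) %>%
    group_by(group = as.character({{ group }})) %>%
    summarise(median = median({{ response }}), n = dplyr::n(),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$median))
  omnibus <- kw_test(data, {{ response }}, {{ group }})
  if (omnibus$p_value >= alpha) {
    return(mutate(med, letters = "a"))
  }
  cmp <- dunn_test(data, {{ response }}, {{ group }}, alpha = alpha,
                   adjust = adjust)
  left_join(med, cld_letters(cmp, med$group), by = "group")
}

#' Saturated logit-link binomial model for stage survival
#'
#' Per-group survival proportions on the logit scale with Wald pairwise
#' contrasts, the generalized linear model (binomial error, logit link)
#' treatment of survival across temperatures. For the saturated
#' one-factor model the maximum-likelihood estimate for group g is
#' `logit(p_g)` with standard error `sqrt(1/s + 1/f)` (s survivors, f
#' failures). Degenerate groups (no survivors or no failures) are
#' continuity-corrected by adding 0.5 to both counts and flagged.
#' Contrasts are `z = (logit_i - logit_j) / sqrt(se_i^2 + se_j^2)`,
#' Holm-adjusted by default.
#'
#' @param data A data frame.
#' @param outcome Column (tidy-eval) of 0/1 survival outcomes.
#' @param group Grouping column (tidy-eval).
#' @param alpha Significance level.
#' @param adjust Adjustment for the pairwise contrasts.
#' @return An object of class `survival_fit`: a list with tibbles
#'   `groups` (`group`, `n`, `survived`, `proportion`, `logit`, `se`,
#'   `corrected`) and `contrasts` (`group_a`, `group_b`, `z`, `p_value`,
#'   `adjusted_p`, `significant`).
#' @examples
#' d <- data.frame(t = rep(c(22, 30), each = 10),
#'                 alive = c(rep(1, 8), 0, 0, rep(1, 3), rep(0, 7)))
#' fit <- survival_glm(d, alive, t)
#' fit$groups
#' @export
survival_glm <- function(data, outcome, group, alpha = 0.05,
                         adjust = c("holm", "none", "bonferroni")) {
  adjust <- match.arg(adjust)
  y <- dplyr::pull(data, {{ outcome }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- factor(g[ok])
  if (!all(y %in% c(0, 1))) abort("outcome must be binary 0/1")
  if (any(tabulate(g) == 0)) abort("empty group")

  grp <- tibble(group = levels(g),
                n = as.integer(tabulate(g)),
                survived = as.integer(tapply(y, g, sum))) %>%
    mutate(
      proportion = .data$survived / .data$n,
      corrected = .data$survived == 0 | .data$survived == .data$n,
      s_adj = .data$survived + ifelse(.data$corrected, 0.5, 0),
      f_adj = .data$n - .data$survived + ifelse(.data$corrected, 0.5, 0),
      logit = log(.data$s_adj / .data$f_adj),
      se = sqrt(1 / .data$s_adj + 1 / .data$f_adj)
    ) %>%
    select(-"s_adj", -"f_adj")

  pairs <- utils::combn(nrow(grp), 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se_ij <- sqrt(grp$se[i]^2 + grp$se[j]^2)
    z <- (grp$logit[i] - grp$logit[j]) / se_ij
    tibble(group_a = grp$group[i], group_b = grp$group[j], z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  contrasts$adjusted_p <- p.adjust(contrasts$p_value, method = adjust)
  contrasts$significant <- contrasts$adjusted_p < alpha

  structure(list(groups = grp, contrasts = contrasts,
                 alpha = alpha, adjust = adjust),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Saturated binomial logit survival model\n")
  print(x$groups)
  cat("Pairwise Wald contrasts (", x$adjust, "-adjusted):\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.survival_fit <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.survival_fit <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), n = sum(x$groups$n),
         n_significant = sum(x$contrasts$significant),
         alpha = x$alpha, adjust = x$adjust)
}
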