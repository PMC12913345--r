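#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or JSON-style) key-value file. Recognised
#' keys, with defaults in parentheses: `mode` (`"synthetic"`; or
#' `"file"`), `species` (`"P_nasuta"`), `seed` (required in synthetic
#' mode), `n_per_temperature` (species default), `temperatures` (all
#' configured), `bootstrap_B` (10000), `alpha` (0.05), `adjust`
#' (`"none"`), `cohort_file` (required in file mode), `isotherm_file`,
#' `calendar_file`, `out_dir` (`"parasitherm-output"`). Unknown keys are
#' rejected.
#'
#' @param path Path to the config file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  issues <- validate_config(cfg)
  if (length(issues) > 0) {
    abort(paste0("invalid config:\n", paste("-", issues, collapse = "\n")))
  }
  cfg
}

#' @rdname load_config
#' @param ... Configuration keys (see above).
#' @export
run_config <- function(...) {
  supplied <- list(...)
  known <- c("mode", "species", "seed", "n_per_temperature", "temperatures",
             "bootstrap_B", "alpha", "adjust", "cohort_file",
             "isotherm_file", "calendar_file", "out_dir")
  unknown <- setdiff(names(supplied), known)
  if (length(unknown) > 0) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  defaults <- list(mode = "synthetic", species = "P_nasuta", seed = NULL,
                   n_per_temperature = NULL, temperatures = NULL,
                   bootstrap_B = 10000, alpha = 0.05, adjust = "none",
                   cohort_file = NULL, isotherm_file = NULL,
                   calendar_file = NULL, out_dir = "parasitherm-output")
  cfg <- utils::modifyList(defaults, supplied)
  structure(cfg, class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `run_config`.
#' @return Character vector of issues; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!config$mode %in% c("synthetic", "file")) {
    add("mode: must be 'synthetic' or 'file'")
  }
  if (!config$species %in% c("P_nasuta", "P_coffea")) {
    add("species: must be 'P_nasuta' or 'P_coffea'")
  }
  if (identical(config$mode, "synthetic") && is.null(config$seed)) {
    add("seed: required in synthetic mode")
  }
  if (identical(config$mode, "file")) {
    if (is.null(config$cohort_file)) {
      add("cohort_file: required in file mode")
    } else if (!file.exists(config$cohort_file)) {
      add(paste("cohort_file: not found:", config$cohort_file))
    }
  }
  if (!is.numeric(config$alpha) || length(config$alpha) != 1 ||
      config$alpha <= 0 || config$alpha >= 1) {
    add("alpha: must lie strictly between 0 and 1")
  }
  if (!is.numeric(config$bootstrap_B) || config$bootstrap_B < 100) {
    add("bootstrap_B: must be at least 100")
  }
  if (!config$adjust %in% c("none", "holm", "bonferroni")) {
    add("adjust: must be one of none, holm, bonferroni")
  }
  if (!is.null(config$isotherm_file)) {
    if (!file.exists(config$isotherm_file)) {
      add(paste("isotherm_file: not found:", config$isotherm_file))
    } else {
      iso <- tryCatch(
        validate_isotherms(readr::read_csv(
          config$isotherm_file, show_col_types = FALSE)),
        error = function(e) conditionMessage(e)
      )
      if (is.character(iso)) add(paste0("isotherm_file: ", iso))
    }
  }
  issues
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: synthesize (or load) the
#' cohort, run the nonparametric temperature comparisons and the
#' survival model, fit the thermal models, compute bootstrap life tables
#' per viable temperature with pairwise temperature comparisons, and
#' tabulate generation numbers per isotherm. All tables are written as
#' comma-separated UTF-8 files into `config$out_dir`, each starting with
#' a comment line recording the package version and a hash of the
#' configuration, so identical configurations produce byte-identical
#' outputs. Stages that cannot run on the given cohort (e.g. a life
#' table at a temperature where nothing reproduced) are skipped with a
#' logged warning rather than an error.
#'
#' @param config A `run_config` (see [run_config()] / [load_config()]).
#' @return A `run_report`: list with `files` (named paths), `version`,
#'   `config`, `warnings`.
#' @examples
#' \donttest{
#' cfg <- run_config(species = "P_coffea", seed = 1, n_per_temperature = 30,
#'                   bootstrap_B = 100, out_dir = tempfile())
#' report <- run_pipeline(cfg)
#' report$files
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  issues <- validate_config(config)
  if (length(issues) > 0) {
    abort(paste0("invalid config:\n", paste("-", issues, collapse = "\n")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logs <- character(0)
  note <- function(msg) logs <<- c(logs, msg)
  files <- character(0)
  stamp <- paste0("# parasitherm ",
                  as.character(utils::packageVersion("parasitherm")),
                  "; config ", rlang::hash(unclass(config)[
                    setdiff(names(config), "out_dir")]),
                  "; seed ", config$seed %||% "none",
                  "; B ", config$bootstrap_B)
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    writeLines(stamp, path)
    readr::write_csv(tbl, path, append = TRUE, col_names = TRUE, na = "")
    files[[name]] <<- path
  }

  # seed fan-out: one stream per stage so stages can be re-run alone
  set.seed(as.integer(config$seed %||% 0))
  seeds <- sample.int(2^30, 4)

  spp_cfg <- species_config(config$species,
                            n_per_temperature = config$n_per_temperature)
  if (!is.null(config$temperatures)) {
    spp_cfg$stages <- filter(spp_cfg$stages,
                             .data$temperature %in% config$temperatures)
    spp_cfg$adults <- filter(spp_cfg$adults,
                             .data$temperature %in% config$temperatures)
  }
  records <- if (config$mode == "synthetic") {
    simulate_cohort(spp_cfg, seed = seeds[1])
  } else {
    read_cohort(config$cohort_file)
  }
  cohort_flat <- records %>%
    mutate(egg_counts = purrr::map_chr(.data$egg_counts, function(z) {
      if (length(z) == 0) NA_character_ else paste(z, collapse = ";")
    }))
  emit(cohort_flat, "cohort")

  # --- nonparametric comparisons -------------------------------------
  emerged <- filter(records, is.na(.data$died_in_stage))
  responses <- list(
    egg_duration = records %>%
      filter(completed_stage(records, "egg")) %>%
      select(value = "egg_d", group = "temperature_C"),
    larva_duration = records %>%
      filter(completed_stage(records, "larva")) %>%
      select(value = "larva_d", group = "temperature_C"),
    pupa_duration = records %>%
      filter(completed_stage(records, "pupa")) %>%
      select(value = "pupa_d", group = "temperature_C"),
    total_duration = emerged %>%
      mutate(value = .data$egg_d + .data$larva_d + .data$pupa_d) %>%
      select("value", group = "temperature_C"),
    female_longevity = emerged %>%
      filter(.data$sex == "female") %>%
      select(value = "adult_longevity_d", group = "temperature_C"),
    fecundity = emerged %>%
      filter(.data$sex == "female") %>%
      mutate(value = purrr::map_dbl(.data$egg_counts, sum)) %>%
      select("value", group = "temperature_C"),
    sex_ratio = emerged %>%
      mutate(value = as.numeric(.data$sex == "female")) %>%
      select("value", group = "temperature_C")
  )
  cmp_rows <- list(); letter_rows <- list()
  for (nm in names(responses)) {
    d <- responses[[nm]]
    if (nrow(d) == 0 || length(unique(d$group)) < 2) {
      note(paste("comparisons skipped for", nm,
                 "(fewer than 2 non-empty groups)"))
      next
    }
    cmp <- dunn_test(d, value, group, alpha = config$alpha,
                     adjust = config$adjust)
    lt <- letter_table(d, value, group, alpha = config$alpha,
                       adjust = config$adjust)
    cmp_rows[[nm]] <- mutate(cmp, response = nm, .before = 1)
    letter_rows[[nm]] <- mutate(lt, response = nm, .before = 1)
  }
  if (length(cmp_rows) > 0) {
    emit(bind_rows(cmp_rows), "comparisons")
    emit(bind_rows(letter_rows), "letters")
  }

  # --- survival model -------------------------------------------------
  surv_data <- records %>%
    mutate(alive = as.numeric(is.na(.data$died_in_stage)))
  if (length(unique(surv_data$temperature_C)) >= 2) {
    sfit <- survival_glm(surv_data, alive, temperature_C,
                         alpha = config$alpha)
    emit(sfit$groups, "survival_groups")
    emit(sfit$contrasts, "survival_contrasts")
  } else {
    note("survival model skipped (fewer than 2 temperatures)")
  }

  # --- thermal model ----------------------------------------------------
  therm <- thermal_table(records, species = config$species)
  if (nrow(therm) == 0) {
    note("thermal fit skipped (no stage completed at 2+ temperatures)")
    therm <- NULL
  } else {
    emit(thermal_table(records, species = config$species, rounded = TRUE),
         "thermal")
  }

  # --- life tables ------------------------------------------------------
  temps <- sort(unique(records$temperature_C))
  viable <- temps[vapply(temps, function(tt) {
    sub <- filter(records, .data$temperature_C == tt)
    sum(purrr::map_dbl(sub$egg_counts, sum)) > 0
  }, logical(1))]
  skipped <- setdiff(temps, viable)
  if (length(skipped) > 0) {
    note(paste("life table skipped at", paste(skipped, collapse = ", "),
               "degrees C (no reproduction observed)"))
  }
  if (length(viable) > 0) {
    lt_tbl <- purrr::map_dfr(viable, function(tt) {
      sub <- filter(records, .data$temperature_C == tt)
      bootstrap_params(sub, B = config$bootstrap_B, seed = seeds[2],
                       observation_interval = spp_cfg$observation_interval) %>%
        mutate(temperature = tt, .before = 1)
    })
    emit(lt_tbl, "life_table")
    if (length(viable) > 1) {
      pairs <- utils::combn(viable, 2)
      pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        a <- pairs[1, k]; b <- pairs[2, k]
        compare_temperatures(
          filter(records, .data$temperature_C == a),
          filter(records, .data$temperature_C == b),
          B = config$bootstrap_B, seed = seeds[3],
          observation_interval = spp_cfg$observation_interval
        ) %>%
          mutate(temp_a = a, temp_b = b, .before = 1)
      })
      emit(pw, "life_table_pairwise")
    }
  }

  # --- generations ------------------------------------------------------
  ea <- if (!is.null(therm)) filter(therm, .data$stage == "egg_adult") else NULL
  if (!is.null(ea) && nrow(ea) == 1 && is.finite(ea$t) && is.finite(ea$K)) {
    iso <- if (!is.null(config$isotherm_file)) {
      validate_isotherms(readr::read_csv(config$isotherm_file,
                                         show_col_types = FALSE))
    } else {
      default_isotherms()
    }
    cal <- if (!is.null(config$calendar_file)) {
      readr::read_csv(config$calendar_file, show_col_types = FALSE)
    } else {
      default_calendar()
    }
    gt <- generation_table(tibble(species = config$species,
                                  t = ea$t, K = ea$K),
                           isotherms = iso, calendar = cal, rounded = TRUE)
    emit(gt, "generations")
  } else {
    note("generation table skipped (no valid egg-adult thermal fit)")
  }

  for (w in logs) warn(w)
  structure(
    list(files = files,
         version = as.character(utils::packageVersion("parasitherm")),
         config = config, warnings = logs),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("parasitherm pipeline run (version", x$version, ")\n")
  cat("Output tables:\n")
  for (nm in names(x$files)) cat("  -", nm, "->", x$files[[nm]], "\n")
  if (length(x$warnings) > 0) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  *", w, "\n")
  }
  invisible(x)
}
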