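#' Read and write cohort files
#'
#' Cohort files are plain comma-separated UTF-8 text with one row per
#' individual and columns `id, temperature_C, egg_d, larva_d, pupa_d,
#' died_in_stage, sex, adult_longevity_d, egg_counts`, where `egg_counts`
#' is a semicolon-joined list of per-interval egg counts and missing
#' values are empty fields. `read_cohort(write_cohort(x, path))` returns
#' `x` unchanged, including the absent-field encoding for individuals
#' that died before reaching later stages.
#'
#' @param records A cohort tibble as returned by [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a cohort tibble.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(species_config("P_coffea", 5), seed = 2)
#' write_cohort(cohort, p)
#' identical_back <- read_cohort(p)
#' @export
write_cohort <- function(records, path) {
  flat <- records %>%
    mutate(egg_counts = purrr::map_chr(.data$egg_counts, function(z) {
      if (length(z) == 0) NA_character_ else paste(z, collapse = ";")
    }))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(),
      temperature_C = readr::col_double(),
      egg_d = readr::col_double(),
      larva_d = readr::col_double(),
      pupa_d = readr::col_double(),
      died_in_stage = readr::col_character(),
      sex = readr::col_character(),
      adult_longevity_d = readr::col_double(),
      egg_counts = readr::col_character()
    ),
    na = ""
  )
  missing_cols <- setdiff(names(empty_cohort()), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- purrr::imap(raw$egg_counts, function(s, i) {
    if (is.na(s)) return(integer(0))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.integer(parts))
    if (anyNA(vals) || any(vals < 0)) {
      abort(paste0("malformed egg_counts on line ", i + 1, ": '", s, "'"))
    }
    vals
  })
  for (col in c("egg_d", "larva_d", "pupa_d", "adult_longevity_d")) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad) > 0) {
      abort(paste0("negative ", col, " on line ", bad[1] + 1))
    }
  }
  bad_stage <- which(!is.na(raw$died_in_stage) &
                       !raw$died_in_stage %in% STAGES)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown died_in_stage on line ", bad_stage[1] + 1, ": '",
                 raw$died_in_stage[bad_stage[1]], "'"))
  }
  raw$egg_counts <- counts
  raw
}
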