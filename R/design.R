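#' Specify a factorial functional-response experiment
#'
#' Describes a fully crossed feeding-trial design: prey densities crossed
#' with predator sex and abiotic factors (temperature, salinity), a fixed
#' number of predator replicates per cell, and predator-free control
#' replicates per abiotic cell used to quantify background prey mortality.
#'
#' The default is an eight-density design (1, 2, 4, 6, 8, 16, 32, 64 prey)
#' with five predator replicates per sex x temperature x salinity x density
#' cell and three predator-free controls per temperature x salinity x density
#' cell, i.e. 416 experimental units in total.
#'
#' Durations are expressed in experimental-period units: `duration = 1` is
#' one feeding period, whose wall-clock length (`period_hours`, default 72)
#' is carried as metadata only. Attack rates and handling times fitted from
#' such trials are therefore per-period quantities.
#'
#' @param densities Integer vector of initial prey densities, strictly
#'   increasing, all >= 1.
#' @param replicates_predator Predator replicates per treatment cell (>= 1).
#' @param replicates_control Predator-free replicates per abiotic cell
#'   (>= 0; 0 disables controls).
#' @param sexes,temperatures,salinities Factor levels of the crossed design.
#' @param duration Trial length in periods (> 0).
#' @param period_hours Wall-clock hours in one period (metadata).
#' @return An object of class `fr_design`.
#' @seealso [enumerate_units()], [simulate_experiment()]
#' @examples
#' d <- fr_design()
#' nrow(enumerate_units(d))  # 416
#' @export
fr_design <- function(densities = c(1, 2, 4, 6, 8, 16, 32, 64),
                      replicates_predator = 5,
                      replicates_control = 3,
                      sexes = c("M", "F"),
                      temperatures = c(16, 22),
                      salinities = c(15, 10),
                      duration = 1,
                      period_hours = 72) {
  densities <- as.integer(densities)
  if (length(densities) == 0 || any(densities < 1L)) {
    abort("`densities` must be a non-empty vector of counts >= 1.")
  }
  if (any(diff(densities) <= 0)) {
    abort("`densities` must be strictly increasing.")
  }
  if (replicates_predator < 1) abort("`replicates_predator` must be >= 1.")
  if (replicates_control < 0) abort("`replicates_control` must be >= 0.")
  if (length(sexes) == 0 || length(temperatures) == 0 || length(salinities) == 0) {
    abort("Each factor must have at least one level (invalid design).")
  }
  if (anyDuplicated(sexes) || anyDuplicated(temperatures) || anyDuplicated(salinities)) {
    abort("Factor levels must be distinct.")
  }
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0.")
  structure(
    list(
      densities = densities,
      replicates_predator = as.integer(replicates_predator),
      replicates_control = as.integer(replicates_control),
      sexes = as.character(sexes),
      temperatures = as.numeric(temperatures),
      salinities = as.numeric(salinities),
      duration = as.numeric(duration),
      period_hours = as.numeric(period_hours)
    ),
    class = "fr_design"
  )
}

#' @export
print.fr_design <- function(x, ...) {
  n <- nrow(enumerate_units(x))
  cat("<fr_design>\n")
  cat("  densities:  ", paste(x$densities, collapse = ", "), "\n")
  cat("  sexes:      ", paste(x$sexes, collapse = ", "),
      " | temperatures: ", paste(x$temperatures, collapse = ", "),
      " | salinities: ", paste(x$salinities, collapse = ", "), "\n")
  cat("  replicates: ", x$replicates_predator, "predator,",
      x$replicates_control, "control per cell\n")
  cat("  duration:   ", x$duration, "period(s) (1 period =",
      x$period_hours, "h)\n")
  cat("  units:      ", n, "\n")
  invisible(x)
}

#' Enumerate the experimental units of a design
#'
#' Expands an [fr_design()] into one row per experimental unit: every
#' sex x temperature x salinity x density cell repeated
#' `replicates_predator` times, plus every temperature x salinity x density
#' cell repeated `replicates_control` times as predator-free controls
#' (`is_control = TRUE`, `sex = NA`). The `n_killed` column is left `NA`;
#' it is filled by [simulate_experiment()] or by observation.
#'
#' @param design An [fr_design()].
#' @return A tibble with columns `sex`, `temperature`, `salinity`,
#'   `n_initial`, `n_killed`, `duration`, `is_control`.
#' @examples
#' enumerate_units(fr_design())
#' @export
enumerate_units <- function(design) {
  stopifnot(inherits(design, "fr_design"))
  pred <- tidyr::expand_grid(
    sex = design$sexes,
    temperature = design$temperatures,
    salinity = design$salinities,
    n_initial = design$densities,
    replicate = seq_len(design$replicates_predator)
  ) |>
    dplyr::mutate(is_control = FALSE)
  out <- pred
  if (design$replicates_control > 0) {
    ctrl <- tidyr::expand_grid(
      sex = NA_character_,
      temperature = design$temperatures,
      salinity = design$salinities,
      n_initial = design$densities,
      replicate = seq_len(design$replicates_control)
    ) |>
      dplyr::mutate(is_control = TRUE)
    out <- dplyr::bind_rows(pred, ctrl)
  }
  out |>
    dplyr::mutate(
      n_killed = NA_integer_,
      duration = design$duration
    ) |>
    dplyr::select("sex", "temperature", "salinity", "n_initial",
                  "n_killed", "duration", "is_control")
}

trial_columns <- c("sex", "temperature", "salinity", "n_initial",
                   "n_killed", "duration", "is_control")

#' Validate a trial table
#'
#' Checks the structural invariants of a feeding-trial table: required
#' columns present, counts non-negative integers with
#' `n_killed <= n_initial`, positive durations, and controls carrying no
#' predator sex. Errors name the offending rows.
#'
#' @param trials A data frame of feeding trials (see [enumerate_units()] for
#'   the column contract).
#' @param allow_missing_kills Accept `NA` in `n_killed` (e.g. a design
#'   skeleton not yet run)? Default `FALSE`.
#' @return The validated trials, invisibly coerced to a tibble.
#' @export
validate_trials <- function(trials, allow_missing_kills = FALSE) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing trial columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(paste0(what, " (row", if (length(idx) > 1) "s", " ",
                   paste(head(idx, 5), collapse = ", "),
                   if (length(idx) > 5) ", ..." else "", ")."))
    }
  }
  bad_row(is.na(trials$n_initial) | trials$n_initial < 1 |
            trials$n_initial != round(trials$n_initial),
          "`n_initial` must be an integer >= 1")
  if (!allow_missing_kills) {
    bad_row(is.na(trials$n_killed), "`n_killed` is missing")
  }
  known <- !is.na(trials$n_killed)
  bad_row(known & (trials$n_killed < 0 |
                     trials$n_killed != round(trials$n_killed)),
          "`n_killed` must be a non-negative integer")
  bad_row(known & trials$n_killed > trials$n_initial,
          "`n_killed` exceeds `n_initial`")
  bad_row(is.na(trials$duration) | trials$duration <= 0,
          "`duration` must be > 0")
  bad_row(is.na(trials$is_control), "`is_control` must be TRUE/FALSE")
  bad_row(trials$is_control & !is.na(trials$sex),
          "control trials must have no predator sex")
  invisible(trials)
}

#' Read feeding trials from CSV
#'
#' Reads a comma-separated trial table with a header row and validates it.
#' Files whose headers differ from the standard names can be ingested by
#' supplying `col_map`, a named character vector mapping standard names to
#' the file's column names, e.g.
#' `c(n_initial = "Density", n_killed = "Killed")`. Sex levels are matched
#' case-insensitively and normalised to upper case; empty or `"none"` sex
#' denotes a control. A missing `duration` column defaults to 1 period; a
#' missing `is_control` column is inferred from a missing sex.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping standard column
#'   names (`sex`, `temperature`, ...) to the file's header names.
#' @return A validated tibble of trials.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      abort("`col_map` must be a named character vector.")
    }
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("Columns named in `col_map` not found in file: ",
                   paste(missing_src, collapse = ", "), "."))
    }
    raw <- dplyr::rename(raw, !!!setNames(unname(col_map), names(col_map)))
  }
  if (!"duration" %in% names(raw)) raw$duration <- 1
  if ("sex" %in% names(raw)) {
    sex <- toupper(trimws(as.character(raw$sex)))
    sex[sex %in% c("", "NONE", "NA")] <- NA_character_
    known <- c("M", "F", "MALE", "FEMALE")
    bad <- !is.na(sex) & !(sex %in% known)
    if (any(bad)) {
      abort(paste0("Unknown sex level(s): ",
                   paste(unique(sex[bad]), collapse = ", "),
                   " (rows ", paste(head(which(bad), 5), collapse = ", "),
                   ")."))
    }
    sex[sex == "MALE"] <- "M"
    sex[sex == "FEMALE"] <- "F"
    raw$sex <- sex
  } else {
    raw$sex <- NA_character_
  }
  if (!"is_control" %in% names(raw)) {
    raw$is_control <- is.na(raw$sex)
  } else if (!is.logical(raw$is_control)) {
    raw$is_control <- tolower(as.character(raw$is_control)) %in%
      c("true", "t", "1", "yes")
  }
  trials <- raw |>
    dplyr::mutate(
      temperature = as.numeric(.data$temperature),
      salinity = as.numeric(.data$salinity),
      n_initial = as.integer(.data$n_initial),
      n_killed = as.integer(.data$n_killed),
      duration = as.numeric(.data$duration)
    ) |>
    dplyr::select(dplyr::all_of(trial_columns))
  validate_trials(trials)
  trials
}

#' Write feeding trials to CSV
#'
#' @param trials A trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, allow_missing_kills = TRUE)
  readr::write_csv(tibble::as_tibble(trials)[trial_columns], path,
                   progress = FALSE)
  invisible(path)
}
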