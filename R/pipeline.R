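#' Analysis configuration
#'
#' Collects the knobs of [run_analysis()]: where to read trials, how to
#' group them for per-treatment functional response fits, the significance
#' level, bootstrap size, RNG seed, and the control-mortality threshold
#' above which kill counts are background-corrected before analysis.
#'
#' @param input Optional path to a trial CSV (used when [run_analysis()]
#'   is not handed a table directly).
#' @param col_map Optional column mapping for [read_trials()].
#' @param group_vars Grouping variables for per-treatment fits.
#' @param alpha Significance level.
#' @param n_boot Bootstrap replicates per group.
#' @param seed Integer seed driving every stochastic stage.
#' @param control_threshold Background mortality rate in `[0, 1)` above
#'   which the Abbott correction is applied.
#' @param density_grid Optional density grid for bootstrap envelopes.
#' @return An object of class `fr_config`.
#' @export
fr_config <- function(input = NULL, col_map = NULL,
                      group_vars = c("sex", "temperature", "salinity"),
                      alpha = 0.05, n_boot = 2000, seed = NULL,
                      control_threshold = 0.05, density_grid = NULL) {
  if (control_threshold < 0 || control_threshold >= 1) {
    abort("`control_threshold` must be in [0, 1).")
  }
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(input = input, col_map = col_map, group_vars = group_vars,
         alpha = alpha, n_boot = as.integer(n_boot), seed = seed,
         control_threshold = control_threshold, density_grid = density_grid),
    class = "fr_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Accepts the same keys as [fr_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @return An `fr_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(fr_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", "), "."))
  }
  do.call(fr_config, raw)
}

#' Background prey mortality in predator-free controls
#'
#' Pools control trials within each abiotic (temperature x salinity) cell
#' and computes the background mortality rate
#' `sum(n_killed) / sum(n_initial)`, plus the overall pooled rate. The
#' correction flag is raised when any cell exceeds `threshold`; feeding
#' rates then need the Abbott adjustment ([abbott_correct()]) before
#' analysis. With control survival above `1 - threshold` everywhere, kill
#' counts are attributed to predation and used uncorrected.
#'
#' @param trials A trial table (controls identified by `is_control`).
#' @param threshold Mortality rate above which correction is flagged.
#' @return An object of class `fr_control_check`: `per_cell` tibble,
#'   `overall` rate, `overall_survival`, `needs_correction`,
#'   `has_controls`.
#' @export
control_mortality_check <- function(trials, threshold = 0.05) {
  trials <- validate_trials(trials)
  ctrl <- dplyr::filter(trials, .data$is_control)
  if (nrow(ctrl) == 0) {
    warn("No control trials present; proceeding without background-mortality correction.")
    return(structure(
      list(per_cell = tibble::tibble(temperature = numeric(0),
                                     salinity = numeric(0),
                                     n_initial = integer(0),
                                     n_killed = integer(0),
                                     mortality = numeric(0)),
           overall = NA_real_, overall_survival = NA_real_,
           needs_correction = FALSE, has_controls = FALSE,
           threshold = threshold),
      class = "fr_control_check"
    ))
  }
  per_cell <- ctrl |>
    dplyr::group_by(.data$temperature, .data$salinity) |>
    dplyr::summarise(
      n_initial = sum(.data$n_initial),
      n_killed = sum(.data$n_killed),
      mortality = sum(.data$n_killed) / sum(.data$n_initial),
      .groups = "drop"
    )
  overall <- sum(per_cell$n_killed) / sum(per_cell$n_initial)
  structure(
    list(per_cell = per_cell, overall = overall,
         overall_survival = 1 - overall,
         needs_correction = any(per_cell$mortality > threshold),
         has_controls = TRUE, threshold = threshold),
    class = "fr_control_check"
  )
}

#' @export
print.fr_control_check <- function(x, ...) {
  cat("<fr_control_check>\n")
  if (!x$has_controls) {
    cat("  no control trials\n")
    return(invisible(x))
  }
  cat(sprintf("  overall control survival: %.2f%%\n", 100 * x$overall_survival))
  cat("  correction needed:", x$needs_correction,
      sprintf("(threshold %.2f)\n", x$threshold))
  invisible(x)
}

#' Abbott background-mortality correction
#'
#' Subtracts the expected background kills
#' (`n_initial x` the control mortality rate of the trial's abiotic cell)
#' from each predator trial's kill count, rounding to the nearest integer
#' and flooring at zero. Control rows are passed through unchanged.
#'
#' @param trials A trial table.
#' @param control_rates Either an [control_mortality_check()] result or a
#'   data frame with `temperature`, `salinity`, `mortality`.
#' @return The adjusted trial table.
#' @export
abbott_correct <- function(trials, control_rates) {
  trials <- validate_trials(trials)
  if (inherits(control_rates, "fr_control_check")) {
    control_rates <- control_rates$per_cell
  }
  rates <- tibble::as_tibble(control_rates)[c("temperature", "salinity", "mortality")]
  pred_cells <- trials |>
    dplyr::filter(!.data$is_control) |>
    dplyr::distinct(.data$temperature, .data$salinity)
  missing_cells <- dplyr::anti_join(pred_cells, rates,
                                    by = c("temperature", "salinity"))
  if (nrow(missing_cells) > 0) {
    abort(paste0(
      "No control mortality rate for cell(s): ",
      paste(sprintf("%g/%g", missing_cells$temperature,
                    missing_cells$salinity), collapse = "; "), "."
    ))
  }
  trials |>
    dplyr::left_join(rates, by = c("temperature", "salinity")) |>
    dplyr::mutate(
      n_killed = dplyr::if_else(
        .data$is_control,
        .data$n_killed,
        pmax(0L, as.integer(round(.data$n_killed -
                                    .data$n_initial * .data$mortality)))
      )
    ) |>
    dplyr::select(dplyr::all_of(trial_columns))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage: ", stage, "] ", conditionMessage(e)))
  })
}

#' Run the full comparative functional response analysis
#'
#' Orchestrates the whole workflow on a trial table: background-mortality
#' check on the predator-free controls (with Abbott correction when the
#' threshold is exceeded), the factorial quasibinomial consumption-rate
#' model with Type III deviance tests and backward elimination, then per
#' treatment group the functional response type test, the Rogers
#' random-predator fit with derived impact metrics, and a nonparametric
#' bootstrap confidence envelope. All randomness derives from
#' `config$seed`, so identical inputs and config give identical outputs.
#'
#' @param trials A trial table, or `NULL` to read `config$input`.
#' @param config An [fr_config()].
#' @param out_dir Optional directory; when given, the deviance table,
#'   type-test table, parameter table, envelopes and summary are written
#'   as CSV files there, plus a `run_log.yaml`.
#' @return An object of class `fr_report`: `control`, `glm_full`,
#'   `glm_reduced`, `deviance_table`, `slope_contrasts`, `type_tests`,
#'   `fits`, `bootstraps`, `table_types`, `table_params`, `envelopes`,
#'   `summary`, `log`.
#' @examples
#' \donttest{
#' tr <- simulate_experiment(fr_design(), fr_scenario(), seed = 1)
#' rep <- run_analysis(tr, fr_config(n_boot = 100, seed = 1))
#' rep$summary
#' }
#' @export
run_analysis <- function(trials = NULL, config = fr_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "fr_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, prev) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), prev, units = "secs"))
    Sys.time()
  }

  trials <- run_stage("input", {
    if (is.null(trials)) {
      if (is.null(config$input)) abort("No trials given and no `input` configured.")
      read_trials(config$input, config$col_map)
    } else {
      validate_trials(trials)
    }
  })
  pred <- dplyr::filter(trials, !.data$is_control)
  if (nrow(pred) == 0) abort("[stage: input] no predator trials.")
  tmark <- tick("input", t0)

  control <- run_stage("controls", {
    check <- control_mortality_check(trials, config$control_threshold)
    if (check$needs_correction) {
      trials <- abbott_correct(trials, check)
      pred <- dplyr::filter(trials, !.data$is_control)
    }
    check
  })
  tmark <- tick("controls", tmark)

  glm_full <- run_stage("glm", fit_quasibinomial(pred))
  deviance_table <- run_stage("glm", anova_type3(glm_full))
  glm_reduced <- run_stage("glm", backward_select(glm_full, config$alpha))
  deviance_table$retained <- deviance_table$term %in% retained_terms(glm_reduced)
  slope_contrasts <- tryCatch(
    purrr::map_dfr(levels(glm_reduced$data$sex),
                   function(s) density_slope_contrast(glm_reduced, s)),
    error = function(e) NULL
  )
  tmark <- tick("glm", tmark)

  groups <- pred |>
    dplyr::group_by(dplyr::across(dplyr::all_of(config$group_vars))) |>
    dplyr::group_split()
  group_keys <- pred |>
    dplyr::group_by(dplyr::across(dplyr::all_of(config$group_vars))) |>
    dplyr::group_keys()
  n_groups <- length(groups)
  group_seeds <- if (is.null(config$seed)) {
    rep(list(NULL), n_groups)
  } else {
    as.list(withr::with_seed(config$seed,
                             sample.int(2147483646L, n_groups)))
  }
  grid <- config$density_grid %||% seq_len(max(pred$n_initial))

  type_tests <- run_stage("frtype",
    purrr::map(groups, type_test, alpha = config$alpha))
  tmark <- tick("frtype", tmark)
  fits <- run_stage("rogers", purrr::map(groups, fit_rogers))
  tmark <- tick("rogers", tmark)
  bootstraps <- run_stage("bootstrap", purrr::map2(
    groups, seq_len(n_groups),
    function(g, i) bootstrap_fit(g, n_boot = config$n_boot,
                                 seed = group_seeds[[i]],
                                 density_grid = grid,
                                 fit = fits[[i]])
  ))
  tmark <- tick("bootstrap", tmark)

  table_types <- dplyr::bind_cols(
    group_keys,
    purrr::map_dfr(type_tests, function(tt) {
      tibble::tibble(z = tt$z1, first_order_term = tt$coef1,
                     p.value = tt$p1, fr_type = tt$call)
    })
  )
  table_params <- dplyr::bind_cols(
    group_keys,
    purrr::map_dfr(fits, function(f) {
      td <- tidy(f)
      tibble::tibble(
        attack_rate = td$estimate[1], p_attack = td$p.value[1],
        handling_time = td$estimate[2], p_handling = td$p.value[2],
        max_feed_rate = 1 / td$estimate[2],
        frr = td$estimate[1] / td$estimate[2]
      )
    })
  )
  envelopes <- purrr::map2_dfr(seq_len(n_groups), bootstraps, function(i, b) {
    dplyr::bind_cols(group_keys[rep(i, nrow(b$envelope)), ], b$envelope)
  })
  summary_tbl <- dplyr::bind_cols(
    group_keys,
    tibble::tibble(
      fr_type = table_types$fr_type,
      attack_rate = table_params$attack_rate,
      handling_time = table_params$handling_time,
      max_feed_rate = table_params$max_feed_rate,
      frr = table_params$frr,
      attack_lo95 = purrr::map_dbl(bootstraps, ~ .x$param_ci$lo95[1]),
      attack_hi95 = purrr::map_dbl(bootstraps, ~ .x$param_ci$hi95[1]),
      handling_lo95 = purrr::map_dbl(bootstraps, ~ .x$param_ci$lo95[2]),
      handling_hi95 = purrr::map_dbl(bootstraps, ~ .x$param_ci$hi95[2]),
      boot_failed = purrr::map_int(bootstraps, ~ .x$n_failed)
    )
  )

  log <- list(
    seed = config$seed,
    n_boot = config$n_boot,
    alpha = config$alpha,
    n_trials = nrow(trials),
    n_predator_trials = nrow(pred),
    n_groups = n_groups,
    correction_applied = control$needs_correction,
    bootstrap_failures = sum(summary_tbl$boot_failed),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("frcompare")),
    stage_seconds = timings
  )

  report <- structure(
    list(control = control, glm_full = glm_full, glm_reduced = glm_reduced,
         deviance_table = deviance_table, slope_contrasts = slope_contrasts,
         type_tests = type_tests, fits = fits, bootstraps = bootstraps,
         table_types = table_types, table_params = table_params,
         envelopes = envelopes, summary = summary_tbl, log = log),
    class = "fr_report"
  )

  if (!is.null(out_dir)) {
    run_stage("output", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(deviance_table, file.path(out_dir, "deviance_table.csv"),
                       progress = FALSE)
      readr::write_csv(table_types, file.path(out_dir, "type_tests.csv"),
                       progress = FALSE)
      readr::write_csv(table_params, file.path(out_dir, "fr_parameters.csv"),
                       progress = FALSE)
      readr::write_csv(envelopes, file.path(out_dir, "envelopes.csv"),
                       progress = FALSE)
      readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"),
                       progress = FALSE)
      yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
    })
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fr_report <- function(x, ...) {
  cat("<fr_report>", x$log$n_groups, "treatment groups,",
      x$log$n_predator_trials, "predator trials\n")
  cat("  control survival:",
      if (x$control$has_controls) {
        sprintf("%.2f%% (correction %s)", 100 * x$control$overall_survival,
                if (x$control$needs_correction) "applied" else "not needed")
      } else "no controls", "\n")
  cat("  functional response types:",
      paste(x$table_types$fr_type, collapse = ", "), "\n")
  invisible(x)
}
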