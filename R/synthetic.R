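#' Default group-level functional response parameters
#'
#' The scenario shipped with the package: eight (attack rate, handling time)
#' pairs over the crossed sex x temperature x salinity design, portraying a
#' strongly sexually dimorphic predator. Males combine high attack rates
#' (1.3-3.1 per period) with short handling times (0.03-0.08 periods per
#' prey) and their handling time lengthens with warming; females feed at a
#' far lower magnitude (attack rate 0.56-0.84, handling time about 0.16-0.18)
#' and are comparatively insensitive to the abiotic factors.
#'
#' @return A tibble with columns `sex`, `temperature`, `salinity`,
#'   `attack_rate`, `handling_time`.
#' @export
default_fr_params <- function() {
  tibble::tribble(
    ~sex, ~temperature, ~salinity, ~attack_rate, ~handling_time,
    "M", 16, 15, 1.584, 0.032,
    "M", 16, 10, 1.340, 0.032,
    "M", 22, 15, 3.134, 0.080,
    "M", 22, 10, 1.971, 0.061,
    "F", 16, 15, 0.563, 0.181,
    "F", 16, 10, 0.783, 0.168,
    "F", 22, 15, 0.813, 0.156,
    "F", 22, 10, 0.838, 0.156
  )
}

#' Define a simulation scenario
#'
#' Couples a table of group-level functional response parameters with a
#' background prey mortality rate for the predator-free controls.
#'
#' @param params A data frame mapping each sex x temperature x salinity cell
#'   to `attack_rate` and `handling_time` (both > 0). Defaults to
#'   [default_fr_params()].
#' @param background_mortality Per-prey probability of dying from causes
#'   other than predation over one period, in `[0, 1)`. The default 0.005
#'   corresponds to better than 99% control survival.
#' @return An object of class `fr_scenario`.
#' @export
fr_scenario <- function(params = default_fr_params(),
                        background_mortality = 0.005) {
  params <- tibble::as_tibble(params)
  needed <- c("sex", "temperature", "salinity", "attack_rate", "handling_time")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    abort(paste0("`params` lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (any(params$attack_rate <= 0) || any(params$handling_time <= 0)) {
    abort("All attack rates and handling times must be > 0.")
  }
  if (background_mortality < 0 || background_mortality >= 1) {
    abort("`background_mortality` must be in [0, 1).")
  }
  structure(
    list(params = params, background_mortality = background_mortality),
    class = "fr_scenario"
  )
}

#' @export
print.fr_scenario <- function(x, ...) {
  cat("<fr_scenario>", nrow(x$params), "parameter cells, background mortality",
      x$background_mortality, "\n")
  print(x$params, n = nrow(x$params))
  invisible(x)
}

#' Simulate one trial with an event-driven forager
#'
#' A stochastic individual-based analogue of the random predator process:
#' a single predator searches among `n_initial` identical, non-depleting-
#' behaviour prey. While searching with `N` prey left it waits an
#' exponential time with rate `attack_rate * N`, then removes one prey and
#' is occupied for a fixed (degenerate) handling time. Captures occurring
#' before the trial ends are counted; the deterministic limit of the mean
#' is the Rogers expected-kill curve.
#'
#' @param n_initial Initial prey count (>= 0).
#' @param attack_rate,handling_time Foraging parameters (>= 0).
#' @param duration Trial length in periods.
#' @param seed Optional integer seed for a self-contained reproducible draw;
#'   when `NULL` the current RNG stream is used.
#' @return Integer number of prey killed, in `[0, n_initial]`.
#' @export
simulate_trial_mechanistic <- function(n_initial, attack_rate, handling_time,
                                       duration = 1, seed = NULL) {
  if (n_initial < 0 || attack_rate < 0 || handling_time < 0 || duration < 0) {
    abort("All arguments must be >= 0.")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_trial_mechanistic(n_initial, attack_rate, handling_time,
                                 duration)))
  }
  n <- as.integer(n_initial)
  if (n == 0L || attack_rate == 0 || duration == 0) return(0L)
  killed <- 0L
  t <- 0
  while (killed < n) {
    wait <- rexp(1, rate = attack_rate * (n - killed))
    if (t + wait > duration) break
    killed <- killed + 1L
    t <- t + wait + handling_time
    if (t >= duration) break
  }
  killed
}

#' Simulate one trial from the binomial observation model
#'
#' Draws `n_killed ~ Binomial(n_initial, p)` with `p` the deterministic
#' Rogers expected fraction killed — exactly the observation model under
#' which [fit_rogers()] is the maximum-likelihood estimator.
#'
#' @inheritParams simulate_trial_mechanistic
#' @return Integer number of prey killed.
#' @export
simulate_trial_binomial <- function(n_initial, attack_rate, handling_time,
                                    duration = 1, seed = NULL) {
  if (n_initial < 0 || attack_rate < 0 || handling_time < 0 || duration < 0) {
    abort("All arguments must be >= 0.")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_trial_binomial(n_initial, attack_rate, handling_time,
                              duration)))
  }
  n <- as.integer(n_initial)
  if (n == 0L) return(0L)
  p <- rogers_expected_kills(n, attack_rate, handling_time, duration) / n
  rbinom(1, n, p)
}

#' Simulate a full factorial feeding experiment
#'
#' Expands the design with [enumerate_units()] and fills in kill counts:
#' predator trials from the chosen trial generator with the cell's
#' scenario parameters, control trials as
#' `Binomial(n_initial, background_mortality)`. One RNG stream is seeded
#' once from `seed` and per-trial sub-seeds are drawn from it up front, so
#' every row's draw is independent of evaluation order and the whole table
#' is reproducible from `seed` alone.
#'
#' @param design An [fr_design()].
#' @param scenario An [fr_scenario()]; must cover every design cell.
#' @param generator `"binomial"` (matches the fitting likelihood) or
#'   `"mechanistic"` (event-driven forager).
#' @param seed Optional integer seed.
#' @return A tibble of trials with `n_killed` filled in.
#' @examples
#' tr <- simulate_experiment(fr_design(), fr_scenario(), seed = 1)
#' nrow(tr)  # 416
#' @export
simulate_experiment <- function(design, scenario = fr_scenario(),
                                generator = c("binomial", "mechanistic"),
                                seed = NULL) {
  stopifnot(inherits(design, "fr_design"), inherits(scenario, "fr_scenario"))
  generator <- match.arg(generator)
  units <- enumerate_units(design)
  pred_cells <- units |>
    dplyr::filter(!.data$is_control) |>
    dplyr::distinct(.data$sex, .data$temperature, .data$salinity)
  covered <- dplyr::semi_join(
    pred_cells, scenario$params,
    by = c("sex", "temperature", "salinity")
  )
  if (nrow(covered) < nrow(pred_cells)) {
    missing_cells <- dplyr::anti_join(
      pred_cells, scenario$params,
      by = c("sex", "temperature", "salinity")
    )
    abort(paste0(
      "Scenario lacks parameters for cell(s): ",
      paste(sprintf("%s/%g/%g", missing_cells$sex, missing_cells$temperature,
                    missing_cells$salinity), collapse = "; "), "."
    ))
  }
  units <- dplyr::left_join(
    units, scenario$params,
    by = c("sex", "temperature", "salinity")
  )
  draw_all <- function() {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(units))
    gen_fun <- switch(generator,
      binomial = simulate_trial_binomial,
      mechanistic = simulate_trial_mechanistic
    )
    purrr::pmap_int(
      list(units$n_initial, units$attack_rate, units$handling_time,
           units$duration, units$is_control, sub_seeds),
      function(n0, a, h, dur, ctrl, s) {
        withr::with_seed(s, {
          if (ctrl) {
            rbinom(1, n0, scenario$background_mortality)
          } else {
            as.integer(gen_fun(n0, a, h, dur))
          }
        })
      }
    )
  }
  units$n_killed <- if (is.null(seed)) draw_all() else {
    withr::with_seed(seed, draw_all())
  }
  units |>
    dplyr::select(dplyr::all_of(trial_columns))
}

#' Simulate one treatment group's trials
#'
#' Convenience wrapper producing predator trials for a single group at the
#' standard densities — the workhorse for power analyses and tests.
#'
#' @param n_per_density Replicates per density.
#' @param attack_rate,handling_time Group parameters.
#' @param densities Prey densities.
#' @param duration Trial length in periods.
#' @param generator `"binomial"` or `"mechanistic"`.
#' @param seed Optional integer seed.
#' @return A tibble of predator trials.
#' @export
simulate_group <- function(n_per_density = 5, attack_rate, handling_time,
                           densities = c(1, 2, 4, 6, 8, 16, 32, 64),
                           duration = 1,
                           generator = c("binomial", "mechanistic"),
                           seed = NULL) {
  generator <- match.arg(generator)
  design <- fr_design(
    densities = densities,
    replicates_predator = n_per_density,
    replicates_control = 0,
    sexes = "M", temperatures = 16, salinities = 15,
    duration = duration
  )
  scenario <- fr_scenario(
    params = tibble::tibble(sex = "M", temperature = 16, salinity = 15,
                            attack_rate = attack_rate,
                            handling_time = handling_time)
  )
  simulate_experiment(design, scenario, generator = generator, seed = seed)
}
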