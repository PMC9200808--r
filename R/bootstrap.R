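#' Nonparametric bootstrap of a Rogers functional response fit
#'
#' Resamples trial rows with replacement (same size, unstratified), refits
#' the random predator model to each resample, and summarises the draws as
#' 2.5/97.5 percentile intervals for the attack rate and handling time and
#' as a pointwise 95% confidence envelope of the fitted curve over a prey
#' density grid. Replicates whose refit fails or does not converge are
#' dropped and counted in `n_failed`, never redrawn, so the seed-to-output
#' map stays deterministic.
#'
#' Refits start from the point estimate (a warm start), using the same
#' log-scale likelihood machinery as [fit_rogers()].
#'
#' @param trials Predator feeding trials; a point fit must succeed on them.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed for the resampling stream.
#' @param density_grid Densities at which to evaluate the envelope; default
#'   the integers 1 to the maximum observed density.
#' @param fit Optional precomputed [fit_rogers()] result for `trials`.
#' @return An object of class `fr_boot`: `draws` (tibble of per-replicate
#'   parameter estimates), `param_ci`, `envelope` (density, fit, lo95,
#'   hi95), `n_boot`, `n_failed`, and the point `fit`.
#' @examples
#' set.seed(3)
#' tr <- simulate_group(5, attack_rate = 1.2, handling_time = 0.1)
#' bb <- bootstrap_fit(tr, n_boot = 50, seed = 1)
#' bb$param_ci
#' @export
bootstrap_fit <- function(trials, n_boot = 2000, seed = NULL,
                          density_grid = NULL, fit = NULL) {
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  if (is.null(fit)) fit <- fit_rogers(trials)
  if (!fit$converged) abort("Point fit did not converge; cannot bootstrap.")
  d <- kills_from_trials(trials)
  n <- length(d$y)
  if (is.null(density_grid)) density_grid <- seq_len(max(d$n0))
  th_hat <- fit$log_par

  one_rep <- function(idx) {
    n0 <- d$n0[idx]; y <- d$y[idx]; tt <- d$tt[idx]
    if (sum(y) == 0 || length(unique(n0)) < 2) return(c(NA_real_, NA_real_))
    fn <- function(th) rogers_kernel_nll(n0, y, tt, exp(th[1]), exp(th[2]))
    o <- suppressWarnings(
      tryCatch(optim(th_hat, fn, method = "BFGS",
                     control = list(reltol = 1e-8, maxit = 200)),
               error = function(e) NULL)
    )
    if (is.null(o) || o$convergence != 0 || !all(is.finite(o$par))) {
      return(c(NA_real_, NA_real_))
    }
    exp(o$par)
  }

  run <- function() {
    idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE),
                      nrow = n_boot, byrow = TRUE)
    t(apply(idx_mat, 1, one_rep))
  }
  pars <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  ok <- stats::complete.cases(pars)
  n_failed <- sum(!ok)
  if (n_failed == n_boot) abort("Every bootstrap refit failed.")
  if (n_failed > 0.2 * n_boot) {
    warn(sprintf("%d of %d bootstrap refits failed (> 20%%); intervals may be unreliable.",
                 n_failed, n_boot))
  }
  draws <- tibble::tibble(
    replicate = seq_len(n_boot),
    attack_rate = pars[, 1],
    handling_time = pars[, 2],
    converged = ok
  )
  usable <- draws[ok, ]
  ci <- function(v) unname(quantile(v, c(0.025, 0.975), type = 7))
  a_ci <- ci(usable$attack_rate)
  h_ci <- ci(usable$handling_time)
  param_ci <- tibble::tibble(
    term = c("attack_rate", "handling_time"),
    estimate = c(fit$attack_rate, fit$handling_time),
    lo95 = c(a_ci[1], h_ci[1]),
    hi95 = c(a_ci[2], h_ci[2])
  )
  dur <- d$tt[1]
  curve_mat <- vapply(
    seq_len(nrow(usable)),
    function(i) rogers_expected_kills(density_grid, usable$attack_rate[i],
                                      usable$handling_time[i], dur),
    numeric(length(density_grid))
  )
  envelope <- tibble::tibble(
    n_initial = density_grid,
    fit = rogers_expected_kills(density_grid, fit$attack_rate,
                                fit$handling_time, dur),
    lo95 = apply(curve_mat, 1, function(v) quantile(v, 0.025, type = 7)),
    hi95 = apply(curve_mat, 1, function(v) quantile(v, 0.975, type = 7))
  )
  structure(
    list(draws = draws, param_ci = param_ci, envelope = envelope,
         n_boot = n_boot, n_failed = n_failed, fit = fit, seed = seed),
    class = "fr_boot"
  )
}

#' @export
print.fr_boot <- function(x, ...) {
  cat("<fr_boot>", x$n_boot, "replicates,", x$n_failed, "failed\n")
  print(x$param_ci)
  invisible(x)
}

#' @rdname bootstrap_fit
#' @param x An `fr_boot`.
#' @param ... Unused.
#' @export
tidy.fr_boot <- function(x, ...) {
  x$param_ci
}

#' Compare two bootstrap confidence envelopes
#'
#' The standard visual comparison between treatment groups: at each grid
#' density, do the two 95% envelopes intersect? Disjoint envelopes across a
#' range of densities indicate a clear difference in functional response
#' magnitude; overlap indicates convergence.
#'
#' @param res_a,res_b Two [bootstrap_fit()] results computed on identical
#'   density grids.
#' @return An object of class `fr_overlap`: a tibble (`n_initial`,
#'   `overlap`) plus the `disjoint_fraction` summary (share of grid points
#'   with disjoint envelopes).
#' @export
envelope_overlap <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "fr_boot"), inherits(res_b, "fr_boot"))
  ga <- res_a$envelope$n_initial
  gb <- res_b$envelope$n_initial
  if (length(ga) != length(gb) || any(ga != gb)) {
    abort("The two envelopes were computed on different density grids.")
  }
  overlap <- res_a$envelope$lo95 <= res_b$envelope$hi95 &
    res_b$envelope$lo95 <= res_a$envelope$hi95
  structure(
    list(
      by_density = tibble::tibble(n_initial = ga, overlap = overlap),
      disjoint_fraction = mean(!overlap)
    ),
    class = "fr_overlap"
  )
}

#' @export
print.fr_overlap <- function(x, ...) {
  cat("<fr_overlap> disjoint over", sprintf("%.1f%%", 100 * x$disjoint_fraction),
      "of the density grid\n")
  invisible(x)
}
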