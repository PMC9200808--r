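#' Expected kills under Rogers' random predator equation
#'
#' For a feeding trial without prey replacement, the expected number of prey
#' killed solves the implicit random predator equation
#' `Ne = N0 * (1 - exp(a * (Ne * h - T)))`, where `a` is the attack rate
#' (per period), `h` the handling time (periods per prey) and `T` the trial
#' duration (periods). The unique root in `[0, N0]` has the closed form
#' `Ne = N0 - W(a h N0 exp(-a (T - h N0))) / (a h)` with `W` the principal
#' Lambert branch, evaluated here through the log-domain
#' [lambert_w_exp()] so extreme parameter values remain finite.
#'
#' Boundary cases are taken by their limits: `a = 0` or `T = 0` or `N0 = 0`
#' give 0 kills; `h = 0` gives exponential depletion
#' `N0 * (1 - exp(-a T))`.
#'
#' @param n_initial Initial prey density N0 (>= 0); vectorised.
#' @param attack_rate Attack rate a (>= 0).
#' @param handling_time Handling time h (>= 0).
#' @param duration Trial length T in periods (>= 0).
#' @return Expected kills, a numeric vector in `[0, n_initial]`.
#' @examples
#' rogers_expected_kills(64, attack_rate = 1.5, handling_time = 0.03)
#' @export
rogers_expected_kills <- function(n_initial, attack_rate, handling_time,
                                  duration = 1) {
  if (any(attack_rate < 0, na.rm = TRUE) ||
      any(handling_time < 0, na.rm = TRUE)) {
    abort("`attack_rate` and `handling_time` must be >= 0.")
  }
  if (any(n_initial < 0, na.rm = TRUE) || any(duration < 0, na.rm = TRUE)) {
    abort("`n_initial` and `duration` must be >= 0.")
  }
  v <- cbind(n_initial, attack_rate, handling_time, duration)  # recycles
  n0 <- v[, 1]; a <- v[, 2]; h <- v[, 3]; tt <- v[, 4]
  ne <- numeric(nrow(v))
  zero <- n0 == 0 | a == 0 | tt == 0
  expo <- !zero & h == 0
  ne[expo] <- n0[expo] * (1 - exp(-a[expo] * tt[expo]))
  main <- !zero & !expo
  if (any(main)) {
    z <- log(a[main] * h[main] * n0[main]) -
      a[main] * (tt[main] - h[main] * n0[main])
    ne[main] <- n0[main] - lambert_w_exp(z) / (a[main] * h[main])
  }
  pmin(pmax(ne, 0), n0)
}

kills_from_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) abort("No trials supplied.")
  if (any(trials$is_control)) {
    abort("Control rows present; functional responses are fitted to predator trials only.")
  }
  validate_trials(trials)
  list(
    n0 = as.numeric(trials$n_initial),
    y = as.numeric(trials$n_killed),
    tt = as.numeric(trials$duration)
  )
}

#' Negative binomial log-likelihood of the Rogers model
#'
#' The likelihood treats each trial's kill count as
#' `Binomial(n_initial, p)` with `p` the Rogers expected fraction killed,
#' `rogers_expected_kills(N0, a, h, T) / N0`, clamped to
#' `[1e-9, 1 - 1e-9]` so that total depletion (or zero kills under tiny
#' attack rates) keeps the log-likelihood finite.
#'
#' @param trials Predator feeding trials (no control rows).
#' @param attack_rate,handling_time Parameters at which to evaluate.
#' @return The negative log-likelihood (scalar).
#' @seealso [fit_rogers()]
#' @export
rogers_nll <- function(trials, attack_rate, handling_time) {
  d <- kills_from_trials(trials)
  rogers_nll_vec(d$n0, d$y, d$tt, attack_rate, handling_time)
}

prob_clamp <- 1e-9

# unvalidated vectorised expected kills for the optimizer hot path;
# assumes a > 0, h > 0, n0 >= 1, tt > 0
rogers_ne_fast <- function(n0, a, h, tt) {
  z <- log(a * h * n0) - a * (tt - h * n0)
  ne <- n0 - lambert_w_exp(z) / (a * h)
  pmin(pmax(ne, 0), n0)
}

rogers_nll_vec <- function(n0, y, tt, a, h) {
  p <- rogers_expected_kills(n0, a, h, tt) / n0
  p <- pmin(pmax(p, prob_clamp), 1 - prob_clamp)
  -sum(dbinom(y, size = n0, prob = p, log = TRUE))
}

# the same likelihood up to the data-only binomial coefficient: identical
# argmax, gradients and Hessian, cheaper per evaluation
rogers_kernel_nll <- function(n0, y, tt, a, h) {
  p <- rogers_ne_fast(n0, a, h, tt) / n0
  p[p < prob_clamp] <- prob_clamp
  p[p > 1 - prob_clamp] <- 1 - prob_clamp
  -sum(y * log(p) + (n0 - y) * log1p(-p))
}

# Hanes-style linearisation of the disc equation: T/Ne ~ (1/a)(1/N0) + h.
# Used only to seed the optimizer.
rogers_init <- function(n0, y, tt) {
  keep <- y > 0
  a0 <- 1
  h0 <- 1 / max(n0)
  if (sum(keep) >= 2 && length(unique(n0[keep])) >= 2) {
    fit <- stats::lm.fit(cbind(1, 1 / n0[keep]), tt[keep] / y[keep])
    h_lin <- fit$coefficients[1]
    a_lin <- 1 / fit$coefficients[2]
    if (is.finite(a_lin) && a_lin > 0) a0 <- a_lin
    if (is.finite(h_lin) && h_lin > 0) h0 <- h_lin
  }
  c(log(a0), log(h0))
}

#' Fit Rogers' random predator equation by maximum likelihood
#'
#' Maximises the binomial likelihood of [rogers_nll()] over
#' `(log a, log h)` — the log scale enforces positivity — using a
#' derivative-free Nelder-Mead search started from a Hanes-style
#' linearisation of the disc equation, followed by a BFGS polish.
#' Standard errors come from the inverse numerical Hessian at the optimum
#' and are delta-method transformed back to the natural scale.
#'
#' @param trials Predator feeding trials (no control rows), with at least
#'   two distinct densities and at least one kill overall.
#' @param init Optional starting values, a numeric vector
#'   `c(attack_rate, handling_time)` on the natural scale.
#' @param nll_tol Convergence tolerance on the negative log-likelihood.
#' @return An object of class `fr_fit` with components `attack_rate`,
#'   `handling_time`, `log_par`, `se_log`, `vcov_log`, `loglik`,
#'   `converged`, `n_trials`, and the fitted `trials`. Supports
#'   [coef()], [tidy()], [glance()], [predict()], [autoplot()].
#' @examples
#' set.seed(42)
#' tr <- simulate_group(n_per_density = 5, attack_rate = 1.5,
#'                      handling_time = 0.08)
#' fit <- fit_rogers(tr)
#' tidy(fit)
#' @export
fit_rogers <- function(trials, init = NULL, nll_tol = 1e-8) {
  d <- kills_from_trials(trials)
  single_density <- length(unique(d$n0)) < 2
  if (sum(d$y) == 0) {
    abort("All trials have zero kills; the attack rate is not identifiable.")
  }
  if (!is.null(init)) {
    if (length(init) != 2 || any(init <= 0)) {
      abort("`init` must be two positive values c(attack_rate, handling_time).")
    }
    th0 <- log(init)
  } else {
    th0 <- rogers_init(d$n0, d$y, d$tt)
  }
  fn <- function(th) rogers_kernel_nll(d$n0, d$y, d$tt, exp(th[1]), exp(th[2]))
  o1 <- optim(th0, fn, method = "Nelder-Mead",
              control = list(reltol = nll_tol, maxit = 500))
  o2 <- suppressWarnings(
    optim(o1$par, fn, method = "BFGS", hessian = TRUE,
          control = list(reltol = nll_tol, maxit = 200))
  )
  best <- if (o2$value <= o1$value) o2 else o1
  hess <- o2$hessian
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 2, 2))
  se_log <- suppressWarnings(sqrt(diag(vc)))
  converged <- best$convergence == 0 && all(is.finite(se_log))
  fit <- structure(
    list(
      attack_rate = exp(best$par[[1]]),
      handling_time = exp(best$par[[2]]),
      log_par = unname(best$par),
      se_log = unname(se_log),
      vcov_log = vc,
      loglik = -rogers_nll_vec(d$n0, d$y, d$tt,
                               exp(best$par[[1]]), exp(best$par[[2]])),
      converged = converged,
      n_trials = length(d$y),
      single_density = single_density,
      trials = tibble::as_tibble(trials)
    ),
    class = "fr_fit"
  )
  if (single_density) {
    warn("Only one prey density present; the fit is ill-posed (a and h are confounded).")
  }
  fit
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("<fr_fit> Rogers random predator model,", x$n_trials, "trials\n")
  cat(sprintf("  attack rate    a = %.4f\n", x$attack_rate))
  cat(sprintf("  handling time  h = %.4f  (1/h = %.3f)\n",
              x$handling_time, 1 / x$handling_time))
  cat(sprintf("  logLik = %.3f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) {
  c(attack_rate = object$attack_rate, handling_time = object$handling_time)
}

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n_trials, class = "logLik")
}

#' @rdname fit_rogers
#' @param x,object An `fr_fit`.
#' @param ... Unused.
#' @export
tidy.fr_fit <- function(x, ...) {
  est <- c(x$attack_rate, x$handling_time)
  se <- est * x$se_log  # delta method from the log scale
  z <- est / se
  tibble::tibble(
    term = c("attack_rate", "handling_time"),
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' @rdname fit_rogers
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 4,
    nobs = x$n_trials,
    converged = x$converged
  )
}

#' @export
predict.fr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- tibble::tibble(
      n_initial = object$trials$n_initial,
      duration = object$trials$duration
    )
  }
  if (is.numeric(newdata)) {
    newdata <- tibble::tibble(n_initial = newdata, duration = 1)
  }
  if (!"duration" %in% names(newdata)) newdata$duration <- 1
  rogers_expected_kills(newdata$n_initial, object$attack_rate,
                        object$handling_time, newdata$duration)
}

#' Derived impact metrics from a fitted functional response
#'
#' The maximum feeding rate `1/h` (prey per period, the curve's asymptote)
#' and the functional response ratio `FRR = a/h`, a composite impact metric:
#' higher values indicate greater expected ecological impact. Both are exact
#' arithmetic on the unrounded fitted parameters.
#'
#' @param fit An [fit_rogers()] result (must have converged).
#' @return A one-row tibble with `attack_rate`, `handling_time`,
#'   `max_feed_rate`, `frr`.
#' @export
impact_metrics <- function(fit) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!fit$converged) abort("Impact metrics require a converged fit.")
  if (fit$handling_time == 0) {
    abort("Handling time is zero; maximum feeding rate is undefined.")
  }
  tibble::tibble(
    attack_rate = fit$attack_rate,
    handling_time = fit$handling_time,
    max_feed_rate = 1 / fit$handling_time,
    frr = fit$attack_rate / fit$handling_time
  )
}
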