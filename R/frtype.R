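#' Determine functional response type by logistic regression
#'
#' Applies the standard sign/significance rule for classifying a
#' functional response from the relationship between the proportion of
#' prey killed and initial prey density. A logistic regression of
#' `cbind(killed, surviving)` on density supplies the first-order term: a
#' significant negative slope indicates a Type II (saturating,
#' inversely density-dependent) response. When the first-order term is
#' instead significantly positive, the quadratic logistic fit
#' (`~ density + density^2`) is consulted: a significant negative
#' second-order term then indicates a Type III (sigmoidal) response.
#' Anything else is indeterminate. Inference is by Wald z tests at level
#' `alpha`.
#'
#' The headline first-order term is taken from the linear fit — the same
#' single coefficient comparative studies tabulate per treatment group —
#' while both terms of the quadratic fit are retained in the coefficient
#' table for the Type III rule and for inspection.
#'
#' Complete (or quasi-complete) separation leaves a slope unbounded; such
#' fits are flagged and the call set to indeterminate rather than trusting
#' the diverged coefficients.
#'
#' @param trials Predator feeding trials spanning at least three distinct
#'   densities.
#' @param alpha Significance level for the classification rule.
#' @return An object of class `fr_type_test` with the coefficient table
#'   and a `call` of `"TypeII"`, `"TypeIII"` or `"indeterminate"`.
#'   Supports [tidy()].
#' @examples
#' set.seed(7)
#' tr <- simulate_group(5, attack_rate = 1.5, handling_time = 0.05)
#' type_test(tr)
#' @export
type_test <- function(trials, alpha = 0.05) {
  d <- kills_from_trials(trials)
  if (length(unique(d$n0)) < 3) {
    abort("Type testing needs at least 3 distinct prey densities.")
  }
  dat <- data.frame(n0 = d$n0, killed = d$y, alive = d$n0 - d$y)
  separated <- FALSE
  catch_sep <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1",
              conditionMessage(w))) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  lin <- withCallingHandlers(
    glm(cbind(killed, alive) ~ n0, family = binomial(), data = dat),
    warning = catch_sep
  )
  quad <- withCallingHandlers(
    glm(cbind(killed, alive) ~ n0 + I(n0^2), family = binomial(),
        data = dat),
    warning = catch_sep
  )
  sl <- summary(lin)$coefficients
  sq <- summary(quad)$coefficients
  separated <- separated && (sl[2, 2] > 50 || any(sq[-1, 2] > 50))
  coef1 <- sl[2, 1]; z1 <- sl[2, 3]; p1 <- sl[2, 4]
  coef2 <- sq[3, 1]; z2 <- sq[3, 3]; p2 <- sq[3, 4]
  call <- if (separated) {
    "indeterminate"
  } else if (p1 < alpha && coef1 < 0) {
    "TypeII"
  } else if (p1 < alpha && coef1 > 0 && p2 < alpha && coef2 < 0) {
    "TypeIII"
  } else {
    "indeterminate"
  }
  coef_tbl <- tibble::tibble(
    model = c("linear", "quadratic", "quadratic", "quadratic"),
    term = c("density", "(Intercept)", "density", "density^2"),
    estimate = c(sl[2, 1], sq[, 1]),
    std.error = c(sl[2, 2], sq[, 2]),
    statistic = c(sl[2, 3], sq[, 3]),
    p.value = c(sl[2, 4], sq[, 4])
  )
  structure(
    list(
      coefficients = coef_tbl,
      coef1 = unname(coef1), coef2 = unname(coef2),
      z1 = unname(z1), z2 = unname(z2),
      p1 = unname(p1), p2 = unname(p2),
      alpha = alpha,
      separated = separated,
      call = call,
      n_trials = nrow(dat)
    ),
    class = "fr_type_test"
  )
}

#' @export
print.fr_type_test <- function(x, ...) {
  cat("<fr_type_test>", x$n_trials, "trials\n")
  cat(sprintf("  first-order term  %+.4f (z = %.3f, p = %.3g)\n",
              x$coef1, x$z1, x$p1))
  cat(sprintf("  second-order term %+.6f (z = %.3f, p = %.3g) [quadratic fit]\n",
              x$coef2, x$z2, x$p2))
  if (x$separated) cat("  [separation detected]\n")
  cat("  call:", x$call, "\n")
  invisible(x)
}

#' @rdname type_test
#' @param x An `fr_type_test`.
#' @param ... Unused.
#' @export
tidy.fr_type_test <- function(x, ...) {
  x$coefficients
}

#' Locally weighted scatterplot smoothing of kill proportions
#'
#' The visual diagnostic companion to [type_test()]: a LOWESS trend
#' (tricube-weighted local linear regression over the nearest
#' `span`-fraction of points, default smoothing factor 9/10, zero
#' robustifying iterations) of the proportion of prey killed against
#' initial density, evaluated at the observed densities. A falling trend
#' corroborates a Type II response; a rising-then-falling trend a Type III.
#'
#' @param trials Predator feeding trials with at least two distinct
#'   densities.
#' @param span Smoothing span in (0, 1], the fraction of points entering
#'   each local fit.
#' @param iterations Robustifying iterations (0 = plain tricube weights).
#' @return A tibble with `n_initial` and the smoothed `proportion`
#'   (clipped to `[0, 1]`), one row per observed point, ordered by density.
#' @export
lowess_proportions <- function(trials, span = 0.9, iterations = 0) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    abort("`span` must be a single value in (0, 1].")
  }
  d <- kills_from_trials(trials)
  if (length(unique(d$n0)) < 2) {
    abort("LOWESS needs at least 2 distinct prey densities.")
  }
  sm <- lowess(d$n0, d$y / d$n0, f = span, iter = iterations, delta = 0)
  tibble::tibble(
    n_initial = sm$x,
    proportion = pmin(pmax(sm$y, 0), 1)
  )
}
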