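glm_factors <- c("sex", "temperature", "salinity")

prepare_glm_data <- function(trials, factors = glm_factors) {
  d <- tibble::as_tibble(trials)
  if (any(d$is_control)) {
    abort("Control rows present; the consumption-rate model uses predator trials only.")
  }
  validate_trials(d)
  dat <- data.frame(
    proportion = d$n_killed / d$n_initial,
    density = as.numeric(d$n_initial),
    .w = as.numeric(d$n_initial)
  )
  for (f in factors) {
    v <- d[[f]]
    if (length(unique(v)) < 2) {
      abort(paste0("Factor `", f, "` is constant; it cannot enter the model."))
    }
    dat[[f]] <- factor(v)
  }
  dat
}

#' Factorial consumption-rate model (quasibinomial GLM)
#'
#' Models the proportion of prey killed as a function of predator sex,
#' temperature and salinity (two-level factors, sum-to-zero coded) and prey
#' density (continuous, untransformed), with all interactions up to the
#' four-way term by default. The fit is a binomial-logit IRLS weighted by
#' initial prey density; the quasibinomial family leaves the coefficients
#' identical to the binomial fit but scales all inference by the Pearson
#' dispersion `phi = chi^2 / df_resid`, accommodating the overdispersion
#' typical of consumption proportions.
#'
#' Sum-to-zero factor coding is applied unconditionally: Type III analysis
#' of deviance ([anova_type3()]) is only meaningful under it.
#'
#' @param trials Predator feeding trials.
#' @param formula Optional model formula over `sex`, `temperature`,
#'   `salinity`, `density` with response `proportion`; default the full
#'   four-way factorial `proportion ~ sex * temperature * salinity * density`.
#' @return An object of class `fr_glm` wrapping the [stats::glm] fit, with
#'   `dispersion` (Pearson phi). Supports [tidy()], [glance()],
#'   [anova_type3()], [backward_select()], [density_slope_contrast()].
#' @examples
#' tr <- simulate_experiment(fr_design(), fr_scenario(), seed = 1) |>
#'   dplyr::filter(!is_control)
#' m <- fit_quasibinomial(tr)
#' anova_type3(m)
#' @export
fit_quasibinomial <- function(trials, formula = NULL) {
  dat <- prepare_glm_data(trials)
  if (is.null(formula)) {
    formula <- proportion ~ sex * temperature * salinity * density
  }
  ctr <- lapply(glm_factors[glm_factors %in% all.vars(formula)],
                function(f) "contr.sum")
  names(ctr) <- glm_factors[glm_factors %in% all.vars(formula)]
  fit <- glm(formula, family = quasibinomial(), data = dat,
             weights = .w, contrasts = ctr,
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) {
    abort("IRLS did not converge for the consumption-rate model.")
  }
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  structure(
    list(fit = fit, dispersion = phi, data = dat, formula = formula),
    class = "fr_glm"
  )
}

#' @export
print.fr_glm <- function(x, ...) {
  cat("<fr_glm> quasibinomial consumption-rate model\n")
  cat("  terms:", paste(attr(terms(x$fit), "term.labels"), collapse = ", "), "\n")
  cat(sprintf("  Pearson dispersion phi = %.3f, resid. df = %d\n",
              x$dispersion, x$fit$df.residual))
  invisible(x)
}

#' @export
coef.fr_glm <- function(object, ...) coef(object$fit)

#' @rdname fit_quasibinomial
#' @param x An `fr_glm`.
#' @param ... Unused.
#' @export
tidy.fr_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @rdname fit_quasibinomial
#' @export
glance.fr_glm <- function(x, ...) {
  tibble::tibble(
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance,
    df.residual = x$fit$df.residual,
    dispersion = x$dispersion,
    nobs = length(x$fit$y)
  )
}

term_vars <- function(labels) strsplit(labels, ":", fixed = TRUE)

# is term i marginal to (contained in) term j?
is_subset <- function(a, b) length(a) < length(b) && all(a %in% b)

#' Type III analysis of deviance with F tests
#'
#' Tests each model term by comparing the full model with the model from
#' which that term's design-matrix columns are removed, all remaining terms
#' kept in place: `F = (Delta deviance / Delta df) / phi` with `phi` the
#' full model's Pearson dispersion, referred to an F distribution on
#' `(Delta df, df_resid)`. Meaningful only under the sum-to-zero factor
#' coding that [fit_quasibinomial()] enforces.
#'
#' @param model An [fit_quasibinomial()] result.
#' @return A `fr_deviance` tibble with `term`, `F`, `df`, `p.value`.
#' @export
anova_type3 <- function(model) {
  stopifnot(inherits(model, "fr_glm"))
  fit <- model$fit
  cf <- coef(fit)
  if (anyNA(cf)) {
    asgn <- attr(model.matrix(fit), "assign")
    labels <- attr(terms(fit), "term.labels")
    bad <- unique(labels[asgn[which(is.na(cf))]])
    abort(paste0("Aliased term(s) in the model: ",
                 paste(bad, collapse = ", "),
                 ". Type III tests are undefined."))
  }
  X <- model.matrix(fit)
  asgn <- attr(X, "assign")
  labels <- attr(terms(fit), "term.labels")
  y <- fit$y
  w <- fit$prior.weights
  phi <- model$dispersion
  dev_full <- fit$deviance
  df_res <- fit$df.residual
  rows <- purrr::map_dfr(seq_along(labels), function(j) {
    keep <- asgn != j
    sub <- suppressWarnings(
      glm.fit(X[, keep, drop = FALSE], y, weights = w, family = binomial(),
              control = stats::glm.control(epsilon = 1e-12, maxit = 50))
    )
    ddf <- sum(!keep)
    f_stat <- ((sub$deviance - dev_full) / ddf) / phi
    tibble::tibble(
      term = labels[j],
      F = f_stat,
      df = ddf,
      p.value = pf(f_stat, ddf, df_res, lower.tail = FALSE)
    )
  })
  structure(rows, class = c("fr_deviance", class(rows)))
}

#' Backward stepwise elimination of non-significant terms
#'
#' Starting from the fitted model, repeatedly removes the single least
#' significant removable term — the highest Type III p-value at or above
#' `alpha` among terms that are not contained in any other term still in
#' the model (marginality is respected: main effects under retained
#' interactions are never candidates) — refitting after each removal,
#' until every removable term is significant.
#'
#' @param model An [fit_quasibinomial()] result.
#' @param alpha Retention threshold.
#' @return The reduced `fr_glm`; the removal order is recorded in the
#'   `eliminated` attribute, and `retained_terms()` lists what survived.
#' @export
backward_select <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "fr_glm"))
  current <- model
  eliminated <- character(0)
  repeat {
    tab <- anova_type3(current)
    labels <- tab$term
    vars <- term_vars(labels)
    removable <- vapply(seq_along(labels), function(i) {
      !any(vapply(seq_along(labels), function(j) {
        i != j && is_subset(vars[[i]], vars[[j]])
      }, logical(1)))
    }, logical(1))
    cand <- tab[removable & tab$p.value >= alpha, ]
    if (nrow(cand) == 0 || length(labels) == 1) break
    drop_term <- cand$term[which.max(cand$p.value)]
    remaining <- setdiff(labels, drop_term)
    if (length(remaining) == 0) {
      eliminated <- c(eliminated, drop_term)
      new_formula <- proportion ~ 1
      dat <- current$data
      fit <- glm(new_formula, family = quasibinomial(), data = dat,
                 weights = .w)
      phi <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
      current <- structure(
        list(fit = fit, dispersion = phi, data = dat, formula = new_formula),
        class = "fr_glm"
      )
      break
    }
    new_formula <- stats::reformulate(remaining, response = "proportion")
    current <- fit_quasibinomial_formula(current$data, new_formula)
    eliminated <- c(eliminated, drop_term)
  }
  attr(current, "eliminated") <- eliminated
  current
}

# refit on already-prepared data (keeps factor coding stable)
fit_quasibinomial_formula <- function(dat, formula) {
  ctr <- lapply(glm_factors[glm_factors %in% all.vars(formula)],
                function(f) "contr.sum")
  names(ctr) <- glm_factors[glm_factors %in% all.vars(formula)]
  fit <- glm(formula, family = quasibinomial(), data = dat,
             weights = .w, contrasts = ctr,
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  phi <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
  structure(
    list(fit = fit, dispersion = phi, data = dat, formula = formula),
    class = "fr_glm"
  )
}

#' Retained model terms
#'
#' @param model An `fr_glm`.
#' @return Character vector of term labels in the model.
#' @export
retained_terms <- function(model) {
  attr(terms(model$fit), "term.labels")
}

#' Wald contrast of density slopes between temperatures within a sex
#'
#' Tests whether the (logit-scale) slope of consumption on prey density
#' differs between two temperatures for a given sex, averaging over the
#' remaining factors — the explicit post-hoc contrast behind a
#' sex x temperature x density interaction. The contrast vector is built
#' numerically from the model matrix (slopes are exact since density enters
#' linearly), and its variance uses the dispersion-scaled quasibinomial
#' covariance, so the standard error scales with `sqrt(phi)`.
#'
#' @param model An `fr_glm` whose model contains the
#'   sex x temperature x density interaction.
#' @param sex The sex level at which to compare slopes.
#' @param temperatures Length-2 vector of temperature levels (defaults to
#'   the two levels in the data, low minus high computed as first minus
#'   second).
#' @return A one-row tibble: `sex`, `estimate` (slope difference,
#'   temperature 1 minus temperature 2), `std.error`, `statistic`,
#'   `p.value`.
#' @export
density_slope_contrast <- function(model, sex, temperatures = NULL) {
  stopifnot(inherits(model, "fr_glm"))
  labels <- retained_terms(model)
  has_3way <- any(vapply(term_vars(labels), function(v) {
    all(c("sex", "temperature", "density") %in% v)
  }, logical(1)))
  if (!has_3way) {
    abort("The model does not contain the sex x temperature x density interaction.")
  }
  dat <- model$data
  sex_levels <- levels(dat$sex)
  if (!as.character(sex) %in% sex_levels) {
    abort(paste0("Unknown sex level `", sex, "`."))
  }
  temp_levels <- levels(dat$temperature)
  if (is.null(temperatures)) temperatures <- temp_levels
  temperatures <- as.character(temperatures)
  if (length(temperatures) != 2 || !all(temperatures %in% temp_levels)) {
    abort("`temperatures` must be two levels present in the data.")
  }
  sal_levels <- if ("salinity" %in% names(dat)) levels(dat$salinity) else NA
  slope_vec <- function(temp) {
    grid0 <- expand.grid(sex = factor(sex, levels = sex_levels),
                         temperature = factor(temp, levels = temp_levels),
                         salinity = factor(sal_levels, levels = sal_levels),
                         density = 0)
    grid1 <- transform(grid0, density = 1)
    tt <- stats::delete.response(terms(model$fit))
    x0 <- model.matrix(tt, grid0, contrasts.arg = attr(model.matrix(model$fit), "contrasts"))
    x1 <- model.matrix(tt, grid1, contrasts.arg = attr(model.matrix(model$fit), "contrasts"))
    colMeans(x1 - x0)  # marginal over salinity; exact: density is linear
  }
  L <- slope_vec(temperatures[1]) - slope_vec(temperatures[2])
  cf <- coef(model$fit)
  vc <- vcov(model$fit)  # already phi-scaled for quasibinomial
  est <- drop(L %*% cf)
  se <- drop(sqrt(L %*% vc %*% L))
  z <- est / se
  tibble::tibble(
    sex = as.character(sex),
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}
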