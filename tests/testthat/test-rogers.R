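test_that("lambert_w_exp satisfies the defining identity and matches pracma", {
  z <- c(-200, -30.5, -10, -1, 0, 0.5, 1, 2, 10, 100, 700, 5000)
  w <- lambert_w_exp(z)
  mid <- z > -600  # w + log(w) defined
  expect_lt(max(abs(w[mid] + log(w[mid]) - z[mid])), 1e-12)
  library(pracma)
  ref <- vapply(z[z <= 700], function(zz) pracma::lambertWp(exp(zz)),
                numeric(1))
  expect_lt(max(abs(w[z <= 700] - ref) / pmax(ref, 1e-300)), 1e-12)
})

test_that("expected kills solve the fixed point and match the bisection oracle", {
  # frozen value computed by uniroot bracketing on [0, N0] before the solver
  expect_equal(rogers_expected_kills(64, 1.584, 0.032, 1),
               22.638060877354, tolerance = 1e-10)

  set.seed(202)
  for (i in 1:200) {
    n0 <- sample(1:128, 1)
    a <- runif(1, 0.01, 5)
    h <- runif(1, 0.001, 0.5)
    tt <- runif(1, 0.1, 3)
    ne <- rogers_expected_kills(n0, a, h, tt)
    oracle <- bisect_rogers(n0, a, h, tt)
    expect_lt(abs(ne - oracle) / max(oracle, 1e-12), 1e-9)
    # residual of the implicit equation
    expect_lt(abs(ne - n0 * (1 - exp(a * (ne * h - tt)))), 1e-10 * n0)
  }
})

test_that("expected kills honour limits and bounds", {
  expect_equal(rogers_expected_kills(0, 1, 0.1, 1), 0)
  expect_equal(rogers_expected_kills(10, 0, 0.1, 1), 0)
  expect_equal(rogers_expected_kills(10, 1, 0.1, 0), 0)
  # h = 0 reduces to exponential depletion
  expect_equal(rogers_expected_kills(10, 1.3, 0, 2), 10 * (1 - exp(-1.3 * 2)),
               tolerance = 1e-12)
  expect_error(rogers_expected_kills(10, -1, 0.1, 1), ">= 0")
  expect_error(rogers_expected_kills(10, 1, -0.1, 1), ">= 0")

  set.seed(203)
  for (i in 1:100) {
    n0 <- sample(1:100, 1); a <- runif(1, 0, 4); h <- runif(1, 0, 0.5)
    tt <- runif(1, 0, 2)
    ne <- rogers_expected_kills(n0, a, h, tt)
    expect_gte(ne, 0)
    expect_lte(ne, min(n0, tt / max(h, 1e-12) + 1))
  }
})

test_that("expected kills are monotone in each argument", {
  set.seed(204)
  for (i in 1:50) {
    n0 <- sample(2:100, 1); a <- runif(1, 0.05, 3); h <- runif(1, 0.01, 0.4)
    tt <- runif(1, 0.2, 2); eps <- 1e-4
    ne <- rogers_expected_kills(n0, a, h, tt)
    expect_gte(rogers_expected_kills(n0 + 1, a, h, tt), ne - 1e-12)
    expect_gte(rogers_expected_kills(n0, a + eps, h, tt), ne - 1e-12)
    expect_gte(rogers_expected_kills(n0, a, h, tt + eps), ne - 1e-12)
    expect_lte(rogers_expected_kills(n0, a, h + eps, tt), ne + 1e-12)
  }
})

test_that("the binomial likelihood is additive, clamped and grid-optimal", {
  one <- toy_trials(n_killed = 5, n_initial = 16)
  two <- dplyr::bind_rows(one, one)
  expect_equal(rogers_nll(two, 1.2, 0.05), 2 * rogers_nll(one, 1.2, 0.05))

  # total depletion under a tiny attack rate stays finite via the clamp
  depleted <- toy_trials(n_killed = 16, n_initial = 16)
  expect_true(is.finite(rogers_nll(depleted, 1e-6, 0.01)))

  # a trial killed at (rounded) expectation beats coarse perturbations
  a0 <- 1.4; h0 <- 0.06
  ne <- rogers_expected_kills(32, a0, h0, 1)
  tr <- toy_trials(n_killed = round(ne), n_initial = 32)
  base <- rogers_nll(tr, a0, h0)
  for (fa in c(0.5, 2)) for (fh in c(0.5, 2)) {
    expect_gt(rogers_nll(tr, a0 * fa, h0 * fh), base)
  }

  expect_error(
    rogers_nll(dplyr::mutate(toy_trials(), is_control = TRUE,
                             sex = NA_character_), 1, 0.1),
    "Control rows"
  )
})

test_that("fit_rogers recovers generating parameters and is deterministic", {
  a0 <- 1.5; h0 <- 0.03
  tr <- simulate_group(25, attack_rate = a0, handling_time = h0, seed = 301)
  expect_equal(nrow(tr), 200)
  fit <- fit_rogers(tr)
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[1] - a0), 3 * td$std.error[1])
  expect_lt(abs(td$estimate[2] - h0), 3 * td$std.error[2])

  tr2 <- simulate_group(5, attack_rate = 1, handling_time = 0.2, seed = 302)
  f1 <- fit_rogers(tr2)
  f2 <- fit_rogers(tr2)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the optimum beats a 50x50 log-grid around it", {
  tr <- simulate_group(5, attack_rate = 1.2, handling_time = 0.08, seed = 303)
  fit <- fit_rogers(tr)
  nll_opt <- rogers_nll(tr, fit$attack_rate, fit$handling_time)
  grid_a <- fit$attack_rate * exp(seq(-0.5, 0.5, length.out = 50))
  grid_h <- fit$handling_time * exp(seq(-0.5, 0.5, length.out = 50))
  grid_nll <- outer(grid_a, grid_h,
                    Vectorize(function(a, h) rogers_nll(tr, a, h)))
  expect_lte(nll_opt, min(grid_nll) + 1e-6)
})

test_that("degenerate inputs raise informative fitting errors", {
  zeros <- toy_trials(n_killed = c(0, 0, 0))
  expect_error(fit_rogers(zeros), "not identifiable")
  single <- toy_trials(n_killed = c(1, 2), n_initial = c(8, 8))
  expect_warning(fit_rogers(single), "ill-posed")
  expect_error(fit_rogers(toy_trials(), init = c(-1, 0.1)), "positive")
})

test_that("impact metrics are exact arithmetic on fitted parameters", {
  fake <- structure(
    list(attack_rate = 2, handling_time = 0.5, converged = TRUE),
    class = "fr_fit"
  )
  m <- impact_metrics(fake)
  expect_equal(m$max_feed_rate, 2)
  expect_equal(m$frr, 4)

  tr <- simulate_group(10, attack_rate = 0.838, handling_time = 0.156,
                       seed = 304)
  fit <- fit_rogers(tr)
  m2 <- impact_metrics(fit)
  expect_identical(m2$max_feed_rate, 1 / fit$handling_time)
  expect_identical(m2$frr, fit$attack_rate / fit$handling_time)

  fake$converged <- FALSE
  expect_error(impact_metrics(fake), "converged")
  fake$converged <- TRUE; fake$handling_time <- 0
  expect_error(impact_metrics(fake), "undefined")
})

test_that("refitting data generated at the default scenario recovers each group", {
  # 10x the default replication, binomial generator
  pars <- default_fr_params()
  design <- fr_design(replicates_predator = 50, replicates_control = 0)
  tr <- simulate_experiment(design, fr_scenario(), seed = 305)
  covered <- 0L
  for (i in seq_len(nrow(pars))) {
    g <- dplyr::filter(tr, .data$sex == pars$sex[i],
                       .data$temperature == pars$temperature[i],
                       .data$salinity == pars$salinity[i])
    fit <- fit_rogers(g)
    expect_lt(abs(fit$attack_rate - pars$attack_rate[i]) /
                pars$attack_rate[i], 0.15)
    expect_lt(abs(fit$handling_time - pars$handling_time[i]) /
                pars$handling_time[i], 0.15)
    bb <- bootstrap_fit(g, n_boot = 200, seed = 306 + i, fit = fit)
    covered <- covered +
      (bb$param_ci$lo95[1] <= pars$attack_rate[i] &&
         pars$attack_rate[i] <= bb$param_ci$hi95[1]) +
      (bb$param_ci$lo95[2] <= pars$handling_time[i] &&
         pars$handling_time[i] <= bb$param_ci$hi95[2])
  }
  # 16 simultaneous 95% intervals: expect a small number of misses
  expect_gte(covered, 12L)
})
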