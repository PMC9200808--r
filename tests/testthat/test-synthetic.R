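test_that("trial generators honour degenerate limits", {
  expect_equal(simulate_trial_mechanistic(10, 0, 0.1, seed = 1), 0L)
  expect_equal(simulate_trial_mechanistic(0, 2, 0.1, seed = 1), 0L)
  # huge attack rate, no handling, long duration: total depletion
  expect_equal(simulate_trial_mechanistic(20, 1e6, 0, duration = 10, seed = 2),
               20L)
  # zero expected fraction killed: always zero
  expect_equal(simulate_trial_binomial(10, 0, 0.1, seed = 3), 0L)
  expect_error(simulate_trial_mechanistic(-1, 1, 0.1), ">= 0")
  expect_error(simulate_trial_binomial(10, -1, 0.1), ">= 0")
})

test_that("generators are reproducible given a seed", {
  expect_identical(simulate_trial_mechanistic(32, 1.5, 0.03, seed = 42),
                   simulate_trial_mechanistic(32, 1.5, 0.03, seed = 42))
  expect_identical(simulate_trial_binomial(32, 1.5, 0.03, seed = 42),
                   simulate_trial_binomial(32, 1.5, 0.03, seed = 42))
  t1 <- simulate_experiment(paper_design(), fr_scenario(), seed = 9)
  t2 <- simulate_experiment(paper_design(), fr_scenario(), seed = 9)
  expect_identical(t1, t2)
})

test_that("mechanistic mean tracks the Rogers closed form", {
  # the event-driven forager is a finite-population process: its mean sits
  # within ~1% of the mean-field Rogers solution (a small demographic /
  # discreteness bias that does not vanish with more replicates)
  n0 <- 32; a <- 1.5; h <- 0.03
  set.seed(401)
  kills <- vapply(1:10000, function(i)
    simulate_trial_mechanistic(n0, a, h), integer(1))
  target <- rogers_expected_kills(n0, a, h, 1)
  expect_lt(abs(mean(kills) - target) / target, 0.025)
})

test_that("binomial generator mean matches its deterministic target", {
  n0 <- 32; a <- 1.5; h <- 0.03
  target <- rogers_expected_kills(n0, a, h, 1)
  set.seed(402)
  kills <- vapply(1:10000, function(i)
    simulate_trial_binomial(n0, a, h), integer(1))
  se <- stats::sd(kills) / sqrt(length(kills))
  expect_lt(abs(mean(kills) - target), 3 * se)
})

test_that("mechanistic and binomial generators agree in mean", {
  # the binomial generator's mean is the mean-field closed form exactly, so
  # the gap between the two generators is the forager's demographic bias:
  # ~1% in depletion-driven regimes, up to ~5% when handling dominates
  set.seed(403)
  for (pars in list(c(32, 1.5, 0.03, 0.025), c(16, 0.8, 0.15, 0.075))) {
    mech <- vapply(1:4000, function(i)
      simulate_trial_mechanistic(pars[1], pars[2], pars[3]), integer(1))
    binm <- vapply(1:4000, function(i)
      simulate_trial_binomial(pars[1], pars[2], pars[3]), integer(1))
    expect_lt(abs(mean(mech) - mean(binm)) / mean(binm), pars[4])
  }
})

test_that("simulate_experiment fills the design and respects controls", {
  tr <- simulate_experiment(paper_design(), fr_scenario(), seed = 404)
  expect_equal(nrow(tr), 416)
  expect_false(anyNA(tr$n_killed))
  expect_true(all(tr$n_killed <= tr$n_initial))

  no_bg <- simulate_experiment(
    paper_design(), flat_scenario(background_mortality = 0), seed = 405
  )
  expect_true(all(no_bg$n_killed[no_bg$is_control] == 0L))

  # default background mortality keeps control survival above 99% with high
  # probability: 1548 control prey at rate 0.005, P(mortality > 1%) ~ 0.004
  for (s in 406:410) {
    tr_s <- simulate_experiment(paper_design(), fr_scenario(), seed = s)
    ctrl <- tr_s[tr_s$is_control, ]
    expect_gt(1 - sum(ctrl$n_killed) / sum(ctrl$n_initial), 0.99)
  }
})

test_that("a missing parameter cell is reported by name", {
  pars <- default_fr_params()[-3, ]  # drop M/22/15
  expect_error(
    simulate_experiment(paper_design(), fr_scenario(pars), seed = 1),
    "M/22/15"
  )
})

test_that("scenario validation rejects bad parameters", {
  bad <- default_fr_params()
  bad$attack_rate[1] <- -1
  expect_error(fr_scenario(bad), "> 0")
  expect_error(fr_scenario(background_mortality = 1), "\\[0, 1\\)")
  expect_error(fr_scenario(default_fr_params()[, 1:3]), "lacks column")
})

test_that("the full pipeline recovers generating parameters across replications", {
  # median relative bias of (a, h) over repeated experiments; single group
  # per experiment at the default male 16/15 parameters
  bias_at <- function(reps, n_sims, seed0) {
    out <- vapply(seq_len(n_sims), function(i) {
      tr <- simulate_group(reps, attack_rate = 1.584, handling_time = 0.032,
                           seed = seed0 + i)
      fit <- fit_rogers(tr)
      c(abs(fit$attack_rate - 1.584) / 1.584,
        abs(fit$handling_time - 0.032) / 0.032)
    }, numeric(2))
    apply(out, 1, stats::median)
  }
  b1 <- bias_at(5, 25, 500)    # design-scale replication
  b10 <- bias_at(50, 25, 600)  # 10x replication
  expect_lt(b1[1], 0.15)
  expect_lt(b1[2], 0.15)
  expect_lt(b10[1], 0.05)
  expect_lt(b10[2], 0.05)
})
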