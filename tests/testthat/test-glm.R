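pred_trials <- function(seed, scenario = fr_scenario(),
                        design = fr_design(replicates_control = 0)) {
  simulate_experiment(design, scenario, seed = seed)
}

test_that("quasibinomial coefficients equal the binomial fit's bitwise", {
  tr <- pred_trials(701)
  m <- fit_quasibinomial(tr)
  dat <- m$data
  ctr <- list(sex = "contr.sum", temperature = "contr.sum",
              salinity = "contr.sum")
  bin <- glm(proportion ~ sex * temperature * salinity * density,
             family = binomial(), data = dat, weights = .w, contrasts = ctr,
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  expect_identical(unname(coef(m)), unname(coef(bin)))
})

test_that("row duplication leaves coefficients unchanged", {
  tr <- pred_trials(702)
  m1 <- fit_quasibinomial(tr)
  m2 <- fit_quasibinomial(dplyr::bind_rows(tr, tr))
  expect_equal(unname(coef(m1)), unname(coef(m2)), tolerance = 1e-10)
})

test_that("no-effect data give null factor coefficients and unit dispersion", {
  tr <- pred_trials(703, scenario = flat_scenario(1, 0.1))
  m <- fit_quasibinomial(tr)
  td <- tidy(m)
  factor_terms <- td[grepl("sex|temperature|salinity", td$term) &
                       !grepl("density", td$term), ]
  expect_true(all(abs(factor_terms$estimate) <
                    3 * factor_terms$std.error))
  phis <- vapply(1:20, function(i) {
    fit_quasibinomial(pred_trials(7030 + i,
                                  scenario = flat_scenario(1, 0.1)))$dispersion
  }, numeric(1))
  expect_lt(abs(mean(phis) - 1), 0.1)
})

test_that("Type III deviance table matches the car oracle", {
  tr <- pred_trials(704)
  m <- fit_quasibinomial(tr)
  mine <- anova_type3(m)
  library(car)
  ref <- car::Anova(m$fit, type = 3, test.statistic = "F")
  ref <- ref[rownames(ref) != "Residuals", ]
  expect_equal(mine$term, rownames(ref))
  expect_equal(mine$F, ref[["F values"]], tolerance = 1e-8)
  expect_equal(mine$p.value, ref[["Pr(>F)"]], tolerance = 1e-8)
  expect_true(all(mine$df == ref$Df))
  expect_true(all(mine$p.value >= 0 & mine$p.value <= 1))
})

test_that("Type III equals Type I where the classical equivalence is exact", {
  # balanced factorial without the density covariate: the highest-order term
  # is the same contrast in both decompositions; lower-order terms agree
  # only approximately in a GLM (the IRLS metric varies with cell means)
  set.seed(705)
  d <- tidyr::expand_grid(sex = c("M", "F"), temperature = c(16, 22),
                          salinity = c(15, 10), rep = 1:12)
  d$n_initial <- 8L
  d$n_killed <- rbinom(nrow(d), 8L,
                       stats::plogis(-0.4 + 0.6 * (d$sex == "M") +
                                       0.4 * (d$sex == "M") *
                                       (d$temperature == 22) *
                                       (d$salinity == 10)))
  d$duration <- 1
  d$is_control <- FALSE
  m <- fit_quasibinomial(d, proportion ~ sex * temperature * salinity)
  t3 <- anova_type3(m)
  t1 <- anova(m$fit, test = "F")
  expect_equal(t3$F[nrow(t3)], t1$F[nrow(t1)], tolerance = 1e-6)
  expect_equal(t3$F, t1$F[-1], tolerance = 0.15)
})

test_that("aliased and constant-factor models are rejected", {
  tr <- pred_trials(706)
  tr$salinity <- ifelse(tr$temperature == 16, 15, 10)  # confounded
  m <- fit_quasibinomial(tr, proportion ~ sex + temperature + salinity)
  expect_error(anova_type3(m), "Aliased")
  tr2 <- pred_trials(707)
  tr2$salinity <- 15
  expect_error(fit_quasibinomial(tr2), "constant")
})

test_that("backward elimination respects marginality and significance", {
  # strong effects only: model returned unchanged
  tr <- pred_trials(708)
  m_small <- fit_quasibinomial(tr, proportion ~ sex + density)
  red <- backward_select(m_small)
  expect_setequal(retained_terms(red), c("sex", "density"))
  expect_length(attr(red, "eliminated"), 0)

  # pure noise in the factors: collapses to density alone
  tr_null <- pred_trials(709, scenario = flat_scenario(1, 0.1))
  m_null <- fit_quasibinomial(tr_null,
                              proportion ~ sex * temperature + density)
  red_null <- backward_select(m_null)
  expect_true("density" %in% retained_terms(red_null))
  expect_false(any(grepl("temperature", retained_terms(red_null))))

  # retained interactions protect their main effects
  m_full <- fit_quasibinomial(pred_trials(710))
  red_full <- backward_select(m_full)
  kept <- retained_terms(red_full)
  for (t in kept[grepl(":", kept)]) {
    for (v in strsplit(t, ":")[[1]]) expect_true(v %in% kept)
  }
  expect_true(all(c("sex", "density") %in% kept))
})

test_that("slope contrasts are zero under mirrored data and scale with sqrt(phi)", {
  # duplicate one temperature's data into the other: all temperature terms
  # vanish by symmetry, so the between-temperature slope contrast is 0
  tr <- pred_trials(711) |> dplyr::filter(temperature == 16)
  mirrored <- dplyr::bind_rows(tr, dplyr::mutate(tr, temperature = 22))
  m <- fit_quasibinomial(mirrored)
  cm <- density_slope_contrast(m, "M")
  expect_lt(abs(cm$estimate), 1e-10)

  tr2 <- pred_trials(712)
  m2 <- fit_quasibinomial(tr2)
  c2 <- density_slope_contrast(m2, "F")
  bin <- glm(m2$formula, family = binomial(), data = m2$data, weights = .w,
             contrasts = list(sex = "contr.sum", temperature = "contr.sum",
                              salinity = "contr.sum"))
  phi <- m2$dispersion
  # rebuild the same contrast against the unit-dispersion fit
  m2_bin <- m2
  m2_bin$fit <- bin
  c2_bin <- density_slope_contrast(m2_bin, "F")
  # the two IRLS solves agree to optimizer precision, not bitwise
  expect_equal(c2$std.error / c2_bin$std.error, sqrt(phi), tolerance = 1e-5)

  m3 <- fit_quasibinomial(tr2, proportion ~ sex + density)
  expect_error(density_slope_contrast(m3, "M"), "does not contain")
  expect_error(density_slope_contrast(m2, "X"), "Unknown sex")
})

test_that("a sex-specific temperature-density interaction is detected in males only", {
  # the default scenario carries the interaction (male handling time rises
  # with warming; females barely change): the male slope contrast should be
  # significant far more often than the female one
  n_sims <- 60
  res <- vapply(seq_len(n_sims), function(i) {
    tr <- pred_trials(7200 + i)
    m <- fit_quasibinomial(tr)
    c(density_slope_contrast(m, "M")$p.value,
      density_slope_contrast(m, "F")$p.value)
  }, numeric(2))
  male_rate <- mean(res[1, ] < 0.05)
  female_rate <- mean(res[2, ] < 0.05)
  expect_gte(male_rate, 0.8)
  expect_lt(female_rate, 0.3)
})
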