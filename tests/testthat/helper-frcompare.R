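# Shared fixtures and independent oracles for the test suite.

paper_design <- function(...) fr_design(...)

# independent 1-D root-bracketing oracle for the random predator fixed point
# f(Ne) = Ne - N0 (1 - exp(a (Ne h - T))) on [0, N0]
bisect_rogers <- function(n0, a, h, tt) {
  if (n0 == 0 || a == 0 || tt == 0) return(0)
  f <- function(ne) ne - n0 * (1 - exp(a * (ne * h - tt)))
  stats::uniroot(f, lower = 0, upper = n0, tol = 1e-13,
                 extendInt = "no")$root
}

# independent tricube local-linear LOWESS oracle (no robustness iterations),
# evaluated at the observed x
hand_lowess <- function(x, y, span) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  r <- ceiling(span * n)
  fitted <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    hmax <- sort(d, partial = r)[r]
    w <- (1 - pmin(d / max(hmax, 1e-300), 1)^3)^3
    keep <- w > 0
    xm <- cbind(1, x[keep] - x[i])
    wk <- w[keep]
    beta <- solve(crossprod(xm, wk * xm), crossprod(xm, wk * y[keep]))
    beta[1]
  }, numeric(1))
  list(x = x, y = fitted)
}

# a small valid predator trial table built in code
toy_trials <- function(n_killed = c(1, 2, 3), n_initial = c(2, 4, 8),
                       sex = "M", temperature = 16, salinity = 15) {
  tibble::tibble(
    sex = sex, temperature = temperature, salinity = salinity,
    n_initial = as.integer(n_initial), n_killed = as.integer(n_killed),
    duration = 1, is_control = FALSE
  )
}

# scenario with one shared parameter set across all cells (null structure)
flat_scenario <- function(attack_rate = 1, handling_time = 0.1,
                          background_mortality = 0.005) {
  pars <- default_fr_params()
  pars$attack_rate <- attack_rate
  pars$handling_time <- handling_time
  fr_scenario(pars, background_mortality = background_mortality)
}
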