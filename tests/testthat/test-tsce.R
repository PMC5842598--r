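# independently coded pointwise evaluator of the susceptible trajectory:
# pubertal ramp times the factors of all events at or before t
oracle_X <- function(profile, t) {
  vapply(t, function(ti) {
    base <- if (ti < profile$age_menarche) 0
    else if (profile$ramp_years > 0 &&
             ti < profile$age_menarche + profile$ramp_years)
      profile$plateau_cells * (ti - profile$age_menarche) / profile$ramp_years
    else profile$plateau_cells
    f <- profile$parity_factor ^ sum(profile$birth_ages <= ti)
    if (!is.na(profile$age_menopause) && ti >= profile$age_menopause)
      f <- f * profile$menopause_factor
    base * f
  }, 0)
}

test_that("trajectory matches an independent piecewise evaluator", {
  profiles <- list(
    reproductive_profile(),                                   # defaults
    reproductive_profile(age_menarche = 12, ramp_years = 0,
                         age_menopause = NA),                 # step, no pause
    reproductive_profile(age_menarche = 13, birth_ages = c(24, 27, 33),
                         age_menopause = 48, ramp_years = 4,
                         parity_factor = 0.9, menopause_factor = 0.4),
    reproductive_profile(birth_ages = c(14.5, 16),            # births in ramp
                         ramp_years = 6, parity_factor = 0.85))
  grid <- seq(0, 90, by = 0.25)
  for (pr in profiles) {
    traj <- build_trajectory(pr)
    expect_equal(trajectory_at(traj, grid), oracle_X(pr, grid))
  }
  # degenerate ramp is a step from 0 to the plateau at menarche
  pr0 <- reproductive_profile(ramp_years = 0, age_menopause = NA)
  tr0 <- build_trajectory(pr0)
  expect_equal(trajectory_at(tr0, pr0$age_menarche - 1e-9), 0)
  expect_equal(trajectory_at(tr0, pr0$age_menarche), pr0$plateau_cells)
  # two births compose multiplicatively before menopause
  pr2 <- reproductive_profile(birth_ages = c(25, 30), parity_factor = 0.9,
                              age_menopause = 50)
  expect_equal(trajectory_at(build_trajectory(pr2), 45),
               pr2$plateau_cells * 0.81)
})

test_that("reproductive profiles are validated", {
  expect_error(reproductive_profile(age_menarche = 13, birth_ages = 12),
               "menarche")
  expect_error(reproductive_profile(age_menopause = 10), "menarche")
  expect_error(reproductive_profile(parity_factor = 0), "0, 1")
  expect_error(reproductive_profile(menopause_factor = 1.2), "0, 1")
})

test_that("F_of_t integrates the trajectory exactly", {
  pr <- reproductive_profile(age_menarche = 13, birth_ages = c(24, 29),
                             age_menopause = 49, ramp_years = 5)
  traj <- build_trajectory(pr)
  expect_equal(F_of_t(traj, 12), 0)          # nothing accrues before menarche
  # constant X = N from menarche with no ramp: F(t) = N (t - m)
  pr0 <- reproductive_profile(ramp_years = 0, age_menopause = NA,
                              plateau_cells = 500)
  tr0 <- build_trajectory(pr0)
  expect_equal(F_of_t(tr0, 40), 500 * (40 - pr0$age_menarche))
  # trapezoid oracle at step 1e-3 years on an irregular profile
  for (t_end in c(20, 35, 60, 85)) {
    s <- seq(0, t_end, by = 1e-3)
    x <- trajectory_at(traj, s)
    trap <- sum((x[-1] + x[-length(x)]) / 2) * 1e-3
    expect_equal(F_of_t(traj, t_end), trap, tolerance = 1e-5)
  }
  # F is nondecreasing
  grid <- seq(0, 90, by = 0.5)
  expect_true(all(diff(F_of_t(traj, grid)) >= -1e-9))
})

test_that("approx_hazard is bilinear in the mutation rates and uses the lag", {
  pr <- reproductive_profile()
  traj <- build_trajectory(pr)
  t <- c(20, 40, 60, 80)
  p0 <- tsce_params(mu1 = 0, mu2 = 1e-3)
  expect_equal(approx_hazard(p0, traj, t), rep(0, 4))
  p <- tsce_params(mu1 = 1e-5, mu2 = 1e-5, lag_tau = 0)
  p2 <- tsce_params(mu1 = 2e-5, mu2 = 1e-5, lag_tau = 0)
  expect_equal(approx_hazard(p2, traj, t), 2 * approx_hazard(p, traj, t))
  # constant X = N, no lag: hazard slope is mu1 mu2 N past menarche
  pr0 <- reproductive_profile(ramp_years = 0, age_menopause = NA,
                              plateau_cells = 1000)
  tr0 <- build_trajectory(pr0)
  h <- approx_hazard(p, tr0, c(20, 30))
  expect_equal(diff(h) / 10, p$mu1 * p$mu2 * 1000)
  # lag shifts the hazard in time
  pl <- tsce_params(mu1 = 1e-5, mu2 = 1e-5, lag_tau = 5)
  expect_equal(approx_hazard(pl, tr0, t), approx_hazard(p, tr0, t - 5))
  # hazard is nondecreasing for nonnegative X
  grid <- seq(0, 90, 0.5)
  expect_true(all(diff(approx_hazard(pl, traj, grid)) >= -1e-15))
})

test_that("expansion_hazard matches closed form and quadrature", {
  pr0 <- reproductive_profile(age_menarche = 13, ramp_years = 0,
                              age_menopause = NA, plateau_cells = 100)
  tr0 <- build_trajectory(pr0)
  # alpha2 == beta2 collapses the kernel to 1: identical to approx_hazard
  p_eq <- tsce_params(mu1 = 1e-3, mu2 = 1e-4, alpha2 = 0.3, beta2 = 0.3,
                      lag_tau = 5)
  t <- c(10, 25, 50, 80)
  expect_identical(expansion_hazard(p_eq, tr0, t),
                   approx_hazard(p_eq, tr0, t))
  # constant X = N, growth g, lag 0: mu1 mu2 N (e^{g(t-m)} - 1)/g
  for (g in c(0.02, 0.1, -0.05)) {
    p <- tsce_params(mu1 = 1e-3, mu2 = 1e-4, alpha2 = max(g, 0),
                     beta2 = max(-g, 0), lag_tau = 0)
    tt <- c(30, 60)
    closed <- p$mu1 * p$mu2 * 100 * (exp(g * (tt - 13)) - 1) / g
    expect_equal(expansion_hazard(p, tr0, tt), closed, tolerance = 1e-10)
  }
  # piecewise trajectory vs trapezoid quadrature of the kernel integral
  pr <- reproductive_profile(birth_ages = c(26, 31), age_menopause = 50)
  traj <- build_trajectory(pr)
  p <- tsce_params(mu1 = 1e-6, mu2 = 1e-6, alpha2 = 0.32, beta2 = 0.25,
                   lag_tau = 5)
  g <- p$alpha2 - p$beta2
  for (t_end in c(40, 70)) {
    u <- t_end - p$lag_tau
    s <- seq(0, u, by = 1e-3)
    f <- trajectory_at(traj, s) * exp(g * (u - s))
    trap <- sum((f[-1] + f[-length(f)]) / 2) * 1e-3
    expect_equal(expansion_hazard(p, traj, t_end),
                 p$mu1 * p$mu2 * trap, tolerance = 1e-4)
  }
})

test_that("simulator is seed-deterministic and silent when mu1 = 0", {
  pr <- reproductive_profile(plateau_cells = 100)
  p0 <- tsce_params(mu1 = 0, mu2 = 1e-3)
  out0 <- simulate_tsce(p0, pr, n_subjects = 50, horizon = 80, seed = 1)
  expect_true(all(is.na(out0$tumor_age)))
  expect_true(all(out0$n_first_mutations == 0))
  p <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, alpha2 = 0.1, beta2 = 0.12,
                   lag_tau = 5)
  a <- simulate_tsce(p, pr, n_subjects = 200, horizon = 80, seed = 42)
  b <- simulate_tsce(p, pr, n_subjects = 200, horizon = 80, seed = 42)
  expect_identical(a, b)
  c_ <- simulate_tsce(p, pr, n_subjects = 200, horizon = 80, seed = 43)
  expect_false(identical(a$tumor_age, c_$tumor_age))
  # tumors never precede menarche + lag
  expect_true(all(is.na(a$tumor_age) |
                    a$tumor_age >= pr$age_menarche + p$lag_tau))
})

test_that("no-expansion simulation matches the analytic survival curve", {
  pr <- reproductive_profile(plateau_cells = 100)
  p <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, alpha2 = 0, beta2 = 0,
                   lag_tau = 5)
  traj <- build_trajectory(pr)
  n <- 4000   # scaled-down unit check; the full-size run lives in acceptance
  sim <- simulate_tsce(p, pr, n_subjects = n, horizon = 80, seed = 9)
  for (a in c(40, 60, 80)) {
    p_th <- cumulative_incidence_approx(p, traj, a)
    p_emp <- mean(!is.na(sim$tumor_age) & sim$tumor_age <= a)
    se <- sqrt(p_th * (1 - p_th) / n)
    expect_lt(abs(p_emp - p_th), 3 * se)
  }
})

test_that("clonal growth increases cumulative incidence (coupled seeds)", {
  pr <- reproductive_profile(plateau_cells = 100)
  base <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, alpha2 = 0, beta2 = 0,
                      lag_tau = 5)
  grow <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, alpha2 = 0.1, beta2 = 0,
                      lag_tau = 5)
  s0 <- simulate_tsce(base, pr, n_subjects = 1500, horizon = 80, seed = 21)
  s1 <- simulate_tsce(grow, pr, n_subjects = 1500, horizon = 80, seed = 21)
  inc0 <- mean(!is.na(s0$tumor_age) & s0$tumor_age <= 70)
  inc1 <- mean(!is.na(s1$tumor_age) & s1$tumor_age <= 70)
  expect_gt(inc1, inc0)
})

test_that("empirical_hazard reproduces hand-computed person-years", {
  # three subjects: tumors at 42 and 51, one censored at the horizon 80
  out <- structure(
    data.frame(subject_id = c("A", "B", "C"),
               tumor_age = c(42, 51, NA),
               n_first_mutations = c(1L, 2L, 0L),
               flagged = FALSE, stringsAsFactors = FALSE),
    class = c("tsce_cohort", "data.frame"), horizon = 80, seed = 1L)
  emp <- empirical_hazard(out)
  # bin 40-44: A contributes 2 years, B and C 5 each; one event
  expect_equal(emp$person_years[6], 12)
  expect_equal(emp$cases[6], 1)
  expect_equal(emp$rate[6], 1 / 12 * 1e5)
  # bin 50-54: B contributes 1 year, C 5; one event
  expect_equal(emp$person_years[8], 6)
  expect_equal(emp$rate[8], 1 / 6 * 1e5)
  # bin 75-79: only C, no events
  expect_equal(emp$person_years[13], 5)
  expect_equal(emp$rate[13], 0)
  # open bin beyond the horizon: no exposure, missing rate
  expect_equal(emp$person_years[14], 0)
  expect_true(is.na(emp$rate[14]))
  # no events anywhere -> all zero rates (where exposure exists)
  out0 <- out
  out0$tumor_age <- NA_real_
  emp0 <- empirical_hazard(out0)
  expect_true(all(emp0$rate[emp0$person_years > 0] == 0))
})

test_that("binned empirical rates track the analytic hazard", {
  pr <- reproductive_profile(plateau_cells = 100)
  p <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, alpha2 = 0, beta2 = 0,
                   lag_tau = 5)
  traj <- build_trajectory(pr)
  sim <- simulate_tsce(p, pr, n_subjects = 8000, horizon = 80, seed = 13)
  emp <- empirical_hazard(sim)
  # analytic counterpart of events/person-years: the average hazard over
  # the bin, i.e. the cumulative-hazard increment divided by the bin width
  hi <- pmin(ifelse(is.finite(emp$upper), emp$upper, 80), 80)
  analytic <- (cumulative_hazard_approx(p, traj, hi) -
                 cumulative_hazard_approx(p, traj, emp$lower)) /
    (hi - emp$lower) * 1e5
  # global Poisson goodness of fit across bins (a per-bin 3-SE band over a
  # dozen bins trips on routine single-bin fluctuations); expected counts
  # use the realized person-years
  expected <- analytic / 1e5 * emp$person_years
  ok <- emp$person_years > 0 & expected >= 5
  z2 <- (emp$cases[ok] - expected[ok])^2 / expected[ok]
  expect_lt(sum(z2), stats::qchisq(0.999, df = sum(ok)))
})

test_that("outcomes CSV carries censoring as empty fields", {
  pr <- reproductive_profile(plateau_cells = 100)
  p <- tsce_params(mu1 = 5e-3, mu2 = 2e-4)
  sim <- simulate_tsce(p, pr, n_subjects = 100, horizon = 80, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tsce_outcomes(sim, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 100)
  expect_equal(is.na(back$tumor_age), is.na(sim$tumor_age))
  expect_true(all(back$seed == 3))
})
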