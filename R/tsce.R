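#' Two-stage clonal-expansion (Moolgavkar) model of breast carcinogenesis
#'
#' Normal susceptible epithelial cells acquire a first mutation at rate
#' \code{mu1} per cell-year, founding intermediate clones whose cells divide
#' at rate \code{alpha2}, die or differentiate at rate \code{beta2}, and
#' acquire the second (malignant) mutation at rate \code{mu2}.  A malignant
#' cell becomes a detectable tumor after a deterministic lag.  The
#' susceptible population X(t) is not simulated at the cell level: it is a
#' deterministic piecewise-linear trajectory shaped by reproductive history
#' (zero before menarche, a linear ramp to a plateau, multiplicative
#' reductions at each birth and at menopause).  Writing F(t) for the
#' integral of X to age t, the hazard of the model is approximately
#' mu1 * mu2 * F(t), the form used throughout for analytic work; an extended
#' hazard with net clonal growth alpha2 - beta2 and a stochastic cell-level
#' simulator are provided alongside it.
#'
#' @name tsce
NULL

#' Parameters of the two-stage model
#'
#' \code{alpha1} and \code{beta1} (normal-cell division and death rates) are
#' carried for completeness but not used: the susceptible population is
#' prescribed deterministically by the reproductive profile.
#'
#' @param mu1 First mutation rate per susceptible cell per year.
#' @param mu2 Second (malignant) mutation rate per intermediate cell per
#'   year.
#' @param alpha2 Intermediate-cell division rate per year.
#' @param beta2 Intermediate-cell death/differentiation rate per year.
#' @param alpha1,beta1 Normal-cell division and death rates (not simulated).
#' @param lag_tau Deterministic lag in years between the first malignant
#'   cell and a detectable tumor.
#' @return A \code{tsce_params} object.
#' @export
tsce_params <- function(mu1 = 2.5e-6, mu2 = 2.5e-6, alpha2 = 0, beta2 = 0,
                        alpha1 = NA_real_, beta1 = NA_real_, lag_tau = 5) {
  vals <- c(mu1 = mu1, mu2 = mu2, alpha2 = alpha2, beta2 = beta2,
            lag_tau = lag_tau)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("mu1, mu2, alpha2, beta2 and lag_tau must be finite and >= 0")
  structure(list(mu1 = mu1, mu2 = mu2, alpha2 = alpha2, beta2 = beta2,
                 alpha1 = alpha1, beta1 = beta1, lag_tau = lag_tau),
            class = "tsce_params")
}

#' Reproductive profile shaping the susceptible-cell trajectory
#'
#' Defaults are illustrative, not estimates: a plateau of 1e7 susceptible
#' stem cells reached over a 5-year pubertal ramp from menarche at 13, a 5%
#' reduction per birth, and a halving at menopause (age 50).
#'
#' @param age_menarche Age at menarche in years; X(t) = 0 before it.
#' @param birth_ages Ordered ages at each birth (years); may be empty.
#' @param age_menopause Age at menopause, or \code{NA} for none.
#' @param plateau_cells Susceptible stem-cell count at maturity.
#' @param ramp_years Years from menarche to the plateau (0 = step).
#' @param parity_factor Multiplicative reduction of X at each birth, in
#'   (0, 1].
#' @param menopause_factor Multiplicative reduction at menopause, in (0, 1].
#' @return A \code{reproductive_profile} object.
#' @export
reproductive_profile <- function(age_menarche = 13,
                                 birth_ages = numeric(0),
                                 age_menopause = 50,
                                 plateau_cells = 1e7,
                                 ramp_years = 5,
                                 parity_factor = 0.95,
                                 menopause_factor = 0.5) {
  birth_ages <- sort(as.numeric(birth_ages))
  if (length(birth_ages) && min(birth_ages) <= age_menarche)
    stop("births must come after menarche")
  if (!is.na(age_menopause) && age_menopause <= age_menarche)
    stop("menopause must come after menarche")
  if (parity_factor <= 0 || parity_factor > 1 ||
      menopause_factor <= 0 || menopause_factor > 1)
    stop("parity_factor and menopause_factor must lie in (0, 1]")
  if (plateau_cells < 0 || ramp_years < 0)
    stop("plateau_cells and ramp_years must be >= 0")
  structure(list(age_menarche = age_menarche, birth_ages = birth_ages,
                 age_menopause = age_menopause,
                 plateau_cells = plateau_cells, ramp_years = ramp_years,
                 parity_factor = parity_factor,
                 menopause_factor = menopause_factor),
            class = "reproductive_profile")
}

#' Build the susceptible-cell trajectory X(t)
#'
#' X(t) is the pubertal ramp (0 before menarche, linear to the plateau over
#' \code{ramp_years}, constant after) multiplied by \code{parity_factor} for
#' every birth at or before t and by \code{menopause_factor} from menopause
#' on.  The result is piecewise linear and right-continuous, stored as
#' segments with an exact running integral so that F(t) and kernel
#' integrals can be evaluated in closed form.
#'
#' @param profile A \code{reproductive_profile}.
#' @return A \code{susceptible_trajectory}: data frame of segments
#'   (\code{t0}, \code{x0}, \code{slope}, \code{F0} = integral of X from 0
#'   to \code{t0}), the last segment extending to infinity.
#' @export
build_trajectory <- function(profile) {
  stopifnot(inherits(profile, "reproductive_profile"))
  m <- profile$age_menarche
  ramp_end <- m + profile$ramp_years
  ev <- c(0, m, ramp_end, profile$birth_ages,
          if (!is.na(profile$age_menopause)) profile$age_menopause)
  t0 <- sort(unique(ev))
  # multiplicative factor in force on [t, next event)
  factor_at <- function(t) {
    f <- profile$parity_factor ^ sum(profile$birth_ages <= t)
    if (!is.na(profile$age_menopause) && t >= profile$age_menopause)
      f <- f * profile$menopause_factor
    f
  }
  ramp_value <- function(t) {
    if (t < m) return(0)
    if (profile$ramp_years == 0 || t >= ramp_end) return(profile$plateau_cells)
    profile$plateau_cells * (t - m) / profile$ramp_years
  }
  ramp_slope <- function(t) {
    if (profile$ramp_years > 0 && t >= m && t < ramp_end)
      profile$plateau_cells / profile$ramp_years else 0
  }
  x0 <- vapply(t0, function(t) ramp_value(t) * factor_at(t), 0)
  slope <- vapply(t0, function(t) ramp_slope(t) * factor_at(t), 0)
  dt <- diff(t0)
  seg_area <- x0[-length(x0)] * dt + slope[-length(slope)] * dt^2 / 2
  F0 <- c(0, cumsum(seg_area))
  structure(data.frame(t0 = t0, x0 = x0, slope = slope, F0 = F0),
            class = c("susceptible_trajectory", "data.frame"),
            profile = profile)
}

#' Evaluate the susceptible-cell trajectory
#'
#' @param trajectory A \code{susceptible_trajectory}.
#' @param t Ages in years (>= 0).
#' @return X(t), vectorized.
#' @export
trajectory_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "susceptible_trajectory"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("ages must be >= 0")
  j <- findInterval(t, trajectory$t0)
  j[j == 0L] <- 1L
  trajectory$x0[j] + trajectory$slope[j] * (t - trajectory$t0[j])
}

#' Cumulative susceptible-cell exposure F(t)
#'
#' The integral of X from 0 to t, exact on the piecewise-linear segments.
#'
#' @inheritParams trajectory_at
#' @return F(t) in cell-years, vectorized.
#' @export
F_of_t <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "susceptible_trajectory"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("ages must be >= 0")
  j <- findInterval(t, trajectory$t0)
  j[j == 0L] <- 1L
  dt <- t - trajectory$t0[j]
  trajectory$F0[j] + trajectory$x0[j] * dt + trajectory$slope[j] * dt^2 / 2
}

# integral of F from 0 to t (F is piecewise quadratic); used for the
# analytic cumulative hazard of the approximate model
integral_F <- function(trajectory, t) {
  tt <- trajectory$t0
  dt_seg <- diff(tt)
  x0 <- trajectory$x0
  sl <- trajectory$slope
  F0 <- trajectory$F0
  seg_int <- F0[-length(F0)] * dt_seg + x0[-length(x0)] * dt_seg^2 / 2 +
    sl[-length(sl)] * dt_seg^3 / 6
  G0 <- c(0, cumsum(seg_int))
  vapply(as.numeric(t), function(ti) {
    if (ti <= 0) return(0)
    j <- max(findInterval(ti, tt), 1L)
    d <- ti - tt[j]
    G0[j] + F0[j] * d + x0[j] * d^2 / 2 + sl[j] * d^3 / 6
  }, 0)
}

#' Approximate two-stage hazard mu1 * mu2 * F(t)
#'
#' The detection hazard at age t uses exposure accumulated up to t minus the
#' lag: h(t) = mu1 * mu2 * F(t - lag_tau), zero while t < lag_tau.
#'
#' @param params A \code{tsce_params}.
#' @param trajectory A \code{susceptible_trajectory}.
#' @param t Ages in years.
#' @return Hazard per year, vectorized.
#' @export
approx_hazard <- function(params, trajectory, t) {
  stopifnot(inherits(params, "tsce_params"))
  u <- pmax(as.numeric(t) - params$lag_tau, 0)
  params$mu1 * params$mu2 * F_of_t(trajectory, u)
}

#' Cumulative hazard and cumulative incidence of the approximate model
#'
#' The integral of \code{\link{approx_hazard}} from 0 to t is
#' mu1 * mu2 * integral of F over [0, t - lag], computed in closed form on
#' the trajectory's segments; cumulative incidence is 1 - exp(-H(t)).
#'
#' @inheritParams approx_hazard
#' @return Cumulative hazard (dimensionless), or probability for
#'   \code{cumulative_incidence_approx}.
#' @export
cumulative_hazard_approx <- function(params, trajectory, t) {
  stopifnot(inherits(params, "tsce_params"))
  u <- pmax(as.numeric(t) - params$lag_tau, 0)
  params$mu1 * params$mu2 * integral_F(trajectory, u)
}

#' @rdname cumulative_hazard_approx
#' @export
cumulative_incidence_approx <- function(params, trajectory, t) {
  1 - exp(-cumulative_hazard_approx(params, trajectory, t))
}

#' Two-stage hazard with clonal expansion
#'
#' Extends the approximate hazard with net growth g = alpha2 - beta2 of
#' intermediate clones: h(t) = mu1 * mu2 * integral over s in [0, t - lag]
#' of X(s) * exp(g * (t - lag - s)) ds, evaluated exactly segment by
#' segment.  With alpha2 = beta2 the kernel is 1 and the expression reduces
#' to \code{\link{approx_hazard}}.
#'
#' @inheritParams approx_hazard
#' @return Hazard per year, vectorized.
#' @export
expansion_hazard <- function(params, trajectory, t) {
  stopifnot(inherits(params, "tsce_params"))
  g <- params$alpha2 - params$beta2
  if (g == 0) return(approx_hazard(params, trajectory, t))
  tt <- trajectory$t0
  x0 <- trajectory$x0
  sl <- trajectory$slope
  nseg <- length(tt)
  one <- function(u) {
    if (u <= 0) return(0)
    total <- 0
    for (j in seq_len(nseg)) {
      s0 <- tt[j]
      s1 <- if (j < nseg) min(tt[j + 1L], u) else u
      if (s1 <= s0) {
        if (s0 >= u) break
        next
      }
      a <- x0[j] - sl[j] * tt[j]           # X(s) = a + b s on the segment
      b <- sl[j]
      antider <- function(s)
        exp(g * (u - s)) * (-(a + b * s) / g - b / g^2)
      total <- total + antider(s1) - antider(s0)
      if (s1 >= u) break
    }
    total
  }
  u <- pmax(as.numeric(t) - params$lag_tau, 0)
  params$mu1 * params$mu2 * vapply(u, one, 0)
}

# first malignant-cell time of one intermediate clone founded at t0, or Inf
# if the clone goes extinct / no malignancy before `horizon`; NA if the
# clone exceeds `cap` cells (runaway guard)
simulate_clone <- function(t0, alpha2, beta2, mu2, horizon, cap) {
  n <- 1L
  t <- t0
  total_rate <- alpha2 + beta2 + mu2
  if (total_rate == 0) return(Inf)
  repeat {
    t <- t + stats::rexp(1L, n * total_rate)
    if (t > horizon) return(Inf)
    u <- stats::runif(1L)
    if (u < mu2 / total_rate) return(t)          # malignant transformation
    if (u < (mu2 + beta2) / total_rate) {        # death / differentiation
      n <- n - 1L
      if (n == 0L) return(Inf)
    } else {                                     # symmetric division
      n <- n + 1L
      if (n > cap) return(NA_real_)
    }
  }
}

#' Simulate a cohort under the two-stage model
#'
#' Per subject, first mutations arrive as a nonhomogeneous Poisson process
#' with intensity mu1 * X(t) on [0, horizon], simulated by thinning against
#' the trajectory's maximum.  Each mutation founds an independent
#' intermediate clone evolving as a continuous-time birth/death/mutation
#' branching process; the subject's tumor age is the earliest malignant-cell
#' time plus the lag, when that falls within the horizon.  Only the first
#' tumor counts.  A clone growing past \code{clone_cap} cells flags the
#' subject instead of looping unboundedly.
#'
#' @param params A \code{tsce_params}.
#' @param profile A \code{reproductive_profile}.
#' @param n_subjects Number of subjects (>= 1).
#' @param horizon Follow-up ends at this age (years).
#' @param seed Integer seed; the run is reproducible from it.
#' @param clone_cap Cell-count guard per clone.
#' @return A \code{tsce_cohort} data frame with columns \code{subject_id},
#'   \code{tumor_age} (NA if none within the horizon),
#'   \code{n_first_mutations}, \code{flagged}; attributes carry the seed,
#'   horizon, params and profile.
#' @export
simulate_tsce <- function(params, profile, n_subjects, horizon, seed,
                          clone_cap = 1e6) {
  stopifnot(inherits(params, "tsce_params"),
            inherits(profile, "reproductive_profile"),
            n_subjects >= 1, horizon > 0)
  set.seed(as.integer(seed))
  traj <- build_trajectory(profile)
  # piecewise-linear X attains its max at a knot or at the horizon
  cand <- c(traj$t0[traj$t0 <= horizon], horizon)
  lambda_max <- params$mu1 * max(trajectory_at(traj, cand))
  no_expansion <- params$alpha2 == 0 && params$beta2 == 0
  tumor_age <- rep(NA_real_, n_subjects)
  n_mut <- integer(n_subjects)
  flagged <- logical(n_subjects)
  for (i in seq_len(n_subjects)) {
    if (lambda_max > 0) {
      n_cand <- stats::rpois(1L, lambda_max * horizon)
      tc <- sort(stats::runif(n_cand, 0, horizon))
      keep <- stats::runif(n_cand) * lambda_max <=
        params$mu1 * trajectory_at(traj, tc)
      t_mut <- tc[keep]
    } else t_mut <- numeric(0)
    n_mut[i] <- length(t_mut)
    if (length(t_mut) == 0L) next
    if (no_expansion) {
      malig <- if (params$mu2 > 0)
        t_mut + stats::rexp(length(t_mut), params$mu2) else rep(Inf, length(t_mut))
    } else {
      malig <- vapply(t_mut, simulate_clone, 0,
                      alpha2 = params$alpha2, beta2 = params$beta2,
                      mu2 = params$mu2, horizon = horizon, cap = clone_cap)
      if (anyNA(malig)) {
        flagged[i] <- TRUE
        malig <- malig[!is.na(malig)]
      }
    }
    if (length(malig) && any(is.finite(malig))) {
      ta <- min(malig) + params$lag_tau
      if (ta <= horizon) tumor_age[i] <- ta
    }
  }
  structure(data.frame(subject_id = sprintf("S%05d", seq_len(n_subjects)),
                       tumor_age = tumor_age,
                       n_first_mutations = n_mut,
                       flagged = flagged,
                       stringsAsFactors = FALSE),
            class = c("tsce_cohort", "data.frame"),
            seed = as.integer(seed), horizon = horizon,
            params = params, profile = profile)
}

#' Empirical age-specific hazard from simulated outcomes
#'
#' Per-bin rate = events / person-years at risk, scaled to 100,000
#' person-years.  Subjects are at risk from age 0 until tumor or the
#' simulation horizon, whichever is first; a bin with zero person-years gets
#' a missing rate.
#'
#' @param outcome A \code{tsce_cohort}.
#' @param bins An \code{age_bins} table.
#' @return An \code{incidence_series} with \code{person_years} and
#'   \code{cases} filled in.
#' @export
empirical_hazard <- function(outcome, bins = default_bins()) {
  stopifnot(inherits(outcome, "tsce_cohort"), inherits(bins, "age_bins"),
            nrow(outcome) > 0)
  horizon <- attr(outcome, "horizon")
  exit <- ifelse(is.na(outcome$tumor_age), horizon,
                 pmin(outcome$tumor_age, horizon))
  up <- ifelse(is.finite(bins$upper), bins$upper, horizon)
  py <- vapply(seq_len(nrow(bins)), function(j)
    sum(pmax(pmin(exit, up[j]) - bins$lower[j], 0)), 0)
  ev <- vapply(seq_len(nrow(bins)), function(j)
    sum(!is.na(outcome$tumor_age) &
          outcome$tumor_age >= bins$lower[j] &
          outcome$tumor_age < up[j] + (j == nrow(bins))), 0)
  rate <- ifelse(py > 0, ev / py * 1e5, NA_real_)
  incidence_series(bins, rate, person_years = py, cases = ev)
}

#' Write simulated outcomes to CSV
#'
#' Columns \code{subject_id}, \code{tumor_age} (empty when censored),
#' \code{n_first_mutations}, \code{flagged}, \code{seed}.
#'
#' @param outcome A \code{tsce_cohort}.
#' @param path CSV path.
#' @export
write_tsce_outcomes <- function(outcome, path) {
  stopifnot(inherits(outcome, "tsce_cohort"))
  out <- as.data.frame(outcome)
  out$seed <- attr(outcome, "seed")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
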