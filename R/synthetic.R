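#' Synthetic cohorts, calibration pairs, and incidence series
#'
#' The pipeline's reference inputs (a cross-sectional density cohort, the
#' paired water/density calibration sample, and registry incidence tables)
#' are not redistributable, so the package generates stand-ins with the
#' statistical structure the analysis assumes.  The cohort generator is
#' median-exact: within each age bin, values are placed as antithetic +/-
#' pairs around the target median (plus one value exactly at the median when
#' the count is odd), so the sample median equals the target for every seed
#' and the downstream density-years arithmetic is an exact check, not an
#' approximate one.
#'
#' @name synthetic_data
NULL

#' Default cohort specification
#'
#' Fourteen 5-year bins from 15-19 to 80+ with per-bin counts
#' (974, 86, 83, 15, 49, 405, 654, 789, 546, 324, 259, 171, 76, 23; total
#' 4454) and target median calibrated densities falling from 51.7 percent in
#' the youngest group to 15.2 in the oldest.  Subjects under 35 are measured
#' as percent breast water by MR, the rest by mammography.  The within-bin
#' dispersion of the source population is unreported, so \code{noise_sd}
#' defaults to a placeholder 5 percent.
#'
#' @param noise_sd Spread (sd, percent) of the antithetic perturbations.
#' @param mr_age_cutoff Age below which subjects are measured by MR.
#' @return A \code{cohort_spec}: bins plus per-bin \code{count} and
#'   \code{target_median}, with \code{noise_sd} and \code{mr_age_cutoff}
#'   attributes.
#' @export
default_cohort_spec <- function(noise_sd = 5, mr_age_cutoff = 35) {
  bins <- default_bins()
  counts <- c(974L, 86L, 83L, 15L, 49L, 405L, 654L, 789L, 546L, 324L,
              259L, 171L, 76L, 23L)
  medians <- c(51.7, 46.5, 47.0, 46.3, 45.9, 40.4, 37.3, 28.4, 23.8, 23.1,
               19.2, 18.5, 18.3, 15.2)
  cohort_spec(bins, counts, medians, noise_sd = noise_sd,
              mr_age_cutoff = mr_age_cutoff)
}

#' Construct a cohort specification
#'
#' @param bins An \code{age_bins} table.
#' @param counts Per-bin subject counts (>= 0).
#' @param medians Per-bin target median calibrated densities in [0, 100].
#' @inheritParams default_cohort_spec
#' @return A \code{cohort_spec} data frame.
#' @export
cohort_spec <- function(bins, counts, medians, noise_sd = 5,
                        mr_age_cutoff = 35) {
  stopifnot(inherits(bins, "age_bins"),
            length(counts) == nrow(bins), length(medians) == nrow(bins))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(medians < 0 | medians > 100))
    stop("target medians must lie in [0, 100]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  out <- bins
  out$count <- as.integer(counts)
  out$target_median <- as.numeric(medians)
  structure(out, class = c("cohort_spec", "age_bins", "data.frame"),
            noise_sd = noise_sd, mr_age_cutoff = mr_age_cutoff)
}

# antithetic +/- perturbations whose sample median is exactly zero:
# floor(n/2) magnitudes applied with both signs, plus a zero when n is odd.
# Magnitudes are truncated at `cap` so both members stay in range.
median_exact_deltas <- function(n, sd, cap) {
  k <- n %/% 2L
  mags <- if (k > 0) pmin(abs(stats::rnorm(k, 0, sd)), cap) else numeric(0)
  out <- c(if (n %% 2L == 1L) 0, mags, -mags)
  sample(out)   # shuffle so order carries no signal
}

#' Generate a median-exact synthetic cohort
#'
#' Ages are uniform within each bin (the open last bin uses its width).
#' Densities are the bin's target median plus antithetic perturbations
#' truncated symmetrically so every value stays in [0, 100]; the sample
#' median therefore equals the target exactly.  MR records carry
#' \code{raw_percent} as water, obtained by inverting the calibration, so
#' calibrating the cohort recovers the intended densities; perturbation
#' magnitudes are additionally truncated so the inverted water stays in
#' (0, 100].
#'
#' @param spec A \code{cohort_spec}.
#' @param calibration The \code{calibration_model} the MR back-transform
#'   inverts (use the same one downstream).
#' @param seed Integer seed.
#' @return A cohort data frame (\code{subject_id}, \code{age},
#'   \code{modality}, \code{raw_percent}).
#' @export
generate_cohort <- function(spec, calibration = default_calibration(),
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  noise_sd <- attr(spec, "noise_sd")
  cutoff <- attr(spec, "mr_age_cutoff")
  # densities must invert to water in (0, 100]: d <= a - b/100
  mr_max <- calibration$intercept_a - calibration$scale_b / 100
  rows <- lapply(seq_len(nrow(spec)), function(j) {
    n <- spec$count[j]
    if (n == 0L) return(NULL)
    lo <- spec$lower[j]
    hi <- if (is.finite(spec$upper[j])) spec$upper[j] else lo + spec$width[j]
    age <- stats::runif(n, lo, hi)
    m <- spec$target_median[j]
    is_mr_bin <- hi <= cutoff
    cap <- min(m, 100 - m)
    if (is_mr_bin) cap <- min(cap, mr_max - m)   # keep water invertible
    if (cap < 0) stop("target median ", m, " cannot be represented for an ",
                      "MR bin under the given calibration")
    d <- m + median_exact_deltas(n, noise_sd, cap)
    modality <- if (is_mr_bin) "magnetic_resonance" else "mammography"
    raw <- if (is_mr_bin) invert_calibration(calibration, d) else d
    data.frame(age = age, modality = modality, raw_percent = raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(subject_id = sprintf("C%05d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate synthetic paired calibration measurements
#'
#' Water values are uniform over a physiological range; densities follow the
#' hyperbolic calibration curve plus Gaussian noise, clamped to [0, 100].
#'
#' @param n Number of pairs (default 100, the size of the reference paired
#'   sample).
#' @param model Generating \code{calibration_model}.
#' @param water_range Range of percent water to sample.
#' @param noise_sd Residual sd in percent density.
#' @param seed Integer seed.
#' @return Data frame \code{subject_id}, \code{water_percent},
#'   \code{pmd_percent}.
#' @export
generate_calibration_pairs <- function(n = 100L,
                                       model = default_calibration(),
                                       water_range = c(20, 90),
                                       noise_sd = 2, seed = 1L) {
  stopifnot(n >= 2, water_range[1] > 0, diff(water_range) > 0)
  set.seed(as.integer(seed))
  w <- stats::runif(n, water_range[1], water_range[2])
  d <- apply_calibration(model, w) + stats::rnorm(n, 0, noise_sd)
  data.frame(subject_id = sprintf("P%04d", seq_len(n)),
             water_percent = w,
             pmd_percent = pmin(pmax(d, 0), 100),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic incidence series
#'
#' Rates are produced either from a power law in cumulative breast density,
#' rate_j = c * CBD_j^k evaluated at each bin's representative age, or from
#' the two-stage model's expansion hazard (scaled to 100,000 person-years).
#' Optional noise: multiplicative lognormal (sdlog \code{noise_sd}) or
#' Poisson case counts at the given person-years.
#'
#' @param cbd A \code{cbd_table} (power-law generator), or \code{NULL} when
#'   generating from the two-stage model.
#' @param generator \code{"power_law"} or \code{"tsce"}.
#' @param c0,k Power-law scale (per 100,000 person-years) and exponent; the
#'   defaults give rates of registry magnitude at the shipped CBD scale.
#' @param params,profile Two-stage model inputs (generator \code{"tsce"}).
#' @param person_years Per-bin person-years (recycled); used by the Poisson
#'   noise model and reported in the output.
#' @param noise \code{"none"}, \code{"lognormal"}, or \code{"poisson"}.
#' @param noise_sd sdlog of the lognormal noise.
#' @param representative,open_bin_age Bin-age convention (see
#'   \code{\link{bin_ages}}).
#' @param seed Integer seed (used only when noise is drawn).
#' @param bins Bins when \code{cbd} is not supplied.
#' @return An \code{incidence_series}.
#' @export
generate_incidence <- function(cbd = NULL, generator = c("power_law", "tsce"),
                               c0 = 1e-9, k = 3.5,
                               params = tsce_params(),
                               profile = reproductive_profile(),
                               person_years = 1e6,
                               noise = c("none", "lognormal", "poisson"),
                               noise_sd = 0.1,
                               representative = "upper", open_bin_age = 82.5,
                               seed = 1L, bins = default_bins()) {
  generator <- match.arg(generator)
  noise <- match.arg(noise)
  if (generator == "power_law") {
    stopifnot(inherits(cbd, "cbd_table"), c0 > 0)
    bins <- age_bins(cbd$lower, cbd$upper, cbd$width)
    ages <- bin_ages(bins, representative, open_bin_age)
    x <- cbd_at_age(cbd, ages)
    if (any(x <= 0) && k < 0)
      stop("nonpositive CBD with negative exponent")
    rate <- c0 * x^k
  } else {
    ages <- bin_ages(bins, representative, open_bin_age)
    traj <- build_trajectory(profile)
    rate <- expansion_hazard(params, traj, ages) * 1e5
  }
  py <- rep_len(person_years, length(rate))
  if (any(py <= 0)) stop("person_years must be positive")
  cases <- NULL
  if (noise == "lognormal") {
    set.seed(as.integer(seed))
    rate <- rate * stats::rlnorm(length(rate), 0, noise_sd)
  } else if (noise == "poisson") {
    set.seed(as.integer(seed))
    cases <- stats::rpois(length(rate), rate / 1e5 * py)
    rate <- cases / py * 1e5
  }
  incidence_series(age_bins(bins$lower, bins$upper, bins$width), rate,
                   person_years = py, cases = cases)
}
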