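#' Calibration of MR percent breast water to mammographic density
#'
#' In cohorts mixing imaging modalities, percent breast water measured by
#' magnetic resonance (used in young women, typically under age 35) must be
#' expressed on the mammographic percent-density scale before densities can
#' be pooled across ages.  The mapping used here is hyperbolic in water:
#'
#'   density = a - b / water
#'
#' which rises steeply at low water content and saturates towards the
#' asymptote \code{a} as water increases.  It is linear in the transformed
#' predictor 1/water, so it is fitted by ordinary least squares of density
#' on the reciprocal of water.
#'
#' @name calibration
NULL

#' Construct a calibration model
#'
#' @param intercept_a Asymptotic density (percent) approached as water grows.
#' @param scale_b Coefficient (percent squared) of the reciprocal-water term;
#'   must be nonnegative so that predicted density increases with water.
#' @param n_pairs Number of paired measurements used in fitting (NA if the
#'   coefficients were supplied rather than fitted).
#' @param residual_sd Residual standard deviation of the fit, in percent.
#' @return An object of class \code{calibration_model}.
#' @export
calibration_model <- function(intercept_a, scale_b, n_pairs = NA_integer_,
                              residual_sd = NA_real_) {
  stopifnot(is.numeric(intercept_a), length(intercept_a) == 1L,
            is.finite(intercept_a),
            is.numeric(scale_b), length(scale_b) == 1L, is.finite(scale_b))
  if (scale_b < 0)
    stop("scale_b must be >= 0 so that density increases with water")
  structure(
    list(intercept_a = as.numeric(intercept_a),
         scale_b = as.numeric(scale_b),
         n_pairs = as.integer(n_pairs),
         residual_sd = as.numeric(residual_sd)),
    class = "calibration_model")
}

#' Default water-to-density calibration
#'
#' The package's shipped calibration coefficients: density =
#' 80.00813 - 1365.42571 / water.  These were derived from 100 adult women
#' measured by both modalities; the paired data behind them are not
#' redistributable, so the coefficients are taken as given.
#'
#' @return A \code{calibration_model}.
#' @export
default_calibration <- function() {
  calibration_model(intercept_a = 80.00813, scale_b = 1365.42571,
                    n_pairs = 100L, residual_sd = NA_real_)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Water-to-density calibration: density = ",
      format(x$intercept_a), " - ", format(x$scale_b), " / water\n", sep = "")
  if (!is.na(x$n_pairs))
    cat("  fitted on", x$n_pairs, "pairs; residual sd",
        format(x$residual_sd), "percent\n")
  invisible(x)
}

#' Fit the water-to-density calibration from paired measurements
#'
#' Ordinary least squares of mammographic percent density on the reciprocal
#' of percent breast water, reported in the form density = a - b / water.
#'
#' @param pairs A data frame with columns \code{water_percent} (in (0, 100])
#'   and \code{pmd_percent} (in [0, 100]); a \code{subject_id} column is
#'   carried but not used.
#' @return A \code{calibration_model} with \code{residual_sd} taken from the
#'   fit (0 when the points lie exactly on a single hyperbola).
#' @export
fit_calibration <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("water_percent", "pmd_percent")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("calibration pairs lack column(s): ", paste(miss, collapse = ", "))
  w <- as.numeric(pairs$water_percent)
  d <- as.numeric(pairs$pmd_percent)
  if (any(!is.finite(w)) || any(!is.finite(d)))
    stop("non-finite values in calibration pairs")
  if (any(w <= 0))
    stop("water_percent must be strictly positive")
  if (length(unique(w)) < 2L)
    stop("degenerate design: need at least 2 distinct water_percent values")
  fit <- stats::lm(d ~ I(1 / w))
  cf <- stats::coef(fit)
  a <- unname(cf[1L])
  b <- -unname(cf[2L])          # model is d = a + c/w with c = -b
  if (b < 0)
    warning("fitted scale_b is negative: density decreases with water; ",
            "check the pairing of the input columns")
  # residual sd computed directly; an interpolating fit (2 points, or all
  # points on one hyperbola) reports 0
  res <- stats::residuals(fit)
  rsd <- if (length(w) > 2L) sqrt(sum(res^2) / (length(w) - 2L)) else 0
  calibration_model(intercept_a = a, scale_b = max(b, 0),
                    n_pairs = length(w), residual_sd = rsd)
}

#' Apply a calibration model to percent breast water
#'
#' Evaluates density = a - b / water and clamps the result to [0, 100]
#' (the hyperbola is negative at very low water and would exceed 100 only
#' for intercepts above 100).
#'
#' @param model A \code{calibration_model}.
#' @param water_percent Numeric vector of percent breast water, all > 0.
#' @return Calibrated percent density in [0, 100], same length as input.
#' @export
apply_calibration <- function(model, water_percent) {
  stopifnot(inherits(model, "calibration_model"))
  w <- as.numeric(water_percent)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("water_percent must be finite and strictly positive")
  pmin(pmax(model$intercept_a - model$scale_b / w, 0), 100)
}

#' Invert a calibration model
#'
#' Water content that maps to a given density: water = b / (a - density).
#' Used by the synthetic-data generator to construct MR raw measurements
#' whose calibrated values are known exactly.
#'
#' @param model A \code{calibration_model} with \code{scale_b > 0}.
#' @param density_percent Densities strictly below \code{intercept_a}.
#' @return Percent water values.
#' @export
invert_calibration <- function(model, density_percent) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$scale_b <= 0)
    stop("calibration with scale_b = 0 is not invertible")
  d <- as.numeric(density_percent)
  if (any(d >= model$intercept_a))
    stop("density at or above the asymptote ", format(model$intercept_a),
         " has no finite water preimage")
  model$scale_b / (model$intercept_a - d)
}

#' Read calibration pairs from CSV
#'
#' Expects columns \code{subject_id}, \code{water_percent},
#' \code{pmd_percent} with a header row.
#'
#' @param path Path to the CSV file.
#' @return A data frame of paired measurements.
#' @export
read_calibration_pairs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "water_percent", "pmd_percent")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("calibration CSV lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Serialize / deserialize a calibration model as flat key-value text
#'
#' @param model A \code{calibration_model}.
#' @param path File to write to / read from.
#' @return \code{read_calibration_model} returns a \code{calibration_model};
#'   \code{write_calibration_model} returns \code{path} invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  lines <- c(
    paste0("intercept_a=", format(model$intercept_a, digits = 17)),
    paste0("scale_b=", format(model$scale_b, digits = 17)),
    paste0("n_pairs=", model$n_pairs),
    paste0("residual_sd=", format(model$residual_sd, digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) as.numeric(vals[match(k, keys)])
  calibration_model(intercept_a = get1("intercept_a"),
                    scale_b = get1("scale_b"),
                    n_pairs = suppressWarnings(as.integer(get1("n_pairs"))),
                    residual_sd = get1("residual_sd"))
}
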