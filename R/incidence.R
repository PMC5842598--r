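#' Power-law models of age-specific incidence
#'
#' Registry incidence rises with age roughly as a power law; on the log-log
#' scale the age-incidence curve is close to a straight line whose slope is
#' the power-law exponent k.  The same construction applies with cumulative
#' breast density CBD(t) in place of age: log I(t) ~ k log CBD(t).  These
#' functions fit such models by unweighted ordinary least squares on logs
#' and compare the three candidate predictors (age alone, CBD alone, age and
#' CBD together) by the proportion of log-rate variance explained.
#'
#' @name incidence_models
NULL

#' Construct an incidence series
#'
#' @param bins An \code{age_bins} table.
#' @param rate Incidence rate per 100,000 person-years, one per bin.
#' @param person_years Optional person-years denominators.
#' @param cases Optional case counts.
#' @return An \code{incidence_series} data frame.
#' @export
incidence_series <- function(bins, rate, person_years = NULL, cases = NULL) {
  stopifnot(inherits(bins, "age_bins"), length(rate) == nrow(bins))
  out <- bins
  out$rate <- as.numeric(rate)
  out$person_years <- if (is.null(person_years)) NA_real_ else
    as.numeric(person_years)
  out$cases <- if (is.null(cases)) NA_real_ else as.numeric(cases)
  class(out) <- c("incidence_series", "age_bins", "data.frame")
  out
}

#' Representative age for each bin
#'
#' The single age standing for a 5-year bin in "log age" and in CBD(t).
#' Default is the bin's upper boundary (exposure accumulated through the end
#' of the interval); \code{"midpoint"} is the alternative.  The open-ended
#' last bin has no upper boundary, so its representative age is set
#' explicitly; the default 82.5 is the midpoint of a closed 80-85 bin.
#'
#' @param bins An \code{age_bins} table.
#' @param representative \code{"upper"} or \code{"midpoint"}.
#' @param open_bin_age Age standing for an open-ended bin.
#' @return Numeric vector of ages, one per bin.
#' @export
bin_ages <- function(bins, representative = c("upper", "midpoint"),
                     open_bin_age = 82.5) {
  stopifnot(inherits(bins, "age_bins"))
  representative <- match.arg(representative)
  a <- switch(representative,
              upper = bins$upper,
              midpoint = (bins$lower + bins$upper) / 2)
  a[!is.finite(a)] <- open_bin_age
  a
}

#' Fit a log-log (power-law) model of incidence
#'
#' Ordinary least squares of log rate on the log of one or two positive
#' per-bin predictor series, with intercept.  The slope on each log
#' predictor is the power-law exponent for that predictor; r-squared is the
#' proportion of log-rate variance explained.
#'
#' @param incidence An \code{incidence_series} (all rates strictly positive).
#' @param predictors Named list (or data frame) of one or two numeric
#'   vectors, each the per-bin values of a strictly positive predictor.
#' @param weights Optional per-bin weights (e.g. person-years) for a
#'   sensitivity analysis; default unweighted.
#' @return A \code{power_law_fit} with elements \code{exponent_k} (named
#'   vector of slopes), \code{log_intercept}, \code{r_squared},
#'   \code{residuals} (log scale), \code{fitted_log}, \code{predictor_names},
#'   \code{lm} (the underlying fit).
#' @export
fit_log_log <- function(incidence, predictors, weights = NULL) {
  stopifnot(inherits(incidence, "incidence_series"))
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  if (!is.list(predictors)) predictors <- list(predictor = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("x", seq_along(predictors))
  p <- length(predictors)
  if (p < 1L || p > 2L)
    stop("one or two predictor series required")
  n <- nrow(incidence)
  rate <- incidence$rate
  if (any(!is.finite(rate) | rate <= 0))
    stop("nonpositive or missing rate in bin(s): ",
         paste(incidence$label[!is.finite(rate) | rate <= 0], collapse = ", "))
  for (nm in names(predictors)) {
    v <- predictors[[nm]]
    if (length(v) != n)
      stop("predictor '", nm, "' has length ", length(v), ", expected ", n)
    if (any(!is.finite(v) | v <= 0))
      stop("nonpositive value in predictor '", nm, "' at bin(s): ",
           paste(incidence$label[!is.finite(v) | v <= 0], collapse = ", "))
  }
  # a saturated fit (n = p + 1, zero residual df) is permitted: it is the
  # unique interpolating power law and reports r-squared 1
  if (n < p + 1L)
    stop("need at least ", p + 1L, " bins to fit ", p, " predictor(s)")
  df <- data.frame(lapply(predictors, log))
  df$.lograte <- log(rate)
  form <- stats::as.formula(paste(".lograte ~",
                                  paste(names(predictors), collapse = " + ")))
  fit <- if (is.null(weights)) stats::lm(form, data = df) else
    stats::lm(form, data = df, weights = weights)
  if (fit$rank < p + 1L)
    stop("rank-deficient design: predictors are collinear on the log scale")
  cf <- stats::coef(fit)
  # r-squared computed directly (summary.lm warns on noiseless data)
  wts <- if (is.null(weights)) rep(1, n) else weights
  res <- stats::residuals(fit)
  tss <- sum(wts * (df$.lograte - stats::weighted.mean(df$.lograte, wts))^2)
  r2 <- 1 - sum(wts * res^2) / tss
  structure(
    list(exponent_k = cf[-1L],
         log_intercept = unname(cf[1L]),
         r_squared = r2,
         residuals = unname(stats::residuals(fit)),
         fitted_log = unname(stats::fitted(fit)),
         predictor_names = names(predictors),
         n_bins = n,
         lm = fit),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law incidence fit: log(rate) ~ ",
      paste("log", x$predictor_names, collapse = " + "), "\n", sep = "")
  cat("  exponent k: ",
      paste(sprintf("%s = %.4g", names(x$exponent_k), x$exponent_k),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  log intercept: %.4g   r-squared: %.4f   bins: %d\n",
              x$log_intercept, x$r_squared, x$n_bins))
  invisible(x)
}

#' Predict incidence rates from a power-law fit
#'
#' Exponentiates the fitted linear predictor on new (or the training)
#' predictor values.
#'
#' @param fit A \code{power_law_fit}.
#' @param predictors Named list/data frame matching the fit's predictors; if
#'   omitted, the training values are used.
#' @return Numeric vector of rates per 100,000 person-years.
#' @export
predict_incidence <- function(fit, predictors = NULL) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (is.null(predictors)) return(exp(fit$fitted_log))
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  if (!is.list(predictors)) predictors <- list(predictors)
  if (length(predictors) != length(fit$predictor_names))
    stop("fit has ", length(fit$predictor_names), " predictor(s), got ",
         length(predictors))
  names(predictors) <- fit$predictor_names
  for (nm in names(predictors))
    if (any(predictors[[nm]] <= 0))
      stop("nonpositive value in predictor '", nm, "'")
  nd <- data.frame(lapply(predictors, log))
  exp(unname(stats::predict(fit$lm, newdata = nd)))
}

#' Compare the three power-law incidence models
#'
#' Fits log rate on (i) log age alone, (ii) log CBD alone, and (iii) log age
#' + log CBD, on bins aligned across the incidence series and the CBD table,
#' and reports whether adding age to CBD changes r-squared by more than a
#' tolerance.
#'
#' @param incidence An \code{incidence_series}.
#' @param cbd A \code{cbd_table} on the same bins.
#' @param representative Bin age convention passed to \code{\link{bin_ages}}.
#' @param open_bin_age Representative age of an open-ended bin.
#' @param age_tolerance r-squared change below which adding age to CBD is
#'   reported as immaterial.
#' @return A \code{model_comparison}: list with \code{fits} (named list of
#'   the three \code{power_law_fit}s, ranked by decreasing r-squared in
#'   \code{ranking}), \code{table} (per-model k and r-squared),
#'   \code{age_adds} (logical) and \code{delta_r2_age}.
#' @export
compare_models <- function(incidence, cbd,
                           representative = c("upper", "midpoint"),
                           open_bin_age = 82.5, age_tolerance = 1e-3) {
  stopifnot(inherits(incidence, "incidence_series"),
            inherits(cbd, "cbd_table"))
  if (nrow(incidence) != nrow(cbd) ||
      any(incidence$lower != cbd$lower) ||
      any(incidence$upper != cbd$upper & is.finite(incidence$upper)))
    stop("incidence and CBD tables are not on aligned bins")
  ages <- bin_ages(incidence, representative, open_bin_age)
  cbd_vals <- cbd_at_age(cbd, ages)
  fits <- list(
    age = fit_log_log(incidence, list(age = ages)),
    cbd = fit_log_log(incidence, list(cbd = cbd_vals)),
    age_cbd = fit_log_log(incidence, list(age = ages, cbd = cbd_vals)))
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  tab <- data.frame(
    model = names(fits),
    predictors = vapply(fits, function(f)
      paste(f$predictor_names, collapse = "+"), ""),
    r_squared = unname(r2),
    k = vapply(fits, function(f)
      unname(f$exponent_k[length(f$exponent_k)]), 0),
    stringsAsFactors = FALSE)
  delta <- r2[["age_cbd"]] - r2[["cbd"]]
  structure(
    list(fits = fits,
         ranking = names(sort(r2, decreasing = TRUE)),
         table = tab,
         delta_r2_age = delta,
         age_adds = delta > age_tolerance,
         ages = ages,
         cbd_values = cbd_vals),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Age-specific incidence: three log-log models\n")
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("ranking by r-squared: %s\n", paste(x$ranking, collapse = " > ")))
  cat(sprintf("adding log age to log CBD changes r-squared by %.2g (%s)\n",
              x$delta_r2_age,
              if (x$age_adds) "material" else "immaterial"))
  invisible(x)
}

#' Observed versus predicted incidence per bin
#'
#' The tabular analogue of an observed/predicted age-incidence plot.
#'
#' @param fit A \code{power_law_fit}.
#' @param incidence The \code{incidence_series} it was fitted to.
#' @return Data frame with label, observed and predicted rates, and the
#'   log-scale residual.
#' @export
observed_vs_predicted <- function(fit, incidence) {
  stopifnot(inherits(fit, "power_law_fit"),
            inherits(incidence, "incidence_series"),
            nrow(incidence) == fit$n_bins)
  data.frame(label = incidence$label,
             observed = incidence$rate,
             predicted = exp(fit$fitted_log),
             log_residual = fit$residuals,
             stringsAsFactors = FALSE)
}

#' Read / write an incidence series CSV
#'
#' Columns \code{bin_lower}, \code{bin_upper}, \code{rate_per_100k},
#' optional \code{person_years} and \code{cases}; open-ended upper bounds
#' use the sentinel \code{Inf}.
#'
#' @param path CSV path.
#' @param width Bin widths if the upper bound alone does not determine them
#'   (open bins); default 5 for an open bin.
#' @return \code{read_incidence} returns an \code{incidence_series}.
#' @export
read_incidence <- function(path, width = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bin_lower", "bin_upper", "rate_per_100k")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("incidence CSV lacks column(s): ", paste(miss, collapse = ", "))
  up <- as.numeric(x$bin_upper)
  if (is.null(width)) {
    width <- up - x$bin_lower
    width[!is.finite(width)] <- 5
  }
  b <- age_bins(x$bin_lower, up, width = width)
  incidence_series(b, x$rate_per_100k,
                   person_years = x$person_years, cases = x$cases)
}

#' @rdname read_incidence
#' @param incidence An \code{incidence_series} to write.
#' @export
write_incidence <- function(incidence, path) {
  stopifnot(inherits(incidence, "incidence_series"))
  out <- data.frame(bin_lower = incidence$lower,
                    bin_upper = incidence$upper,
                    rate_per_100k = incidence$rate,
                    person_years = incidence$person_years,
                    cases = incidence$cases)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
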