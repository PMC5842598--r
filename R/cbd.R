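#' Cumulative breast density (CBD) from a cross-sectional cohort
#'
#' Percent mammographic density (PMD) falls with age while breast cancer
#' incidence rises.  Treating PMD as a cumulative exposure resolves the
#' apparent paradox: each 5-year age bin contributes "breast density years"
#' (median PMD in the bin times the bin width in years), and the running sum
#' from age 15 gives cumulative breast density CBD(t).  These functions build
#' that table from a calibrated cross-sectional cohort.
#'
#' @name cbd
NULL

# -- age bins ---------------------------------------------------------------

#' Age bins for density and incidence tabulation
#'
#' @param lower Inclusive lower bounds in years.
#' @param upper Exclusive upper bounds in years; \code{Inf} for an open-ended
#'   last bin.
#' @param width Exposure width in years used as the density-years multiplier;
#'   defaults to \code{upper - lower}, and must be supplied for an open bin.
#' @return A data frame of class \code{age_bins} with columns \code{lower},
#'   \code{upper}, \code{width}, \code{label}.
#' @export
age_bins <- function(lower, upper, width = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (is.null(width)) width <- upper - lower
  if (any(!is.finite(width) | width <= 0))
    stop("every bin needs a finite positive width (supply one for open bins)")
  if (is.unsorted(lower, strictly = TRUE))
    stop("bins must be ordered by lower bound")
  if (any(utils::head(upper, -1L) > utils::tail(lower, -1L)))
    stop("bins overlap")
  label <- ifelse(is.finite(upper),
                  sprintf("%g-%g", lower, upper - 1),
                  sprintf("%g+", lower))
  structure(data.frame(lower = lower, upper = upper, width = width,
                       label = label, stringsAsFactors = FALSE),
            class = c("age_bins", "data.frame"))
}

#' Default 5-year age bins, 15-19 through 80+
#'
#' Fourteen half-open bins [15,20), [20,25), ..., [75,80), [80,Inf).  The
#' open-ended last bin carries width 5 like the others, so the oldest group
#' contributes exactly five density-years' worth of exposure.
#'
#' @return An \code{age_bins} data frame with 14 rows.
#' @export
default_bins <- function() {
  lo <- seq(15, 80, by = 5)
  hi <- c(seq(20, 80, by = 5), Inf)
  age_bins(lo, hi, width = rep(5, length(lo)))
}

#' Assign ages to bins
#'
#' Bins are half-open, lower-inclusive: age 20 belongs to [20,25), not
#' [15,20).  Ages below the first bin get \code{NA}.
#'
#' @param bins An \code{age_bins} data frame.
#' @param age Numeric vector of ages in years.
#' @return Integer vector of row indices into \code{bins} (NA when the age
#'   precedes the first bin).
#' @export
assign_bin <- function(bins, age) {
  stopifnot(inherits(bins, "age_bins"))
  idx <- findInterval(age, bins$lower)
  idx[idx == 0L] <- NA_integer_
  # findInterval handles the open last bin; finite-topped tables need a cap
  top <- bins$upper[nrow(bins)]
  if (is.finite(top)) idx[age >= top] <- NA_integer_
  idx
}

# -- cohort records ---------------------------------------------------------

#' Calibrate a cross-sectional cohort
#'
#' Adds a \code{calibrated_percent} column: mammography records keep their
#' raw percent density; magnetic-resonance records (percent breast water)
#' are passed through the calibration model.  The design splits modality at
#' age 35 (MR below, mammography at or above); records violating that rule
#' are calibrated anyway but counted in a message.
#'
#' @param cohort Data frame with columns \code{subject_id}, \code{age},
#'   \code{modality} (\code{"mammography"} or \code{"magnetic_resonance"}),
#'   \code{raw_percent}.
#' @param calibration A \code{calibration_model}; default the shipped one.
#' @param mr_age_cutoff Age below which MR is the expected modality.
#' @param quiet Suppress the mixed-modality message.
#' @return The cohort with \code{calibrated_percent} added.
#' @export
calibrate_cohort <- function(cohort, calibration = default_calibration(),
                             mr_age_cutoff = 35, quiet = FALSE) {
  need <- c("subject_id", "age", "modality", "raw_percent")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  mod <- cohort$modality
  bad <- setdiff(unique(mod), c("mammography", "magnetic_resonance"))
  if (length(bad))
    stop("unknown modality value(s): ", paste(bad, collapse = ", "))
  is_mr <- mod == "magnetic_resonance"
  cal <- as.numeric(cohort$raw_percent)
  if (any(is_mr)) cal[is_mr] <- apply_calibration(calibration,
                                                  cohort$raw_percent[is_mr])
  cal <- pmin(pmax(cal, 0), 100)
  off <- sum(is_mr & cohort$age >= mr_age_cutoff) +
         sum(!is_mr & cohort$age < mr_age_cutoff)
  if (off > 0 && !quiet)
    message(off, " record(s) use a modality unexpected for their age ",
            "(cutoff ", mr_age_cutoff, "); calibrated as given")
  cohort$calibrated_percent <- cal
  cohort
}

#' Per-bin counts and median calibrated density
#'
#' Sample medians use the usual midpoint convention for even counts.  Ages
#' below the first bin are excluded (with a message giving the count).
#'
#' @param cohort Calibrated cohort (see \code{\link{calibrate_cohort}}).
#' @param bins An \code{age_bins} table.
#' @param quiet Suppress the excluded-ages message.
#' @return Data frame with \code{lower}, \code{upper}, \code{width},
#'   \code{label}, \code{n}, \code{median_density} (NA for empty bins).
#' @export
median_density_by_bin <- function(cohort, bins = default_bins(),
                                  quiet = FALSE) {
  stopifnot(inherits(bins, "age_bins"))
  if (!"calibrated_percent" %in% names(cohort))
    stop("cohort has no calibrated_percent column; run calibrate_cohort()")
  idx <- assign_bin(bins, cohort$age)
  n_excl <- sum(is.na(idx))
  if (n_excl > 0 && !quiet)
    message(n_excl, " record(s) below age ", bins$lower[1L], " excluded")
  out <- bins
  out$n <- vapply(seq_len(nrow(bins)), function(j)
    sum(idx == j, na.rm = TRUE), 0L)
  out$median_density <- vapply(seq_len(nrow(bins)), function(j) {
    v <- cohort$calibrated_percent[which(idx == j)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, 0)
  out
}

# -- the CBD table ----------------------------------------------------------

#' Breast density years for one bin
#'
#' @param median_density Median percent density in the bin, in [0, 100].
#' @param width Bin width in years.
#' @return \code{median_density * width}, in percent-years.
#' @export
density_years <- function(median_density, width) {
  stopifnot(all(width > 0))
  if (any(is.finite(median_density) &
          (median_density < 0 | median_density > 100)))
    stop("median_density must lie in [0, 100]")
  median_density * width
}

#' Accumulate density years into a CBD table
#'
#' Takes per-bin medians (from \code{\link{median_density_by_bin}} or
#' entered directly) and adds \code{density_years} and the running
#' \code{cumulative} column.  An empty bin (undefined median) is a hard
#' error because the cumulative sum past it would be meaningless.
#'
#' @param binned Data frame with \code{lower}, \code{upper}, \code{width},
#'   \code{median_density}, optionally \code{n} and \code{label}.
#' @return A \code{cbd_table}: the input plus \code{density_years} and
#'   \code{cumulative}.
#' @export
cumulative_density <- function(binned) {
  need <- c("lower", "upper", "width", "median_density")
  miss <- setdiff(need, names(binned))
  if (length(miss))
    stop("binned table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(binned$lower, strictly = TRUE))
    stop("rows must be ordered by bin")
  bad <- which(!is.finite(binned$median_density))
  if (length(bad)) {
    lab <- if ("label" %in% names(binned)) binned$label[bad] else
      paste0("[", binned$lower[bad], ",", binned$upper[bad], ")")
    stop("undefined median density (empty bin?) in bin(s): ",
         paste(lab, collapse = ", "))
  }
  binned$density_years <- density_years(binned$median_density, binned$width)
  binned$cumulative <- cumsum(binned$density_years)
  class(binned) <- c("cbd_table", "data.frame")
  binned
}

#' Build the CBD table straight from a cohort
#'
#' Convenience wrapper: calibrate, bin, take medians, accumulate.
#'
#' @inheritParams calibrate_cohort
#' @inheritParams median_density_by_bin
#' @return A \code{cbd_table}.
#' @export
cbd_table <- function(cohort, bins = default_bins(),
                      calibration = default_calibration(),
                      mr_age_cutoff = 35, quiet = FALSE) {
  if (!"calibrated_percent" %in% names(cohort))
    cohort <- calibrate_cohort(cohort, calibration, mr_age_cutoff, quiet)
  cumulative_density(median_density_by_bin(cohort, bins, quiet = quiet))
}

#' @export
print.cbd_table <- function(x, ...) {
  cat("Cumulative breast density table (", nrow(x), " bins)\n", sep = "")
  cols <- intersect(c("label", "n", "median_density", "width",
                      "density_years", "cumulative"), names(x))
  print.data.frame(x[, cols], row.names = FALSE, ...)
  invisible(x)
}

#' Cumulative breast density at an arbitrary age
#'
#' CBD accrues at rate \code{median_density} percent per year inside each
#' bin: within a bin the cumulative value is interpolated linearly, beyond
#' the last bin's width it stops accruing (an 80+ bin of width 5 stops at
#' 85).  Ages below the first bin return 0 with a warning.
#'
#' @param table A \code{cbd_table}.
#' @param t Ages in years.
#' @return CBD(t) in percent-years, same length as \code{t}.
#' @export
cbd_at_age <- function(table, t) {
  stopifnot(inherits(table, "cbd_table"))
  t <- as.numeric(t)
  if (any(t < table$lower[1L]))
    warning("ages below ", table$lower[1L],
            " precede the first bin; returning 0 there")
  prev_cum <- c(0, utils::head(table$cumulative, -1L))
  end_age <- table$lower + table$width   # accrual stops here for open bins
  vapply(t, function(ti) {
    if (ti <= table$lower[1L]) return(0)
    j <- findInterval(ti, table$lower)
    elapsed <- min(ti - table$lower[j], table$width[j])
    prev_cum[j] + table$median_density[j] * elapsed
  }, 0)
}

# -- I/O --------------------------------------------------------------------

#' Read a cohort CSV
#'
#' Columns \code{subject_id}, \code{age}, \code{modality},
#' \code{raw_percent}; \code{calibrated_percent} is always recomputed, never
#' read.
#'
#' @param path CSV path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "modality", "raw_percent")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  x$calibrated_percent <- NULL
  x
}

#' Write / read a CBD table as CSV
#'
#' Open-ended upper bounds are written as the sentinel \code{Inf} and read
#' back as such; columns mirror the tabulated report: bin bounds, n, median
#' density, density years, cumulative.
#'
#' @param table A \code{cbd_table}.
#' @param path CSV path.
#' @return \code{read_cbd_table} returns a \code{cbd_table};
#'   \code{write_cbd_table} returns \code{path} invisibly.
#' @export
write_cbd_table <- function(table, path) {
  stopifnot(inherits(table, "cbd_table"))
  out <- data.frame(bin_lower = table$lower, bin_upper = table$upper,
                    width = table$width,
                    n = if ("n" %in% names(table)) table$n else NA_integer_,
                    median_density = table$median_density,
                    density_years = table$density_years,
                    cumulative = table$cumulative)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cbd_table
#' @export
read_cbd_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bin_lower", "bin_upper", "width", "median_density")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("CBD CSV lacks column(s): ", paste(miss, collapse = ", "))
  b <- age_bins(x$bin_lower, as.numeric(x$bin_upper), width = x$width)
  b$n <- if ("n" %in% names(x)) x$n else NA_integer_
  b$median_density <- x$median_density
  cumulative_density(b)
}
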