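# Reference quantities shared across tests.
#
# Published per-bin summary of the cross-sectional density study: counts,
# median calibrated percent density, the printed "breast density years"
# (median x 5, as printed, reflecting unrounded upstream medians) and the
# printed running cumulative.  These are the external values the pipeline's
# arithmetic is checked against.

ref_counts <- c(974L, 86L, 83L, 15L, 49L, 405L, 654L, 789L, 546L, 324L,
                259L, 171L, 76L, 23L)

ref_medians <- c(51.7, 46.5, 47.0, 46.3, 45.9, 40.4, 37.3, 28.4, 23.8, 23.1,
                 19.2, 18.5, 18.3, 15.2)

ref_density_years_printed <- c(258.5, 232.5, 235.0, 231.5, 229.6, 202.0,
                               186.6, 141.9, 119.0, 115.3, 96.1, 92.5,
                               91.3, 76.0)

ref_cumulative_printed <- c(258.6, 491.1, 726.1, 957.6, 1187.3, 1389.3,
                            1575.9, 1717.8, 1836.9, 1952.2, 2048.3, 2140.8,
                            2232.1, 2308.1)

# shipped calibration coefficients
ref_cal_a <- 80.00813
ref_cal_b <- 1365.42571

# a reference CBD table built directly from the published medians
ref_cbd_table <- function() {
  b <- default_bins()
  b$n <- ref_counts
  b$median_density <- ref_medians
  cumulative_density(b)
}
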