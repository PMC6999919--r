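# expect_equal() falls back to absolute comparison when the reference value
# is smaller than the tolerance, which silently loosens checks on
# small-magnitude quantities (exponents, short delays). These helpers make
# the comparison mode explicit.
expect_close <- function(actual, expected, rel = NULL, abs = NULL) {
  if (!is.null(rel)) {
    testthat::expect_lt(max(abs(actual / expected - 1)), rel)
  }
  if (!is.null(abs)) {
    testthat::expect_lt(max(abs(actual - expected)), abs)
  }
  invisible(actual)
}

# Baseline surfaces and fits are reused by several files; compute them once.
.shared <- new.env(parent = emptyenv())

shared <- function(name, build) {
  if (is.null(.shared[[name]])) .shared[[name]] <- build()
  .shared[[name]]
}

baseline_config <- function() shared("config", analysis_config)

swing_surface_baseline <- function() {
  shared("swing_surface",
         function() delay_surface_swing(config = baseline_config()))
}

posture_surface_baseline <- function() {
  shared("posture_surface",
         function() delay_surface_posture(config = baseline_config()))
}

swing_fits_baseline <- function() {
  shared("swing_fits", function() fit_delay_scaling(swing_surface_baseline()))
}

posture_fits_baseline <- function() {
  shared("posture_fits",
         function() fit_delay_scaling(posture_surface_baseline()))
}
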