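#' Fit a power law by log-log least squares
#'
#' Ordinary least squares of `log10(value)` on `log10(mass)`; the fitted
#' power law is `value = coefficient * mass^exponent` with
#' `coefficient = 10^intercept`. This is the regression used to extract the
#' allometric coefficient and exponent of inertial delay from the simulated
#' surfaces.
#'
#' @param masses Body masses, kg (length >= 2, positive).
#' @param values Response values (same length, strictly positive).
#' @return An object of class `power_law_fit`: a list with `coefficient`,
#'   `exponent`, `r_squared`, `n_points`, and per-point log10 `residuals`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' m <- c(0.01, 1, 100)
#' fit_power_law(m, 3 * m^0.5) # recovers (3, 0.5) exactly
#' @export
fit_power_law <- function(masses, values) {
  if (length(masses) != length(values)) {
    stop("masses and values must have the same length", call. = FALSE)
  }
  if (length(masses) < 2) {
    stop("power-law fit needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be positive and finite (log-log regression)",
         call. = FALSE)
  }
  lx <- log10(masses)
  ly <- log10(values)
  fit <- stats::lm(ly ~ lx)
  # R^2 by hand: summary.lm warns on the (common here) essentially perfect fit
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(coefficient = 10^unname(stats::coef(fit)[1]),
         exponent = unname(stats::coef(fit)[2]),
         r_squared = r2,
         n_points = length(masses),
         residuals = unname(stats::residuals(fit))),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> %.4g * M^%.4g  (R^2 = %.4f, n = %d)\n",
              x$coefficient, x$exponent, x$r_squared, x$n_points))
  invisible(x)
}

#' Evaluate a fitted power law
#'
#' @param object A `power_law_fit`.
#' @param mass Body mass, kg.
#' @param ... Unused.
#' @return `coefficient * mass^exponent`.
#' @export
predict.power_law_fit <- function(object, mass, ...) {
  object$coefficient * mass^object$exponent
}

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("coefficient", "exponent"),
                 estimate = c(x$coefficient, x$exponent))
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(coefficient = x$coefficient, exponent = x$exponent,
                 r.squared = x$r_squared, nobs = x$n_points)
}

#' Power-law fits of a delay surface, one per movement magnitude
#'
#' For each movement-magnitude (swing) or perturbation (posture) level of an
#' inertial-delay surface, fits `delay = a * M^b` across body masses. Rows
#' with unconverged cells are skipped with a message.
#'
#' @param surface An `inertial_delay_surface` from [delay_surface_swing()] or
#'   [delay_surface_posture()].
#' @return A tibble of class `delay_scaling_fits` with columns `magnitude`
#'   (degrees or dimensionless velocity, per the surface's task),
#'   `coefficient` (s at 1 kg), `exponent`, `r_squared`, `n`; attribute
#'   `task` is carried over.
#' @examples
#' \donttest{
#' delay_surface_swing(masses = c(0.01, 1, 100), magnitudes = c(10, 60)) |>
#'   fit_delay_scaling()
#' }
#' @export
fit_delay_scaling <- function(surface) {
  stopifnot(inherits(surface, "inertial_delay_surface"))
  task <- attr(surface, "task")
  mag_col <- if (task == "swing") "magnitude_deg" else "vnd"
  levels <- unique(surface[[mag_col]])
  rows <- purrr::map(levels, function(m) {
    sub <- surface[surface[[mag_col]] == m, ]
    if (!all(sub$converged)) {
      message("skipping ", mag_col, " = ", signif(m, 3),
              ": ", sum(!sub$converged), " unconverged cell(s)")
      return(NULL)
    }
    fit <- fit_power_law(sub$mass_kg, sub$delay_s)
    tibble::tibble(magnitude = m, coefficient = fit$coefficient,
                   exponent = fit$exponent, r_squared = fit$r_squared,
                   n = fit$n_points)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no complete magnitude rows to fit", call. = FALSE)
  structure(out, class = c("delay_scaling_fits", class(out)), task = task)
}

#' Average scaling exponent across movement magnitudes
#'
#' Unweighted arithmetic mean of the per-magnitude exponents — the headline
#' scaling result for each task.
#'
#' @param fits A `delay_scaling_fits` tibble from [fit_delay_scaling()].
#' @return The mean exponent (dimensionless).
#' @export
average_exponent <- function(fits) {
  stopifnot(is.data.frame(fits), "exponent" %in% names(fits))
  if (nrow(fits) == 0) stop("no fits to average", call. = FALSE)
  mean(fits$exponent)
}

# power law of the fitted 1-kg coefficient against movement magnitude
# (swing: ~ sqrt(magnitude); posture: ~ linear in v_nd)
coefficient_magnitude_law <- function(fits) {
  fit_power_law(fits$magnitude, fits$coefficient)
}
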