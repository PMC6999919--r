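#' Allometric scaling law
#'
#' A power law `value = a * M^b` relating body mass `M` (kg) to a morphometric
#' or muscular quantity, together with 95% confidence bounds on the coefficient
#' `a` and the exponent `b`. The coefficient is the quantity's value at
#' `M = 1` kg, in the quantity's SI unit. Scaling laws are the atom of all
#' allometric inputs and outputs in this package.
#'
#' @param coefficient Positive value of the quantity at 1 kg body mass.
#' @param exponent Dimensionless scaling exponent.
#' @param coefficient_ci Length-2 numeric, lower/upper 95% bound on the
#'   coefficient. Defaults to a degenerate interval at `coefficient`.
#' @param exponent_ci Length-2 numeric, lower/upper 95% bound on the exponent.
#' @param quantity Short label naming the quantity (e.g. `"forelimb_moi"`).
#' @param unit Unit label (e.g. `"kg m^2"`).
#'
#' @return An object of class `scaling_law`.
#' @examples
#' moi <- scaling_law(2.52e-4, 1.75, c(1.61e-4, 3.95e-4), c(1.60, 1.89),
#'                    "forelimb_moi", "kg m^2")
#' evaluate_scaling_law(moi, 70)
#' @export
scaling_law <- function(coefficient, exponent,
                        coefficient_ci = c(coefficient, coefficient),
                        exponent_ci = c(exponent, exponent),
                        quantity = "", unit = "") {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.numeric(exponent), length(exponent) == 1L,
            length(coefficient_ci) == 2L, length(exponent_ci) == 2L)
  if (coefficient <= 0) {
    stop("scaling law coefficient must be strictly positive", call. = FALSE)
  }
  if (coefficient_ci[1] > coefficient || coefficient_ci[2] < coefficient) {
    stop("coefficient must lie inside its confidence interval", call. = FALSE)
  }
  if (exponent_ci[1] > exponent || exponent_ci[2] < exponent) {
    stop("exponent must lie inside its confidence interval", call. = FALSE)
  }
  structure(
    list(coefficient = coefficient, exponent = exponent,
         coefficient_ci = as.numeric(coefficient_ci),
         exponent_ci = as.numeric(exponent_ci),
         quantity = quantity, unit = unit),
    class = "scaling_law"
  )
}

#' @export
print.scaling_law <- function(x, ...) {
  cat(sprintf("<scaling_law> %s [%s]: %.4g * M^%.3g  (a: %.4g-%.4g, b: %.3g-%.3g)\n",
              x$quantity, x$unit, x$coefficient, x$exponent,
              x$coefficient_ci[1], x$coefficient_ci[2],
              x$exponent_ci[1], x$exponent_ci[2]))
  invisible(x)
}

#' Evaluate a scaling law at a body mass
#'
#' @param law A [scaling_law()].
#' @param mass Body mass in kg; vectorized, all values must be positive.
#' @return `a * mass^b` in the law's unit.
#' @examples
#' evaluate_scaling_law(scaling_law(5.82e-2, 1), 1) # the coefficient itself
#' @export
evaluate_scaling_law <- function(law, mass) {
  stopifnot(inherits(law, "scaling_law"))
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be a positive finite number (kg)", call. = FALSE)
  }
  law$coefficient * mass^law$exponent
}

#' Scaling-law tables
#'
#' Scaling laws travel between functions as tibbles with one row per law and
#' columns `quantity, unit, coefficient, coef_ci_lo, coef_ci_hi, exponent,
#' exp_ci_lo, exp_ci_hi`. `read_scaling_table()` / `write_scaling_table()`
#' round-trip this schema through CSV; `as_scaling_law()` extracts one row as a
#' [scaling_law()] object.
#'
#' @param path Path to a CSV file.
#' @return `read_scaling_table()` returns a tibble in the schema above.
#' @export
read_scaling_table <- function(path) {
  # base read.csv: strtod parses doubles with correct rounding, so tables
  # written by write_scaling_table() round-trip bit-exactly
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_scaling_table(tbl)
  tbl
}

#' @rdname read_scaling_table
#' @param table A scaling-law tibble.
#' @export
write_scaling_table <- function(table, path) {
  validate_scaling_table(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  # 17 significant digits so doubles round-trip bit-exactly through CSV
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

scaling_table_cols <- c("quantity", "unit", "coefficient", "coef_ci_lo",
                        "coef_ci_hi", "exponent", "exp_ci_lo", "exp_ci_hi")

validate_scaling_table <- function(tbl) {
  missing <- setdiff(scaling_table_cols, names(tbl))
  if (length(missing)) {
    stop("scaling table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$coefficient <= 0)) {
    stop("scaling table coefficients must be strictly positive", call. = FALSE)
  }
  invisible(tbl)
}

#' @rdname read_scaling_table
#' @param table A scaling-law tibble.
#' @param quantity Name of the law to extract.
#' @export
as_scaling_law <- function(table, quantity) {
  validate_scaling_table(table)
  row <- table[table$quantity == quantity, ]
  if (nrow(row) != 1L) {
    stop("expected exactly one law named '", quantity, "', found ", nrow(row),
         call. = FALSE)
  }
  scaling_law(row$coefficient, row$exponent,
              c(row$coef_ci_lo, row$coef_ci_hi),
              c(row$exp_ci_lo, row$exp_ci_hi),
              row$quantity, row$unit)
}

#' Published scaling-law tables for the two tasks
#'
#' `swing_laws()` returns the forelimb inertial properties (limb mass, distance
#' from shoulder to limb center of mass, moment of inertia about the shoulder)
#' and triceps muscle architecture (muscle mass, fascicle length, moment arm)
#' used to parameterize the swing task. `posture_laws()` returns fore- and
#' hindlimb lengths and ankle-extensor muscle architecture for the posture
#' task. Values are read from the CSV fixtures shipped under `extdata/`.
#'
#' @return A scaling-law tibble (see [read_scaling_table()]).
#' @examples
#' swing_laws()
#' @export
swing_laws <- function() {
  read_scaling_table(system.file("extdata", "swing_scaling_laws.csv",
                                 package = "inertialdelay", mustWork = TRUE))
}

#' @rdname swing_laws
#' @export
posture_laws <- function() {
  read_scaling_table(system.file("extdata", "posture_scaling_laws.csv",
                                 package = "inertialdelay", mustWork = TRUE))
}
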