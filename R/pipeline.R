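#' Run one stage of the full analysis, writing CSV artifacts
#'
#' Ties the package's stages into the complete analysis: simulate the two
#' delay surfaces, fit the per-magnitude power laws, propagate Monte Carlo
#' uncertainty, derive the sensorimotor-delay comparisons, and summarize.
#' Each stage writes CSV artifacts plus a JSON manifest (stage, config hash,
#' package version, seed, artifact list) into `out_dir`; downstream stages
#' read the upstream CSVs and fail with an actionable message naming the
#' stage to run first. Deterministic stages are idempotent: a rerun rewrites
#' byte-identical artifacts.
#'
#' @param stage One of `"swing"`, `"posture"`, `"fit"`, `"montecarlo"`,
#'   `"response"`, `"report"`, `"synth"`.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; required by the stochastic stages
#'   (`"montecarlo"`, `"synth"`).
#' @return Invisibly, a list with `status` (0 on success), `stage`, and
#'   `artifacts` (paths written).
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_stage("swing", out_dir = dir)
#' run_stage("fit", out_dir = dir)
#' }
#' @export
run_stage <- function(stage = c("swing", "posture", "fit", "montecarlo",
                                "response", "report", "synth"),
                      config = analysis_config(),
                      out_dir = "inertialdelay-artifacts",
                      seed = NULL) {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  artifacts <- character()

  need <- function(path, upstream) {
    if (!file.exists(path)) {
      stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                   path, upstream), call. = FALSE)
    }
    path
  }
  read_fits <- function(task) {
    f <- readr::read_csv(need(p(paste0(task, "_fits.csv")), "fit"),
                         show_col_types = FALSE, progress = FALSE)
    structure(f, class = c("delay_scaling_fits", class(f)), task = task)
  }

  if (stage == "swing") {
    surface <- delay_surface_swing(swing_laws(), config = config)
    readr::write_csv(as.data.frame(surface), p("swing_surface.csv"))
    artifacts <- p("swing_surface.csv")
  } else if (stage == "posture") {
    surface <- delay_surface_posture(posture_laws(), config = config)
    readr::write_csv(as.data.frame(surface), p("posture_surface.csv"))
    artifacts <- p("posture_surface.csv")
  } else if (stage == "fit") {
    for (task in c("swing", "posture")) {
      f <- need(p(paste0(task, "_surface.csv")), task)
      surf <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      surf <- structure(surf, class = c("inertial_delay_surface", class(surf)),
                        task = task)
      fits <- fit_delay_scaling(surf)
      out <- dplyr::mutate(tibble::as_tibble(fits), coef_unit = "s",
                           .after = "coefficient")
      readr::write_csv(out, p(paste0(task, "_fits.csv")))
      artifacts <- c(artifacts, p(paste0(task, "_fits.csv")))
    }
  } else if (stage == "montecarlo") {
    if (is.null(seed)) stop("the montecarlo stage requires a seed", call. = FALSE)
    mc <- dplyr::bind_rows(
      propagate_uncertainty(swing_laws(), "swing",
                            n_draws = config$mc_draws, seed = seed,
                            config = config),
      propagate_uncertainty(posture_laws(), "posture",
                            n_draws = config$mc_draws, seed = seed + 1L,
                            config = config)
    )
    readr::write_csv(as.data.frame(mc), p("montecarlo.csv"))
    artifacts <- p("montecarlo.csv")
  } else if (stage == "response") {
    swing_fits <- read_fits("swing")
    posture_fits <- read_fits("posture")
    smd <- build_sensorimotor_model(swing_fits, config = config)
    smd_p <- build_sensorimotor_model(posture_fits, config = config)
    cross <- dplyr::bind_rows(
      purrr::map(list(list(f = swing_fits, s = smd),
                      list(f = posture_fits, s = smd_p)),
                 function(x) {
                   law <- fit_crossover_law(x$f, x$s, config = config)
                   tibble::tibble(task = law$task,
                                  smd_coefficient_ms = 1e3 * x$s$coefficient,
                                  coefficient = law$coefficient,
                                  exponent = law$exponent)
                 })
    )
    readr::write_csv(cross, p("crossover_laws.csv"))
    rrt <- relative_response_time(swing_fits, smd, config = config)
    law <- attr(rrt, "law")
    frac <- dplyr::mutate(rrt,
                          sensorimotor_fraction = .data$sensorimotor_s / .data$available_s,
                          inertial_fraction = .data$inertial_s / .data$available_s)
    readr::write_csv(frac, p("relative_response_time.csv"))
    readr::write_csv(tibble::tibble(coefficient = law$coefficient,
                                    exponent = law$exponent),
                     p("relative_response_law.csv"))
    artifacts <- p(c("crossover_laws.csv", "relative_response_time.csv",
                     "relative_response_law.csv"))
  } else if (stage == "report") {
    report <- dplyr::bind_rows(
      purrr::map(c("swing", "posture"), function(task) {
        fits <- read_fits(task)
        tibble::tibble(task = task,
                       average_exponent = average_exponent(fits),
                       min_coefficient_ms = 1e3 * min(fits$coefficient),
                       max_coefficient_ms = 1e3 * max(fits$coefficient),
                       n_magnitudes = nrow(fits))
      })
    )
    readr::write_csv(report, p("report.csv"))
    jsonlite::write_json(
      list(swing_average_exponent = report$average_exponent[1],
           posture_average_exponent = report$average_exponent[2]),
      p("report.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- p(c("report.csv", "report.json"))
  } else if (stage == "synth") {
    if (is.null(seed)) stop("the synth stage requires a seed", call. = FALSE)
    set.seed(seed)
    for (task in c("swing", "posture")) {
      ref <- if (task == "swing") swing_laws() else posture_laws()
      tbl <- generate_parameter_table(ref, seed = NULL)
      write_scaling_table(tbl, p(paste0("synthetic_", task, "_laws.csv")))
      artifacts <- c(artifacts, p(paste0("synthetic_", task, "_laws.csv")))
    }
  }

  manifest <- list(
    stage = stage,
    package = "inertialdelay",
    version = as.character(utils::packageVersion("inertialdelay")),
    seed = seed,
    config_hash = rlang::hash(config),
    artifacts = basename(artifacts)
  )
  jsonlite::write_json(manifest, p(paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, stage = stage,
                 artifacts = c(artifacts, p(paste0("manifest_", stage, ".json")))))
}
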