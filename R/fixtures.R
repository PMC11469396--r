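#' Specification for the synthetic input generator
#'
#' Describes the shape and ground truth of a fully synthetic set of pipeline
#' inputs: regions, air-monitoring-style exposures, screening-style
#' concentration-response curves, census-style age pyramids,
#' surveillance-style obesity prevalences, handbook-style inhalation rates,
#' and toxicokinetic-style Css samples. Defaults mirror a modest
#' single-assay study: 10 regions, 7 chemicals, 1 assay, with Hill tops in
#' 50-120 percent activity, AC50s spanning 0.1-10 uM, Hill coefficients in
#' 0.8-2, and residual noise of 3 percent activity.
#'
#' @param n_regions,n_chemicals,n_assays Shape of the synthetic study.
#' @param n_per_stratum Stored Css samples per stratum (the tractable
#'   toxicokinetic simulation size that bootstrap resampling then expands).
#' @param tp_range,log10_ga_range,gw_range True Hill parameter ranges.
#' @param noise_sd Residual noise of the concentration-response responses,
#'   percent activity.
#' @param exposure_mean_range Range of per-region per-chemical exposure
#'   means, ug/m3; standard deviations are 30 percent of the mean.
#' @param obesity_range Range of regional obesity prevalences, percent.
#' @param css_meanlog_range Range of per-chemical lognormal `meanlog` for
#'   Css samples (log uM per mg/kg/day); `sdlog` is fixed at 0.5 and obese
#'   strata shift `meanlog` by +0.2.
#' @param seed Generator seed (mandatory: fixtures are reproducible).
#' @return A list of class `mixrisk_fixture_spec`.
#' @export
fixture_spec <- function(n_regions = 10, n_chemicals = 7, n_assays = 1,
                         n_per_stratum = 200,
                         tp_range = c(50, 120), log10_ga_range = c(-1, 1),
                         gw_range = c(0.8, 2), noise_sd = 3,
                         exposure_mean_range = c(0.05, 2),
                         obesity_range = c(20, 45),
                         css_meanlog_range = c(-1, 1),
                         seed = 1L) {
  stopifnot(n_regions >= 1, n_chemicals >= 1, n_assays >= 1,
            noise_sd >= 0, n_per_stratum >= 1)
  structure(
    list(n_regions = n_regions, n_chemicals = n_chemicals,
         n_assays = n_assays, n_per_stratum = n_per_stratum,
         tp_range = tp_range, log10_ga_range = log10_ga_range,
         gw_range = gw_range, noise_sd = noise_sd,
         exposure_mean_range = exposure_mean_range,
         obesity_range = obesity_range,
         css_meanlog_range = css_meanlog_range,
         seed = as.integer(seed)),
    class = "mixrisk_fixture_spec"
  )
}

fixture_casrns <- function(n) sprintf("%d-%02d-%d", 100 + seq_len(n),
                                      (17 * seq_len(n)) %% 100,
                                      seq_len(n) %% 10)
fixture_assays <- function(n) sprintf("ASSAY_%03d", seq_len(n))

#' Generate synthetic region polygons
#'
#' Lays `n_regions` unit squares on a grid, ids `"SYN001"` upward, and
#' optionally writes them as a GeoJSON FeatureCollection.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional GeoJSON output file.
#' @return Tibble with `region_id` and `geometry` (one closed square ring
#'   each), compatible with [read_regions()] output.
#' @export
gen_regions <- function(spec, path = NULL) {
  n <- spec$n_regions
  ncol_grid <- ceiling(sqrt(n))
  geoms <- lapply(seq_len(n) - 1L, function(k) {
    x <- k %% ncol_grid
    y <- k %/% ncol_grid
    ring <- rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1),
                  c(x, y))
    list(ring)
  })
  regions <- tibble::tibble(
    region_id = sprintf("SYN%03d", seq_len(n)),
    geometry = geoms
  )
  if (!is.null(path)) {
    empty <- tibble::tibble(region_id = character(0), metric = character(0),
                            prob = numeric(0), value = numeric(0))
    write_region_results(empty, regions, path)
  }
  regions
}

#' Generate synthetic concentration-response data with known truth
#'
#' For each chemical-by-assay pair, draws true Hill parameters uniformly
#' from the spec ranges and emits noisy responses
#' `hill_response(conc) + Normal(0, noise_sd)` on a log-spaced concentration
#' grid.
#'
#' @param spec A [fixture_spec()].
#' @param n_conc Number of grid concentrations (log-spaced over `1e-3` to
#'   `1e2` uM).
#' @param n_rep Replicates per concentration.
#' @return List with `records` (a `conc_resp` table with a `hit` column,
#'   all `TRUE`) and `truth` (casrn, assay, true `tp`, `log10_ga`, `gw`,
#'   `sigma`).
#' @export
gen_concresp <- function(spec, n_conc = 11, n_rep = 3) {
  set.seed(spec$seed + 1L)
  chems <- fixture_casrns(spec$n_chemicals)
  assays <- fixture_assays(spec$n_assays)
  conc_grid <- 10^seq(-3, 2, length.out = n_conc)
  truth <- tidyr::expand_grid(casrn = chems, assay = assays) |>
    dplyr::mutate(
      tp = stats::runif(dplyr::n(), spec$tp_range[1], spec$tp_range[2]),
      log10_ga = stats::runif(dplyr::n(), spec$log10_ga_range[1],
                              spec$log10_ga_range[2]),
      gw = stats::runif(dplyr::n(), spec$gw_range[1], spec$gw_range[2]),
      sigma = spec$noise_sd
    )
  records <- truth |>
    dplyr::rowwise() |>
    dplyr::reframe(
      casrn = .data$casrn, assay = .data$assay,
      conc = rep(conc_grid, n_rep),
      resp = hill_response(rep(conc_grid, n_rep), .data$tp,
                           10^.data$log10_ga, .data$gw) +
        stats::rnorm(n_conc * n_rep, 0, .data$sigma),
      hit = TRUE
    )
  list(records = records, truth = truth)
}

#' Generate synthetic population input tables
#'
#' Emits schema-valid age, obesity, inhalation-rate, exposure, and Css
#' tables for the spec's regions and chemicals, plus the ground-truth
#' parameters behind them. The age pyramid is a gently declining decade
#' structure; inhalation rates decline with age as in exposure-factor
#' handbooks; Css samples are lognormal per stratum with recorded
#' `(meanlog, sdlog)`.
#'
#' @param spec A [fixture_spec()].
#' @param degenerate If `TRUE`, all variances are zeroed (exposure sd 0,
#'   obesity CI collapsed, inhalation-rate sd 0, single-age bins, constant
#'   Css per stratum), making the downstream pipeline fully deterministic
#'   and predictable in closed form.
#' @return List of tibbles: `age`, `obesity`, `ir`, `exposure`, `css`, and
#'   `css_truth` (per casrn-by-stratum `meanlog`, `sdlog`).
#' @export
gen_population_inputs <- function(spec, degenerate = FALSE) {
  set.seed(spec$seed + 2L)
  regions <- sprintf("SYN%03d", seq_len(spec$n_regions))
  chems <- fixture_casrns(spec$n_chemicals)

  if (degenerate) {
    age <- tidyr::expand_grid(region_id = regions) |>
      dplyr::mutate(age_lo = 40L, age_hi = 40L, count = 100)
  } else {
    decades <- tibble::tibble(age_lo = seq(0L, 80L, 10L),
                              age_hi = c(seq(9L, 79L, 10L), 100L))
    age <- tidyr::expand_grid(region_id = regions, decades) |>
      dplyr::mutate(count = round(1000 * (1 - 0.07 * (.data$age_lo / 10)) *
                                    stats::runif(dplyr::n(), 0.8, 1.2)))
  }

  prev <- stats::runif(length(regions), spec$obesity_range[1],
                       spec$obesity_range[2])
  half_ci <- if (degenerate) 0 else 1.5
  obesity <- tibble::tibble(region_id = regions, prev = prev,
                            ci_lo = pmax(prev - half_ci, 0),
                            ci_hi = pmin(prev + half_ci, 100))

  ir <- tibble::tibble(
    age_lo = c(0L, 2L, 6L, 11L, 16L, 21L, 31L, 61L),
    age_hi = c(1L, 5L, 10L, 15L, 20L, 30L, 60L, 100L),
    ir_mean = c(0.50, 0.45, 0.38, 0.30, 0.25, 0.22, 0.20, 0.18)
  )
  ir$ir_sd <- if (degenerate) 0 else 0.15 * ir$ir_mean

  exposure <- tidyr::expand_grid(region_id = regions, casrn = chems) |>
    dplyr::mutate(
      mean = stats::runif(dplyr::n(), spec$exposure_mean_range[1],
                          spec$exposure_mean_range[2]),
      sd = if (degenerate) 0 else 0.3 * .data$mean
    )

  strata <- tidyr::expand_grid(
    casrn = chems,
    age_group = css_age_groups()$age_group,
    weight_status = c("Normal", "Obese")
  )
  css_truth <- strata |>
    dplyr::group_by(.data$casrn) |>
    dplyr::mutate(
      meanlog = stats::runif(1, spec$css_meanlog_range[1],
                             spec$css_meanlog_range[2]) +
        ifelse(.data$weight_status == "Obese", 0.2, 0),
      sdlog = if (degenerate) 0 else 0.5
    ) |>
    dplyr::ungroup()
  css <- css_truth |>
    dplyr::rowwise() |>
    dplyr::reframe(
      casrn = .data$casrn, age_group = .data$age_group,
      weight_status = .data$weight_status,
      css = stats::rlnorm(spec$n_per_stratum, .data$meanlog, .data$sdlog)
    )

  list(age = age, obesity = obesity, ir = ir, exposure = exposure,
       css = css, css_truth = css_truth)
}

#' Write a complete synthetic input directory
#'
#' Generates every pipeline input plus ground-truth tables and writes them
#' to `dir`: `regions.geojson`, the canonical CSVs (`exposure.csv`,
#' `age.csv`, `obesity.csv`, `ir.csv`, `css.csv`, `conc_resp.csv`), and the
#' truth tables (`true_hill.csv`, `true_css.csv`).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param degenerate Passed to [gen_population_inputs()].
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(spec, dir, degenerate = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen_regions(spec, file.path(dir, "regions.geojson"))
  cr <- gen_concresp(spec)
  pop <- gen_population_inputs(spec, degenerate = degenerate)
  readr::write_csv(cr$records, file.path(dir, "conc_resp.csv"))
  readr::write_csv(cr$truth, file.path(dir, "true_hill.csv"))
  for (nm in c("age", "obesity", "ir", "exposure", "css")) {
    readr::write_csv(pop[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(pop$css_truth, file.path(dir, "true_css.csv"))
  invisible(dir)
}

#' Load a fixture directory into a state
#'
#' @param dir Directory written by [write_fixtures()].
#' @param config A [risk_config()].
#' @return A `mixrisk_state` ready for [run_pipeline()].
#' @export
load_inputs <- function(dir, config = risk_config()) {
  need <- c("regions.geojson", "exposure.csv", "age.csv", "obesity.csv",
            "ir.csv", "css.csv", "conc_resp.csv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files) > 0) {
    stop("input directory is missing: ",
         paste(file.path(dir, missing_files), collapse = ", "),
         call. = FALSE)
  }
  risk_state(
    config = config,
    regions = read_regions(file.path(dir, "regions.geojson")),
    exposure = read_table(file.path(dir, "exposure.csv"), "exposure"),
    age = read_table(file.path(dir, "age.csv"), "age"),
    obesity = read_table(file.path(dir, "obesity.csv"), "obesity"),
    ir = read_table(file.path(dir, "ir.csv"), "ir"),
    css = read_table(file.path(dir, "css.csv"), "css"),
    conc_resp = read_table(file.path(dir, "conc_resp.csv"), "conc_resp")
  )
}
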