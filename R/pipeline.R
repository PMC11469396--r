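metric_column <- function(metric) {
  cols <- c("GCA.Eff" = "gca_eff", "IA.Eff" = "ia_eff",
            "GCA.HQ" = "gca_hq", "IA.HQ" = "ia_hq")
  if (!metric %in% names(cols)) {
    stop("unknown metric `", metric, "`; expected one of ",
         paste(names(cols), collapse = ", "), call. = FALSE)
  }
  cols[[metric]]
}

#' Fit Hill models for every chemical-by-assay pair in a state
#'
#' Fits the state's concentration-response table with [fit_hill_all()] and
#' stores the result in `hill_params`. If the table carries a logical `hit`
#' column (an upstream hit-call: the assay response was a statistically
#' significant departure from null), non-hit chemical-by-assay pairs are
#' excluded before fitting, so they never enter the mixture step.
#'
#' @param state A `mixrisk_state` with `conc_resp` populated.
#' @param n_params,error_model Passed to [fit_hill()].
#' @return The state with `hill_params` populated.
#' @export
fit_hill_state <- function(state, n_params = 2, error_model = "normal") {
  stopifnot(inherits(state, "mixrisk_state"))
  if (is.null(state$conc_resp)) {
    stop("state has no concentration-response data", call. = FALSE)
  }
  cr <- state$conc_resp
  if ("hit" %in% names(cr)) {
    cr <- cr |>
      dplyr::group_by(.data$casrn, .data$assay) |>
      dplyr::filter(all(.data$hit)) |>
      dplyr::ungroup()
  }
  set.seed(state$config$seed)  # jittered optimizer restarts
  state$hill_params <- fit_hill_all(cr, n_params = n_params,
                                    error_model = error_model)
  state
}

# Region-filtered input bundle used by the simulators.
region_inputs <- function(state, rid) {
  list(
    age = state$age[state$age$region_id == rid, ],
    obesity = state$obesity[state$obesity$region_id == rid, ],
    ir = state$ir,
    exposure = state$exposure[state$exposure$region_id == rid, ],
    css = state$css
  )
}

#' Simulate populations for every region in a state
#'
#' Runs the Monte Carlo population chain ([simulate_population()]) for each
#' region under the state's configuration. The whole simulation is seeded
#' once from `config$seed`, so a given state yields bit-identical
#' populations on every run.
#'
#' @param state A `mixrisk_state` with the population input tables loaded.
#' @return The state with `population` populated (one entry per region).
#' @export
simulate_state <- function(state) {
  stopifnot(inherits(state, "mixrisk_state"))
  for (nm in c("age", "obesity", "ir", "exposure", "css")) {
    if (is.null(state[[nm]])) {
      stop("state is missing input table `", nm, "`", call. = FALSE)
    }
  }
  set.seed(state$config$seed)
  n <- state$config$n_per_region
  pops <- lapply(state$regions$region_id, function(rid) {
    simulate_population(rid, region_inputs(state, rid), n,
                        config = state$config)
  })
  names(pops) <- state$regions$region_id
  state$population <- pops
  state
}

#' Compute mixture responses for every region and assay
#'
#' Applies [calc_response()] to each simulated region for each fitted assay.
#' The same population draw is reused across assays, so an individual's
#' metrics are matched between assays.
#'
#' @param state A `mixrisk_state` with `population` and `hill_params`.
#' @return The state with `responses`: a long tibble with `region_id`,
#'   `assay`, `individual`, `gca_eff`, `ia_eff`, `gca_hq`, `ia_hq`.
#' @export
calc_response_state <- function(state) {
  stopifnot(inherits(state, "mixrisk_state"))
  if (is.null(state$population)) stop("simulate the population first",
                                      call. = FALSE)
  if (is.null(state$hill_params)) stop("fit Hill models first", call. = FALSE)
  assays <- unique(state$hill_params$assay)
  res <- purrr::map_dfr(state$population, function(p) {
    purrr::map_dfr(assays, function(a) {
      hp <- state$hill_params[state$hill_params$assay == a, ]
      out <- calc_response(p$c_invitro, hp,
                           fraction = state$config$hq_fraction)
      out$region_id <- p$region_id
      out$assay <- a
      out
    })
  })
  state$responses <- res |>
    dplyr::select("region_id", "assay", "individual", "gca_eff", "ia_eff",
                  "gca_hq", "ia_hq", "gca_flag", "hq_flag")
  attr(state$responses, "chemicals") <-
    intersect(colnames(state$population[[1]]$c_invitro),
              state$hill_params$casrn)
  state
}

#' Run the full source-to-outcome pipeline
#'
#' Fit, simulate, compute responses, and summarize, in order.
#'
#' @param state A `mixrisk_state` with all input tables loaded.
#' @param n_params Hill model size for the fitting step.
#' @return The state with every pipeline field populated.
#' @export
run_pipeline <- function(state, n_params = 2) {
  state |>
    fit_hill_state(n_params = n_params) |>
    simulate_state() |>
    calc_response_state() |>
    summarize_state_responses()
}
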