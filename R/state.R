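#' Analysis configuration
#'
#' Collects the tunable parameters of a mixture-risk analysis.
#'
#' @param seed Integer seed controlling every stochastic step.
#' @param n_per_region Simulated individuals per region.
#' @param time_days Exposure duration, days. Default 1: the plasma
#'   concentration step assumes steady state, reached within a day.
#' @param dose_scaling Unit conversion in the internal-dose step. Default
#'   `1e-3` (ug to mg).
#' @param hq_fraction Benchmark fraction of the limiting mixture response
#'   used by the hazard quotients. Default 0.10.
#' @param assay_quantiles Probabilities for the per-assay (individual-level)
#'   quantile summaries.
#' @param summary_quantiles Probabilities for the across-assay summary of
#'   the assay-level quantiles.
#' @param metric Default risk metric, one of `"GCA.Eff"`, `"IA.Eff"`,
#'   `"GCA.HQ"`, `"IA.HQ"`.
#' @return A list of class `mixrisk_config`.
#' @export
risk_config <- function(seed = 1L,
                        n_per_region = 100L,
                        time_days = 1,
                        dose_scaling = 1e-3,
                        hq_fraction = 0.10,
                        assay_quantiles = c(0.1, 0.5, 0.9),
                        summary_quantiles = c(0.05, 0.10),
                        metric = c("GCA.Eff", "IA.Eff", "GCA.HQ", "IA.HQ")) {
  metric <- match.arg(metric)
  stopifnot(n_per_region >= 1,
            all(assay_quantiles > 0), all(assay_quantiles < 1),
            all(summary_quantiles > 0), all(summary_quantiles < 1),
            hq_fraction > 0, hq_fraction < 1)
  structure(
    list(seed = as.integer(seed), n_per_region = as.integer(n_per_region),
         time_days = time_days, dose_scaling = dose_scaling,
         hq_fraction = hq_fraction, assay_quantiles = assay_quantiles,
         summary_quantiles = summary_quantiles, metric = metric),
    class = "mixrisk_config"
  )
}

#' Assemble a mixture-risk analysis state
#'
#' The state is the single container threaded through the pipeline: input
#' tables in, then fitted Hill parameters, simulated populations, mixture
#' responses, and summaries as the corresponding steps run. Chemical
#' identity is keyed by CASRN throughout; matrices order their chemical
#' columns by sorted CASRN.
#'
#' @param config A [risk_config()].
#' @param regions Tibble with `region_id` and an optional `geometry`
#'   list-column (polygon rings), e.g. from [read_regions()].
#' @param exposure,age,obesity,ir,css,conc_resp Input tables (see the
#'   `read_*` readers for their schemas). Any may be `NULL` for a partially
#'   constructed state.
#' @return A list of class `mixrisk_state` with additionally `chemicals`,
#'   and empty slots `hill_params`, `population`, `responses`, `sensitivity`.
#' @export
risk_state <- function(config = risk_config(), regions = NULL,
                       exposure = NULL, age = NULL, obesity = NULL,
                       ir = NULL, css = NULL, conc_resp = NULL) {
  chems <- sort(unique(c(exposure$casrn, css$casrn, conc_resp$casrn)))
  st <- structure(
    list(config = config, regions = regions,
         chemicals = tibble::tibble(casrn = chems),
         exposure = exposure, age = age, obesity = obesity, ir = ir,
         css = css, conc_resp = conc_resp,
         hill_params = NULL, population = NULL, responses = NULL,
         region_summary = NULL, multi_assay = NULL, sensitivity = NULL),
    class = "mixrisk_state"
  )
  validate_state(st)
  st
}

# Cross-table consistency checks; called at construction and after load.
validate_state <- function(st) {
  ids <- st$regions$region_id
  if (!is.null(ids) && anyDuplicated(ids)) {
    stop("duplicate region_id in regions", call. = FALSE)
  }
  for (nm in c("exposure", "age", "obesity")) {
    tab <- st[[nm]]
    if (!is.null(tab) && !is.null(ids) &&
        !all(unique(tab$region_id) %in% ids)) {
      stop("table `", nm, "` references unknown region_id", call. = FALSE)
    }
  }
  if (!is.null(st$responses)) {
    resp_chems <- attr(st$responses, "chemicals")
    if (!is.null(resp_chems)) {
      for (tab in c("exposure", "css")) {
        have <- unique(st[[tab]]$casrn)
        if (!all(resp_chems %in% have)) {
          stop("responses reference chemicals missing from `", tab, "`",
               call. = FALSE)
        }
      }
    }
  }
  invisible(st)
}

populated_fields <- function(st) {
  fields <- c("regions", "exposure", "age", "obesity", "ir", "css",
              "conc_resp", "hill_params", "population", "responses",
              "region_summary", "multi_assay", "sensitivity")
  vapply(fields, function(f) !is.null(st[[f]]), logical(1))
}

#' Summarize a mixture-risk state
#'
#' Reports region count, simulated individuals per region, chemicals,
#' assays, and which pipeline fields are populated. Never mutates the state.
#'
#' @param state A `mixrisk_state`.
#' @return A character vector of summary lines, invisibly printed.
#' @export
summarize_state <- function(state) {
  stopifnot(inherits(state, "mixrisk_state"))
  n_regions <- if (is.null(state$regions)) 0L else nrow(state$regions)
  n_chem <- nrow(state$chemicals)
  assays <- if (!is.null(state$hill_params)) {
    unique(state$hill_params$assay)
  } else if (!is.null(state$conc_resp)) {
    unique(state$conc_resp$assay)
  } else character(0)
  n_per <- if (!is.null(state$population)) {
    unique(vapply(state$population, function(p) p$n, integer(1)))
  } else integer(0)
  pf <- populated_fields(state)
  lines <- c(
    "mixture-risk analysis state",
    sprintf("  %d regions, %s simulated individuals per region",
            n_regions,
            if (length(n_per) == 0) "0" else
              paste(sort(n_per), collapse = "/")),
    sprintf("  %d chemicals, %d assays", n_chem, length(assays)),
    "  fields:",
    sprintf("    %-16s %s", names(pf), ifelse(pf, "present", "absent"))
  )
  lines
}

#' @export
print.mixrisk_state <- function(x, ...) {
  cat(summarize_state(x), sep = "\n")
  invisible(x)
}

#' @export
print.mixrisk_config <- function(x, ...) {
  cat("mixture-risk configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy the fitted Hill parameters of a state
#'
#' @param x A `mixrisk_state` with fitted `hill_params`.
#' @param ... Unused.
#' @return The `hill_params` tibble (one row per chemical-by-assay).
#' @export
tidy.mixrisk_state <- function(x, ...) {
  if (is.null(x$hill_params)) {
    stop("state has no fitted Hill parameters; run `fit_hill_state()`",
         call. = FALSE)
  }
  x$hill_params
}

#' One-row overview of a state
#'
#' @param x A `mixrisk_state`.
#' @param ... Unused.
#' @return A one-row tibble: region, chemical, assay, and individual counts,
#'   plus flags for the populated pipeline stages.
#' @export
glance.mixrisk_state <- function(x, ...) {
  pf <- populated_fields(x)
  tibble::tibble(
    n_regions = if (is.null(x$regions)) 0L else nrow(x$regions),
    n_chemicals = nrow(x$chemicals),
    n_assays = if (is.null(x$hill_params)) 0L else
      length(unique(x$hill_params$assay)),
    n_per_region = x$config$n_per_region,
    fitted = pf[["hill_params"]],
    simulated = pf[["population"]],
    responses = pf[["responses"]],
    summarized = pf[["region_summary"]]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
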