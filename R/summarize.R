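#' Regional quantile summaries of a risk metric
#'
#' Summarizes the per-individual mixture metrics as empirical quantiles
#' (linear interpolation of order statistics, quantile type 7) per region
#' and assay.
#'
#' @param responses Long response tibble as produced by
#'   [calc_response_state()] (columns `region_id`, `assay`, and the metric
#'   columns `gca_eff`, `ia_eff`, `gca_hq`, `ia_hq`).
#' @param metric Metric name: `"GCA.Eff"`, `"IA.Eff"`, `"GCA.HQ"`, or
#'   `"IA.HQ"`.
#' @param probs Quantile probabilities.
#' @return Tibble with `region_id`, `assay`, `metric`, `prob`, `value`.
#' @export
summarize_region <- function(responses, metric = "GCA.Eff",
                             probs = c(0.1, 0.5, 0.9)) {
  col <- metric_column(metric)
  stopifnot(nrow(responses) > 0)
  responses |>
    dplyr::group_by(.data$region_id, .data$assay) |>
    dplyr::reframe(
      metric = metric,
      prob = probs,
      value = stats::quantile(.data[[col]], probs, type = 7, names = FALSE,
                              na.rm = TRUE)
    )
}

#' Multi-assay quantile-of-quantiles summary
#'
#' Condenses many assay endpoints into one regional number: for each region,
#' the value is the `summary_p` quantile, across assays, of the assay-level
#' `assay_q` quantiles of the per-individual metric. Low summary
#' probabilities give conservative estimates that avoid the extreme low
#' points of departure of any single assay.
#'
#' @param region_summaries Output of [summarize_region()], covering every
#'   assay at each requested `assay_q`.
#' @param assay_q Assay-level (individual-quantile) probabilities.
#' @param summary_p Across-assay summary probabilities.
#' @return Tibble with `region_id`, `metric`, `assay_q`, `summary_p`,
#'   `value`.
#' @export
summarize_multi_assay <- function(region_summaries,
                                  assay_q = c(0.1, 0.5, 0.9),
                                  summary_p = c(0.05, 0.10)) {
  assays <- unique(region_summaries$assay)
  grid <- tidyr::expand_grid(assay_q = assay_q, summary_p = summary_p)
  purrr::pmap_dfr(grid, function(assay_q, summary_p) {
    at_q <- region_summaries[abs(region_summaries$prob - assay_q) < 1e-12, ]
    missing_assays <- setdiff(assays, unique(at_q$assay))
    if (length(missing_assays) > 0) {
      stop("assay(s) missing their quantile at prob ", assay_q, ": ",
           paste(missing_assays, collapse = ", "), call. = FALSE)
    }
    at_q |>
      dplyr::group_by(.data$region_id, .data$metric) |>
      dplyr::summarise(
        value = stats::quantile(.data$value, summary_p, type = 7,
                                names = FALSE),
        .groups = "drop"
      ) |>
      dplyr::mutate(assay_q = assay_q, summary_p = summary_p)
  }) |>
    dplyr::select("region_id", "metric", "assay_q", "summary_p", "value")
}

#' Summarize a state's responses
#'
#' Fills `region_summary` (per-assay regional quantiles at the configured
#' `assay_quantiles`) and `multi_assay` (quantile-of-quantiles at the
#' configured `summary_quantiles`) for the configured metric.
#'
#' @param state A `mixrisk_state` with `responses`.
#' @return The state with both summary fields populated.
#' @export
summarize_state_responses <- function(state) {
  stopifnot(inherits(state, "mixrisk_state"))
  if (is.null(state$responses)) stop("compute responses first", call. = FALSE)
  cfg <- state$config
  state$region_summary <- summarize_region(state$responses, cfg$metric,
                                           probs = cfg$assay_quantiles)
  state$multi_assay <- summarize_multi_assay(state$region_summary,
                                             assay_q = cfg$assay_quantiles,
                                             summary_p = cfg$summary_quantiles)
  state
}

# Central (fixed) values used by the sensitivity baseline, per region.
central_values <- function(state, rid) {
  cfg <- state$config
  inputs <- region_inputs(state, rid)
  # median simulated age, deterministic under the state's seed
  set.seed(cfg$seed)
  age_c <- as.integer(round(stats::median(
    simulate_age(inputs$age, cfg$n_per_region))))
  obese_c <- inputs$obesity$prev >= 50
  j <- which(state$ir$age_lo <= age_c & age_c <= state$ir$age_hi)[1]
  ir_c <- state$ir$ir_mean[j]
  grp <- age_to_css_group(age_c)
  ws <- if (obese_c) "Obese" else "Normal"
  css_tab <- state$css[state$css$age_group == grp &
                         state$css$weight_status == ws, ]
  css_c <- tapply(css_tab$css, css_tab$casrn, stats::median)
  exp_tab <- inputs$exposure[order(inputs$exposure$casrn), ]
  list(age = age_c, obese = obese_c, ir = ir_c,
       css = css_c[sort(names(css_c))],
       exposure_mean = stats::setNames(exp_tab$mean, exp_tab$casrn))
}

# Build one region's population with a single quantity stochastic and the
# rest pinned at central values.
simulate_population_oat <- function(state, rid, vary) {
  cfg <- state$config
  n <- cfg$n_per_region
  cv <- central_values(state, rid)
  inputs <- region_inputs(state, rid)

  age <- if (vary == "age") simulate_age(inputs$age, n) else
    rep(cv$age, n)
  obese <- if (vary == "obesity") {
    simulate_obesity(inputs$obesity$prev, inputs$obesity$ci_lo,
                     inputs$obesity$ci_hi, n)
  } else rep(cv$obese, n)
  ir <- if (vary == "inhalation_rate") {
    simulate_inhalation_rate(age, inputs$ir)
  } else if (vary == "age") {
    # inhalation rate follows age deterministically through bracket means
    idx <- vapply(age, function(a) {
      which(inputs$ir$age_lo <= a & a <= inputs$ir$age_hi)[1]
    }, integer(1))
    inputs$ir$ir_mean[idx]
  } else rep(cv$ir, n)

  chems <- sort(names(cv$exposure_mean))
  c_ext <- if (vary == "exposure") {
    simulate_exposure(inputs$exposure, n)
  } else {
    matrix(rep(cv$exposure_mean[chems], each = n), n,
           dimnames = list(NULL, chems))
  }
  css <- if (vary == "css") {
    sample_css(inputs$css, age, obese)
  } else {
    css_chems <- sort(names(cv$css))
    m <- matrix(rep(cv$css[css_chems], each = n), n,
                dimnames = list(NULL, css_chems))
    if (vary %in% c("age", "obesity")) {
      # stratum medians follow the varied covariate
      grp <- age_to_css_group(age)
      ws <- ifelse(obese, "Obese", "Normal")
      for (ch in css_chems) {
        tab <- state$css[state$css$casrn == ch, ]
        med <- tapply(tab$css, paste(tab$age_group, tab$weight_status),
                      stats::median)
        m[, ch] <- med[paste(grp, ws)]
      }
    }
    m
  }
  shared <- intersect(colnames(c_ext), colnames(css))
  c_ext <- c_ext[, sort(shared), drop = FALSE]
  css <- css[, sort(shared), drop = FALSE]
  d_int <- calc_internal_dose(c_ext, ir, time_days = cfg$time_days,
                              scaling = cfg$dose_scaling)
  structure(
    list(region_id = rid, n = n, age = age, obese = obese, ir = ir,
         c_ext = c_ext, d_int = d_int, css = css,
         c_invitro = calc_invitro_concentration(d_int, css)),
    class = "mixrisk_population"
  )
}

# Perturb fitted Hill parameters with their standard errors (independent
# normals on tp and log10_ga; parameter covariance ignored).
perturb_hill_params <- function(hill_params) {
  hp <- hill_params
  se_tp <- ifelse(is.finite(hp$se_tp), hp$se_tp, 0)
  se_ga <- ifelse(is.finite(hp$se_log10_ga), hp$se_log10_ga, 0)
  hp$tp <- pmax(stats::rnorm(nrow(hp), hp$tp, se_tp), 1e-6)
  hp$log10_ga <- stats::rnorm(nrow(hp), hp$log10_ga, se_ga)
  hp
}

#' One-at-a-time sensitivity analysis
#'
#' Reruns the pipeline once per named parameter, letting only that
#' parameter's input distribution vary while everything else is pinned to a
#' central value: exposure at its reported mean, age at the region's median
#' simulated age, obesity at the majority status, inhalation rate at its
#' bracket mean, Css at its stratum median, and Hill parameters at their
#' point estimates. `fit_params` instead perturbs the fitted `(tp,
#' log10_ga)` with their standard errors per individual. The all-fixed
#' baseline (`vary = "baseline"`) is degenerate: every individual in a
#' region gets the same metric value.
#'
#' @param state A `mixrisk_state` that has been fitted (`hill_params`).
#' @param vary Character vector from `"age"`, `"obesity"`,
#'   `"inhalation_rate"`, `"css"`, `"exposure"`, `"fit_params"`,
#'   `"baseline"`.
#' @param metric Metric to record; default the configured one.
#' @return The state with `sensitivity`: a long tibble with `param`,
#'   `region_id`, `assay`, `individual`, `metric`, `value`.
#' @export
compute_sensitivity <- function(state,
                                vary = c("age", "obesity", "inhalation_rate",
                                         "css", "exposure", "fit_params"),
                                metric = NULL) {
  stopifnot(inherits(state, "mixrisk_state"))
  if (is.null(state$hill_params)) stop("fit Hill models first", call. = FALSE)
  known <- c("age", "obesity", "inhalation_rate", "css", "exposure",
             "fit_params", "baseline")
  bad <- setdiff(vary, known)
  if (length(bad) > 0) {
    stop("unknown sensitivity parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(metric)) metric <- state$config$metric
  col <- metric_column(metric)
  cfg <- state$config
  assays <- unique(state$hill_params$assay)

  out <- purrr::map_dfr(vary, function(v) {
    set.seed((cfg$seed + match(v, known) * 1009L) %% .Machine$integer.max)
    purrr::map_dfr(state$regions$region_id, function(rid) {
      pop_vary <- if (v == "fit_params") "baseline" else v
      p <- simulate_population_oat(state, rid, pop_vary)
      purrr::map_dfr(assays, function(a) {
        hp <- state$hill_params[state$hill_params$assay == a, ]
        vals <- if (v == "fit_params") {
          vapply(seq_len(p$n), function(i) {
            hp_i <- perturb_hill_params(hp)
            r <- calc_response(p$c_invitro[i, , drop = FALSE], hp_i,
                               fraction = cfg$hq_fraction)
            r[[col]][1]
          }, numeric(1))
        } else {
          calc_response(p$c_invitro, hp,
                        fraction = cfg$hq_fraction)[[col]]
        }
        tibble::tibble(param = v, region_id = rid, assay = a,
                       individual = seq_len(p$n), metric = metric,
                       value = vals)
      })
    })
  })
  state$sensitivity <- out
  state
}
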