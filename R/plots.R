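#' Exposure concentration densities
#'
#' Kernel densities of the simulated external exposure concentrations, one
#' panel per chemical, colored by region.
#'
#' @param state A `mixrisk_state` with `population`.
#' @return A ggplot object.
#' @export
plot_exposure <- function(state) {
  if (is.null(state$population)) stop("simulate the population first",
                                      call. = FALSE)
  df <- purrr::map_dfr(state$population, function(p) {
    tibble::as_tibble(p$c_ext) |>
      dplyr::mutate(region_id = p$region_id) |>
      tidyr::pivot_longer(-"region_id", names_to = "casrn",
                          values_to = "c_ext")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$c_ext, color = .data$region_id)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~casrn, scales = "free") +
    ggplot2::labs(x = "external concentration (ug/m3)", y = "density",
                  color = "region") +
    ggplot2::theme_minimal()
}

#' Fitted Hill curves over their data
#'
#' One panel per chemical-by-assay combination: the concentration-response
#' points and the fitted curve on a log concentration axis.
#'
#' @param state A `mixrisk_state` with `conc_resp` and `hill_params`.
#' @return A ggplot object.
#' @export
plot_hill <- function(state) {
  if (is.null(state$hill_params)) stop("fit Hill models first", call. = FALSE)
  obs <- state$conc_resp |> dplyr::filter(.data$conc > 0)
  grid <- state$hill_params |>
    dplyr::rowwise() |>
    dplyr::reframe(
      casrn = .data$casrn, assay = .data$assay,
      conc = 10^seq(log10(min(obs$conc)), log10(max(obs$conc)),
                    length.out = 100),
      resp = hill_response(10^seq(log10(min(obs$conc)), log10(max(obs$conc)),
                                  length.out = 100),
                           .data$tp, 10^.data$log10_ga, .data$gw)
    )
  ggplot2::ggplot(obs, ggplot2::aes(.data$conc, .data$resp)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ casrn + assay) +
    ggplot2::labs(x = "concentration (uM)", y = "response (% activity)") +
    ggplot2::theme_minimal()
}

#' Mixture response or hazard-quotient densities
#'
#' Kernel densities of a per-individual metric grouped by obesity status,
#' faceted by assay.
#'
#' @param state A `mixrisk_state` with `responses` and `population`.
#' @param metric Metric name (see [summarize_region()]).
#' @return A ggplot object.
#' @export
plot_response <- function(state, metric = NULL) {
  if (is.null(state$responses)) stop("compute responses first", call. = FALSE)
  if (is.null(metric)) metric <- state$config$metric
  col <- metric_column(metric)
  obese <- purrr::map_dfr(state$population, function(p) {
    tibble::tibble(region_id = p$region_id, individual = seq_len(p$n),
                   obese = p$obese)
  })
  df <- dplyr::left_join(state$responses, obese,
                         by = c("region_id", "individual")) |>
    dplyr::mutate(weight_status = ifelse(.data$obese, "Obese", "Normal"))
  ggplot2::ggplot(df, ggplot2::aes(.data[[col]], fill = .data$weight_status)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~assay, scales = "free") +
    ggplot2::labs(x = metric, y = "density", fill = "weight status") +
    ggplot2::theme_minimal()
}

#' Sensitivity analysis densities
#'
#' Kernel densities of the metric under each one-at-a-time varied
#' parameter.
#'
#' @param state A `mixrisk_state` with `sensitivity` results.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(state) {
  if (is.null(state$sensitivity)) {
    stop("no sensitivity results; run `compute_sensitivity()` first",
         call. = FALSE)
  }
  ggplot2::ggplot(state$sensitivity,
                  ggplot2::aes(.data$value, color = .data$param)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = unique(state$sensitivity$metric)[1], y = "density",
                  color = "varied parameter") +
    ggplot2::theme_minimal()
}

#' Regional choropleth of a metric quantile
#'
#' Fills each region polygon with its summary value for the chosen metric
#' and quantile probability.
#'
#' @param state A `mixrisk_state` with `region_summary` and region
#'   geometries.
#' @param metric Metric name; default the configured one.
#' @param prob Quantile probability; default 0.5.
#' @return A ggplot object.
#' @export
plot_map <- function(state, metric = NULL, prob = 0.5) {
  if (is.null(state$region_summary)) stop("summarize responses first",
                                          call. = FALSE)
  if (is.null(metric)) metric <- state$config$metric
  vals <- state$region_summary |>
    dplyr::filter(.data$metric == !!metric,
                  abs(.data$prob - !!prob) < 1e-12) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  if (nrow(vals) == 0) {
    stop("no summary at metric ", metric, ", prob ", prob, call. = FALSE)
  }
  poly <- purrr::map_dfr(seq_len(nrow(state$regions)), function(i) {
    rings <- state$regions$geometry[[i]]
    if (is.null(rings)) return(NULL)
    purrr::map_dfr(seq_along(rings), function(j) {
      m <- rings[[j]]
      tibble::tibble(region_id = state$regions$region_id[i],
                     ring = paste(i, j), x = m[, 1], y = m[, 2])
    })
  })
  df <- dplyr::left_join(poly, vals, by = "region_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$ring,
                                   fill = .data$value)) +
    ggplot2::geom_polygon(color = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = sprintf("%s q%g", metric, 100 * prob),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
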