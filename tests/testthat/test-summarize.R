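fake_responses <- function(values, region = "R1", assay = "a1") {
  tibble::tibble(region_id = region, assay = assay,
                 individual = seq_along(values),
                 gca_eff = values, ia_eff = values,
                 gca_hq = values, ia_hq = values)
}

test_that("regional summaries are empirical quantiles", {
  rs <- summarize_region(fake_responses(1:5), "GCA.Eff", probs = 0.5)
  expect_equal(rs$value, 3)
  rs2 <- summarize_region(fake_responses(rep(7, 10)), "IA.HQ",
                          probs = c(0.1, 0.5, 0.9))
  expect_equal(rs2$value, rep(7, 3))
  expect_error(summarize_region(fake_responses(1:5), "nope"),
               "unknown metric")
  set.seed(15)
  u <- runif(1e4)
  rs3 <- summarize_region(fake_responses(u), "GCA.Eff",
                          probs = c(0.1, 0.5, 0.9))
  expect_lt(max(abs(rs3$value - c(0.1, 0.5, 0.9))), 0.02)
  # values are non-decreasing in the probability
  expect_true(all(diff(rs3$value) >= 0))
})

test_that("multi-assay summaries collapse assay quantiles", {
  rs <- dplyr::bind_rows(
    summarize_region(fake_responses(1:5, assay = "a1"), probs = 0.5),
    summarize_region(fake_responses(11:15, assay = "a2"), probs = 0.5),
    summarize_region(fake_responses(21:25, assay = "a3"), probs = 0.5)
  )
  ma <- summarize_multi_assay(rs, assay_q = 0.5, summary_p = 0.5)
  expect_equal(ma$value, 13)  # median of the three assay medians 3, 13, 23
  # a single assay passes its quantile through unchanged
  one <- summarize_region(fake_responses(1:5), probs = 0.5)
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(summarize_multi_assay(one, 0.5, p)$value, 3)
  }
  # a missing assay-level quantile is an error naming the assay
  rs_missing <- dplyr::bind_rows(rs, tibble::tibble(
    region_id = "R1", assay = "a4", metric = "GCA.Eff", prob = 0.9,
    value = 1
  ))
  expect_error(summarize_multi_assay(rs_missing, 0.5, 0.5), "a4")
})

test_that("quantile-of-quantiles matches a brute-force two-pass oracle", {
  set.seed(16)
  n_assay <- 200
  n_region <- 20
  df <- tidyr::expand_grid(region_id = sprintf("R%02d", 1:n_region),
                           assay = sprintf("a%03d", 1:n_assay)) |>
    tidyr::expand_grid(individual = 1:25) |>
    dplyr::mutate(value = rlnorm(dplyr::n(), 0, 1))
  responses <- df |>
    dplyr::mutate(gca_eff = value, ia_eff = value, gca_hq = value,
                  ia_hq = value)
  for (q in c(0.1, 0.5, 0.9)) {
    rs <- summarize_region(responses, "GCA.HQ", probs = q)
    for (p in c(0.05, 0.1)) {
      ma <- summarize_multi_assay(rs, assay_q = q, summary_p = p)
      oracle <- brute_multi_assay(df, q, p)
      m <- ma$value[match(oracle$region_id, ma$region_id)]
      expect_identical(m, oracle$value)
    }
  }
})

test_that("sensitivity baseline is degenerate and OAT runs respond to
           their input spread", {
  st <- run_pipeline(tiny_state(n_regions = 2, n_per_region = 25, seed = 21))
  st <- compute_sensitivity(st, vary = c("baseline", "age", "obesity",
                                         "inhalation_rate", "css",
                                         "exposure", "fit_params"))
  v <- st$sensitivity |>
    dplyr::group_by(.data$param, .data$region_id, .data$assay) |>
    dplyr::summarise(v = stats::var(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(vmax = max(.data$v))
  expect_equal(v$vmax[v$param == "baseline"], 0)
  for (p in setdiff(v$param, "baseline")) {
    expect_gt(v$vmax[v$param == p], 0)
  }
  expect_error(compute_sensitivity(st, vary = "phase_of_moon"), "unknown")
})

test_that("degenerate inputs collapse every OAT distribution onto the
           baseline", {
  st <- tiny_state(n_regions = 1, n_assays = 1, n_per_region = 20,
                   seed = 22, degenerate = TRUE)
  # degenerate fixtures: single-age bins, collapsed CIs, zero sds
  st <- fit_hill_state(st)
  st <- compute_sensitivity(st, vary = c("baseline", "exposure", "css",
                                         "inhalation_rate", "age"))
  spread <- st$sensitivity |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(v = stats::var(.data$value))
  expect_true(all(spread$v[spread$param != "baseline"] < 1e-20))
  base <- st$sensitivity$value[st$sensitivity$param == "baseline"][1]
  expect_equal(unique(st$sensitivity$value), base, tolerance = 1e-12)
})

test_that("varying Css alone brackets the baseline (two-point oracle)", {
  st <- tiny_state(n_regions = 1, n_chemicals = 1, n_assays = 1,
                   n_per_region = 400, seed = 23, degenerate = TRUE)
  # replace the Css table by a two-point {1, 3} sample in every stratum;
  # the stratum median (baseline central value) is then 2
  st$css <- tidyr::expand_grid(
    casrn = unique(st$css$casrn),
    age_group = css_age_groups()$age_group,
    weight_status = c("Normal", "Obese")
  ) |> tidyr::expand_grid(css = c(1, 3))
  st <- fit_hill_state(st)
  st <- compute_sensitivity(st, vary = c("baseline", "css"))

  base <- unique(st$sensitivity$value[st$sensitivity$param == "baseline"])
  expect_length(base, 1)
  vals <- st$sensitivity$value[st$sensitivity$param == "css"]
  expect_true(all(vals <= max(vals) + 1e-12 & vals >= min(vals) - 1e-12))
  expect_gt(base, min(vals)); expect_lt(base, max(vals))

  # enumeration oracle: recompute the metric at css = 1 and css = 3 exactly
  p <- mixrisk:::simulate_population_oat(st, st$regions$region_id[1],
                                         "baseline")
  hp <- st$hill_params
  metric_at <- function(css_val) {
    ci <- p$d_int[1, , drop = FALSE] * css_val
    calc_response(ci, hp, fraction = st$config$hq_fraction)$gca_eff
  }
  two_point_mean <- mean(c(metric_at(1), metric_at(3)))
  expect_lt(abs(mean(vals) - two_point_mean),
            3 * stats::sd(vals) / sqrt(length(vals)) + 1e-9)
  # and every varied value equals one of the two enumerated outcomes
  expect_setequal(round(unique(vals), 9),
                  round(c(metric_at(1), metric_at(3)), 9))
})
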