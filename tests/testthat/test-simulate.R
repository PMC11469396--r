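test_that("age simulation respects bins, weights, and degenerate cases", {
  one <- tibble::tibble(age_lo = 20L, age_hi = 20L, count = 10)
  expect_equal(simulate_age(one, 5), rep(20L, 5))
  two <- tibble::tibble(age_lo = c(0L, 50L), age_hi = c(49L, 99L),
                        count = c(100, 0))
  set.seed(1)
  expect_true(all(simulate_age(two, 200) <= 49))
  expect_error(simulate_age(tibble::tibble(age_lo = 0L, age_hi = 9L,
                                           count = 0), 5), "zero")
  # bin mass 1:3 puts three quarters of draws in the second bin
  bins <- tibble::tibble(age_lo = c(0L, 10L), age_hi = c(9L, 19L),
                         count = c(1, 3))
  set.seed(2)
  frac <- mean(simulate_age(bins, 40000) >= 10)
  expect_lt(abs(frac - 0.75), 0.01)
  # within a bin, ages are uniform on the integers
  set.seed(3)
  a <- simulate_age(one |> dplyr::mutate(age_lo = 0L, age_hi = 9L), 40000)
  expect_true(all(table(a) / 40000 > 0.08 & table(a) / 40000 < 0.12))
})

test_that("obesity simulation propagates prevalence and its uncertainty", {
  expect_false(any(simulate_obesity(0, 0, 0, 100)))
  expect_true(all(simulate_obesity(100, 100, 100, 100)))
  set.seed(4)
  frac <- mean(simulate_obesity(40, 40, 40, 40000))
  expect_lt(abs(frac - 0.40), 0.01)
  # a wide CI inflates the variance of regional prevalence draws but not
  # the mean
  set.seed(5)
  frac_wide <- mean(simulate_obesity(40, 30, 50, 40000))
  expect_lt(abs(frac_wide - 0.40), 0.015)
  expect_error(simulate_obesity(40, 45, 50, 10))
})

test_that("inhalation rates follow the age brackets", {
  irt <- tibble::tibble(age_lo = c(0L, 50L), age_hi = c(49L, 100L),
                        ir_mean = c(0.4, 0.2), ir_sd = c(0, 0))
  ir <- simulate_inhalation_rate(c(10L, 60L, 20L), irt)
  expect_equal(ir, c(0.4, 0.2, 0.4))
  expect_error(simulate_inhalation_rate(150L, irt), "outside")
  set.seed(6)
  irt2 <- tibble::tibble(age_lo = 0L, age_hi = 100L, ir_mean = 0.25,
                         ir_sd = 0.05)
  draws <- simulate_inhalation_rate(rep(30L, 40000), irt2)
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - 0.25), 0.002)
})

test_that("exposure draws are truncated normals matching quadrature", {
  exp0 <- tibble::tibble(casrn = c("A", "B"), mean = c(0.5, 0), sd = c(0, 0))
  m <- simulate_exposure(exp0, 10)
  expect_equal(unname(m[, "A"]), rep(0.5, 10))
  expect_equal(unname(m[, "B"]), rep(0, 10))
  set.seed(7)
  expt <- tibble::tibble(casrn = "A", mean = 1, sd = 0.3)
  x <- simulate_exposure(expt, 40000)[, 1]
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - quadrature_truncnorm_mean(1, 0.3)), 0.005)
  # heavier truncation case against the quadrature oracle
  set.seed(8)
  y <- simulate_exposure(tibble::tibble(casrn = "A", mean = 0.2, sd = 0.5),
                         40000)[, 1]
  expect_lt(abs(mean(y) - quadrature_truncnorm_mean(0.2, 0.5)), 0.005)
})

test_that("empirical truncated-normal distribution matches its CDF", {
  set.seed(9)
  x <- simulate_exposure(tibble::tibble(casrn = "A", mean = 1, sd = 0.4),
                         40000)[, 1]
  cdf <- function(q) {
    (pnorm(q, 1, 0.4) - pnorm(0, 1, 0.4)) / (1 - pnorm(0, 1, 0.4))
  }
  grid <- seq(0.01, 3, length.out = 200)
  ks <- max(abs(ecdf(x)(grid) - cdf(grid)))
  expect_lt(ks, 0.02)
})

test_that("Css bootstrap respects strata", {
  groups <- css_age_groups()$age_group
  css <- tidyr::expand_grid(casrn = "X", age_group = groups,
                            weight_status = c("Normal", "Obese")) |>
    dplyr::mutate(css = 2.0)
  m <- sample_css(css, ages = c(10L, 30L, 70L), obese = c(TRUE, FALSE, TRUE))
  expect_equal(unname(m[, "X"]), rep(2.0, 3))
  # strata with disjoint ranges never leak into each other
  css2 <- tidyr::expand_grid(casrn = "X", age_group = groups,
                             weight_status = c("Normal", "Obese")) |>
    dplyr::rowwise() |>
    dplyr::reframe(casrn = .data$casrn, age_group = .data$age_group,
                   weight_status = .data$weight_status,
                   css = if (.data$weight_status == "Obese") {
                     runif(20, 10, 11)
                   } else runif(20, 1, 2))
  set.seed(10)
  m2 <- sample_css(css2, ages = rep(30L, 200),
                   obese = rep(c(TRUE, FALSE), 100))
  expect_true(all(m2[rep(c(TRUE, FALSE), 100), "X"] >= 10))
  expect_true(all(m2[rep(c(FALSE, TRUE), 100), "X"] <= 2))
  # bootstrap mean of a {1,3} stratum converges to 2
  css3 <- tidyr::expand_grid(casrn = "X", age_group = groups,
                             weight_status = c("Normal", "Obese")) |>
    tidyr::expand_grid(css = c(1, 3))
  set.seed(11)
  m3 <- sample_css(css3, ages = rep(30L, 40000), obese = rep(FALSE, 40000))
  expect_lt(abs(mean(m3[, "X"]) - 2), 0.02)
  expect_error(sample_css(css[css$weight_status == "Normal", ],
                          ages = 30L, obese = TRUE), "stratum")
})

test_that("simulators are bit-identical under a fixed seed", {
  spec <- fixture_spec(n_regions = 2, n_chemicals = 2, seed = 12)
  pop <- gen_population_inputs(spec)
  run_once <- function() {
    set.seed(99)
    simulate_population("SYN001", list(
      age = pop$age[pop$age$region_id == "SYN001", ],
      obesity = pop$obesity[pop$obesity$region_id == "SYN001", ],
      ir = pop$ir,
      exposure = pop$exposure[pop$exposure$region_id == "SYN001", ],
      css = pop$css
    ), n = 50)
  }
  expect_identical(run_once(), run_once())
})

test_that("population arrays are consistent and non-negative", {
  spec <- fixture_spec(n_regions = 1, n_chemicals = 3, seed = 13)
  pop <- gen_population_inputs(spec)
  set.seed(14)
  p <- simulate_population("SYN001", list(
    age = pop$age, obesity = pop$obesity, ir = pop$ir,
    exposure = pop$exposure, css = pop$css
  ), n = 40)
  expect_equal(length(p$age), 40)
  expect_equal(dim(p$c_ext), dim(p$css))
  expect_true(all(p$ir >= 0) && all(p$c_ext >= 0) && all(p$css >= 0))
  # derived stages are elementwise products of upstream stages
  expect_equal(p$d_int, p$c_ext * p$ir * 1e-3)
  expect_equal(p$c_invitro, p$d_int * p$css)
})
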