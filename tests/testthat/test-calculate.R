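test_that("dosimetry identities hold exactly", {
  expect_equal(calc_internal_dose(1000, ir = 0.25), 0.25)
  expect_equal(calc_internal_dose(0, ir = 0.25), 0)
  expect_equal(calc_internal_dose(3, ir = 0.5), 2 * calc_internal_dose(3, 0.25))
  expect_equal(calc_invitro_concentration(0.5, css = 2), 1.0)
  expect_equal(calc_invitro_concentration(0.5, css = 0), 0)
  # matrix form equals elementwise scalar application
  m <- matrix(1:6, 2)
  css <- matrix(seq(0.5, 3, 0.5), 2)
  expect_equal(calc_invitro_concentration(m, css),
               matrix(mapply(calc_invitro_concentration, m, css), 2))
  expect_error(calc_internal_dose(-1, 0.2), "non-negative")
  expect_error(calc_invitro_concentration(-1, 2), "non-negative")
})

test_that("independent action reduces, combines, and bounds correctly", {
  expect_equal(calc_independent_action(3, tp = 80, ga = 1, gw = 2),
               hill_response(3, 80, 1, 2))
  # two chemicals at half effect with a 100 ceiling
  expect_equal(
    calc_independent_action(c(10, 10), tp = c(100, 100), ga = c(10, 10),
                            Emax = 100),
    75
  )
  expect_equal(calc_independent_action(c(0, 0), c(100, 50), c(1, 1)), 0)
  set.seed(31)
  for (k in 1:50) {
    m <- sample(1:8, 1)
    conc <- runif(m, 0, 50); tp <- runif(m, 30, 120); ga <- 10^runif(m, -1, 1)
    gw <- runif(m, 0.5, 3)
    ia <- calc_independent_action(conc, tp, ga, gw)
    singles <- hill_response(conc, tp, ga, gw)
    expect_gte(ia, max(singles) - 1e-12)
    expect_lte(ia, max(tp))
  }
})

test_that("GCA closed form, numeric solver, and sham mixtures agree", {
  # closed-form arithmetic example
  expect_equal(calc_gca(c(10, 5), tp = c(100, 50), ga = c(10, 5))$eff, 50)
  expect_equal(calc_gca(c(0, 0), c(100, 50), c(10, 5))$eff, 0)
  set.seed(17)
  for (k in 1:200) {
    m <- sample(1:10, 1)
    conc <- runif(m, 0, 30); tp <- runif(m, 40, 130); ga <- 10^runif(m, -1, 1)
    closed <- calc_gca(conc, tp, ga)$eff
    numeric <- gca_solve_numeric(conc, tp, ga)$eff
    expect_lt(abs(closed - numeric), 1e-8)
  }
  # single chemical of any slope is a sham mixture
  for (gw in c(0.7, 1, 2.5)) {
    e <- calc_gca(4, tp = 90, ga = 2, gw = gw)$eff
    expect_equal(e, hill_response(4, 90, 2, gw), tolerance = 1e-8)
  }
  # splitting one dose across duplicated curves leaves GCA unchanged
  set.seed(23)
  for (k in 1:20) {
    tp <- runif(1, 40, 130); ga <- 10^runif(1, -1, 1); ctot <- runif(1, 0.1, 30)
    a <- runif(1, 0.05, 0.95)
    whole <- calc_gca(ctot, tp, ga)$eff
    split2 <- calc_gca(c(a, 1 - a) * ctot, rep(tp, 2), rep(ga, 2))$eff
    expect_lt(abs(whole - split2), 1e-8)
    expect_lt(abs(whole - hill_response(ctot, tp, ga)), 1e-8)
  }
})

test_that("GCA and IA coincide for one chemical and rise with any dose", {
  set.seed(41)
  for (k in 1:20) {
    tp <- runif(1, 40, 130); ga <- 10^runif(1, -1, 1); cc <- runif(1, 0.1, 20)
    expect_lt(abs(calc_gca(cc, tp, ga)$eff -
                    calc_independent_action(cc, tp, ga)), 1e-8)
  }
  # monotone non-decreasing in every component, by finite differences
  set.seed(43)
  for (k in 1:20) {
    m <- sample(2:6, 1)
    conc <- runif(m, 0.1, 20); tp <- runif(m, 40, 130)
    ga <- 10^runif(m, -1, 1); gw <- runif(m, 0.6, 2.5)
    i <- sample(m, 1)
    bump <- conc; bump[i] <- bump[i] * 1.05
    expect_gte(calc_gca(bump, tp, ga, gw)$eff - calc_gca(conc, tp, ga, gw)$eff,
               -1e-10)
    expect_gte(calc_independent_action(bump, tp, ga, gw) -
                 calc_independent_action(conc, tp, ga, gw), -1e-10)
  }
})

test_that("hazard quotient matches its closed-form single-chemical case", {
  hq <- calc_hazard_quotient(5, tp = 100, ga = 10, fraction = 0.10)
  expect_equal(hq$ec_fraction, 10 * 10 / 90, tolerance = 1e-9)
  expect_equal(hq$hq, 5 / (10 * 10 / 90), tolerance = 1e-9)  # 4.5
  # at exactly the benchmark dose the quotient is 1
  at_bench <- calc_hazard_quotient(hq$ec_fraction, tp = 100, ga = 10)
  expect_equal(at_bench$hq, 1, tolerance = 1e-9)
  expect_equal(calc_hazard_quotient(0, 100, 10)$hq, 0)
})

test_that("hazard quotient is homogeneous and sham-invariant", {
  set.seed(53)
  for (k in 1:20) {
    m <- sample(2:6, 1)
    conc <- runif(m, 0.1, 10); tp <- runif(m, 40, 130); ga <- 10^runif(m, -1, 1)
    h1 <- calc_hazard_quotient(conc, tp, ga)$hq
    h2 <- calc_hazard_quotient(2 * conc, tp, ga)$hq
    expect_equal(h2, 2 * h1, tolerance = 1e-8)
    # relabeling chemicals changes nothing
    p <- sample(m)
    expect_equal(calc_hazard_quotient(conc[p], tp[p], ga[p])$hq, h1,
                 tolerance = 1e-10)
    # splitting one chemical into two identical pseudo-chemicals changes
    # nothing
    hsplit <- calc_hazard_quotient(c(conc[1] / 2, conc[1] / 2, conc[-1]),
                                   c(tp[1], tp[1], tp[-1]),
                                   c(ga[1], ga[1], ga[-1]))$hq
    expect_equal(hsplit, h1, tolerance = 1e-8)
  }
  # IA-based quotient is defined and positive too
  expect_gt(calc_hazard_quotient(c(2, 3), c(100, 80), c(1, 2),
                                 method = "IA")$hq, 0)
})

test_that("per-individual responses join chemicals and flag mismatches", {
  hp <- tibble::tibble(casrn = c("A", "B"), assay = "a1",
                       tp = c(100, 80), log10_ga = c(0, 0.3), gw = c(1, 1))
  cmat <- matrix(c(1, 0, 2, 0), 2, dimnames = list(NULL, c("A", "B")))
  out <- calc_response(cmat, hp)
  expect_equal(nrow(out), 2)
  # first individual: metrics consistent with the scalar operations
  expect_equal(out$gca_eff[1],
               calc_gca(c(1, 2), c(100, 80), c(1, 10^0.3))$eff,
               tolerance = 1e-10)
  expect_equal(out$ia_eff[1],
               calc_independent_action(c(1, 2), c(100, 80), c(1, 10^0.3)),
               tolerance = 1e-10)
  # second individual has zero exposure everywhere
  expect_equal(unlist(out[2, c("gca_eff", "ia_eff", "gca_hq", "ia_hq")]),
               c(gca_eff = 0, ia_eff = 0, gca_hq = 0, ia_hq = 0))
  # unknown chemical dropped with warning; empty intersection errors
  cmat3 <- cbind(cmat, C = c(1, 1))
  expect_warning(calc_response(cmat3, hp), "dropping")
  expect_error(
    calc_response(matrix(1, 1, 1, dimnames = list(NULL, "Z")), hp),
    "no chemicals joinable"
  )
})

test_that("responses are identical across repeated calls", {
  set.seed(61)
  hp <- tibble::tibble(casrn = sprintf("c%d", 1:3), assay = "a1",
                       tp = runif(3, 50, 120), log10_ga = runif(3, -1, 1),
                       gw = 1)
  cmat <- matrix(runif(300, 0, 5), 100, 3,
                 dimnames = list(NULL, sprintf("c%d", 1:3)))
  expect_identical(calc_response(cmat, hp), calc_response(cmat, hp))
})
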