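#' Internal dose from external air concentration
#'
#' Converts an external inhaled concentration into an internal dose rate:
#' `d_int = c_ext * ir * time_days * scaling`. With the defaults the input is
#' ug/m3, the inhalation rate is m3/day/kg body weight, time is 1 day (the
#' steady-state assumption behind the downstream plasma-concentration step),
#' and `scaling = 1e-3` converts ug to mg, giving mg/kg/day.
#'
#' @param c_ext External concentration(s), ug/m3 (scalar, vector, or matrix).
#' @param ir Inhalation rate(s), m3/day/kg.
#' @param time_days Exposure duration in days. Default 1.
#' @param scaling Unit conversion factor. Default `1e-3` (ug to mg).
#' @return Internal dose(s), mg/kg/day, with the shape of `c_ext * ir`.
#' @examples
#' calc_internal_dose(1000, ir = 0.25)  # 0.25 mg/kg/day
#' @export
calc_internal_dose <- function(c_ext, ir, time_days = 1, scaling = 1e-3) {
  if (any(c_ext < 0) || any(ir < 0) || time_days < 0 || scaling < 0) {
    stop("all dosimetry inputs must be non-negative", call. = FALSE)
  }
  c_ext * ir * time_days * scaling
}

#' In-vitro-equivalent concentration
#'
#' Multiplies internal dose by the steady-state plasma concentration per unit
#' dose rate (Css, uM per mg/kg/day) to obtain the in-vitro-equivalent
#' tissue concentration in uM — the reverse-dosimetry step that puts
#' population exposures on the concentration scale of the screening assays.
#'
#' @param d_int Internal dose(s), mg/kg/day (scalar, vector, or matrix).
#' @param css Steady-state plasma concentration(s), uM per mg/kg/day.
#' @return Concentration(s), uM, elementwise `d_int * css`.
#' @examples
#' calc_invitro_concentration(0.5, css = 2)  # 1 uM
#' @export
calc_invitro_concentration <- function(d_int, css) {
  if (any(d_int < 0) || any(css < 0)) {
    stop("dose and Css must be non-negative", call. = FALSE)
  }
  d_int * css
}

#' Independent action mixture response
#'
#' Combines single-chemical Hill responses under the independent action (IA)
#' model: `E = Emax * (1 - prod(1 - E_i / Emax))`, treating the chemicals'
#' effects as probabilistically independent. `Emax` defaults to the largest
#' top among the curves.
#'
#' @param conc Concentrations for one individual, uM (one per chemical).
#' @param tp,ga,gw Hill parameters, one per chemical (see [hill_response()]).
#' @param Emax Assay ceiling, percent activity. Default `max(tp)`.
#' @return Mixture response, percent activity, in `[0, Emax]`.
#' @examples
#' calc_independent_action(c(10, 5), tp = c(100, 50), ga = c(10, 5))
#' @export
calc_independent_action <- function(conc, tp, ga, gw = rep(1, length(conc)),
                                    Emax = max(tp)) {
  stopifnot(length(conc) == length(tp), length(tp) == length(ga),
            length(ga) == length(gw))
  if (Emax < max(tp)) stop("`Emax` must be at least max(tp)", call. = FALSE)
  e_i <- hill_response(conc, tp, ga, gw)
  if (any(e_i > Emax)) {
    stop("single-chemical response exceeds `Emax`", call. = FALSE)
  }
  Emax * (1 - prod(1 - e_i / Emax))
}

#' Generalized concentration addition mixture response
#'
#' Solves the generalized concentration addition (GCA) equation
#' `sum_i C_i / f_i^{-1}(E) = 1` for the mixture response `E`. For slope-one
#' curves the extended inverse `f^{-1}(E) = ga * E / (tp - E)` gives the
#' closed form `E = sum(tp * C / ga) / (1 + sum(C / ga))`, which handles
#' partial agonists (responses above a weaker chemical's top). When any Hill
#' coefficient differs from 1 the extended inverse is undefined (fractional
#' powers of negatives), so the equation is solved numerically with the
#' restricted inverse on `E` in `(0, min(tp))`; a solution pinned at the
#' bracket edge is flagged.
#'
#' @inheritParams calc_independent_action
#' @param tol Relative convergence tolerance of the root finder.
#' @return A list: `eff` (percent activity) and `bracket_limited` (flag, TRUE
#'   when the numeric solve hit the feasible bracket's edge).
#' @examples
#' calc_gca(c(10, 5), tp = c(100, 50), ga = c(10, 5))$eff  # 50
#' @export
calc_gca <- function(conc, tp, ga, gw = rep(1, length(conc)), tol = 1e-12) {
  stopifnot(length(conc) == length(tp), length(tp) == length(ga),
            length(ga) == length(gw))
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  keep <- conc > 0
  if (!any(keep)) return(list(eff = 0, bracket_limited = FALSE))
  conc <- conc[keep]; tp <- tp[keep]; ga <- ga[keep]; gw <- gw[keep]

  if (all(gw == 1)) {
    s <- sum(conc / ga)
    eff <- sum(tp * conc / ga) / (1 + s)
    return(list(eff = eff, bracket_limited = FALSE))
  }
  gca_solve_numeric(conc, tp, ga, gw, tol = tol)
}

#' Numeric generalized concentration addition solver
#'
#' Solves `sum_i C_i / f_i^{-1}(E) = 1` by monotone root-finding. Slope-one
#' components use the extended inverse `ga * E / (tp - E)` (valid past their
#' top, so partial agonists are handled); components with other Hill
#' coefficients use the restricted inverse, which confines the feasible
#' response to below their smallest top. This is the route [calc_gca()]
#' takes when any Hill coefficient differs from 1; for all-slope-one
#' mixtures it is an independent check of the closed form.
#'
#' @inheritParams calc_gca
#' @return A list: `eff`, `bracket_limited` (see [calc_gca()]).
#' @export
gca_solve_numeric <- function(conc, tp, ga, gw = rep(1, length(conc)),
                              tol = 1e-12) {
  stopifnot(length(conc) == length(tp), length(tp) == length(ga),
            length(ga) == length(gw))
  keep <- conc > 0
  if (!any(keep)) return(list(eff = 0, bracket_limited = FALSE))
  conc <- conc[keep]; tp <- tp[keep]; ga <- ga[keep]; gw <- gw[keep]

  unit <- gw == 1
  # objective g(E) = sum C_i / f_i^{-1}(E) - 1, strictly decreasing on the
  # feasible bracket; upper limit is min(tp) over non-unit-slope components
  # (their restricted inverse is undefined past the top) or max(tp) when the
  # extended inverse applies throughout
  e_hi <- if (any(!unit)) min(tp[!unit]) else max(tp)
  g <- function(E) {
    inv <- numeric(length(conc))
    inv[unit] <- ga[unit] * E / (tp[unit] - E)
    if (any(!unit)) {
      inv[!unit] <- ga[!unit] / ((tp[!unit] / E) - 1)^(1 / gw[!unit])
    }
    sum(conc / inv) - 1
  }
  eps <- e_hi * 1e-12
  lo <- eps
  hi <- e_hi - eps
  if (g(hi) > 0) {
    # even at the bracket edge the summed scaled doses exceed 1: the weakest
    # non-unit-slope top caps the solvable response
    return(list(eff = hi, bracket_limited = TRUE))
  }
  if (g(lo) < 0) {
    return(list(eff = lo, bracket_limited = TRUE))
  }
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = e_hi * tol)
  list(eff = root$root, bracket_limited = FALSE)
}

# Mixture response at total dose s with fixed proportions w, by method.
mixture_response_at <- function(s, w, tp, ga, gw, method, Emax) {
  conc <- s * w
  if (method == "GCA") {
    calc_gca(conc, tp, ga, gw)$eff
  } else {
    calc_independent_action(conc, tp, ga, gw, Emax = Emax)
  }
}

#' Mixture hazard quotient
#'
#' Computes a hazard quotient for a mixture at fixed component proportions.
#' Holding the proportions `w_i = C_i / sum(C)` fixed, the limiting response
#' `E_lim` as total dose grows without bound is found under the chosen
#' mixture model (for all-slope-one GCA this is
#' `sum(tp * w / ga) / sum(w / ga)`; for IA it is
#' `Emax * (1 - prod(1 - tp_i / Emax))` over chemicals with positive
#' proportion, which equals `Emax` at the default ceiling). The benchmark
#' response is `fraction * E_lim`; the benchmark dose `EC_fraction` is the
#' total concentration whose mixture response equals it, found by monotone
#' root-finding; and `HQ = sum(C) / EC_fraction`. `HQ = 1` therefore means
#' the mixture sits exactly at its benchmark dose.
#'
#' @inheritParams calc_independent_action
#' @param method `"GCA"` (default) or `"IA"`.
#' @param fraction Benchmark fraction of the limiting response. Default 0.10
#'   (an "HQ.10").
#' @return A list: `hq` (dimensionless), `ec_fraction` (uM), and `flag`
#'   (TRUE when the benchmark dose could not be bracketed; `hq` is then `NA`).
#' @examples
#' calc_hazard_quotient(5, tp = 100, ga = 10)$hq  # 4.5
#' @export
calc_hazard_quotient <- function(conc, tp, ga, gw = rep(1, length(conc)),
                                 method = c("GCA", "IA"), fraction = 0.10,
                                 Emax = max(tp)) {
  method <- match.arg(method)
  stopifnot(fraction > 0, fraction < 1)
  total <- sum(conc)
  if (total == 0) return(list(hq = 0, ec_fraction = NA_real_, flag = FALSE))
  w <- conc / total
  pos <- w > 0

  e_lim <- if (method == "GCA") {
    if (all(gw[pos] == 1)) {
      sum(tp[pos] * w[pos] / ga[pos]) / sum(w[pos] / ga[pos])
    } else {
      mixture_response_at(total * 1e12, w, tp, ga, gw, "GCA", Emax)
    }
  } else {
    Emax * (1 - prod(1 - tp[pos] / Emax))
  }
  target <- fraction * e_lim

  f <- function(log_s) {
    mixture_response_at(exp(log_s), w, tp, ga, gw, method, Emax) - target
  }
  lo <- log(total) + log(1e-12)
  hi <- log(total) + log(1e12)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo > 0 || fhi < 0) {
    return(list(hq = NA_real_, ec_fraction = NA_real_, flag = TRUE))
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)
  ec <- exp(root$root)
  list(hq = total / ec, ec_fraction = ec, flag = FALSE)
}

#' Per-individual mixture responses for one assay
#'
#' Applies the GCA, IA, and hazard-quotient calculators to every simulated
#' individual in a region, over the chemicals shared between the in-vitro
#' concentration matrix and the fitted Hill parameters for the assay.
#' Chemicals present in the concentrations but lacking a fitted curve are
#' dropped with a warning (the three-way join across exposure, toxicokinetic,
#' and assay data that defines the analyzable chemical space).
#'
#' @param c_invitro Matrix of in-vitro-equivalent concentrations, uM:
#'   individuals in rows, chemicals (CASRN column names) in columns.
#' @param hill_params Tibble of fitted parameters for one assay, as returned
#'   by [fit_hill_all()] (columns `casrn`, `tp`, `log10_ga`, `gw`).
#' @param fraction Benchmark fraction for the hazard quotients.
#' @param Emax Assay ceiling for IA; default the largest fitted top.
#' @return Tibble with one row per individual: `individual`, `gca_eff`,
#'   `ia_eff`, `gca_hq`, `ia_hq`, `gca_flag`, `hq_flag`.
#' @export
calc_response <- function(c_invitro, hill_params, fraction = 0.10,
                          Emax = NULL) {
  stopifnot(is.matrix(c_invitro), !is.null(colnames(c_invitro)))
  shared <- intersect(colnames(c_invitro), hill_params$casrn)
  if (length(shared) == 0) {
    stop("no chemicals joinable between concentrations and Hill parameters",
         call. = FALSE)
  }
  dropped <- setdiff(colnames(c_invitro), shared)
  if (length(dropped) > 0) {
    warning("dropping chemicals without fitted curves: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  hp <- hill_params[match(shared, hill_params$casrn), ]
  tp <- hp$tp
  ga <- 10^hp$log10_ga
  gw <- hp$gw
  if (is.null(Emax)) Emax <- max(tp)
  cc <- c_invitro[, shared, drop = FALSE]

  n <- nrow(cc)
  out <- tibble::tibble(
    individual = seq_len(n),
    gca_eff = NA_real_, ia_eff = NA_real_,
    gca_hq = NA_real_, ia_hq = NA_real_,
    gca_flag = FALSE, hq_flag = FALSE
  )
  for (i in seq_len(n)) {
    ci <- cc[i, ]
    g <- calc_gca(ci, tp, ga, gw)
    out$gca_eff[i] <- g$eff
    out$gca_flag[i] <- g$bracket_limited
    out$ia_eff[i] <- calc_independent_action(ci, tp, ga, gw, Emax = Emax)
    hg <- calc_hazard_quotient(ci, tp, ga, gw, method = "GCA",
                               fraction = fraction, Emax = Emax)
    hi <- calc_hazard_quotient(ci, tp, ga, gw, method = "IA",
                               fraction = fraction, Emax = Emax)
    out$gca_hq[i] <- hg$hq
    out$ia_hq[i] <- hi$hq
    out$hq_flag[i] <- hg$flag || hi$flag
  }
  out
}
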