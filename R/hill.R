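#' Hill concentration-response value
#'
#' Evaluates the Hill model \eqn{E(c) = tp / (1 + (ga/c)^{gw})}, the standard
#' parameterization for high-throughput screening concentration-response
#' curves: `tp` is the top (maximal) response in percent activity, `ga` the
#' AC50 in micromolar, and `gw` the dimensionless Hill coefficient.
#'
#' @param conc Concentration(s), uM. Must be non-negative; `conc = 0` returns 0.
#' @param tp Top (maximal) response, percent activity. Must be positive.
#' @param ga AC50, uM. Must be positive.
#' @param gw Hill coefficient. Must be positive. Default 1.
#'
#' @return Numeric vector of responses (percent activity), in `[0, tp)`.
#' @examples
#' hill_response(10, tp = 100, ga = 10)        # half-maximal at the AC50
#' hill_response(3, tp = 80, ga = 1, gw = 2)   # 72
#' @export
hill_response <- function(conc, tp, ga, gw = 1) {
  stopifnot(all(tp > 0), all(ga > 0), all(gw > 0))
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  out <- tp / (1 + (ga / conc)^gw)
  out[conc == 0] <- 0
  out
}

#' Invert a Hill curve
#'
#' Returns the concentration producing response `resp`. With
#' `extended = FALSE` this is the ordinary inverse
#' \eqn{ga / ((tp/E) - 1)^{1/gw}}, defined for `0 < resp < tp`. With
#' `extended = TRUE` (slope-one curves only) the inverse
#' \eqn{ga \cdot E / (tp - E)} is continued past the top so that partial
#' agonists (`resp > tp`) map to negative concentrations, as required by
#' generalized concentration addition.
#'
#' @param resp Response(s), percent activity.
#' @inheritParams hill_response
#' @param extended Use the slope-one continuation past `tp`? Default `FALSE`.
#'
#' @return Concentration(s), uM (negative allowed when `extended = TRUE`).
#' @examples
#' hill_conc(50, tp = 100, ga = 10)                    # 10
#' hill_conc(120, tp = 100, ga = 10, extended = TRUE)  # -60
#' @export
hill_conc <- function(resp, tp, ga, gw = 1, extended = FALSE) {
  stopifnot(all(tp > 0), all(ga > 0), all(gw > 0))
  if (extended) {
    if (any(gw != 1)) {
      stop("extended inverse requires a Hill coefficient of exactly 1",
           call. = FALSE)
    }
    return(ga * resp / (tp - resp))
  }
  if (any(resp <= 0) || any(resp >= tp)) {
    stop("`resp` must lie strictly between 0 and `tp` unless `extended = TRUE`",
         call. = FALSE)
  }
  ga / ((tp / resp) - 1)^(1 / gw)
}

# Negative log-likelihood of conc-response residuals.
# theta = (tp, log10_ga, log_gw, log_sigma); log_gw dropped when gw fixed at 1.
hill_negll <- function(theta, conc, resp, n_params, error_model) {
  tp <- theta[1]
  ga <- 10^theta[2]
  gw <- if (n_params == 3) exp(theta[3]) else 1
  sigma <- exp(theta[length(theta)])
  mu <- tp / (1 + (ga / conc)^gw)
  mu[conc == 0] <- 0
  r <- resp - mu
  ll <- if (error_model == "t4") {
    sum(stats::dt(r / sigma, df = 4, log = TRUE) - log(sigma))
  } else {
    sum(stats::dnorm(r, sd = sigma, log = TRUE))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a Hill model by maximum likelihood
#'
#' Fits a 2-parameter (`gw` fixed at 1) or 3-parameter Hill model to
#' concentration-response data for one chemical-by-assay combination,
#' maximizing the likelihood of residuals under a normal or Student-t
#' (4 df, scaled) error model. Optimization is bounded quasi-Newton
#' (`L-BFGS-B`) over `(tp, log10(ga), log(gw), log(sigma))` from a data-driven
#' start plus jittered restarts, followed by a Nelder-Mead polish. Standard
#' errors come from the inverse observed information at the optimum.
#'
#' @param data Data frame with columns `conc` (uM; zeros allowed as vehicle
#'   controls) and `resp` (percent activity). Extra columns are ignored.
#' @param n_params 2 or 3. The 2-parameter model fixes the Hill coefficient
#'   at 1 (the usual choice when fitted curves feed generalized concentration
#'   addition, whose extended inverse needs unit slope).
#' @param error_model `"normal"` (default) or `"t4"` for a heavier-tailed
#'   robust fit.
#' @param n_starts Number of jittered restarts beyond the data-driven start.
#'
#' @return A tibble with one row: `tp`, `log10_ga`, `gw`, `sigma`, standard
#'   errors `se_tp`, `se_log10_ga`, `se_gw`, the maximized `logLik`,
#'   `converged`, and `n_params`. Never throws on non-convergence: the best
#'   point found is returned with `converged = FALSE`.
#' @examples
#' d <- data.frame(conc = 10^seq(-2, 2, length.out = 8))
#' d$resp <- hill_response(d$conc, tp = 100, ga = 1)
#' fit_hill(d, n_params = 2)
#' @export
fit_hill <- function(data, n_params = 2, error_model = c("normal", "t4"),
                     n_starts = 4) {
  error_model <- match.arg(error_model)
  stopifnot(n_params %in% c(2, 3))
  conc <- data$conc
  resp <- data$resp
  if (any(!is.finite(conc)) || any(!is.finite(resp))) {
    stop("concentrations and responses must be finite", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  n_distinct_conc <- length(unique(conc[conc > 0]))
  if (n_distinct_conc < max(4, n_params + 1)) {
    stop("need at least ", max(4, n_params + 1),
         " distinct positive concentrations", call. = FALSE)
  }

  pos <- conc > 0
  lc <- log10(conc[pos])
  resp_sd <- stats::sd(resp)
  if (!is.finite(resp_sd) || resp_sd == 0) resp_sd <- 1e-3
  tp_hi <- 1.5 * max(resp, 1e-6)

  # bounds on (tp, log10_ga, [log_gw], log_sigma)
  lower <- c(1e-6, min(lc) - 2, log(0.3), log(resp_sd * 1e-4))
  upper <- c(tp_hi, max(lc) + 2, log(8), log(2 * resp_sd))
  if (n_params == 2) {
    lower <- lower[-3]
    upper <- upper[-3]
  }

  start0 <- c(max(resp, 1e-3), stats::median(lc), log(1), log(resp_sd))
  if (n_params == 2) start0 <- start0[-3]
  start0 <- pmin(pmax(start0, lower), upper)

  starts <- list(start0)
  jit <- stats::runif(n_starts * length(start0), -1, 1)
  jit <- matrix(jit, nrow = n_starts)
  for (k in seq_len(n_starts)) {
    s <- start0 + jit[k, ] * (upper - lower) / 8
    starts[[k + 1]] <- pmin(pmax(s, lower), upper)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, hill_negll, conc = conc, resp = resp,
                   n_params = n_params, error_model = error_model,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    best <- list(par = start0, value = hill_negll(start0, conc, resp,
                                                  n_params, error_model),
                 convergence = 1L)
  }
  # Nelder-Mead polish from the best bounded solution (clamped back to bounds).
  polish <- tryCatch(
    stats::optim(best$par, function(th) {
      hill_negll(pmin(pmax(th, lower), upper), conc, resp, n_params,
                 error_model)
    }, method = "Nelder-Mead", control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value < best$value) {
    best <- list(par = pmin(pmax(polish$par, lower), upper),
                 value = polish$value, convergence = best$convergence)
  }

  th <- best$par
  tp <- th[1]
  log10_ga <- th[2]
  gw <- if (n_params == 3) exp(th[3]) else 1
  sigma <- exp(th[length(th)])

  hess <- tryCatch(
    stats::optimHess(th, hill_negll, conc = conc, resp = resp,
                     n_params = n_params, error_model = error_model),
    error = function(e) NULL
  )
  se <- rep(NA_real_, length(th))
  converged <- isTRUE(best$convergence == 0)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      d <- diag(vc)
      se[d >= 0] <- sqrt(d[d >= 0])
    } else {
      converged <- FALSE
    }
  }
  se_gw <- if (n_params == 3) gw * se[3] else 0

  tibble::tibble(
    tp = tp, log10_ga = log10_ga, gw = gw, sigma = sigma,
    se_tp = se[1], se_log10_ga = se[2], se_gw = se_gw,
    logLik = -best$value, converged = converged, n_params = as.integer(n_params)
  )
}

#' Fit Hill models for every chemical-by-assay combination
#'
#' Groups a concentration-response table by `casrn` and `assay` and fits each
#' group with [fit_hill()].
#'
#' @param data Data frame with columns `casrn`, `assay`, `conc`, `resp`.
#' @inheritParams fit_hill
#' @return A tibble with one row per chemical-by-assay combination: `casrn`,
#'   `assay`, and the [fit_hill()] columns.
#' @export
fit_hill_all <- function(data, n_params = 2, error_model = "normal") {
  stopifnot(all(c("casrn", "assay", "conc", "resp") %in% names(data)))
  data |>
    dplyr::group_by(.data$casrn, .data$assay) |>
    dplyr::group_modify(~ fit_hill(.x, n_params = n_params,
                                   error_model = error_model)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$assay, .data$casrn)
}
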