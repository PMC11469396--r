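# Exact truncated-normal sampler via inverse CDF; lower truncation only.
# sd = 0 degenerates to the (clamped) mean.
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  deg <- sd == 0
  out[deg] <- pmax(mean[deg], lower)
  if (any(!deg)) {
    m <- mean[!deg]; s <- sd[!deg]
    p_lo <- stats::pnorm((lower - m) / s)
    u <- stats::runif(sum(!deg), p_lo, 1)
    out[!deg] <- m + s * stats::qnorm(u)
    # guard against qnorm rounding at the boundary
    out[!deg] <- pmax(out[!deg], lower)
  }
  out
}

# Mean of a normal truncated below at `lower` (closed form).
truncnorm_mean <- function(mean, sd, lower = 0) {
  if (sd == 0) return(max(mean, lower))
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Simulate ages from a binned census-style distribution
#'
#' Draws integer ages for one region: a bin is chosen with probability
#' proportional to its population count, then an age is drawn uniformly on
#' the integers of the bin.
#'
#' @param age_bins Data frame with columns `age_lo`, `age_hi` (inclusive,
#'   years) and `count` for one region.
#' @param n Number of individuals.
#' @return Integer vector of ages, length `n`.
#' @export
simulate_age <- function(age_bins, n) {
  stopifnot(all(c("age_lo", "age_hi", "count") %in% names(age_bins)))
  if (sum(age_bins$count) <= 0) {
    stop("all age-bin counts are zero", call. = FALSE)
  }
  idx <- sample.int(nrow(age_bins), n, replace = TRUE,
                    prob = age_bins$count)
  lo <- age_bins$age_lo[idx]
  hi <- age_bins$age_hi[idx]
  # uniform on the integers [lo, hi]
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' Simulate obesity status from a prevalence estimate with uncertainty
#'
#' Propagates the uncertainty of a surveillance-style crude prevalence: for
#' each individual a prevalence is drawn from a normal distribution centred
#' on the point estimate with standard deviation `(ci_hi - ci_lo) / 3.92`
#' (the usual 95 percent confidence-interval conversion), truncated to
#' `[0, 100]`, and status is Bernoulli at that prevalence.
#'
#' @param prev Crude prevalence, percent.
#' @param ci_lo,ci_hi 95 percent confidence limits, percent.
#' @param n Number of individuals.
#' @return Logical vector, `TRUE` = obese.
#' @export
simulate_obesity <- function(prev, ci_lo, ci_hi, n) {
  stopifnot(ci_lo <= prev, prev <= ci_hi, ci_lo >= 0, ci_hi <= 100)
  sd <- (ci_hi - ci_lo) / 3.92
  if (sd == 0) {
    p <- rep(prev, n)
  } else {
    p <- stats::rnorm(n, prev, sd)
    p <- pmin(pmax(p, 0), 100)
  }
  stats::runif(n) < p / 100
}

#' Simulate inhalation rates by age
#'
#' Looks up each individual's age bracket in an inhalation-rate table and
#' draws from a normal distribution truncated at zero with that bracket's
#' mean and standard deviation (per-kilogram daily inhalation volumes
#' decline with age, so the bracket structure carries the age dependence).
#'
#' @param ages Integer ages, years.
#' @param ir_table Data frame with columns `age_lo`, `age_hi`, `ir_mean`,
#'   `ir_sd` (m3/day/kg); brackets must cover every age present.
#' @return Numeric vector of inhalation rates, m3/day/kg.
#' @export
simulate_inhalation_rate <- function(ages, ir_table) {
  stopifnot(all(c("age_lo", "age_hi", "ir_mean", "ir_sd") %in%
                  names(ir_table)))
  idx <- vapply(ages, function(a) {
    j <- which(ir_table$age_lo <= a & a <= ir_table$age_hi)
    if (length(j) == 0) {
      stop("age ", a, " outside every inhalation-rate bracket", call. = FALSE)
    }
    j[1]
  }, integer(1))
  rtruncnorm_lower(length(ages), ir_table$ir_mean[idx], ir_table$ir_sd[idx])
}

#' Simulate external exposure concentrations
#'
#' Draws per-individual external air concentrations for each chemical in a
#' region from a normal distribution truncated at zero with the reported
#' mean and standard deviation; a zero standard deviation gives the constant
#' mean.
#'
#' @param exposure Data frame for one region with columns `casrn`, `mean`,
#'   `sd` (ug/m3).
#' @param n Number of individuals.
#' @return Matrix `n` x chemicals (ug/m3), columns named by CASRN in sorted
#'   order.
#' @export
simulate_exposure <- function(exposure, n) {
  stopifnot(all(c("casrn", "mean", "sd") %in% names(exposure)))
  exposure <- exposure[order(exposure$casrn), ]
  out <- vapply(seq_len(nrow(exposure)), function(j) {
    rtruncnorm_lower(n, exposure$mean[j], exposure$sd[j])
  }, numeric(n))
  out <- matrix(out, nrow = n,
                dimnames = list(NULL, exposure$casrn))
  out
}

# Css age-group brackets used to stratify toxicokinetic samples.
css_age_groups <- function() {
  tibble::tibble(
    age_group = c("0-17", "18-44", "45-64", "65-100"),
    age_lo = c(0L, 18L, 45L, 65L),
    age_hi = c(17L, 44L, 64L, 100L)
  )
}

# Map integer ages to Css age-group labels.
age_to_css_group <- function(ages, groups = css_age_groups()) {
  idx <- vapply(ages, function(a) {
    j <- which(groups$age_lo <= a & a <= groups$age_hi)
    if (length(j) == 0) stop("age ", a, " outside Css age groups",
                             call. = FALSE)
    j[1]
  }, integer(1))
  groups$age_group[idx]
}

#' Bootstrap steady-state plasma concentrations per individual
#'
#' Steady-state plasma concentration per unit dose (Css, uM per mg/kg/day)
#' is an expensive toxicokinetic simulation, so it arrives as a moderate
#' sample per stratum (age group by weight status) and is resampled with
#' replacement to the population size. Each individual is mapped to a
#' stratum by age and obesity status and draws uniformly from that stratum's
#' sample vector, for every chemical.
#'
#' @param css_table Data frame with columns `casrn`, `age_group`,
#'   `weight_status` (`"Normal"`/`"Obese"`), `css` (one row per stored
#'   sample).
#' @param ages Integer ages.
#' @param obese Logical obesity status, same length.
#' @return Matrix individuals x chemicals (uM per mg/kg/day), columns named
#'   by CASRN in sorted order.
#' @export
sample_css <- function(css_table, ages, obese) {
  stopifnot(all(c("casrn", "age_group", "weight_status", "css") %in%
                  names(css_table)),
            length(ages) == length(obese))
  n <- length(ages)
  grp <- age_to_css_group(ages)
  ws <- ifelse(obese, "Obese", "Normal")
  chems <- sort(unique(css_table$casrn))
  out <- matrix(NA_real_, n, length(chems),
                dimnames = list(NULL, chems))
  key <- paste(css_table$casrn, css_table$age_group, css_table$weight_status,
               sep = "|")
  pools <- split(css_table$css, key)
  for (ch in chems) {
    strata <- unique(paste(ch, grp, ws, sep = "|"))
    for (st in strata) {
      rows <- which(paste(ch, grp, ws, sep = "|") == st)
      pool <- pools[[st]]
      if (is.null(pool) || length(pool) == 0) {
        stop("no Css samples for stratum ", st, call. = FALSE)
      }
      out[rows, ch] <- pool[sample.int(length(pool), length(rows),
                                       replace = TRUE)]
    }
  }
  out
}

#' Simulate a region's population
#'
#' Runs the per-region Monte Carlo chain — age, obesity, inhalation rate,
#' external exposure, Css — and the dosimetry steps that derive internal
#' dose and in-vitro-equivalent concentration, returning all per-individual
#' arrays for one region. Chemical columns are shared (sorted CASRN order)
#' across all matrices.
#'
#' @param region_id Region identifier.
#' @param inputs List of region-filtered input tables: `age` (bins),
#'   `obesity` (one row), `ir`, `exposure`, `css`.
#' @param n Individuals to simulate.
#' @param config A [risk_config()].
#' @return A list of class `mixrisk_population`: `region_id`, `n`, `age`,
#'   `obese`, `ir`, and matrices `c_ext`, `d_int`, `css`, `c_invitro`.
#' @export
simulate_population <- function(region_id, inputs, n, config = risk_config()) {
  age <- simulate_age(inputs$age, n)
  ob <- simulate_obesity(inputs$obesity$prev, inputs$obesity$ci_lo,
                         inputs$obesity$ci_hi, n)
  ir <- simulate_inhalation_rate(age, inputs$ir)
  c_ext <- simulate_exposure(inputs$exposure, n)
  css <- sample_css(inputs$css, age, ob)
  chems <- intersect(colnames(c_ext), colnames(css))
  c_ext <- c_ext[, sort(chems), drop = FALSE]
  css <- css[, sort(chems), drop = FALSE]
  d_int <- calc_internal_dose(c_ext, ir, time_days = config$time_days,
                              scaling = config$dose_scaling)
  c_invitro <- calc_invitro_concentration(d_int, css)
  structure(
    list(region_id = region_id, n = n, age = age, obese = ob, ir = ir,
         c_ext = c_ext, d_int = d_int, css = css, c_invitro = c_invitro),
    class = "mixrisk_population"
  )
}
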