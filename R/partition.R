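#' Combined effect under response additivity (independent action)
#'
#' The combined effect of two independently acting toxicants is one minus the
#' product of their survival fractions:
#' `E_total = 1 - (1 - E_particle)(1 - E_ion)`. The result is symmetric in its
#' arguments and never smaller than either single-agent effect.
#'
#' @param e_particle,e_ion effect fractions in `[0, 1]` (vectors recycled).
#' @return combined effect fraction in `[0, 1]`.
#' @export
additivity_total <- function(e_particle, e_ion) {
  if (any(e_particle < 0) || any(e_particle > 1) ||
      any(e_ion < 0) || any(e_ion > 1))
    stop("effects must lie in [0, 1]", call. = FALSE)
  1 - (1 - e_particle) * (1 - e_ion)
}

#' Particle effect implied by a total and an ion effect
#'
#' Algebraic inverse of [additivity_total()]:
#' `E_particle = 1 - (1 - E_total) / (1 - E_ion)`. Under sampling noise the
#' observed total can fall below the ion effect; the result is then clipped to
#' 0 with a warning. Retained for diagnostics; the particle curve itself is
#' estimated by joint likelihood ([fit_particle_curve()]), which avoids the
#' division blowing up as the ion effect nears saturation.
#'
#' @param e_total,e_ion effect fractions in `[0, 1]`, with `e_ion < 1`.
#' @return particle effect fraction in `[0, 1]`.
#' @export
invert_particle_effect <- function(e_total, e_ion) {
  if (any(e_total < 0) || any(e_total > 1) || any(e_ion < 0) || any(e_ion > 1))
    stop("effects must lie in [0, 1]", call. = FALSE)
  if (any(e_ion >= 1))
    stop("ion effect is 1: particle effect unidentifiable", call. = FALSE)
  res <- 1 - (1 - e_total) / (1 - e_ion)
  if (any(res < 0))
    warning(sprintf("%d negative residual particle effect(s) clipped to 0",
                    sum(res < 0)), call. = FALSE)
  pmin(pmax(res, 0), 1)
}

#' Toxic units
#'
#' A potency-scaled dose: the exposure concentration divided by the
#' component's EC50. One toxic unit is the concentration producing 50% effect
#' for that component alone.
#'
#' @param concentration exposure concentration (ug/l), >= 0.
#' @param ec50 the component's EC50 (ug/l), > 0.
#' @return dimensionless toxic units.
#' @export
toxic_units <- function(concentration, ec50) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("ec50 must be positive", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be >= 0", call. = FALSE)
  concentration / ec50
}

#' Relative contributions from toxic units
#'
#' Each component's toxic units divided by the sum of both; the two fractions
#' sum to 1.
#'
#' @param tu_particle,tu_ion toxic units, each >= 0, not both 0.
#' @return named numeric vector `c(particle = ..., ion = ...)`.
#' @export
relative_contributions <- function(tu_particle, tu_ion) {
  if (tu_particle < 0 || tu_ion < 0)
    stop("toxic units must be >= 0", call. = FALSE)
  s <- tu_particle + tu_ion
  if (s == 0)
    stop("both toxic units are zero: contributions undefined", call. = FALSE)
  c(particle = tu_particle / s, ion = tu_ion / s)
}

#' Fit the particle dose-response curve under response additivity
#'
#' Estimates the particle component's log-logistic curve from the
#' nanoparticle-suspension immobility data, holding the ion component fixed at
#' its AgNO3 estimate. For a well at nominal concentration `c` the model
#' probability is
#' `p(c) = 1 - (1 - E_p(particle_dose(c))) (1 - E_i(ion_dose(c)))`,
#' with the ion and particle doses read off the speciation table and
#' `(h_p, e_p)` maximized by binomial likelihood on the log scale. Ion-curve
#' parameter uncertainty is not propagated into the particle covariance (a
#' documented limitation of the procedure).
#'
#' @param np_records immobility records of the suspension series (one
#'   condition, one timepoint).
#' @param ion_curve an `ll4_fit` of the AgNO3 (dissolved silver) series.
#' @param table a `speciation_table` covering every nominal level in
#'   `np_records`.
#' @return an `ll4_fit` whose `slope`/`ec50` are on the particulate-ug/l dose
#'   scale. `wells` carries the nominal concentration plus the mapped
#'   `particle_dose` and `ion_dose`; `fitted` holds the full mixture
#'   probabilities used for the dispersion estimate.
#' @export
fit_particle_curve <- function(np_records, ion_curve, table) {
  stopifnot(inherits(ion_curve, "ll4_fit"), inherits(table, "speciation_table"))
  wells <- .wells_from_records(np_records)
  wells <- wells[wells$conc > 0, , drop = FALSE]
  levels <- sort(unique(wells$conc))
  if (length(levels) < 3L)
    stop("need >= 3 distinct positive concentrations", call. = FALSE)
  doses <- vapply(levels, function(l) dose_at(table, l), numeric(2L))
  idx <- match(wells$conc, levels)
  pd <- pmax(doses["particle_dose", idx], 1e-12)
  id <- doses["ion_dose", idx]
  e_ion <- ll4_effect(id, ion_curve$slope, ion_curve$ec50)

  # identifiability: some pooled observed proportion must exceed the ion effect
  pooled <- vapply(levels, function(l) {
    w <- wells$conc == l
    sum(wells$y[w]) / sum(wells$n[w])
  }, numeric(1L))
  e_ion_lvl <- ll4_effect(doses["ion_dose", ], ion_curve$slope, ion_curve$ec50)
  if (all(pooled <= e_ion_lvl + 1e-9))
    stop(paste("ion effect meets or exceeds observed immobility at every",
               "concentration: particle parameters unidentifiable; widen the",
               "particulate dose range"), call. = FALSE)

  logpd <- log(pd)
  negll <- function(par, dat) {
    logc <- dat$logc; n <- dat$n; y <- dat$y
    h <- exp(par[1L]); eta <- h * (logc - par[2L])
    ep <- stats::plogis(eta)
    p <- 1 - (1 - ep) * (1 - e_ion)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (n - y) * log1p(-p))
  }
  neggrad <- function(par, dat) {
    logc <- dat$logc; n <- dat$n; y <- dat$y
    h <- exp(par[1L]); eta <- h * (logc - par[2L])
    ep <- stats::plogis(eta)
    p <- 1 - (1 - ep) * (1 - e_ion)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dldp <- y / p - (n - y) / (1 - p)
    dpdeta <- (1 - e_ion) * ep * (1 - ep)
    r <- dldp * dpdeta
    -c(sum(r * eta), -h * sum(r))
  }
  fit <- .optimize_multistart(
    negll, neggrad,
    h_grid = c(1, 2.5, 6),
    loge_grid = log(c(min(pd), exp(mean(range(logpd))), max(pd))),
    dat = list(logc = logpd, n = wells$n, y = wells$y))

  h_p <- exp(fit$par[1L]); e_p <- exp(fit$par[2L])
  p_hat <- additivity_total(ll4_effect(pd, h_p, e_p), e_ion)
  wells$particle_dose <- pd
  wells$ion_dose <- id
  out <- .finish_fit(fit, wells, p_hat,
                     condition = unique(as.character(np_records$condition))[1L],
                     timepoint = unique(np_records$timepoint_h)[1L])
  out$slope <- h_p
  out$ec50 <- e_p
  out$effect_fn <- function(particle_dose) ll4_effect(particle_dose, h_p, e_p)
  out$ion_curve <- list(slope = ion_curve$slope, ec50 = ion_curve$ec50)
  out
}

#' Partition suspension toxicity into ion and particle contributions
#'
#' The full decomposition for one condition and timepoint: fits the
#' suspension dose-response curve on nominal concentration ([fit_ll4()]),
#' fits the particle curve under response additivity with the ion curve held
#' fixed ([fit_particle_curve()]), reads the measured ion and particle
#' concentrations at the fitted suspension EC50 off the speciation table,
#' converts them to toxic units against the ion and particle EC50s, and
#' reports each component's share of the summed toxic units.
#'
#' The suspension EC50 is on the nominal concentration scale (the suspension
#' curve is fitted on nominal doses) while the toxic units use measured
#' speciation doses; this asymmetry follows the experimental procedure.
#'
#' @param np_records suspension-series immobility records (one condition and
#'   timepoint).
#' @param ion_curve `ll4_fit` of the AgNO3 series (dissolved-silver dose).
#' @param table `speciation_table` covering the suspension's nominal levels.
#' @return object of class `partition_result`: list with `condition`,
#'   `timepoint`, `suspension_ec50`, `suspension_curve`, `ion_curve`,
#'   `particle_curve`, `c_ion`, `c_particle`, `tu_ion`, `tu_particle`,
#'   `ion_fraction`, `particle_fraction`.
#' @export
partition_condition <- function(np_records, ion_curve, table) {
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  susp <- stage("suspension fit", fit_ll4(np_records))
  part <- stage("particle fit", fit_particle_curve(np_records, ion_curve, table))
  doses <- stage("speciation lookup", dose_at(table, susp$ec50))
  tu_i <- toxic_units(doses[["ion_dose"]], ion_curve$ec50)
  tu_p <- toxic_units(doses[["particle_dose"]], part$ec50)
  fr <- relative_contributions(tu_p, tu_i)
  structure(list(
    condition = susp$condition,
    timepoint = susp$timepoint,
    suspension_ec50 = susp$ec50,
    suspension_curve = susp,
    ion_curve = ion_curve,
    particle_curve = part,
    c_ion = doses[["ion_dose"]],
    c_particle = doses[["particle_dose"]],
    tu_ion = tu_i,
    tu_particle = tu_p,
    ion_fraction = fr[["ion"]],
    particle_fraction = fr[["particle"]]
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Response-additivity partition of suspension toxicity\n")
  cat(sprintf("  condition %s at %s h\n", x$condition, format(x$timepoint)))
  cat(sprintf("  suspension EC50: %.3f ug/l nominal\n", x$suspension_ec50))
  cat(sprintf("  ion EC50 %.3f, particle EC50 %.3f ug/l\n",
              x$ion_curve$ec50, x$particle_curve$ec50))
  cat(sprintf("  doses at EC50: ion %.3f, particle %.3f ug/l\n",
              x$c_ion, x$c_particle))
  cat(sprintf("  toxic units: ion %.3f, particle %.3f\n", x$tu_ion, x$tu_particle))
  cat(sprintf("  contributions: ion %.1f%%, particle %.1f%%\n",
              100 * x$ion_fraction, 100 * x$particle_fraction))
  invisible(x)
}
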