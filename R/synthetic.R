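#' Ground-truth parameter set for a synthetic immobilization experiment
#'
#' Bundles the generating parameters of an in-silico acute immobilization
#' study: a log-logistic ion curve (on dissolved-silver dose), a log-logistic
#' particle curve (on particulate-silver dose), a constant dissolved fraction,
#' ICP-MS measurement noise, and the experimental layout (nanoparticle
#' concentration series, AgNO3 dilution series, wells of neonates, scoring
#' timepoints).
#'
#' Defaults mirror the design of acute immobilization testing with silver
#' nanoparticles: 5 nominal suspension concentrations between 5 and 50 ug/l, a
#' two-fold AgNO3 dilution series from 10 down to 0.625 ug/l, wells of 5
#' neonates with 4 wells (20 animals) per concentration, and scoring at 24 and
#' 48 h. The dissolved fraction is constant over the exposure; a per-timepoint
#' override hook (`dissolved_fraction_by_timepoint`) exists for sensitivity
#' analyses but defaults to the constant value.
#'
#' @param ion_slope,ion_ec50 slope and EC50 of the ion (dissolved Ag) curve.
#' @param particle_slope,particle_ec50 slope and EC50 of the particle
#'   (particulate Ag) curve.
#' @param dissolved_fraction fraction of total silver present as ions,
#'   strictly inside (0, 1).
#' @param recovery_factor fraction of the nominal concentration recovered as
#'   measured total silver (default 1: nominal mass fully recovered).
#' @param icpms_cv coefficient of variation of the multiplicative lognormal
#'   ICP-MS measurement noise (0 disables noise).
#' @param control_mortality baseline immobility probability in `[0, 1)`.
#' @param overdispersion_rho beta-binomial intra-well correlation in `[0, 1)`;
#'   0 gives plain binomial wells.
#' @param np_concentrations nominal nanoparticle concentrations (ug/l).
#' @param agno3_concentrations AgNO3 concentrations (ug/l), treated as fully
#'   dissolved ionic silver.
#' @param n_per_well neonates per well.
#' @param wells_per_concentration wells per concentration and timepoint.
#' @param timepoints scoring times in hours.
#' @param n_icpms_replicates ICP-MS replicate measurements per concentration
#'   and timepoint.
#' @param dissolved_fraction_by_timepoint optional named numeric vector
#'   (names = timepoints) overriding `dissolved_fraction` per timepoint.
#' @param condition label attached to the nanoparticle-series records.
#' @param seed integer seed; all randomness in [generate_experiment()] derives
#'   from it.
#' @return an object of class `synthetic_truth` (a validated list).
#' @export
synthetic_truth <- function(ion_slope = 3, ion_ec50 = 2,
                            particle_slope = 3, particle_ec50 = 20,
                            dissolved_fraction = 0.25,
                            recovery_factor = 1,
                            icpms_cv = 0.05,
                            control_mortality = 0,
                            overdispersion_rho = 0,
                            np_concentrations = c(5, 10, 20, 30, 50),
                            agno3_concentrations = c(10, 5, 2.5, 1.25, 0.625),
                            n_per_well = 5L,
                            wells_per_concentration = 4L,
                            timepoints = c(24, 48),
                            n_icpms_replicates = 3L,
                            dissolved_fraction_by_timepoint = NULL,
                            condition = "synthetic",
                            seed = 1L) {
  truth <- list(ion_slope = ion_slope, ion_ec50 = ion_ec50,
                particle_slope = particle_slope, particle_ec50 = particle_ec50,
                dissolved_fraction = dissolved_fraction,
                recovery_factor = recovery_factor, icpms_cv = icpms_cv,
                control_mortality = control_mortality,
                overdispersion_rho = overdispersion_rho,
                np_concentrations = np_concentrations,
                agno3_concentrations = agno3_concentrations,
                n_per_well = as.integer(n_per_well),
                wells_per_concentration = as.integer(wells_per_concentration),
                timepoints = timepoints,
                n_icpms_replicates = as.integer(n_icpms_replicates),
                dissolved_fraction_by_timepoint = dissolved_fraction_by_timepoint,
                condition = condition,
                seed = as.integer(seed))
  .validate_truth(truth)
  structure(truth, class = "synthetic_truth")
}

.validate_truth <- function(t) {
  pos1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!pos1(t$ion_slope) || !pos1(t$particle_slope))
    stop("slopes must be single positive numbers", call. = FALSE)
  if (!pos1(t$ion_ec50) || !pos1(t$particle_ec50))
    stop("EC50s must be single positive numbers", call. = FALSE)
  if (!is.numeric(t$dissolved_fraction) || t$dissolved_fraction <= 0 ||
      t$dissolved_fraction >= 1)
    stop("dissolved_fraction must lie strictly inside (0, 1)", call. = FALSE)
  if (!pos1(t$recovery_factor))
    stop("recovery_factor must be positive", call. = FALSE)
  if (t$icpms_cv < 0) stop("icpms_cv must be >= 0", call. = FALSE)
  if (t$control_mortality < 0 || t$control_mortality >= 1)
    stop("control_mortality must be in [0, 1)", call. = FALSE)
  if (t$overdispersion_rho < 0 || t$overdispersion_rho >= 1)
    stop("overdispersion_rho must be in [0, 1)", call. = FALSE)
  for (nm in c("np_concentrations", "agno3_concentrations")) {
    x <- t[[nm]]
    if (!length(x)) stop(nm, " must be non-empty", call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0))
      stop(nm, " must be strictly positive", call. = FALSE)
    if (anyDuplicated(x)) stop(nm, " must be distinct", call. = FALSE)
  }
  if (t$n_per_well < 1L || t$wells_per_concentration < 1L)
    stop("n_per_well and wells_per_concentration must be >= 1", call. = FALSE)
  if (!length(t$timepoints)) stop("timepoints must be non-empty", call. = FALSE)
  invisible(TRUE)
}

# Internal: dissolved fraction effective at a given timepoint.
.dissolved_at <- function(truth, timepoint) {
  o <- truth$dissolved_fraction_by_timepoint
  if (!is.null(o) && as.character(timepoint) %in% names(o))
    o[[as.character(timepoint)]]
  else truth$dissolved_fraction
}

# Internal: per-well immobility probability for the nanoparticle series.
.np_probability <- function(truth, conc, timepoint) {
  f <- .dissolved_at(truth, timepoint)
  dose_total <- conc * truth$recovery_factor
  e_ion <- ll4_effect(f * dose_total, truth$ion_slope, truth$ion_ec50)
  e_par <- ll4_effect((1 - f) * dose_total, truth$particle_slope,
                      truth$particle_ec50)
  1 - (1 - truth$control_mortality) * (1 - e_par) * (1 - e_ion)
}

# Internal: binomial or beta-binomial well counts with mean probability p and
# intra-well correlation rho.
.draw_well_counts <- function(n_wells, n_per_well, p, rho) {
  if (rho <= 0 || p <= 0 || p >= 1)
    return(stats::rbinom(n_wells, n_per_well, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  pw <- stats::rbeta(n_wells, a, b)
  stats::rbinom(n_wells, n_per_well, pw)
}

#' Generate a complete synthetic immobilization + speciation experiment
#'
#' Simulates per-well immobile counts for the nanoparticle suspension series
#' and the AgNO3 series, and replicate ICP-MS speciation measurements, from a
#' [synthetic_truth()]. For a nanoparticle well at nominal concentration `c`
#' the ion dose is `f * c * recovery_factor` and the particle dose
#' `(1 - f) * c * recovery_factor`; the immobility probability combines the
#' two log-logistic effects and any control mortality by response additivity,
#' `1 - (1 - cm)(1 - E_particle)(1 - E_ion)`. AgNO3 wells use the ion effect
#' only (the nominal AgNO3 mass is treated as fully dissolved). Speciation
#' rows carry `total = recovery_factor * c * noise` and
#' `dissolved = f * total * noise` with independent multiplicative lognormal
#' noise of unit mean and coefficient of variation `icpms_cv`.
#'
#' The random-number streams for mortality and for ICP-MS noise are seeded
#' separately (both derived from `truth$seed`), so toggling the noise in one
#' stream does not shift the draws of the other. The same truth always yields
#' identical output.
#'
#' @param truth a `synthetic_truth` object.
#' @return list with elements `immobility` (data.frame of well records:
#'   `condition`, `timepoint_h`, `conc_ug_per_l`, `n_exposed`, `n_immobile`,
#'   plus a `series` column, `"np"` or `"agno3"`), `speciation` (data.frame:
#'   `nominal_conc_ug_per_l`, `timepoint_h`, `replicate`, `total_ag_ug_per_l`,
#'   `dissolved_ag_ug_per_l`) and `truth`.
#' @export
generate_experiment <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .validate_truth(truth)

  grid_np <- expand.grid(well = seq_len(truth$wells_per_concentration),
                         conc = truth$np_concentrations,
                         timepoint = truth$timepoints)
  grid_ag <- expand.grid(well = seq_len(truth$wells_per_concentration),
                         conc = truth$agno3_concentrations,
                         timepoint = truth$timepoints)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # mortality stream
  set.seed(truth$seed)
  p_np <- mapply(function(conc, tp) .np_probability(truth, conc, tp),
                 grid_np$conc, grid_np$timepoint)
  y_np <- vapply(p_np, function(p)
    .draw_well_counts(1L, truth$n_per_well, p, truth$overdispersion_rho),
    integer(1L))
  p_ag <- 1 - (1 - truth$control_mortality) *
    (1 - ll4_effect(grid_ag$conc, truth$ion_slope, truth$ion_ec50))
  y_ag <- vapply(p_ag, function(p)
    .draw_well_counts(1L, truth$n_per_well, p, truth$overdispersion_rho),
    integer(1L))

  immobility <- rbind(
    data.frame(condition = truth$condition,
               timepoint_h = grid_np$timepoint,
               conc_ug_per_l = grid_np$conc,
               n_exposed = truth$n_per_well,
               n_immobile = y_np,
               series = "np"),
    data.frame(condition = "agno3",
               timepoint_h = grid_ag$timepoint,
               conc_ug_per_l = grid_ag$conc,
               n_exposed = truth$n_per_well,
               n_immobile = y_ag,
               series = "agno3"))

  # ICP-MS stream, seeded independently of mortality
  set.seed((truth$seed + 499979L) %% .Machine$integer.max)
  sdlog <- sqrt(log1p(truth$icpms_cv^2))
  meanlog <- -sdlog^2 / 2       # unit-mean multiplicative noise
  grid_sp <- expand.grid(replicate = seq_len(truth$n_icpms_replicates),
                         conc = truth$np_concentrations,
                         timepoint = truth$timepoints)
  total <- truth$recovery_factor * grid_sp$conc *
    stats::rlnorm(nrow(grid_sp), meanlog, sdlog)
  f_tp <- vapply(grid_sp$timepoint, function(tp) .dissolved_at(truth, tp),
                 numeric(1L))
  dissolved <- f_tp * total * stats::rlnorm(nrow(grid_sp), meanlog, sdlog)
  speciation <- data.frame(nominal_conc_ug_per_l = grid_sp$conc,
                           timepoint_h = grid_sp$timepoint,
                           replicate = grid_sp$replicate,
                           total_ag_ug_per_l = total,
                           dissolved_ag_ug_per_l = dissolved)

  list(immobility = immobility, speciation = speciation, truth = truth)
}

#' True nominal EC50 of the suspension under the generating model
#'
#' Solves for the nominal concentration `c*` at which the combined
#' response-additivity effect of the ion and particle components reaches 0.5:
#' `1 - (1 - E_particle((1-f) c r))(1 - E_ion(f c r)) = 0.5`, with `f` the
#' dissolved fraction and `r` the recovery factor. The root is bracketed in
#' `(0, 10 max(EC50s) / min(f, 1-f)]` and solved to a relative tolerance of
#' 1e-9.
#'
#' @param truth a `synthetic_truth` object.
#' @param timepoint timepoint whose dissolved fraction applies (default:
#'   first timepoint; irrelevant unless a per-timepoint override is set).
#' @return nominal concentration (ug/l) producing 50% immobility.
#' @export
true_suspension_ec50 <- function(truth, timepoint = truth$timepoints[1L]) {
  stopifnot(inherits(truth, "synthetic_truth"))
  f <- .dissolved_at(truth, timepoint)
  g <- function(c) .np_probability(truth, c, timepoint) - 0.5
  upper <- 10 * max(truth$ion_ec50, truth$particle_ec50) / min(f, 1 - f)
  if (g(upper) < 0)
    stop(sprintf("no 50%% effect level in (0, %.3g]: combined effect tops out at %.3f",
                 upper, g(upper) + 0.5), call. = FALSE)
  stats::uniroot(g, lower = upper * 1e-12, upper = upper,
                 tol = upper * 1e-12)$root
}

#' True toxic-unit relative contributions under the generating model
#'
#' Evaluates the toxic units of each component at the true suspension EC50
#' `c*`: `TU_ion = f c* / ion_ec50`, `TU_particle = (1-f) c* / particle_ec50`
#' (recovery factor applied to both doses), and returns each as a fraction of
#' their sum. The fractions sum to 1 by construction.
#'
#' @inheritParams true_suspension_ec50
#' @return named numeric vector `c(ion = ..., particle = ...)`.
#' @export
true_contributions <- function(truth, timepoint = truth$timepoints[1L]) {
  cstar <- true_suspension_ec50(truth, timepoint)
  f <- .dissolved_at(truth, timepoint)
  tu_ion <- f * cstar * truth$recovery_factor / truth$ion_ec50
  tu_par <- (1 - f) * cstar * truth$recovery_factor / truth$particle_ec50
  c(ion = tu_ion / (tu_ion + tu_par), particle = tu_par / (tu_ion + tu_par))
}

#' Calibrate the ion EC50 so the true ion contribution hits a target
#'
#' Finds, by monotone one-dimensional root search over `ion_ec50`, the truth
#' whose [true_contributions()] ion fraction equals `target_ion_fraction`
#' within 1e-6. All other truth fields are taken from `...` (passed to
#' [synthetic_truth()]). The ion fraction is strictly decreasing in the ion
#' EC50, so the root is unique when attainable; the search bracket is
#' `[1e-4, 1e4] * particle_ec50`.
#'
#' @param target_ion_fraction target ion contribution, strictly inside (0, 1).
#' @param ... fields for [synthetic_truth()] other than `ion_ec50`.
#' @return a `synthetic_truth` whose true ion contribution equals the target.
#' @export
calibrate_to_contribution <- function(target_ion_fraction, ...) {
  if (!is.numeric(target_ion_fraction) || length(target_ion_fraction) != 1L ||
      target_ion_fraction <= 0 || target_ion_fraction >= 1)
    stop("target_ion_fraction must lie strictly inside (0, 1)", call. = FALSE)
  fixed <- list(...)
  if ("ion_ec50" %in% names(fixed))
    stop("ion_ec50 is the calibrated parameter; do not fix it", call. = FALSE)
  make <- function(e_i) do.call(synthetic_truth, c(list(ion_ec50 = e_i), fixed))
  e_p <- make(1)$particle_ec50
  lo <- 1e-4 * e_p; hi <- 1e4 * e_p
  frac <- function(e_i) true_contributions(make(e_i))[["ion"]]
  f_lo <- frac(lo); f_hi <- frac(hi)    # decreasing in ion_ec50
  if (target_ion_fraction > f_lo || target_ion_fraction < f_hi)
    stop(sprintf("target %.4f unattainable: attainable ion fractions are [%.4f, %.4f] over the search bracket",
                 target_ion_fraction, f_hi, f_lo), call. = FALSE)
  root <- stats::uniroot(function(e_i) frac(e_i) - target_ion_fraction,
                         lower = lo, upper = hi, tol = e_p * 1e-12)$root
  out <- make(root)
  achieved <- true_contributions(out)[["ion"]]
  if (abs(achieved - target_ion_fraction) > 1e-6)
    stop(sprintf("calibration did not converge: achieved %.8f for target %.8f",
                 achieved, target_ion_fraction), call. = FALSE)
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic experiment truth\n")
  cat(sprintf("  ion curve     : h = %.3g, EC50 = %.4g ug/l dissolved Ag\n",
              x$ion_slope, x$ion_ec50))
  cat(sprintf("  particle curve: h = %.3g, EC50 = %.4g ug/l particulate Ag\n",
              x$particle_slope, x$particle_ec50))
  cat(sprintf("  dissolved fraction %.3g, recovery %.3g, ICP-MS CV %.3g\n",
              x$dissolved_fraction, x$recovery_factor, x$icpms_cv))
  cat(sprintf("  design: %d NP + %d AgNO3 levels, %d wells x %d neonates, t = %s h, seed %d\n",
              length(x$np_concentrations), length(x$agno3_concentrations),
              x$wells_per_concentration, x$n_per_well,
              paste(x$timepoints, collapse = "/"), x$seed))
  invisible(x)
}
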