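#' Particulate silver from total and dissolved measurements
#'
#' The particulate concentration is the total minus the dissolved
#' (supernatant) concentration. Measurement noise can leave the dissolved
#' value above the total; such differences are clipped to 0 and a warning is
#' recorded rather than dropping the replicate, because dropping one tail of
#' the noise biases the dissolved fraction.
#'
#' @param total_ag,dissolved_ag concentrations in ug/l, each >= 0 (vectors
#'   recycled in the usual way).
#' @return particulate concentration(s), ug/l, >= 0.
#' @export
particle_from_total <- function(total_ag, dissolved_ag) {
  if (any(!is.finite(total_ag)) || any(!is.finite(dissolved_ag)))
    stop("measurements must be finite", call. = FALSE)
  if (any(total_ag < 0) || any(dissolved_ag < 0))
    stop("measurements must be >= 0", call. = FALSE)
  d <- total_ag - dissolved_ag
  if (any(d < 0))
    warning(sprintf("%d measurement(s) with dissolved > total clipped to particle = 0",
                    sum(d < 0)), call. = FALSE)
  pmax(d, 0)
}

#' Build a per-concentration speciation table from ICP-MS measurements
#'
#' Aggregates replicate total/dissolved silver measurements into one ion dose
#' and one particle dose per nominal concentration. Dissolved values above the
#' total are first clipped per measurement (see [particle_from_total()]); then
#' totals and dissolved values are averaged per nominal level, pooling
#' timepoints and replicates by default (ion levels are assumed stable over
#' the exposure). Set `per_timepoint = TRUE` to get one table per timepoint.
#'
#' The table satisfies `ion_dose + particle_dose = mean total` at every level.
#'
#' @param measurements data.frame with columns `nominal_conc_ug_per_l`,
#'   `timepoint_h`, `total_ag_ug_per_l`, `dissolved_ag_ug_per_l` (a
#'   `replicate` column is allowed and ignored by the aggregation).
#' @param required_levels optional nominal concentrations that must be
#'   present (e.g. the levels of the mortality data); missing levels raise an
#'   error naming them.
#' @param per_timepoint if `TRUE`, return a named list of tables, one per
#'   timepoint.
#' @return an object of class `speciation_table`: data.frame with columns
#'   `nominal_conc_ug_per_l`, `ion_dose`, `particle_dose`,
#'   `dissolved_fraction`, `n_measurements`, `clipped`.
#' @export
build_speciation_table <- function(measurements, required_levels = NULL,
                                   per_timepoint = FALSE) {
  needed <- c("nominal_conc_ug_per_l", "total_ag_ug_per_l",
              "dissolved_ag_ug_per_l")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols))
    stop("measurements lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (isTRUE(per_timepoint)) {
    if (!"timepoint_h" %in% names(measurements))
      stop("per_timepoint = TRUE requires a timepoint_h column", call. = FALSE)
    tps <- sort(unique(measurements$timepoint_h))
    out <- lapply(tps, function(tp)
      build_speciation_table(
        measurements[measurements$timepoint_h == tp, , drop = FALSE],
        required_levels = required_levels))
    names(out) <- as.character(tps)
    return(out)
  }
  if (!is.null(required_levels)) {
    absent <- setdiff(required_levels, measurements$nominal_conc_ug_per_l)
    if (length(absent))
      stop("nominal levels missing from speciation measurements: ",
           paste(sort(absent), collapse = ", "), call. = FALSE)
  }
  if (any(measurements$total_ag_ug_per_l < 0) ||
      any(measurements$dissolved_ag_ug_per_l < 0))
    stop("negative concentrations in speciation measurements", call. = FALSE)

  clip_needed <- measurements$dissolved_ag_ug_per_l > measurements$total_ag_ug_per_l
  dissolved <- pmin(measurements$dissolved_ag_ug_per_l,
                    measurements$total_ag_ug_per_l)
  if (any(clip_needed))
    warning(sprintf("%d speciation measurement(s) with dissolved > total clipped",
                    sum(clip_needed)), call. = FALSE)

  key <- measurements$nominal_conc_ug_per_l
  levels <- sort(unique(key))
  mean_total <- vapply(levels, function(l)
    mean(measurements$total_ag_ug_per_l[key == l]), numeric(1L))
  mean_diss <- vapply(levels, function(l) mean(dissolved[key == l]), numeric(1L))
  tab <- data.frame(nominal_conc_ug_per_l = levels,
                    ion_dose = mean_diss,
                    particle_dose = mean_total - mean_diss,
                    dissolved_fraction = ifelse(mean_total > 0,
                                                mean_diss / mean_total, NA_real_),
                    n_measurements = vapply(levels, function(l) sum(key == l),
                                            integer(1L)),
                    clipped = vapply(levels, function(l) any(clip_needed[key == l]),
                                     logical(1L)))
  structure(tab, class = c("speciation_table", "data.frame"))
}

#' Ion and particle doses at a nominal concentration
#'
#' Linear interpolation of the speciation table in nominal concentration
#' (linear, not log, because the doses enter toxic units linearly). Exact at
#' measured levels; queries outside the measured range raise an error rather
#' than extrapolating.
#'
#' @param table a `speciation_table`.
#' @param nominal_concentration scalar query concentration (ug/l).
#' @return named numeric vector `c(ion_dose = ..., particle_dose = ...)`.
#' @export
dose_at <- function(table, nominal_concentration) {
  stopifnot(inherits(table, "speciation_table"))
  x <- table$nominal_conc_ug_per_l
  q <- nominal_concentration
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q))
    stop("nominal_concentration must be a single finite number", call. = FALSE)
  if (q < min(x) || q > max(x))
    stop(sprintf("concentration %.4g outside measured range [%.4g, %.4g]; refusing to extrapolate",
                 q, min(x), max(x)), call. = FALSE)
  if (length(x) == 1L)
    return(c(ion_dose = table$ion_dose, particle_dose = table$particle_dose))
  c(ion_dose = stats::approx(x, table$ion_dose, xout = q)$y,
    particle_dose = stats::approx(x, table$particle_dose, xout = q)$y)
}
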