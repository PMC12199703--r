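#' Read per-well immobility records from CSV
#'
#' The file must start with the exact header
#' `condition,timepoint_h,conc_ug_per_l,n_exposed,n_immobile`; any further
#' columns are preserved as metadata. Each row is validated (counts
#' non-negative, `n_immobile <= n_exposed`, concentrations finite and >= 0)
#' and errors name the offending data row.
#'
#' @param path path to a CSV file (comma-separated, UTF-8, dot decimal).
#' @return data.frame of validated immobility records.
#' @export
read_immobility_csv <- function(path) {
  req <- c("condition", "timepoint_h", "conc_ug_per_l", "n_exposed", "n_immobile")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[seq_along(req)], req))
    stop("immobility CSV must start with header: ", paste(req, collapse = ","),
         call. = FALSE)
  .validate_immobility(df, path)
  df
}

.validate_immobility <- function(df, path = "<data>") {
  num <- c("timepoint_h", "conc_ug_per_l", "n_exposed", "n_immobile")
  for (col in num) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("%s: column '%s' is not numeric", path, col), call. = FALSE)
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s: unparseable or missing '%s' in row %d", path, col, bad[1L]),
           call. = FALSE)
  }
  bad <- which(df$conc_ug_per_l < 0 | df$n_exposed <= 0 | df$n_immobile < 0)
  if (length(bad))
    stop(sprintf("%s: negative value or non-positive n_exposed in row %d",
                 path, bad[1L]), call. = FALSE)
  bad <- which(df$n_immobile > df$n_exposed)
  if (length(bad))
    stop(sprintf("%s: n_immobile > n_exposed in row %d", path, bad[1L]),
         call. = FALSE)
  invisible(df)
}

#' Read ICP-MS speciation measurements from CSV
#'
#' Header: `nominal_conc_ug_per_l,timepoint_h,replicate,total_ag_ug_per_l,dissolved_ag_ug_per_l`.
#'
#' @param path path to a CSV file.
#' @return data.frame of validated speciation measurements.
#' @export
read_speciation_csv <- function(path) {
  req <- c("nominal_conc_ug_per_l", "timepoint_h", "replicate",
           "total_ag_ug_per_l", "dissolved_ag_ug_per_l")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[seq_along(req)], req))
    stop("speciation CSV must start with header: ", paste(req, collapse = ","),
         call. = FALSE)
  for (col in setdiff(req, "replicate")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: unparseable '%s' in row %d", path, col, bad[1L]),
           call. = FALSE)
  }
  bad <- which(df$total_ag_ug_per_l < 0 | df$dissolved_ag_ug_per_l < 0)
  if (length(bad))
    stop(sprintf("%s: negative concentration in row %d", path, bad[1L]),
         call. = FALSE)
  df
}

#' Read bacterial uptake records from CSV
#'
#' Header: `strain,agar_ag_mg_per_l,measured_conc_ug_per_l,final_volume_ml,pellet_dry_weight_mg`
#' (an optional `replicate` column may follow).
#'
#' @param path path to a CSV file.
#' @return data.frame of validated uptake records.
#' @export
read_uptake_csv <- function(path) {
  req <- c("strain", "agar_ag_mg_per_l", "measured_conc_ug_per_l",
           "final_volume_ml", "pellet_dry_weight_mg")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[seq_along(req)], req))
    stop("uptake CSV must start with header: ", paste(req, collapse = ","),
         call. = FALSE)
  bad <- which(df$pellet_dry_weight_mg <= 0 | df$measured_conc_ug_per_l < 0 |
               df$final_volume_ml < 0)
  if (length(bad))
    stop(sprintf("%s: invalid value in row %d", path, bad[1L]), call. = FALSE)
  df
}

#' Write a synthetic experiment to disk
#'
#' Writes `immobility.csv` and `icpms.csv` in the schemas the pipeline reads,
#' plus a `truth.json` sidecar recording every generator parameter and the
#' seed.
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
save_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_imm <- file.path(dir, "immobility.csv")
  p_sp <- file.path(dir, "icpms.csv")
  p_truth <- file.path(dir, "truth.json")
  utils::write.csv(experiment$immobility, p_imm, row.names = FALSE)
  utils::write.csv(experiment$speciation, p_sp, row.names = FALSE)
  truth <- unclass(experiment$truth)
  jsonlite::write_json(truth[!vapply(truth, is.null, logical(1L))], p_truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(immobility = p_imm, speciation = p_sp, truth = p_truth))
}

#' Run the full partition pipeline
#'
#' Drives the analysis end to end: reads the immobility and ICP-MS CSVs,
#' fits the AgNO3 ion curve per timepoint, builds the speciation table
#' (pooled over timepoints by default), runs the response-additivity
#' partition for every non-AgNO3 condition, compares the suspension EC50s of
#' all condition pairs per timepoint, optionally summarizes uptake records,
#' and writes `curves.csv`, `partition.csv`, `comparisons.csv` (and
#' `uptake_summary.csv`) plus a `run.log` collecting every warning, to the
#' output directory.
#'
#' @param config a named list or the path of a JSON/YAML file with fields
#'   `immobility_csv`, `icpms_csv`, optional `uptake_csv`, optional
#'   `timepoints` (default: all in the data), optional `per_timepoint_table`
#'   (default `FALSE`: pool ICP-MS timepoints), optional `alpha`
#'   (default 0.05), and `output_dir`.
#' @return invisibly, a list with the fitted curves, partition results,
#'   comparison table, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- .read_config(config)
  stopifnot(is.list(config))
  for (f in c("immobility_csv", "icpms_csv", "output_dir"))
    if (is.null(config[[f]])) stop("config field missing: ", f, call. = FALSE)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha

  log_lines <- character(0)
  note <- function(level, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", level, msg))
  }
  note("info", sprintf("agmix %s",
                       as.character(utils::packageVersion("agmix"))))

  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note("warning", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  imm <- read_immobility_csv(config$immobility_csv)
  sp <- read_speciation_csv(config$icpms_csv)
  note("info", sprintf("read %d immobility rows, %d speciation rows",
                       nrow(imm), nrow(sp)))

  timepoints <- if (is.null(config$timepoints)) sort(unique(imm$timepoint_h))
                else config$timepoints
  conditions <- setdiff(unique(imm$condition), "agno3")
  np_levels <- sort(unique(imm$conc_ug_per_l[imm$condition != "agno3" &
                                             imm$conc_ug_per_l > 0]))

  per_tp <- isTRUE(config$per_timepoint_table)
  tables <- if (per_tp)
    collect(build_speciation_table(sp, required_levels = np_levels,
                                   per_timepoint = TRUE))
  else collect(build_speciation_table(sp, required_levels = np_levels))

  curves <- list(); partitions <- list(); comp_rows <- list()
  for (tp in timepoints) {
    if (!any(imm$condition == "agno3" & imm$timepoint_h == tp))
      stop(sprintf("[ion fit] no AgNO3 records at %s h", format(tp)),
           call. = FALSE)
    ion <- collect(fit_ll4(imm, condition = "agno3", timepoint = tp))
    curves[[paste0("agno3@", tp)]] <- ion
    if (ion$dispersion > 2)
      note("warning", sprintf("ion curve at %s h: dispersion %.2f exceeds 2",
                              format(tp), ion$dispersion))
    tab <- if (per_tp) tables[[as.character(tp)]] else tables
    for (cond in conditions) {
      sub <- imm[imm$condition == cond & imm$timepoint_h == tp, , drop = FALSE]
      if (!nrow(sub)) next
      pr <- collect(partition_condition(sub, ion, tab))
      partitions[[paste0(cond, "@", tp)]] <- pr
      curves[[paste0(cond, "@", tp)]] <- pr$suspension_curve
      note("info", sprintf("partitioned %s at %s h: ion %.1f%% / particle %.1f%%",
                           cond, format(tp), 100 * pr$ion_fraction,
                           100 * pr$particle_fraction))
    }
    conds_here <- conditions[vapply(conditions, function(cond)
      !is.null(partitions[[paste0(cond, "@", tp)]]), logical(1L))]
    if (length(conds_here) >= 2L) {
      pairs <- utils::combn(conds_here, 2L)
      for (j in seq_len(ncol(pairs))) {
        a <- partitions[[paste0(pairs[1L, j], "@", tp)]]$suspension_curve
        b <- partitions[[paste0(pairs[2L, j], "@", tp)]]$suspension_curve
        cmp <- compare_ec50(a, b)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          timepoint_h = tp, condition_A = pairs[1L, j],
          condition_B = pairs[2L, j], ratio = cmp$ratio,
          se_log_ratio = cmp$se_log_ratio, statistic = cmp$statistic,
          df = cmp$df, p_value = cmp$p_value,
          significant = cmp$p_value < alpha)
      }
    }
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  curve_df <- do.call(rbind, lapply(names(curves), function(k) {
    cv <- curves[[k]]
    data.frame(condition = cv$condition, timepoint_h = cv$timepoint,
               slope = cv$slope, ec50 = cv$ec50,
               se_log_ec50 = sqrt(cv$covariance["log_ec50", "log_ec50"]),
               dispersion = cv$dispersion, residual_df = cv$residual_df,
               loglik = cv$loglik)
  }))
  part_df <- do.call(rbind, lapply(partitions, function(pr)
    data.frame(condition = pr$condition, timepoint_h = pr$timepoint,
               suspension_ec50 = pr$suspension_ec50,
               ion_ec50 = pr$ion_curve$ec50,
               particle_ec50 = pr$particle_curve$ec50,
               c_ion = pr$c_ion, c_particle = pr$c_particle,
               tu_ion = pr$tu_ion, tu_particle = pr$tu_particle,
               ion_fraction = pr$ion_fraction,
               particle_fraction = pr$particle_fraction)))
  rownames(part_df) <- NULL
  comp_df <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(timepoint_h = numeric(0), condition_A = character(0),
               condition_B = character(0), ratio = numeric(0),
               se_log_ratio = numeric(0), statistic = numeric(0),
               df = integer(0), p_value = numeric(0), significant = logical(0))

  paths <- c(curves = file.path(config$output_dir, "curves.csv"),
             partition = file.path(config$output_dir, "partition.csv"),
             comparisons = file.path(config$output_dir, "comparisons.csv"),
             log = file.path(config$output_dir, "run.log"))
  utils::write.csv(curve_df, paths[["curves"]], row.names = FALSE)
  utils::write.csv(part_df, paths[["partition"]], row.names = FALSE)
  utils::write.csv(comp_df, paths[["comparisons"]], row.names = FALSE)

  uptake_df <- NULL
  if (!is.null(config$uptake_csv)) {
    uptake_df <- summarize_uptake(read_uptake_csv(config$uptake_csv))
    paths[["uptake"]] <- file.path(config$output_dir, "uptake_summary.csv")
    utils::write.csv(uptake_df, paths[["uptake"]], row.names = FALSE)
    note("info", sprintf("summarized uptake for %d strata", nrow(uptake_df)))
  }
  note("info", "pipeline complete")
  writeLines(log_lines, paths[["log"]])

  invisible(list(curves = curves, partitions = partitions,
                 comparisons = comp_df, uptake = uptake_df,
                 tables = tables, paths = paths, log = log_lines))
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
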