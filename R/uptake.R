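#' Silver uptake normalized to bacterial dry weight
#'
#' Converts an ICP-MS digest measurement into micrograms of silver per
#' milligram of bacterial dry weight:
#' `(measured_concentration [ug/l] * final_volume [ml] / 1000) / dry_weight [mg]`,
#' i.e. total analyte mass over pellet dry mass. The digestion/dilution chain
#' is absorbed into the single `final_volume_ml` supplied by the user.
#'
#' @param measured_conc_ug_per_l silver concentration in the final analyte,
#'   ug/l, >= 0.
#' @param final_volume_ml final analyte volume after dilution, ml, >= 0.
#' @param pellet_dry_weight_mg pellet dry weight, mg, > 0.
#' @return ug Ag per mg dry weight (vectorized).
#' @examples
#' ag_per_dry_weight(190, 10, 1.0)  # 1.9
#' @export
ag_per_dry_weight <- function(measured_conc_ug_per_l, final_volume_ml,
                              pellet_dry_weight_mg) {
  if (any(!is.finite(measured_conc_ug_per_l)) || any(measured_conc_ug_per_l < 0))
    stop("measured concentration must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(final_volume_ml)) || any(final_volume_ml < 0))
    stop("final volume must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(pellet_dry_weight_mg)) || any(pellet_dry_weight_mg <= 0))
    stop("pellet dry weight must be > 0", call. = FALSE)
  (measured_conc_ug_per_l * final_volume_ml / 1000) / pellet_dry_weight_mg
}

#' Per-strain uptake summaries
#'
#' Mean and standard error of dry-weight-normalized silver uptake per strain
#' and agar silver level. Strata with a single replicate report the mean with
#' the SE flagged unavailable (`NA`), rather than erroring.
#'
#' @param records data.frame with columns `strain`, `agar_ag_mg_per_l`,
#'   `measured_conc_ug_per_l`, `final_volume_ml`, `pellet_dry_weight_mg`
#'   (a `replicate` column is allowed).
#' @return data.frame with columns `strain`, `agar_ag_mg_per_l`,
#'   `n_replicates`, `mean_ug_per_mg`, `se_ug_per_mg` (`NA` when fewer than
#'   two replicates).
#' @export
summarize_uptake <- function(records) {
  needed <- c("strain", "agar_ag_mg_per_l", "measured_conc_ug_per_l",
              "final_volume_ml", "pellet_dry_weight_mg")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  val <- ag_per_dry_weight(records$measured_conc_ug_per_l,
                           records$final_volume_ml,
                           records$pellet_dry_weight_mg)
  key <- interaction(records$strain, records$agar_ag_mg_per_l, drop = TRUE)
  agg <- lapply(split(seq_along(val), key), function(idx) {
    n <- length(idx)
    data.frame(strain = records$strain[idx[1L]],
               agar_ag_mg_per_l = records$agar_ag_mg_per_l[idx[1L]],
               n_replicates = n,
               mean_ug_per_mg = mean(val[idx]),
               se_ug_per_mg = if (n >= 2L) stats::sd(val[idx]) / sqrt(n)
                              else NA_real_)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$strain, out$agar_ag_mg_per_l), , drop = FALSE]
}
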