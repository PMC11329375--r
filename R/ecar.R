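#' Stoichiometric parameters of the Na+ -> ATP -> H+ chain
#'
#' Defaults encode the accounting used to predict channel-dependent
#' extracellular acidification: the Na+/K+ ATPase extrudes 3 Na+ per ATP
#' hydrolysed; glycolytic fermentation yields 2 ATP and 2 lactate per
#' glucose, and coupled to ATP hydrolysis nets one H+ per glycolytic ATP.
#'
#' @param na_per_atp Na+ ions pumped per ATP.
#' @param atp_per_glucose Glycolytic ATP per glucose.
#' @param lactate_per_glucose Lactate per glucose.
#' @param h_per_atp H+ per glycolytic ATP; defaults to
#'   `lactate_per_glucose / atp_per_glucose`.
#' @return Object of class `stoich_params`.
#' @export
stoichiometry_params <- function(na_per_atp = 3, atp_per_glucose = 2,
                                 lactate_per_glucose = 2,
                                 h_per_atp = lactate_per_glucose /
                                   atp_per_glucose) {
  for (nm in c("na_per_atp", "atp_per_glucose", "lactate_per_glucose",
               "h_per_atp")) {
    stop_if_not_positive(get(nm), nm)
  }
  structure(list(na_per_atp = na_per_atp, h_per_atp = h_per_atp,
                 atp_per_glucose = atp_per_glucose,
                 lactate_per_glucose = lactate_per_glucose),
            class = "stoich_params")
}

#' Assay-well geometry and buffering
#'
#' Defaults match the plate-based flux assay the prediction is compared
#' against: 3.0e4 cells per well in a final volume of 180 ul of
#' bicarbonate-free, lightly buffered medium.  `buffering_power_mol_l_ph`
#' is the lumped linear buffering coefficient (mol H+ per litre per pH
#' unit); the default, 1.65e-4 mol/L/pH, is the package's reproduction
#' constant for the published prediction.
#'
#' @param cells_per_well Cell count per well.
#' @param volume_l Assay volume, litres.
#' @param buffering_power_mol_l_ph Buffering power, mol/L/pH.
#' @return Object of class `well_geometry`.
#' @export
well_geometry <- function(cells_per_well = 3e4, volume_l = 180e-6,
                          buffering_power_mol_l_ph = 1.65e-4) {
  stop_if_not_positive(cells_per_well, "cells_per_well")
  stop_if_not_positive(volume_l, "volume_l")
  stop_if_not_positive(buffering_power_mol_l_ph,
                       "buffering_power_mol_l_ph")
  structure(list(cells_per_well = cells_per_well, volume_l = volume_l,
                 buffering_power_mol_l_ph = buffering_power_mol_l_ph),
            class = "well_geometry")
}

FARADAY_C_MOL <- 96485.332

#' Na+ influx per cell from a persistent current density
#'
#' `|density| * capacitance` converted pA -> A and divided by the Faraday
#' constant.
#'
#' @param persistent_density_pa_pf Persistent current density, pA/pF
#'   (sign ignored).
#' @param capacitance_pf Cell capacitance, pF.
#' @return Na+ influx, mol/s/cell.
#' @examples
#' na_flux_per_cell(-0.31, 20)  # ~6.43e-17 mol/s
#' @export
na_flux_per_cell <- function(persistent_density_pa_pf, capacitance_pf) {
  stop_if_not_scalar(persistent_density_pa_pf, "persistent_density_pa_pf")
  stop_if_not_positive(capacitance_pf, "capacitance_pf")
  abs(persistent_density_pa_pf) * capacitance_pf * 1e-12 / FARADAY_C_MOL
}

#' Predict the channel-dependent extracellular acidification rate
#'
#' Chains the persistent Na+ influx through the pump/glycolysis
#' stoichiometry to a bulk acidification rate:
#' Na+ flux -> / `na_per_atp` -> ATP flux -> x `h_per_atp` -> H+ flux per
#' cell -> x cells/well -> / volume -> / buffering power -> x 60 ->
#' mpH/min.  All intermediate fluxes are reported.
#'
#' @inheritParams na_flux_per_cell
#' @param stoich A [stoichiometry_params()].
#' @param well A [well_geometry()].
#' @return Object of class `ecar_prediction`: list with
#'   `na_flux_mol_s_cell`, `atp_flux_mol_s_cell`, `h_flux_mol_s_cell`,
#'   `ecar_mpH_min`, plus the inputs.
#' @examples
#' predict_ecar(-0.31, 20)  # ~1.3 mpH/min under the default constants
#' @export
predict_ecar <- function(persistent_density_pa_pf, capacitance_pf = 20,
                         stoich = stoichiometry_params(),
                         well = well_geometry()) {
  stopifnot(inherits(stoich, "stoich_params"),
            inherits(well, "well_geometry"))
  na_flux <- na_flux_per_cell(persistent_density_pa_pf, capacitance_pf)
  atp_flux <- na_flux / stoich$na_per_atp
  h_flux <- atp_flux * stoich$h_per_atp
  ecar <- h_flux * well$cells_per_well / well$volume_l /
    well$buffering_power_mol_l_ph * 60 * 1000
  structure(list(
    na_flux_mol_s_cell = na_flux,
    atp_flux_mol_s_cell = atp_flux,
    h_flux_mol_s_cell = h_flux,
    ecar_mpH_min = ecar,
    persistent_density_pa_pf = persistent_density_pa_pf,
    capacitance_pf = capacitance_pf,
    stoich = stoich, well = well
  ), class = "ecar_prediction")
}

#' @export
print.ecar_prediction <- function(x, ...) {
  cat("Stoichiometric ECAR prediction\n")
  cat(sprintf("  persistent density %.3g pA/pF x %.3g pF\n",
              x$persistent_density_pa_pf, x$capacitance_pf))
  cat(sprintf("  Na+ influx  %.3e mol/s/cell\n", x$na_flux_mol_s_cell))
  cat(sprintf("  ATP demand  %.3e mol/s/cell\n", x$atp_flux_mol_s_cell))
  cat(sprintf("  H+ export   %.3e mol/s/cell\n", x$h_flux_mol_s_cell))
  cat(sprintf("  predicted ECAR %.2f mpH/min\n", x$ecar_mpH_min))
  invisible(x)
}

#' Simulate a Seahorse-style plate time series
#'
#' Wells follow a constant baseline acidification rate; after the
#' injection cycle, treated wells drop by `step_change_mpH_min` and carry
#' a decaying injection artefact with a ~15 min span (mixing/temperature
#' transient), which the effect estimator excludes.  Measurement cycles
#' are 6 min apart.
#'
#' @param baseline_mpH_min Baseline ECAR, mpH/min.
#' @param step_change_mpH_min Sustained change in treated wells after the
#'   injection (negative = reduction).
#' @param n_wells Wells per group per plate.
#' @param n_timepoints Measurement cycles.
#' @param injection_index Last baseline cycle; the injection happens after
#'   it.
#' @param noise_sd Gaussian per-measurement noise SD, mpH/min.
#' @param seed Integer seed.
#' @param n_plates Experimental repeats (plates).
#' @param artefact_mpH_min Initial amplitude of the injection artefact in
#'   treated wells.
#' @param cycle_min Minutes between measurement cycles.
#' @return data.frame with columns `plate`, `well`, `group`
#'   (`treated`/`control`), `cycle`, `time_min`, `ecar`.
#' @export
simulate_seahorse <- function(baseline_mpH_min = 50,
                              step_change_mpH_min = -9.8,
                              n_wells = 6, n_timepoints = 16,
                              injection_index = 6, noise_sd = 1.5,
                              seed = 1L, n_plates = 1,
                              artefact_mpH_min = -3, cycle_min = 6) {
  stop_if_negative(noise_sd, "noise_sd")
  if (injection_index >= n_timepoints) {
    stop("`injection_index` must be < `n_timepoints`", call. = FALSE)
  }
  if (n_wells < 1) stop("`n_wells` must be >= 1", call. = FALSE)
  seed_stream(seed)
  tau_artefact <- 5  # min; decayed to <5% within the 15 min span
  grid <- expand.grid(cycle = seq_len(n_timepoints),
                      well = seq_len(n_wells),
                      group = c("treated", "control"),
                      plate = seq_len(n_plates),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$time_min <- grid$cycle * cycle_min
  t_inj <- injection_index * cycle_min
  post <- grid$time_min > t_inj
  mu <- rep(baseline_mpH_min, nrow(grid))
  treated_post <- post & grid$group == "treated"
  mu[treated_post] <- mu[treated_post] + step_change_mpH_min +
    artefact_mpH_min *
      exp(-(grid$time_min[treated_post] - t_inj) / tau_artefact)
  grid$ecar <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[c("plate", "well", "group", "cycle", "time_min", "ecar")]
}

#' Estimate a treatment effect on ECAR from plate time series
#'
#' Per well, the mean of the last `n_last` timepoints (all of which must
#' fall at least `exclusion_min` minutes after the injection, excluding
#' the injection-artefact window); the effect is
#' `mean(control) - mean(treated)` per plate, summarised over plates with
#' an SEM.
#'
#' @param plate_data data.frame as produced by [simulate_seahorse()]
#'   (columns `plate`, `well`, `group`, `cycle`, `time_min`, `ecar`).
#' @param injection_index Last pre-injection cycle.
#' @param exclusion_min Artefact exclusion window after the injection,
#'   minutes.
#' @param n_last Number of final timepoints averaged per well.
#' @return List with `effect` (mpH/min), `sem`, `per_plate`, `n_plates`.
#' @export
measure_ecar_effect <- function(plate_data, injection_index = 6,
                                exclusion_min = 15, n_last = 6) {
  need <- c("plate", "well", "group", "cycle", "time_min", "ecar")
  if (!all(need %in% names(plate_data))) {
    stop("`plate_data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cycles <- sort(unique(plate_data$cycle))
  last_cycles <- utils::tail(cycles, n_last)
  t_inj <- max(plate_data$time_min[plate_data$cycle == injection_index])
  sub <- plate_data[plate_data$cycle %in% last_cycles, , drop = FALSE]
  if (length(last_cycles) < n_last ||
      any(sub$time_min <= t_inj + exclusion_min)) {
    stop(sprintf(
      "need %d post-injection timepoints outside the %g min artefact window",
      n_last, exclusion_min), call. = FALSE)
  }
  per_plate <- vapply(split(sub, sub$plate), function(d) {
    # mean of per-well last-n means; equal timepoint counts per well make
    # this the plain group mean
    grp <- tapply(d$ecar, d$group, mean)
    unname(grp["control"] - grp["treated"])
  }, numeric(1))
  list(effect = mean(per_plate),
       sem = if (length(per_plate) > 1) {
         stats::sd(per_plate) / sqrt(length(per_plate))
       } else NA_real_,
       per_plate = per_plate, n_plates = length(per_plate))
}

#' Order-of-magnitude agreement check
#'
#' @param predicted,measured Positive rates in the same units.
#' @param factor Maximal acceptable ratio (10 = one order of magnitude).
#' @return List with `ratio` (`max/min`) and `pass`.
#' @examples
#' order_of_magnitude_check(1.3, 9.8)  # ratio ~7.5, pass
#' @export
order_of_magnitude_check <- function(predicted, measured, factor = 10) {
  stop_if_not_positive(predicted, "predicted")
  stop_if_not_positive(measured, "measured")
  ratio <- max(predicted, measured) / min(predicted, measured)
  list(ratio = ratio, pass = ratio <= factor)
}
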