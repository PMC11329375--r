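#' Simulate a pH-microelectrode voltage series with interleaved calibration
#'
#' The electrode responds linearly, `V = intercept + slope * pH`, with a
#' junction-potential offset that drifts block-wise as the electrode is
#' repeatedly placed.  Measurements are grouped into blocks of at most
#' `block_size`; a calibration event (known-pH buffer readings plus a
#' reference-bath reading) is emitted before the first block, between
#' blocks, and after the last, so a two-block series carries calibration
#' before, half-way and at the end.
#'
#' @param true_ph_sequence True pH of each tissue measurement, in order.
#' @param slope_mv_per_ph Electrode slope, mV/pH (nonzero; ~-58 mV/pH for
#'   a Nernstian H+ electrode).
#' @param intercept_mv Electrode intercept, mV.
#' @param offset_drift_mv_per_block Junction-potential drift added per
#'   block.
#' @param noise_sd_mv Gaussian voltage noise SD, mV.
#' @param seed Integer seed.
#' @param cal_ph Buffer pH values read at each calibration event.
#' @param bath_ph Reference-bath pH (used for offset estimation).
#' @param block_size Measurements per block (<= 12 by convention).
#' @return Object of class `electrode_series`: data.frame with columns
#'   `index`, `block`, `type` (`measurement`/`calibration`/`bath`),
#'   `known_ph` (NA for measurements), `voltage_mv`; the true pH sequence
#'   is attached as attribute `true_ph`.
#' @export
simulate_electrode_series <- function(true_ph_sequence,
                                      slope_mv_per_ph = -58,
                                      intercept_mv = 376,
                                      offset_drift_mv_per_block = 2,
                                      noise_sd_mv = 0, seed = 1L,
                                      cal_ph = c(6, 7, 8),
                                      bath_ph = 7.4, block_size = 12) {
  if (slope_mv_per_ph == 0) stop("`slope_mv_per_ph` must be nonzero",
                                 call. = FALSE)
  stop_if_negative(noise_sd_mv, "noise_sd_mv")
  seed_stream(seed)
  n <- length(true_ph_sequence)
  n_blocks <- max(1L, ceiling(n / block_size))
  volt <- function(ph, offset) {
    intercept_mv + slope_mv_per_ph * ph + offset +
      stats::rnorm(length(ph), 0, noise_sd_mv)
  }
  rows <- list()
  idx <- 0L
  emit <- function(block, type, known_ph, v) {
    idx <<- idx + length(v)
    rows[[length(rows) + 1L]] <<- data.frame(
      index = seq.int(idx - length(v) + 1L, idx), block = block,
      type = type, known_ph = known_ph, voltage_mv = v)
  }
  for (b in seq_len(n_blocks)) {
    off <- (b - 1L) * offset_drift_mv_per_block
    emit(b, "calibration", cal_ph, volt(cal_ph, off))
    emit(b, "bath", bath_ph, volt(bath_ph, off))
    take <- true_ph_sequence[seq.int((b - 1L) * block_size + 1L,
                                     min(b * block_size, n))]
    emit(b, "measurement", NA_real_, volt(take, off))
  }
  # closing calibration event, at the next drift level
  off <- n_blocks * offset_drift_mv_per_block
  emit(n_blocks + 1L, "calibration", cal_ph, volt(cal_ph, off))
  emit(n_blocks + 1L, "bath", bath_ph, volt(bath_ph, off))
  out <- do.call(rbind, rows)
  attr(out, "true_ph") <- true_ph_sequence
  class(out) <- c("electrode_series", "data.frame")
  out
}

#' Correct an electrode series for block-wise junction-potential offsets
#'
#' Each block's offset is estimated from its reference-bath reading
#' relative to the first bath reading and held piecewise-constant over
#' the block (no interpolation across blocks); all rows of the block -
#' calibration points and measurements alike - are corrected by
#' subtracting it.
#'
#' @param series An `electrode_series` (or data.frame with the same
#'   columns).
#' @return The series with corrected `voltage_mv` and an added
#'   `offset_mv` column.
#' @export
apply_offset_schedule <- function(series) {
  need <- c("index", "block", "type", "known_ph", "voltage_mv")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  baths <- series[series$type == "bath", , drop = FALSE]
  if (!nrow(baths)) stop("series carries no bath readings for offsets",
                         call. = FALSE)
  bath_by_block <- tapply(baths$voltage_mv, baths$block, mean)
  blocks <- unique(series$block)
  orphan <- setdiff(as.character(blocks), names(bath_by_block))
  if (length(orphan)) {
    stop("blocks without an offset (bath) reading: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  ref <- bath_by_block[[1L]]
  off <- bath_by_block[as.character(series$block)] - ref
  out <- series
  out$offset_mv <- as.numeric(off)
  out$voltage_mv <- series$voltage_mv - out$offset_mv
  out
}

#' Fit the electrode calibration line
#'
#' Ordinary least squares of voltage on pH over the offset-corrected
#' calibration points (voltage as regressand; with two points the choice
#' of regression direction is immaterial, and it is configurable).
#'
#' @param series An offset-corrected series (see
#'   [apply_offset_schedule()]), or any data.frame whose
#'   `type == "calibration"` rows carry `known_ph` and `voltage_mv`.
#' @param regress `"voltage_on_ph"` (default) or `"ph_on_voltage"`.
#' @return Object of class `electrode_map`: list with `slope_mv_per_ph`,
#'   `intercept_mv`, `r_squared`, `n_points` and the fitted `lm`.
#' @export
fit_electrode <- function(series, regress = c("voltage_on_ph",
                                              "ph_on_voltage")) {
  regress <- match.arg(regress)
  cal <- series[series$type == "calibration", , drop = FALSE]
  if (nrow(cal) < 2L || length(unique(cal$known_ph)) < 2L) {
    stop("need >= 2 calibration points at >= 2 distinct pH values",
         call. = FALSE)
  }
  if (regress == "voltage_on_ph") {
    fit <- stats::lm(voltage_mv ~ known_ph, data = cal)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  } else {
    fit <- stats::lm(known_ph ~ voltage_mv, data = cal)
    slope <- 1 / unname(stats::coef(fit)[2L])
    intercept <- -unname(stats::coef(fit)[1L]) * slope
  }
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate calibration line (zero slope)", call. = FALSE)
  }
  r2 <- stats::cor(cal$known_ph, cal$voltage_mv)^2
  structure(list(slope_mv_per_ph = slope, intercept_mv = intercept,
                 r_squared = r2, n_points = nrow(cal), fit = fit),
            class = "electrode_map")
}

#' @export
print.electrode_map <- function(x, ...) {
  cat(sprintf(
    "Electrode calibration: V = %.2f %+.2f * pH (mV), r^2 = %.4f, n = %d\n",
    x$intercept_mv, x$slope_mv_per_ph, x$r_squared, x$n_points))
  invisible(x)
}

#' Invert the electrode line: voltage -> pH
#'
#' @param map An [fit_electrode()] result.
#' @param voltage_mv Offset-corrected voltage(s), mV.
#' @return pH value(s).
#' @export
invert_electrode <- function(map, voltage_mv) {
  stopifnot(inherits(map, "electrode_map"))
  (voltage_mv - map$intercept_mv) / map$slope_mv_per_ph
}

#' Full electrode pipeline: offsets, line fit, inversion
#'
#' @param series A raw `electrode_series`.
#' @inheritParams fit_electrode
#' @return List with `map` and `measurements` (the measurement rows with
#'   an added `ph` column).
#' @export
electrode_ph <- function(series, regress = "voltage_on_ph") {
  corr <- apply_offset_schedule(series)
  map <- fit_electrode(corr, regress = regress)
  meas <- corr[corr$type == "measurement", , drop = FALSE]
  meas$ph <- invert_electrode(map, meas$voltage_mv)
  list(map = map, measurements = meas)
}

#' Two-point per-cell BCECF intracellular pH calibration
#'
#' For each cell, the clamped fluorescence ratios at pH 7.0 and 8.0
#' (nigericin/high-K+ calibration) define a straight line in ratio-pH
#' space; the resting ratio is inverted through that cell's own line, and
#' the cohort value is the mean over cells.
#'
#' @param ratio_at_7,ratio_at_8,resting_ratio Per-cell ratios (equal
#'   lengths).
#' @return List with `per_cell` pH, `mean`, `sem`, `n`.
#' @export
bcecf_resting_ph <- function(ratio_at_7, ratio_at_8, resting_ratio) {
  n <- length(resting_ratio)
  if (length(ratio_at_7) != n || length(ratio_at_8) != n) {
    stop("per-cell ratio vectors must have equal length", call. = FALSE)
  }
  if (any(ratio_at_8 == ratio_at_7)) {
    stop("degenerate per-cell calibration: equal ratios at pH 7.0 and 8.0",
         call. = FALSE)
  }
  ph <- 7 + (resting_ratio - ratio_at_7) / (ratio_at_8 - ratio_at_7)
  list(per_cell = ph, mean = mean(ph),
       sem = stats::sd(ph) / sqrt(n), n = n)
}

#' Simulate per-cell BCECF calibration data
#'
#' @param n_cells Number of cells (~40 per coverslip is typical).
#' @param true_ph True resting intracellular pH.
#' @param ratio_at_7_mean,ratio_span Mean calibration ratio at pH 7.0 and
#'   mean ratio increase per pH unit; both vary per cell.
#' @param cell_cv CV of per-cell calibration parameters.
#' @param noise_sd Additive ratio noise SD on each reading.
#' @param seed Integer seed.
#' @return data.frame with `cell`, `ratio_at_7`, `ratio_at_8`,
#'   `resting_ratio`.
#' @export
simulate_bcecf_cells <- function(n_cells = 40, true_ph = 6.3,
                                 ratio_at_7_mean = 2, ratio_span = 1,
                                 cell_cv = 0.1, noise_sd = 0.01,
                                 seed = 1L) {
  seed_stream(seed)
  r7 <- ratio_at_7_mean * (1 + stats::rnorm(n_cells, 0, cell_cv))
  span <- ratio_span * (1 + stats::rnorm(n_cells, 0, cell_cv))
  resting <- r7 + (true_ph - 7) * span + stats::rnorm(n_cells, 0, noise_sd)
  data.frame(cell = seq_len(n_cells),
             ratio_at_7 = r7 + stats::rnorm(n_cells, 0, noise_sd),
             ratio_at_8 = r7 + span + stats::rnorm(n_cells, 0, noise_sd),
             resting_ratio = resting)
}

#' Simulate ratiometric plate-reader fluorescence wells
#'
#' Treated and vehicle wells emit fluorescence at 340 and 380 nm such
#' that the background-corrected 340/380 ratio of treated wells is
#' `true_ratio_fold` times that of vehicle wells; dedicated background
#' wells carry only the per-wavelength background.  An uncorrected ratio
#' is biased toward 1 whenever the backgrounds are nonzero.
#'
#' @param true_ratio_fold Treated/vehicle corrected-ratio fold change.
#' @param background_340,background_380 Background fluorescence at each
#'   wavelength (>= 0), a.u.
#' @param n_wells Wells per group.
#' @param noise_sd Gaussian fluorescence noise SD, a.u.
#' @param seed Integer seed.
#' @param vehicle_ratio True corrected 340/380 ratio of vehicle wells.
#' @param f380_signal True background-corrected 380 nm signal, a.u.
#' @param n_background Background wells per plate.
#' @return data.frame with `well`, `group`
#'   (`treated`/`vehicle`/`background`), `f340`, `f380`.
#' @export
simulate_plate_fluorescence <- function(true_ratio_fold = 2.2,
                                        background_340 = 150,
                                        background_380 = 200,
                                        n_wells = 5, noise_sd = 10,
                                        seed = 1L, vehicle_ratio = 0.9,
                                        f380_signal = 1000,
                                        n_background = 3) {
  stop_if_negative(background_340, "background_340")
  stop_if_negative(background_380, "background_380")
  stop_if_negative(noise_sd, "noise_sd")
  stop_if_not_positive(true_ratio_fold, "true_ratio_fold")
  seed_stream(seed)
  mk <- function(group, ratio, n) {
    f380 <- f380_signal + background_380
    f340 <- ratio * f380_signal + background_340
    data.frame(well = paste0(substr(group, 1, 1), seq_len(n)),
               group = group,
               f340 = f340 + stats::rnorm(n, 0, noise_sd),
               f380 = f380 + stats::rnorm(n, 0, noise_sd))
  }
  bg <- data.frame(well = paste0("b", seq_len(n_background)),
                   group = "background",
                   f340 = background_340 +
                     stats::rnorm(n_background, 0, noise_sd),
                   f380 = background_380 +
                     stats::rnorm(n_background, 0, noise_sd))
  rbind(mk("treated", vehicle_ratio * true_ratio_fold, n_wells),
        mk("vehicle", vehicle_ratio, n_wells), bg)
}

#' SBFI-style background-subtracted ratio fold change
#'
#' Per plate: mean background per wavelength is subtracted from every
#' well, per-well 340/380 ratios are formed, the five-well group means
#' are taken, and the fold change is treated/vehicle.  With a list of
#' plates (experimental repeats) the per-repeat folds are summarised
#' with an SEM.
#'
#' @param plates A plate data.frame from [simulate_plate_fluorescence()],
#'   or a list of them (one per experimental repeat).
#' @return List with `fold` (mean over repeats), `sem`, `per_repeat`,
#'   `n_repeats`.
#' @export
sbfi_fold_change <- function(plates) {
  if (is.data.frame(plates)) plates <- list(plates)
  per_repeat <- vapply(plates, function(p) {
    need <- c("group", "f340", "f380")
    if (!all(need %in% names(p))) {
      stop("plate data must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bg <- p[p$group == "background", , drop = FALSE]
    if (!nrow(bg)) stop("missing background wells", call. = FALSE)
    b340 <- mean(bg$f340); b380 <- mean(bg$f380)
    ratio <- (p$f340 - b340) / (p$f380 - b380)
    grp <- tapply(ratio[p$group != "background"],
                  p$group[p$group != "background"], mean)
    unname(grp["treated"] / grp["vehicle"])
  }, numeric(1))
  list(fold = mean(per_repeat),
       sem = if (length(per_repeat) > 1) {
         stats::sd(per_repeat) / sqrt(length(per_repeat))
       } else NA_real_,
       per_repeat = per_repeat, n_repeats = length(per_repeat))
}

#' Cohort recovery of the peripheral tumour-slice pH
#'
#' For each synthetic slice, 12 core and 12 periphery measurements are
#' taken alternately (blocks of 12 between calibration events, junction
#' offsets drifting block-wise), the electrode pipeline is run, and the
#' recovered per-slice periphery and core means are summarised across
#' slices.
#'
#' @param n_slices Number of slices.
#' @param core_ph,periphery_ph True mean pH of the two regions.
#' @param slice_sd Per-slice SD of the true regional pH.
#' @param n_per_region Measurements per region per slice.
#' @param noise_sd_mv Electrode voltage noise SD, mV.
#' @param drift_mv_per_block Junction-potential drift per block, mV.
#' @param seed Integer seed.
#' @return List with `periphery` and `core` summaries (`mean`, `sem`,
#'   `per_slice`, `truth`) and `n_slices`.
#' @export
recover_slice_ph <- function(n_slices = 9, core_ph = 7.0,
                             periphery_ph = 6.8, slice_sd = 0.1,
                             n_per_region = 12, noise_sd_mv = 0.5,
                             drift_mv_per_block = 2, seed = 1L) {
  seed_stream(seed)
  slice_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)
  core_true <- core_ph + stats::rnorm(n_slices, 0, slice_sd)
  peri_true <- periphery_ph + stats::rnorm(n_slices, 0, slice_sd)
  per_slice <- t(vapply(seq_len(n_slices), function(i) {
    seqn <- as.vector(rbind(rep(core_true[i], n_per_region),
                            rep(peri_true[i], n_per_region)))
    region <- rep(c("core", "periphery"), n_per_region)
    res <- electrode_ph(simulate_electrode_series(
      seqn, noise_sd_mv = noise_sd_mv,
      offset_drift_mv_per_block = drift_mv_per_block,
      seed = slice_seeds[i]))
    ph <- res$measurements$ph
    c(core = mean(ph[region == "core"]),
      periphery = mean(ph[region == "periphery"]))
  }, c(core = 0, periphery = 0)))
  list(
    periphery = list(mean = mean(per_slice[, "periphery"]),
                     sem = stats::sd(per_slice[, "periphery"]) /
                       sqrt(n_slices),
                     per_slice = per_slice[, "periphery"],
                     truth = periphery_ph),
    core = list(mean = mean(per_slice[, "core"]),
                sem = stats::sd(per_slice[, "core"]) / sqrt(n_slices),
                per_slice = per_slice[, "core"], truth = core_ph),
    n_slices = n_slices
  )
}
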