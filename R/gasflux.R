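# Closed-chamber CO2 flux: headspace mole fractions -> dry-soil-normalised
# respiration rates and cumulative respiration.

#' Ideal gas constant in L atm K^-1 mol^-1
#' @export
GAS_CONSTANT <- 0.08206

#' Dry soil mass from wet mass and gravimetric water content
#'
#' GWC is defined on a dry-mass basis, (wet - dry) / dry * 100, which is why
#' organic permafrost soils can exceed 100% GWC. Inverting gives
#' dry = wet / (1 + GWC/100).
#'
#' @param wet_mass Wet soil mass in grams (> 0).
#' @param gwc_percent Gravimetric water content in percent (>= 0).
#' @return Dry soil mass in grams.
#' @examples
#' dry_mass(20, 100)  # water mass equals dry mass -> 10 g
#' @export
dry_mass <- function(wet_mass, gwc_percent) {
  if (any(!is.finite(wet_mass)) || any(wet_mass <= 0))
    stop_domain("wet_mass must be > 0")
  if (any(!is.finite(gwc_percent)) || any(gwc_percent < 0))
    stop_domain("gwc_percent must be >= 0")
  wet_mass / (1 + gwc_percent / 100)
}

#' Soil respiration rate from a headspace CO2 measurement
#'
#' Converts a headspace CO2 mole fraction accumulated since the most recent
#' flush into a respiration rate in micrograms of CO2-C per gram of dry soil
#' per hour. The headspace is flushed with CO2-free air after each
#' measurement, so the measured mole fraction is the accumulation over the
#' interval. With n_air = P*V / (R*T) moles of air in the headspace, the
#' accumulated CO2 is `co2_ppm * n_air` micromoles, each carrying 12 ug of
#' carbon:
#'
#'   rate = co2_ppm * (P*V) / (R*T) * 12 / dry_soil / t
#'
#' @param co2_ppm CO2 mole fraction, umol CO2 per mol air (>= 0).
#' @param pressure_atm Headspace pressure in atm (> 0).
#' @param volume_L Headspace volume in litres (> 0).
#' @param temp_K Incubation temperature in kelvin (> 0).
#' @param dry_soil_g Dry soil mass in grams (> 0).
#' @param hours Hours since the most recent flush (> 0).
#' @param R Gas constant, L atm K^-1 mol^-1. Fixed physical constant;
#'   overridable only for testing.
#' @return Respiration rate, ug CO2-C g^-1 dry soil h^-1 (vectorised).
#' @examples
#' flux_rate(1000, 1, 0.5, 275.15, 10, 24)  # ~1.107 ug C g^-1 h^-1
#' @export
flux_rate <- function(co2_ppm, pressure_atm, volume_L, temp_K, dry_soil_g,
                      hours, R = GAS_CONSTANT) {
  if (any(!is.finite(co2_ppm)) || any(co2_ppm < 0))
    stop_domain("co2_ppm must be >= 0")
  if (any(pressure_atm <= 0) || any(volume_L <= 0) || any(temp_K <= 0))
    stop_domain("pressure, volume and temperature must be > 0")
  if (any(dry_soil_g <= 0)) stop_domain("dry_soil_g must be > 0")
  if (any(hours <= 0)) stop_domain("hours since flush must be > 0")
  co2_ppm * (pressure_atm * volume_L) / (R * temp_K) * 12 / dry_soil_g / hours
}

#' Per-interval respiration rates for one gas series
#'
#' Splits a sample's measurement series at its flush events and computes the
#' respiration rate for each flush-delimited interval from the CO2
#' accumulated at the measurement closing the interval. Measurements taken
#' between flushes (if any) give interim rates over the time since the last
#' flush; only flush-closing measurements delimit the cumulative intervals.
#'
#' @param series One element of [read_gas_log()]: a time-sorted data.frame
#'   with columns `elapsed_hours`, `co2_ppm`, `pressure_atm`, `volume_L`,
#'   `temp_K`, `flushed_flag`.
#' @param dry_soil_g Dry soil mass of the incubated sample, grams.
#' @return A data.frame with columns `interval_start_h`, `interval_end_h`,
#'   `rate` (ug CO2-C g^-1 h^-1) and `cumulative` (ug CO2-C g^-1), one row
#'   per flush-delimited interval.
#' @export
flux_series <- function(series, dry_soil_g) {
  stopifnot(is.data.frame(series), nrow(series) >= 2)
  check_scalar(dry_soil_g, "dry_soil_g", positive = TRUE)
  t <- series$elapsed_hours
  if (is.unsorted(t, strictly = TRUE))
    stop_domain("gas series times must be strictly increasing")
  flush_t <- t[series$flushed_flag]
  # interval boundaries: every flush is also a measurement; the series is
  # assumed flushed at its first timepoint (incubation start baseline)
  bounds <- sort(unique(c(t[1L], flush_t)))
  closing <- which(t %in% bounds & seq_along(t) > 1L)
  if (!length(closing))
    stop_domain("no flush-closing measurements after the first timepoint")
  start <- vapply(closing, function(i) max(bounds[bounds < t[i]]), 0)
  dt <- t[closing] - start
  rate <- flux_rate(series$co2_ppm[closing], series$pressure_atm[closing],
                    series$volume_L[closing], series$temp_K[closing],
                    dry_soil_g, dt)
  data.frame(interval_start_h = start, interval_end_h = t[closing],
             rate = rate, cumulative = cumsum(rate * dt))
}

#' Cumulative respiration from per-interval rates
#'
#' Rectangle summation of rate_i * duration_i over non-overlapping
#' flush-delimited intervals; each measured accumulation already integrates
#' its own interval, so no trapezoid correction is applied.
#'
#' @param rate Per-interval rates, ug CO2-C g^-1 h^-1.
#' @param interval_start_h,interval_end_h Interval endpoints in hours.
#' @return Total cumulative respiration, ug CO2-C g^-1 dry soil.
#' @export
cumulative_respiration <- function(rate, interval_start_h, interval_end_h) {
  stopifnot(length(rate) == length(interval_start_h),
            length(rate) == length(interval_end_h))
  if (any(interval_end_h <= interval_start_h))
    stop_domain("intervals must have positive duration")
  o <- order(interval_start_h)
  s <- interval_start_h[o]; e <- interval_end_h[o]
  if (length(s) > 1 && any(s[-1L] < e[-length(e)] - 1e-9))
    stop_domain("overlapping intervals")
  sum(rate[o] * (e - s))
}

#' Flux table for a whole gas log
#'
#' Applies [flux_series()] to every sample in a parsed gas log, looking up
#' each sample's dry soil mass from the metadata (`wet_mass`, `gwc_percent`).
#'
#' @param gas A named list of series from [read_gas_log()].
#' @param metadata Validated metadata from [read_metadata()].
#' @return A data.frame with columns `sample_id`, `interval_start_h`,
#'   `interval_end_h`, `rate`, `cumulative`.
#' @export
flux_table <- function(gas, metadata) {
  rows <- lapply(names(gas), function(id) {
    m <- metadata[metadata$sample_id == id, , drop = FALSE]
    if (nrow(m) != 1L)
      stop_domain("no unique metadata record for gas sample ", id)
    fs <- flux_series(gas[[id]], dry_mass(m$wet_mass, m$gwc_percent))
    cbind(sample_id = id, fs)
  })
  do.call(rbind, rows)
}
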