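# Density of water vapor at STP (mg per ml of vapor volume), the standard
# constant for converting a volumetric water flux to a mass rate.
WATER_VAPOR_DENSITY_STP <- 0.803

#' Oxygen consumption from incurrent and excurrent O2 fractions
#'
#' Dry-air, CO2-unscrubbed flow-through equation (water is removed upstream
#' of the O2 analyzer, CO2 is not):
#' `VO2 = FR * (FiO2 - FeO2) / (1 - FiO2 * (1 - RQ))`.
#'
#' @param FiO2,FeO2 incurrent and excurrent fractional O2 concentrations.
#' @param FR flow rate, ml min^-1 STP.
#' @param RQ respiratory quotient (CO2 produced / O2 consumed); 0.70 for a
#'   postabsorptive bird catabolizing lipid.
#' @return O2 consumption, ml min^-1.
#' @export
vo2_from_fractions <- function(FiO2, FeO2, FR, RQ = 0.70) {
  if (any(FiO2 <= 0 | FiO2 >= 1)) stop("FiO2 must be in (0, 1)", call. = FALSE)
  if (any(FeO2 > FiO2 + 1e-12)) {
    stop("FeO2 exceeds FiO2: negative O2 consumption", call. = FALSE)
  }
  stop_if_not_positive(FR, "FR")
  FR * (FiO2 - FeO2) / (1 - FiO2 * (1 - RQ))
}

#' Evaporative water loss from water-vapor pressures
#'
#' Converts incurrent/excurrent water-vapor pressures to fractional
#' concentrations (`wvp / BP`), forms the volumetric flux
#' `FR * (FeH2O - FiH2O) / (1 - FeH2O)` and multiplies by the STP vapor
#' density (0.803 mg ml^-1) and 60 min h^-1 to obtain a mass rate.
#'
#' @param wvp_in,wvp_ex incurrent and excurrent water-vapor pressures, kPa.
#' @param BP barometric pressure, kPa.
#' @param FR flow rate, ml min^-1 STP.
#' @return evaporative water loss, mg h^-1.
#' @export
ewl_from_wvp <- function(wvp_in, wvp_ex, BP, FR) {
  if (any(wvp_ex >= BP)) {
    stop("excurrent water-vapor pressure must be below barometric pressure",
         call. = FALSE)
  }
  stop_if_not_positive(FR, "FR")
  feh2o <- wvp_ex / BP
  fih2o <- wvp_in / BP
  FR * (feh2o - fih2o) / (1 - feh2o) * WATER_VAPOR_DENSITY_STP * 60
}

# Uniform Catmull-Rom spline through (t, v) anchors with one-sided
# endpoint tangents; linear extrapolation outside the anchor range.
# With two anchors this degenerates to the straight line through them.
catmull_rom <- function(t_anchor, v_anchor, t_out) {
  n <- length(t_anchor)
  if (n == 1) return(rep(v_anchor, length(t_out)))
  slopes <- diff(v_anchor) / diff(t_anchor)
  m <- numeric(n)
  m[1] <- slopes[1]
  m[n] <- slopes[n - 1]
  if (n > 2) {
    for (k in 2:(n - 1)) {
      m[k] <- (v_anchor[k + 1] - v_anchor[k - 1]) /
        (t_anchor[k + 1] - t_anchor[k - 1])
    }
  }
  out <- numeric(length(t_out))
  idx <- findInterval(t_out, t_anchor, all.inside = TRUE)
  h <- t_anchor[idx + 1] - t_anchor[idx]
  s <- (t_out - t_anchor[idx]) / h
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  out <- h00 * v_anchor[idx] + h10 * h * m[idx] +
    h01 * v_anchor[idx + 1] + h11 * h * m[idx + 1]
  # linear extrapolation with the end tangents
  lo <- t_out < t_anchor[1]
  hi <- t_out > t_anchor[n]
  out[lo] <- v_anchor[1] + m[1] * (t_out[lo] - t_anchor[1])
  out[hi] <- v_anchor[n] + m[n] * (t_out[hi] - t_anchor[n])
  out
}

baseline_anchors <- function(time_s, value, segment_id, trim = 0.1) {
  segs <- unique(segment_id)
  t_mid <- vapply(segs, function(s) mean(range(time_s[segment_id == s])),
                  numeric(1))
  v <- vapply(segs, function(s) mean(value[segment_id == s], trim = trim),
              numeric(1))
  list(t = t_mid, v = v)
}

#' Baseline drift correction of a respirometry trace
#'
#' For each analyte a Catmull-Rom spline is passed through anchor points
#' (midpoint time, central-80% trimmed mean) of every baseline segment;
#' the spline is subtracted from the whole signal and the nominal
#' incurrent value (FiO2 for oxygen, the incurrent water-vapor pressure
#' for water) is added back.  With a single baseline segment the
#' correction degenerates to a constant offset (recorded in attribute
#' `drift_method`).
#'
#' @param trace a `resp_trace` (see [generate_trace()]).
#' @return the corrected trace, with attributes `drift_corrected = TRUE`
#'   and `drift_method` (`"catmull-rom"` or `"constant"`).
#' @export
drift_correct <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  bl <- trace[trace$is_baseline, ]
  n_bl <- length(unique(bl$segment_id))
  if (n_bl < 1) stop("trace has no baseline segments", call. = FALSE)
  method <- if (n_bl >= 2) "catmull-rom" else "constant"
  fix_one <- function(col, nominal) {
    a <- baseline_anchors(bl$time_s, bl[[col]], bl$segment_id)
    spline_val <- if (n_bl >= 2) {
      catmull_rom(a$t, a$v, trace$time_s)
    } else {
      rep(a$v, nrow(trace))
    }
    trace[[col]] - spline_val + nominal
  }
  out <- trace
  out$o2_frac <- fix_one("o2_frac", attr(trace, "FiO2"))
  out$wvp_kpa <- fix_one("wvp_kpa", attr(trace, "incurrent_wvp"))
  attr(out, "drift_corrected") <- TRUE
  attr(out, "drift_method") <- method
  out
}

#' Lowest stable window of a rate time series
#'
#' Scans every contiguous window of `duration` samples.  Windows whose
#' internal SD is at most `stability_frac` of the absolute window mean are
#' "stable"; among these the one with the minimal mean is returned (ties
#' broken by earliest start).  If no window qualifies, the minimal-SD
#' window is returned and flagged.
#'
#' @param values rate series sampled at 1 s.
#' @param duration window length in samples (120 = the 2-min convention).
#' @param stability_frac stability threshold as a fraction of the window
#'   mean.
#' @return list with `start` (1-based index), `mean`, `sd` and `stable`.
#' @export
lowest_stable_window <- function(values, duration = 120,
                                 stability_frac = 0.05) {
  n <- length(values)
  if (n < duration) {
    stop("series shorter than the window duration", call. = FALSE)
  }
  cs <- cumsum(c(0, values))
  cs2 <- cumsum(c(0, values^2))
  starts <- seq_len(n - duration + 1)
  ends <- starts + duration - 1
  mu <- (cs[ends + 1] - cs[starts]) / duration
  ssq <- (cs2[ends + 1] - cs2[starts]) - duration * mu^2
  sdv <- sqrt(pmax(ssq, 0) / (duration - 1))
  stable <- sdv <= stability_frac * abs(mu)
  if (any(stable)) {
    i <- which(stable)[which.min(mu[stable])]
    list(start = starts[i], mean = mu[i], sd = sdv[i], stable = TRUE)
  } else {
    i <- which.min(sdv)
    list(start = starts[i], mean = mu[i], sd = sdv[i], stable = FALSE)
  }
}

#' Reduce a trace to a steady-state measurement
#'
#' Applies drift correction (if not already applied), discards the washout
#' transient (`equil_tau` chamber time constants from trial start),
#' converts the instantaneous gas fractions of the remaining animal
#' segments to instantaneous VO2 and EWL, locates the lowest stable
#' 2-min window on the VO2 series within each animal segment, and reports
#' the VO2 and EWL means over the selected window.
#'
#' @param trace a `resp_trace`.
#' @param equil_tau equilibration discard in chamber time constants.
#' @param duration window length, s.
#' @param stability_frac stability threshold (see
#'   [lowest_stable_window()]).
#' @param RQ respiratory quotient used for the O2 equation.
#' @return one-row data frame: `id`, `Ta_C`, `VO2_ml_min`, `EWL_mg_h`,
#'   `window_start_s`, `window_sd`, `stable`.
#' @export
reduce_trace <- function(trace, equil_tau = 5, duration = 120,
                         stability_frac = 0.05, RQ = 0.70) {
  if (!isTRUE(attr(trace, "drift_corrected"))) trace <- drift_correct(trace)
  tau <- attr(trace, "tau")
  fio2 <- attr(trace, "FiO2")
  fr <- attr(trace, "flow_rate")
  bp <- attr(trace, "barometric_pressure")
  wvp_in <- attr(trace, "incurrent_wvp")

  keep <- !trace$is_baseline & trace$time_s >= equil_tau * tau
  an <- trace[keep, ]
  if (nrow(an) < duration) {
    stop("no animal data left after the equilibration discard", call. = FALSE)
  }
  vo2 <- fr * (fio2 - an$o2_frac) / (1 - fio2 * (1 - RQ))
  feh2o <- an$wvp_kpa / bp
  ewl <- fr * (feh2o - wvp_in / bp) / (1 - feh2o) *
    WATER_VAPOR_DENSITY_STP * 60

  best <- NULL
  for (s in unique(an$segment_id)) {
    sel <- an$segment_id == s
    if (sum(sel) < duration) next
    w <- lowest_stable_window(vo2[sel], duration, stability_frac)
    w$idx <- which(sel)[w$start + seq_len(duration) - 1]
    better <- is.null(best) ||
      (w$stable && !best$stable) ||
      (w$stable == best$stable &&
         (if (w$stable) w$mean < best$mean else w$sd < best$sd))
    if (better) best <- w
  }
  if (is.null(best)) {
    stop("no animal segment long enough for the window", call. = FALSE)
  }
  data.frame(
    id = attr(trace, "id") %||% NA_character_,
    Ta_C = attr(trace, "Ta") %||% NA_real_,
    VO2_ml_min = mean(vo2[best$idx]),
    EWL_mg_h = max(mean(ewl[best$idx]), 0),
    window_start_s = an$time_s[best$idx[1]],
    window_sd = best$sd,
    stable = best$stable,
    stringsAsFactors = FALSE
  )
}
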