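#' Configuration for the synthetic metabolic-trial generator
#'
#' Defines the population, physiological and noise parameters used to
#' simulate a stepped-temperature metabolic trial on a small passerine
#' (a ~16 g tit).  The defaults encode the study conditions the package
#' is designed around: a U-shaped metabolic curve with a thermoneutral
#' zone between 17.7 and 34.5 degrees C, a basal metabolic rate of
#' 0.96 ml O2 min^-1, an evaporative water loss (EWL) inflection at
#' 31.85 degrees C, sexual size dimorphism (males larger in wing, body
#' mass and bill area; tarsi equal), and a male-only positive dependence
#' of evaporative cooling efficiency at 40 degrees C on relative tarsi
#' area.
#'
#' @param n_individuals number of birds to simulate.
#' @param sex_ratio fraction of males.
#' @param test_temps chamber temperatures (degrees C), strictly increasing.
#' @param true_Tlc,Tlc_sd population mean and between-individual SD of the
#'   lower critical temperature (degrees C).
#' @param true_Tuc,Tuc_sd mean and SD of the upper critical temperature.
#' @param true_ewl_inflection,ewl_inflection_sd mean and SD of the ambient
#'   temperature at which EWL starts to rise (degrees C).
#' @param true_BMR_mean,true_BMR_sd mean and SD of basal metabolic rate
#'   (ml O2 min^-1).
#' @param cold_slope slope of VO2 vs Ta below Tlc (ml O2 min^-1 per degree
#'   C, negative: metabolism rises as it gets colder).
#' @param hot_slope slope of VO2 vs Ta above Tuc (positive).
#' @param ewl_baseline EWL below the inflection (mg h^-1).
#' @param ewl_hot_slope slope of EWL vs Ta above the inflection
#'   (mg h^-1 per degree C).
#' @param vo2_noise_cv,ewl_noise_cv coefficient of variation of the
#'   multiplicative lognormal measurement noise on the steady-state rates.
#' @param tarsi_effect_male slope, on the log scale, of EWL at 40 degrees C
#'   on the tarsi index in males (females unaffected).  This is what makes
#'   males with relatively large legs show higher EHL/MHP at 40 degrees C.
#' @param morphometrics named list with elements `male` and `female`, each a
#'   list of `c(mean, sd)` pairs for `Mb` (g), `wing` (mm), `BL`, `BW`, `BD`
#'   (bill length/width/depth, mm), `TL`, `TW`, `TD` (tarsus
#'   length/width/depth, mm).
#' @param seed master seed; all randomness is derived from it through
#'   per-individual substreams.
#'
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_individuals = 24,
                             sex_ratio = 0.5,
                             test_temps = c(10, 15, 20, 25, 30, 35, 37, 40),
                             true_Tlc = 17.7, Tlc_sd = 1.5,
                             true_Tuc = 34.5, Tuc_sd = 0.7,
                             true_ewl_inflection = 31.85,
                             ewl_inflection_sd = 0.8,
                             true_BMR_mean = 0.96, true_BMR_sd = 0.12,
                             cold_slope = -0.11,
                             hot_slope = 0.04,
                             ewl_baseline = 100,
                             ewl_hot_slope = 47.65,
                             vo2_noise_cv = 0.05,
                             ewl_noise_cv = 0.05,
                             tarsi_effect_male = 4.0,
                             morphometrics = default_morphometrics(),
                             seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, sex_ratio = sex_ratio,
    test_temps = test_temps,
    true_Tlc = true_Tlc, Tlc_sd = Tlc_sd,
    true_Tuc = true_Tuc, Tuc_sd = Tuc_sd,
    true_ewl_inflection = true_ewl_inflection,
    ewl_inflection_sd = ewl_inflection_sd,
    true_BMR_mean = true_BMR_mean, true_BMR_sd = true_BMR_sd,
    cold_slope = cold_slope, hot_slope = hot_slope,
    ewl_baseline = ewl_baseline, ewl_hot_slope = ewl_hot_slope,
    vo2_noise_cv = vo2_noise_cv, ewl_noise_cv = ewl_noise_cv,
    tarsi_effect_male = tarsi_effect_male,
    morphometrics = morphometrics, seed = seed
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' Default sex-specific morphometric distributions
#'
#' Literature-plausible Great tit values; each entry is `c(mean, sd)`.
#' Males are larger in body mass, wing and bill; tarsus distributions are
#' identical between the sexes.
#'
#' @return named list with `male` and `female` components.
#' @export
default_morphometrics <- function() {
  list(
    male = list(Mb = c(17.5, 0.9), wing = c(76, 1.5),
                BL = c(13.2, 0.5), BW = c(4.1, 0.25), BD = c(4.7, 0.25),
                TL = c(19.8, 0.7), TW = c(2.2, 0.12), TD = c(1.8, 0.12)),
    female = list(Mb = c(16.5, 0.9), wing = c(73, 1.5),
                  BL = c(12.8, 0.5), BW = c(4.0, 0.25), BD = c(4.5, 0.25),
                  TL = c(19.8, 0.7), TW = c(2.2, 0.12), TD = c(1.8, 0.12))
  )
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_individuals) || cfg$n_individuals < 1) {
    stop("n_individuals must be a positive count", call. = FALSE)
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    stop("sex_ratio must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(cfg$test_temps) <= 0)) {
    stop("test_temps must be strictly increasing", call. = FALSE)
  }
  if (cfg$true_Tlc >= cfg$true_Tuc) {
    stop("true_Tlc must be below true_Tuc", call. = FALSE)
  }
  if (cfg$cold_slope >= 0) stop("cold_slope must be negative", call. = FALSE)
  if (cfg$hot_slope <= 0) stop("hot_slope must be positive", call. = FALSE)
  sds <- c(cfg$Tlc_sd, cfg$Tuc_sd, cfg$ewl_inflection_sd, cfg$true_BMR_sd,
           cfg$vo2_noise_cv, cfg$ewl_noise_cv,
           unlist(lapply(cfg$morphometrics, function(s) {
             vapply(s, `[`, numeric(1), 2)
           })))
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Deterministic Bresenham-style sex assignment: stable under adding
# individuals, and exact counts (e.g. 24 at ratio 0.5 -> 12 M, 12 F).
assign_sexes <- function(n, ratio) {
  i <- seq_len(n)
  ifelse(floor(i * ratio) - floor((i - 1) * ratio) == 1, "M", "F")
}

rnorm_trunc_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic population of individuals
#'
#' Draws sex-specific morphometrics and latent physiological truths (Tlc,
#' Tuc, BMR, EWL inflection) for each bird, computes bill and tarsi surface
#' areas and the sex-stratified relative-size indices.  Each individual's
#' latent Tlc/Tuc pair is redrawn until Tlc < Tuc - 5 so the plateau stays
#' identifiable.
#'
#' @param config a [generator_config()].
#' @return a data frame (one row per bird) with columns `id`, `sex`, the
#'   eight caliper/balance measurements, `order` (exposure order of the
#'   cold protocol, alternating increasing/decreasing), latent truths
#'   `Tlc`, `Tuc`, `BMR`, `ewl_inflection`, derived `bill_area`,
#'   `tarsi_area` (mm^2), `body_area` (cm^2) and the residual indices
#'   `bill_index`, `tarsi_index`.  The configuration is attached as
#'   attribute `config`.
#' @export
generate_population <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- as.integer(config$n_individuals)
  sexes <- assign_sexes(n, config$sex_ratio)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- config$morphometrics[[if (sexes[i] == "M") "male" else "female"]]
    rows[[i]] <- withr::with_seed(substream_seed(config$seed, i, 1L), {
      draw <- function(p) rnorm_trunc_pos(1, p[1], p[2])
      repeat {
        tlc <- rnorm(1, config$true_Tlc, config$Tlc_sd)
        tuc <- rnorm(1, config$true_Tuc, config$Tuc_sd)
        if (tlc < tuc - 5) break
      }
      data.frame(
        id = sprintf("bird%02d", i), sex = sexes[i],
        Mb = draw(m$Mb), wing = draw(m$wing),
        BL = draw(m$BL), BW = draw(m$BW), BD = draw(m$BD),
        TL = draw(m$TL), TW = draw(m$TW), TD = draw(m$TD),
        order = if (i %% 2 == 1) "increasing" else "decreasing",
        Tlc = tlc, Tuc = tuc,
        BMR = rnorm_trunc_pos(1, config$true_BMR_mean, config$true_BMR_sd),
        ewl_inflection = rnorm(1, config$true_ewl_inflection,
                               config$ewl_inflection_sd),
        stringsAsFactors = FALSE
      )
    })
  }
  pop <- do.call(rbind, rows)
  pop$bill_area <- bill_surface_area(pop$BW, pop$BD, pop$BL)
  pop$tarsi_area <- tarsi_surface_area(pop$TW, pop$TD, pop$TL)
  pop$body_area <- whole_body_surface_area(pop$Mb)
  if (all(table(pop$sex) >= 3) && length(unique(pop$sex)) == 2) {
    pop$bill_index <- size_index(pop$bill_area, pop$wing, pop$sex)
    pop$tarsi_index <- size_index(pop$tarsi_area, pop$wing, pop$sex)
  } else {
    pop$bill_index <- pop$tarsi_index <- NA_real_
  }
  attr(pop, "config") <- config
  pop
}

# Lognormal multiplicative noise with unit mean and coefficient of
# variation cv (physiological rates are positive and right-skewed).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Steady-state thermal profile for one individual
#'
#' The noise-free rates are piecewise linear in ambient temperature:
#' `VO2 = BMR + cold_slope * min(Ta - Tlc, 0) + hot_slope * max(Ta - Tuc, 0)`
#' (a U-shape with a flat thermoneutral plateau) and
#' `EWL = ewl_baseline + ewl_hot_slope * max(Ta - inflection, 0)`
#' (flat then rising).  Both are multiplied by unit-mean lognormal noise
#' with the configured CV.  For males, EWL at 40 degrees C is additionally
#' scaled by `exp(tarsi_effect_male * tarsi_index)`, producing the
#' male-only association between cooling efficiency and relative leg area.
#'
#' @param individual one row of a [generate_population()] data frame.
#' @param temps test temperatures (degrees C), within \[5, 45\].
#' @param config the [generator_config()] used to create the population.
#' @return data frame with columns `id`, `sex`, `Ta`, `VO2` (ml O2 min^-1)
#'   and `EWL` (mg h^-1).
#' @export
generate_thermal_profile <- function(individual, temps, config) {
  if (length(temps) == 0) stop("temps must be non-empty", call. = FALSE)
  if (any(temps < 5 | temps > 45)) {
    stop("test temperatures must lie within [5, 45] degrees C", call. = FALSE)
  }
  vo2_mu <- individual$BMR +
    config$cold_slope * pmin(temps - individual$Tlc, 0) +
    config$hot_slope * pmax(temps - individual$Tuc, 0)
  ewl_mu <- config$ewl_baseline +
    config$ewl_hot_slope * pmax(temps - individual$ewl_inflection, 0)
  if (identical(individual$sex, "M") && !is.na(individual$tarsi_index)) {
    at40 <- abs(temps - 40) < 1e-8
    ewl_mu[at40] <- ewl_mu[at40] *
      exp(config$tarsi_effect_male * individual$tarsi_index)
  }
  i <- as.integer(sub("bird", "", individual$id))
  noise <- withr::with_seed(substream_seed(config$seed, i, 2L), {
    list(vo2 = lognormal_noise(length(temps), config$vo2_noise_cv),
         ewl = lognormal_noise(length(temps), config$ewl_noise_cv))
  })
  data.frame(id = individual$id, sex = individual$sex, Ta = temps,
             VO2 = vo2_mu * noise$vo2, EWL = ewl_mu * noise$ewl,
             stringsAsFactors = FALSE)
}

#' Thermal profiles for a whole population
#'
#' @param population a [generate_population()] data frame.
#' @param temps test temperatures; defaults to the config's protocol.
#' @param config generator configuration; defaults to the one attached to
#'   `population`.
#' @return long data frame of per-individual profiles.
#' @export
generate_profiles <- function(population, temps = NULL, config = NULL) {
  config <- config %||% attr(population, "config")
  temps <- temps %||% config$test_temps
  out <- lapply(seq_len(nrow(population)), function(i) {
    generate_thermal_profile(population[i, ], temps, config)
  })
  do.call(rbind, out)
}

#' Configuration of the simulated respirometry plumbing
#'
#' Geometry and analyzer characteristics of the simulated flow-through
#' system: a 3.9 L chamber, 360 s multiplexer dwell per channel, 300 s
#' baselines taken at the start and after every two chamber measurements,
#' dry incurrent air and a fixed incurrent O2 fraction.
#'
#' @param flow_rate mass-flow rate, ml min^-1 STP (1000 for the cold
#'   protocol, 3000 for the hot one).
#' @param sample_interval analyzer sampling interval, s.
#' @param channel_dwell dwell per animal segment, s.
#' @param baseline_duration length of each baseline segment, s.
#' @param baseline_every_k_chambers baseline frequency (after every k
#'   animal segments).
#' @param n_cycles number of (k animal segments + baseline) cycles after
#'   the opening baseline.
#' @param chamber_volume effective chamber volume, L.
#' @param FiO2 incurrent O2 fraction.
#' @param incurrent_wvp incurrent water-vapor pressure, kPa (< 1: dried air).
#' @param barometric_pressure kPa.
#' @param drift_rate_O2 linear analyzer drift, O2 fraction per hour.
#' @param analyzer_noise_sd_O2 white noise SD on the O2 fraction.
#' @param analyzer_noise_sd_H2O white noise SD on water-vapor pressure, kPa.
#' @return object of class `trace_config`.
#' @export
trace_config <- function(flow_rate = 1000,
                         sample_interval = 1,
                         channel_dwell = 360,
                         baseline_duration = 300,
                         baseline_every_k_chambers = 2,
                         n_cycles = 4,
                         chamber_volume = 3.9,
                         FiO2 = 0.2095,
                         incurrent_wvp = 0.2,
                         barometric_pressure = 101,
                         drift_rate_O2 = 0,
                         analyzer_noise_sd_O2 = 0,
                         analyzer_noise_sd_H2O = 0) {
  if (flow_rate <= 0) stop("flow_rate must be positive", call. = FALSE)
  if (incurrent_wvp >= 1) {
    stop("incurrent air must be dry (incurrent_wvp < 1 kPa)", call. = FALSE)
  }
  if (channel_dwell < 120) {
    stop("channel_dwell must allow at least a 120 s window", call. = FALSE)
  }
  structure(list(
    flow_rate = flow_rate, sample_interval = sample_interval,
    channel_dwell = channel_dwell, baseline_duration = baseline_duration,
    baseline_every_k_chambers = baseline_every_k_chambers,
    n_cycles = n_cycles, chamber_volume = chamber_volume,
    FiO2 = FiO2, incurrent_wvp = incurrent_wvp,
    barometric_pressure = barometric_pressure,
    drift_rate_O2 = drift_rate_O2,
    analyzer_noise_sd_O2 = analyzer_noise_sd_O2,
    analyzer_noise_sd_H2O = analyzer_noise_sd_H2O
  ), class = "trace_config")
}

# Invert the gas-exchange equations: excurrent steady-state O2 fraction and
# water-vapor pressure implied by given steady rates.
excurrent_steady_state <- function(steady_vo2, steady_ewl, tconfig, rq = 0.70) {
  feo2 <- tconfig$FiO2 -
    steady_vo2 * (1 - tconfig$FiO2 * (1 - rq)) / tconfig$flow_rate
  flux <- steady_ewl / (WATER_VAPOR_DENSITY_STP * 60)  # ml min^-1
  fih2o <- tconfig$incurrent_wvp / tconfig$barometric_pressure
  feh2o <- (flux + tconfig$flow_rate * fih2o) / (tconfig$flow_rate + flux)
  list(FeO2 = feo2, wvp_ex = feh2o * tconfig$barometric_pressure)
}

#' Simulate a raw respirometry trace
#'
#' Forward model of the analyzer chain: the trace alternates baseline and
#' animal segments (opening baseline, then a baseline after every
#' `baseline_every_k_chambers` animal segments).  During animal segments
#' the excurrent gas approaches the steady state implied by inverting the
#' gas-exchange equations, with single-compartment exponential washout
#' (time constant = chamber volume / flow rate, clocked from trial start
#' since the bird occupies the chamber continuously), linear analyzer
#' drift and additive white noise.
#'
#' @param individual one population row (used for the id only).
#' @param Ta chamber temperature, degrees C.
#' @param steady_vo2 steady-state O2 consumption, ml min^-1 (> 0).
#' @param steady_ewl steady-state evaporative water loss, mg h^-1 (>= 0).
#' @param tconfig a [trace_config()].
#' @param seed seed for the analyzer noise.
#' @return a `resp_trace`: data frame with columns `time_s`, `o2_frac`,
#'   `wvp_kpa`, `segment_id`, `is_baseline` and attributes `flow_rate`,
#'   `barometric_pressure`, `Ta`, `FiO2`, `incurrent_wvp`, `tau` (s) and
#'   `washout_limited` (TRUE when fewer than 120 s of animal data remain
#'   after five time constants).
#' @export
generate_trace <- function(individual, Ta, steady_vo2, steady_ewl,
                           tconfig = trace_config(), seed = 1L) {
  if (steady_vo2 <= 0) stop("steady_vo2 must be positive", call. = FALSE)
  if (steady_ewl < 0) stop("steady_ewl must be non-negative", call. = FALSE)
  ss <- excurrent_steady_state(steady_vo2, steady_ewl, tconfig)
  tau <- tconfig$chamber_volume * 1000 / tconfig$flow_rate * 60  # seconds

  k <- tconfig$baseline_every_k_chambers
  seg_is_baseline <- c(TRUE, rep(c(rep(FALSE, k), TRUE), tconfig$n_cycles))
  seg_len <- ifelse(seg_is_baseline, tconfig$baseline_duration,
                    tconfig$channel_dwell)
  segment_id <- rep(seq_along(seg_len), seg_len / tconfig$sample_interval)
  is_baseline <- rep(seg_is_baseline, seg_len / tconfig$sample_interval)
  time_s <- seq(0, by = tconfig$sample_interval,
                length.out = length(segment_id))

  relax <- exp(-time_s / tau)
  o2 <- ifelse(is_baseline, tconfig$FiO2,
               ss$FeO2 + (tconfig$FiO2 - ss$FeO2) * relax)
  wvp <- ifelse(is_baseline, tconfig$incurrent_wvp,
                ss$wvp_ex + (tconfig$incurrent_wvp - ss$wvp_ex) * relax)
  o2 <- o2 + tconfig$drift_rate_O2 * time_s / 3600
  if (tconfig$analyzer_noise_sd_O2 > 0 || tconfig$analyzer_noise_sd_H2O > 0) {
    noise <- withr::with_seed(seed, list(
      o2 = rnorm(length(time_s), 0, tconfig$analyzer_noise_sd_O2),
      h2o = rnorm(length(time_s), 0, tconfig$analyzer_noise_sd_H2O)
    ))
    o2 <- o2 + noise$o2
    wvp <- pmax(wvp + noise$h2o, 0)
  }

  trace <- data.frame(time_s = time_s, o2_frac = o2, wvp_kpa = wvp,
                      segment_id = segment_id, is_baseline = is_baseline)
  animal_after_washout <- sum(!is_baseline & time_s >= 5 * tau) *
    tconfig$sample_interval
  structure(trace,
            id = individual$id, Ta = Ta,
            flow_rate = tconfig$flow_rate,
            barometric_pressure = tconfig$barometric_pressure,
            FiO2 = tconfig$FiO2, incurrent_wvp = tconfig$incurrent_wvp,
            tau = tau,
            washout_limited = animal_after_washout < 120,
            class = c("resp_trace", "data.frame"))
}

#' Write generator outputs as delimited text
#'
#' `write_population()` and `write_profiles()` write plain CSV;
#' `write_trace_csv()` stores the trace columns after `#`-prefixed
#' key=value header lines carrying the trace metadata, and
#' `read_trace_csv()` restores the `resp_trace` object.
#'
#' @param x object to write.
#' @param path file path.
#' @name synthetic_io
#' @export
write_population <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
write_profiles <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
write_trace_csv <- function(x, path) {
  meta <- c(id = attr(x, "id") %||% "", Ta = attr(x, "Ta"),
            flow_rate = attr(x, "flow_rate"),
            barometric_pressure = attr(x, "barometric_pressure"),
            FiO2 = attr(x, "FiO2"), incurrent_wvp = attr(x, "incurrent_wvp"),
            tau = attr(x, "tau"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- strsplit(sub("^# ", "", lines[hdr]), "=", fixed = TRUE)
  keys <- vapply(meta, `[`, character(1), 1)
  vals <- vapply(meta, `[`, character(1), 2)
  df <- read.csv(text = paste(lines[-hdr], collapse = "\n"))
  num <- function(k) as.numeric(vals[keys == k])
  structure(df, id = vals[keys == "id"], Ta = num("Ta"),
            flow_rate = num("flow_rate"),
            barometric_pressure = num("barometric_pressure"),
            FiO2 = num("FiO2"), incurrent_wvp = num("incurrent_wvp"),
            tau = num("tau"), washout_limited = NA,
            class = c("resp_trace", "data.frame"))
}

#' @rdname synthetic_io
#' @export
write_config <- function(x, path) {
  flat <- unlist(x)
  writeLines(sprintf("%s=%s", names(flat), as.character(flat)), path)
  invisible(path)
}
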