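#' Configuration of an end-to-end pipeline run
#'
#' @param generator a [generator_config()].
#' @param trace_cold,trace_hot [trace_config()]s for the cold (Ta <= 30,
#'   1000 ml min^-1) and hot (35/37/40, 3000 ml min^-1) protocols.
#' @param use_traces simulate and reduce raw analyzer traces (TRUE) or
#'   take the generator's steady-state profiles directly (faster).
#' @param grid_step breakpoint grid resolution, degrees C.
#' @param vo2_bounds,ewl_bounds breakpoint search bounds.
#' @param stability_frac stability threshold of the window extraction.
#' @param delta_max dAICc cut for reporting and averaging.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       trace_cold = trace_config(flow_rate = 1000),
                       trace_hot = trace_config(flow_rate = 3000,
                                                n_cycles = 2),
                       use_traces = FALSE,
                       grid_step = 0.05,
                       vo2_bounds = list(c(12, 28), c(28, 38)),
                       ewl_bounds = c(28, 38),
                       stability_frac = 0.05,
                       delta_max = 2) {
  structure(list(generator = generator, trace_cold = trace_cold,
                 trace_hot = trace_hot, use_traces = use_traces,
                 grid_step = grid_step, vo2_bounds = vo2_bounds,
                 ewl_bounds = ewl_bounds, stability_frac = stability_frac,
                 delta_max = delta_max),
            class = "run_config")
}

config_hash <- function(config) {
  flat <- paste(names(unlist(config)), unlist(config), sep = "=",
                collapse = ";")
  # 32-bit polynomial rolling hash over the flattened key=value string
  h <- 0
  for (b in utf8ToInt(flat)) h <- (h * 31 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

steady_states_from_traces <- function(population, profiles, config) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    tc <- if (pr$Ta <= 30) config$trace_cold else config$trace_hot
    ind <- population[population$id == pr$id, ]
    j <- as.integer(sub("bird", "", pr$id))
    tr <- generate_trace(ind, pr$Ta, pr$VO2, pr$EWL, tc,
                         seed = substream_seed(config$generator$seed, j,
                                               100L + round(pr$Ta)))
    reduce_trace(tr, stability_frac = config$stability_frac)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> (optionally) trace-process -> breakpoint fits ->
#' morphometric indices -> energetics -> model selection, producing the
#' tables a stepped-temperature metabolic study reports: per-individual
#' and population TNZ estimates, an energy budget, AICc model-selection
#' tables and model-averaged coefficients.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV along with a `run_metadata.txt` carrying the seed and a hash
#'   of the configuration.
#' @param responses which responses to run model selection on.
#' @return list with `population`, `profiles`, `steady_states`,
#'   `individual_estimates`, `population_estimates`, `energy_budget`,
#'   `order_effect`, `vif`, `model_tables`, `averaged_coefficients`,
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         responses = c("Tlc", "Tuc", "breadth", "ewl_infl",
                                       "ratio35", "ratio37", "ratio40")) {
  gen <- config$generator
  population <- generate_population(gen)
  profiles <- generate_profiles(population)

  steady <- if (config$use_traces) {
    st <- steady_states_from_traces(population, profiles, config)
    data.frame(id = st$id, Ta = st$Ta_C, VO2 = st$VO2_ml_min,
               EWL = st$EWL_mg_h, stringsAsFactors = FALSE)
  } else {
    profiles[, c("id", "Ta", "VO2", "EWL")]
  }

  est <- fit_population(steady, config$vo2_bounds, config$ewl_bounds,
                        config$grid_step)
  pop_est <- population_summary(est)

  budget <- energy_budget(steady)
  ratios <- stats::reshape(
    budget[, c("id", "Ta", "ratio")], direction = "wide",
    idvar = "id", timevar = "Ta"
  )
  names(ratios) <- sub("ratio.", "ratio", names(ratios), fixed = TRUE)

  # drop the generator's latent truths before merging in the fitted
  # estimates (same column names, and the analysis must not see truths)
  observed <- population[, setdiff(names(population),
                                   c("Tlc", "Tuc", "BMR",
                                     "ewl_inflection"))]
  frame <- merge(observed, est, by = "id")
  frame <- merge(frame, ratios, by = "id", all.x = TRUE)
  frame$sex <- factor(frame$sex, levels = c("F", "M"))

  # order-of-exposure check on mass-independent rates over the cold profile
  cold <- steady[steady$Ta <= 30, ]
  mi <- do.call(rbind, lapply(split(cold, cold$Ta), function(d) {
    d <- merge(d, population[, c("id", "Mb", "order")], by = "id")
    d$mi_vo2 <- mass_independent(d$VO2, d$Mb)
    d$mi_ewl <- mass_independent(d$EWL, d$Mb)
    d
  }))
  order_effect <- list(
    vo2 = t_test2(mi$mi_vo2[mi$order == "increasing"],
                  mi$mi_vo2[mi$order == "decreasing"]),
    ewl = t_test2(mi$mi_ewl[mi$order == "increasing"],
                  mi$mi_ewl[mi$order == "decreasing"])
  )

  frame$sex01 <- as.integer(frame$sex == "M")
  vifs <- vif(frame, c("sex01", "bill_index", "tarsi_index", "Mb"))

  base_terms <- c("sex", "bill_index", "tarsi_index",
                  "bill_index:sex", "tarsi_index:sex")
  model_tables <- list()
  averaged <- list()
  for (resp in responses) {
    if (!resp %in% names(frame) || all(is.na(frame[[resp]]))) next
    terms <- if (grepl("^ratio", resp)) c(base_terms, "Mb") else base_terms
    tab <- model_selection(frame[!is.na(frame[[resp]]), ], resp, terms)
    model_tables[[resp]] <- top_models(tab, config$delta_max)
    attr(model_tables[[resp]], "full") <- tab
    averaged[[resp]] <- model_average(tab, config$delta_max)
  }

  result <- list(population = population, profiles = profiles,
                 steady_states = steady, individual_estimates = est,
                 population_estimates = pop_est, energy_budget = budget,
                 order_effect = order_effect, vif = vifs,
                 model_tables = model_tables,
                 averaged_coefficients = averaged,
                 seed = gen$seed, config_hash = config_hash(config))

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.csv(result$population, p("individuals.csv"), row.names = FALSE)
  write.csv(result$steady_states, p("steady_states.csv"), row.names = FALSE)
  write.csv(result$individual_estimates, p("tnz_individual.csv"),
            row.names = FALSE)
  write.csv(result$population_estimates, p("tnz_population.csv"),
            row.names = FALSE)
  write.csv(result$energy_budget, p("energy_budget.csv"), row.names = FALSE)
  for (resp in names(result$model_tables)) {
    write.csv(as.data.frame(result$model_tables[[resp]]),
              p(sprintf("model_table_%s.csv", resp)), row.names = FALSE)
    write.csv(result$averaged_coefficients[[resp]],
              p(sprintf("averaged_coefficients_%s.csv", resp)),
              row.names = FALSE)
  }
  writeLines(c(sprintf("seed=%s", result$seed),
               sprintf("config_hash=%s", result$config_hash)),
             p("run_metadata.txt"))
  invisible(out_dir)
}

#' Diagnostic figures for a pipeline run
#'
#' `plot_vo2_curve()` shows the U-shaped VO2 vs Ta scatter with the mean
#' fitted breakpoints; `plot_ewl_curve()` the flat-then-rising EWL curve.
#'
#' @param result a [run_pipeline()] result.
#' @return a ggplot object.
#' @name pipeline_figures
#' @export
plot_vo2_curve <- function(result) {
  pe <- result$population_estimates
  tlc <- pe$mean[pe$quantity == "Tlc"]
  tuc <- pe$mean[pe$quantity == "Tuc"]
  ggplot2::ggplot(result$steady_states,
                  ggplot2::aes(x = Ta, y = VO2)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(tlc, tuc), linetype = "dashed") +
    ggplot2::labs(x = expression(T[a] ~ (degree * C)),
                  y = expression(VO[2] ~ (ml ~ O[2] ~ min^-1)),
                  title = "Metabolic rate and the thermoneutral zone")
}

#' @rdname pipeline_figures
#' @export
plot_ewl_curve <- function(result) {
  pe <- result$population_estimates
  infl <- pe$mean[pe$quantity == "ewl_infl"]
  ggplot2::ggplot(result$steady_states,
                  ggplot2::aes(x = Ta, y = EWL)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = infl, linetype = "dashed") +
    ggplot2::labs(x = expression(T[a] ~ (degree * C)),
                  y = expression(EWL ~ (mg ~ h^-1)),
                  title = "Evaporative water loss inflection")
}
utils::globalVariables(c("Ta", "VO2", "EWL"))
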