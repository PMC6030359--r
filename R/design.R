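#' Experimental design for a stepped-temperature chamber run
#'
#' Describes one chamber schedule: how many plants, how many 3-day
#' temperature steps, the starting day temperature and per-step increment,
#' the photoperiod, and (for control groups) whether the temperature is held
#' constant instead of ramped. Night temperature is always 6 degC below the
#' day setpoint, so the 24-h mean follows from the day setpoint and the dark
#' hours alone.
#'
#' @param n_plants number of plants followed through the schedule.
#' @param n_steps number of temperature steps (each lasting `step_days`).
#' @param start_day_temp day-time setpoint (degC) of the first step.
#' @param increment day-temperature increase per step (degC); must be > 0
#'   for experimental (ramped) schedules.
#' @param light_hours light phase length (h), strictly between 0 and 24.
#' @param flowers_sampled flowers sampled per plant per step (default 3).
#' @param control_mode `"none"` for an experimental ramp,
#'   `"constant_temp"` for a chamber control held at `control_temp`,
#'   `"ambient_series"` for an outdoor control following a supplied series.
#' @param control_temp constant day setpoint (degC) when
#'   `control_mode = "constant_temp"`.
#' @param step_days days per temperature step (default 3; sampling happens on
#'   the last day of each step).
#' @param day_temps optional explicit vector of day setpoints, one per step,
#'   overriding the arithmetic ramp (used for schedules with an irregular
#'   first increment, or for `"ambient_series"` controls).
#'
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(n_plants,
                              n_steps,
                              start_day_temp,
                              increment,
                              light_hours,
                              flowers_sampled = 3L,
                              control_mode = c("none", "constant_temp",
                                               "ambient_series"),
                              control_temp = NULL,
                              step_days = 3L,
                              day_temps = NULL) {
  control_mode <- match.arg(control_mode)
  stopifnot(is.numeric(n_plants), length(n_plants) == 1L, n_plants >= 1)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("invalid design: n_steps must be a positive integer", call. = FALSE)
  if (light_hours <= 0 || light_hours >= 24)
    stop("invalid design: light_hours must lie strictly in (0, 24)",
         call. = FALSE)
  if (flowers_sampled < 1)
    stop("invalid design: flowers_sampled must be >= 1", call. = FALSE)
  if (control_mode == "none" && is.null(day_temps) && increment <= 0)
    stop("invalid design: increment must be > 0 for experimental schedules",
         call. = FALSE)
  if (control_mode == "constant_temp" && is.null(control_temp))
    stop("invalid design: control_temp required for constant_temp mode",
         call. = FALSE)
  if (!is.null(day_temps) && length(day_temps) != n_steps)
    stop("invalid design: day_temps must have one entry per step",
         call. = FALSE)
  structure(
    list(n_plants = as.integer(n_plants),
         n_steps = as.integer(n_steps),
         start_day_temp = start_day_temp,
         increment = increment,
         light_hours = light_hours,
         flowers_sampled = as.integer(flowers_sampled),
         control_mode = control_mode,
         control_temp = control_temp,
         step_days = as.integer(step_days),
         day_temps = day_temps),
    class = "experiment_design")
}

#' 24-h mean chamber temperature
#'
#' Night setpoints sit 6 degC below the day setpoint, so the time-weighted
#' 24-h mean is `day_temp - 6 * dark_hours / 24`.
#'
#' @param day_temp day setpoint (degC).
#' @param dark_hours dark phase length (h), strictly in (0, 24).
#' @return 24-h mean temperature (degC).
#' @examples
#' compute_24h_mean(20, 10) # 17.5
#' compute_24h_mean(7, 14)  # 3.5
#' @export
compute_24h_mean <- function(day_temp, dark_hours) {
  if (any(dark_hours <= 0) || any(dark_hours >= 24))
    stop("invalid design: dark_hours must lie strictly in (0, 24)",
         call. = FALSE)
  day_temp - 6 * dark_hours / 24
}

#' Temperature schedule implied by a design
#'
#' Expands a design into its per-step day setpoints and 24-h means. Ramped
#' schedules form an arithmetic progression from `start_day_temp`; constant
#' controls repeat `control_temp`; explicit `day_temps` override both.
#'
#' @param design an [experiment_design()].
#' @return a data.frame with columns `step`, `time_index` (days since the
#'   start, sampling day of each step), `day_temp`, `mean24_temp`.
#' @export
build_temperature_schedule <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  k <- seq_len(design$n_steps)
  day_temp <- if (!is.null(design$day_temps)) {
    design$day_temps
  } else if (design$control_mode == "constant_temp") {
    rep(design$control_temp, design$n_steps)
  } else {
    design$start_day_temp + (k - 1L) * design$increment
  }
  dark <- 24 - design$light_hours
  data.frame(step = k,
             time_index = k * design$step_days,
             day_temp = day_temp,
             mean24_temp = compute_24h_mean(day_temp, dark))
}

#' Species profile: the true generative curves of the simulator
#'
#' Parameterises one species' "true" temperature responses on the model
#' scale, i.e. the scale on which the analysis models are linear: natural
#' log for nectar volume (ul), sugar traits and flower counts, logit for
#' sugar concentration (as a proportion). Each trait response is the concave
#' parabola
#' \deqn{f(T) = amplitude - ((T - true\_opt) / breadth)^2}
#' so `true_opt` is the thermal optimum in degC, `amplitude` the peak value
#' on the model scale, and `breadth` the temperature offset (degC) at which
#' the response has dropped by one model-scale unit. `breadth = Inf` gives a
#' flat (no-temperature-effect) response.
#'
#' @param species_name species label.
#' @param flowering_month month (1-12) of peak flowering, used for climate
#'   comparisons.
#' @param volume,concentration,flowers lists with elements `amplitude`,
#'   `true_opt`, `breadth` describing the trait curves (concentration
#'   amplitude is on the logit scale of the proportion).
#' @param plant_sd between-plant random-intercept SD on the model scale.
#' @param resid_sd residual SD on the model scale (volume and
#'   concentration measurements).
#' @param nb_size negative-binomial size (dispersion) of per-plant daily
#'   flower counts; larger is closer to Poisson, and `Inf` is the
#'   deterministic limit (count equals its mean exactly, used by
#'   noiseless-closure tests).
#' @param zero_inflation_base probability that a sampled flower is empty at
#'   the thermal optimum.
#' @param zero_inflation_heat_slope per-degC logit slope of the empty-flower
#'   probability in the absolute distance from `true_opt` (positive values
#'   give more empties at both temperature extremes).
#' @param drift_linear,drift_quad shared time-drift coefficients (per day,
#'   per day squared) added on the model scale in both the experimental and
#'   control group.
#' @return an object of class `species_profile`.
#' @export
species_profile <- function(species_name,
                            flowering_month,
                            volume = list(amplitude = log(2), true_opt = 20,
                                          breadth = 8),
                            concentration = list(amplitude = stats::qlogis(0.35),
                                                 true_opt = 20, breadth = 14),
                            flowers = list(amplitude = log(30), true_opt = 20,
                                           breadth = 10),
                            plant_sd = 0.3,
                            resid_sd = 0.4,
                            nb_size = 10,
                            zero_inflation_base = 0,
                            zero_inflation_heat_slope = 0,
                            drift_linear = 0,
                            drift_quad = 0) {
  traits <- list(volume = volume, concentration = concentration,
                 flowers = flowers)
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (!all(c("amplitude", "true_opt", "breadth") %in% names(tr)))
      stop("invalid profile: trait '", nm,
           "' needs amplitude, true_opt, breadth", call. = FALSE)
    if (tr$breadth <= 0)
      stop("invalid profile: breadth must be > 0 (use Inf for no effect)",
           call. = FALSE)
  }
  if (plant_sd < 0 || resid_sd < 0)
    stop("invalid profile: plant_sd and resid_sd must be >= 0", call. = FALSE)
  if (zero_inflation_base < 0 || zero_inflation_base >= 1)
    stop("invalid profile: zero_inflation_base must be in [0, 1)",
         call. = FALSE)
  if (nb_size <= 0)
    stop("invalid profile: nb_size must be > 0", call. = FALSE)
  structure(
    list(species_name = species_name,
         flowering_month = as.integer(flowering_month),
         volume = volume, concentration = concentration, flowers = flowers,
         plant_sd = plant_sd, resid_sd = resid_sd, nb_size = nb_size,
         zero_inflation_base = zero_inflation_base,
         zero_inflation_heat_slope = zero_inflation_heat_slope,
         drift_linear = drift_linear, drift_quad = drift_quad),
    class = "species_profile")
}

# true model-scale response of one trait at temperature T and day t
profile_true_value <- function(profile, trait, temp, time_index = 0) {
  tr <- profile[[trait]]
  quad <- if (is.infinite(tr$breadth)) 0 else ((temp - tr$true_opt) / tr$breadth)^2
  tr$amplitude - quad +
    profile$drift_linear * time_index + profile$drift_quad * time_index^2
}

# empty-flower probability at temperature T
profile_empty_prob <- function(profile, temp) {
  if (profile$zero_inflation_base <= 0) return(rep(0, length(temp)))
  stats::plogis(stats::qlogis(profile$zero_inflation_base) +
                  profile$zero_inflation_heat_slope *
                    abs(temp - profile$volume$true_opt))
}

#' Built-in chamber designs of the six study species
#'
#' The stepped-temperature schedules used for the six Mediterranean species
#' (day setpoints, increments, steps, photoperiod, plant numbers). The
#' rosemary run started with an irregular 3 degC first increment, encoded
#' via an explicit setpoint vector. The aloe-like asphodel control ran in
#' the chamber at a constant 15 degC day setpoint.
#'
#' @return named list of [experiment_design()] objects, one per species,
#'   with the asphodel chamber control as `"A_ramosus_control"`.
#' @export
species_designs <- function() {
  list(
    R_officinalis = experiment_design(
      n_plants = 19, n_steps = 8, start_day_temp = 7, increment = 4,
      light_hours = 10, day_temps = c(7, 10, 14, 18, 22, 26, 30, 34)),
    A_ramosus = experiment_design(
      n_plants = 12, n_steps = 6, start_day_temp = 12, increment = 2,
      light_hours = 11),
    L_stoechas = experiment_design(
      n_plants = 20, n_steps = 7, start_day_temp = 16, increment = 2,
      light_hours = 11),
    E_plantagineum = experiment_design(
      n_plants = 15, n_steps = 7, start_day_temp = 14.5, increment = 4,
      light_hours = 14),
    B_acetabulosa = experiment_design(
      n_plants = 15, n_steps = 8, start_day_temp = 20, increment = 3,
      light_hours = 14),
    T_divaricatum = experiment_design(
      n_plants = 15, n_steps = 8, start_day_temp = 20, increment = 3,
      light_hours = 14),
    A_ramosus_control = experiment_design(
      n_plants = 11, n_steps = 6, start_day_temp = 15, increment = 0,
      light_hours = 11, control_mode = "constant_temp", control_temp = 15))
}
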