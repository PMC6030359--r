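# Shared fixtures: small designs/profiles built in code, a hand-made
# quadratic "fit" for closed-form optima tests, and the grid-search oracle.

small_design <- function(n_plants = 6, n_steps = 8, ...) {
  experiment_design(n_plants = n_plants, n_steps = n_steps,
                    start_day_temp = 20, increment = 3, light_hours = 14,
                    ...)
}

small_control_design <- function(n_plants = 6, n_steps = 8, temp = 20) {
  experiment_design(n_plants = n_plants, n_steps = n_steps,
                    start_day_temp = temp, increment = 0, light_hours = 14,
                    control_mode = "constant_temp", control_temp = temp)
}

quiet_profile <- function(plant_sd = 0.3, resid_sd = 0.4, ...) {
  species_profile("testspec", flowering_month = 5,
                  volume = list(amplitude = log(2), true_opt = 26,
                                breadth = 8),
                  concentration = list(amplitude = qlogis(0.3),
                                       true_opt = 25, breadth = 14),
                  flowers = list(amplitude = log(30), true_opt = 24,
                                 breadth = 10),
                  plant_sd = plant_sd, resid_sd = resid_sd, ...)
}

sim_plant_days <- function(profile, design, seed) {
  sim <- generate_experiment(profile, design, seed)
  aggregate_plant_day(impute_concentration(sim$flowers), sim$counts)
}

# a mixed_fit-shaped object with known coefficients, for closed-form checks
make_quad_fit <- function(b0, b1, b2, temp_center = 0, temp_scale = 1,
                          value_range = c(-1, 1), tempz_range = c(-2, 2),
                          p_quad = 1e-4, trait = "volume",
                          species = "testspec") {
  terms <- c("(Intercept)", "temp_z", "I(temp_z^2)")
  ct <- cbind(Estimate = c(b0, b1, b2), `Std. Error` = c(0.1, 0.1, 0.1),
              `t value` = c(b0, b1, b2) / 0.1,
              `p value` = c(1e-4, 1e-4, p_quad))
  rownames(ct) <- terms
  structure(list(trait = trait, scope = paste0("species:", species),
                 coefficients = ct, varcomp = c(plant_id = 0.1),
                 sigma2 = 0.2, converged = TRUE, df_method = "normal",
                 meta = list(temp_center = temp_center,
                             temp_scale = temp_scale),
                 observed_value_range = value_range,
                 observed_tempz_range = tempz_range),
            class = "mixed_fit")
}

# independent grid-search oracle for the 5%-band interval (standardized x)
grid_optimal_range <- function(b0, b1, b2, delta, step = 1e-4) {
  stopifnot(b2 < 0)
  x_star <- -b1 / (2 * b2)
  half <- sqrt(delta / abs(b2))
  x <- seq(x_star - half - 0.5, x_star + half + 0.5, by = step)
  f <- b0 + b1 * x + b2 * x^2
  inside <- x[f >= (b0 + b1 * x_star + b2 * x_star^2) - delta]
  c(lo = min(inside), hi = max(inside))
}
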