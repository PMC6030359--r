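test_that("noiseless quadratic data are recovered exactly", {
  prof <- quiet_profile(plant_sd = 0, resid_sd = 0)
  pd <- sim_plant_days(prof, small_design(n_plants = 4), seed = 1)
  f <- fit_quadratic_lmm(pd, "volume")
  expect_true("degenerate_noiseless" %in% f$notes)
  # true coefficients in standardized coordinates, by exact algebra
  m <- f$meta
  w <- prof$volume$breadth; opt <- prof$volume$true_opt
  b2_true <- -m$temp_scale^2 / (w^2 * m$trait_scale)
  b1_true <- -2 * m$temp_scale * (m$temp_center - opt) /
    (w^2 * m$trait_scale)
  b0_true <- (prof$volume$amplitude - ((m$temp_center - opt) / w)^2 -
                m$trait_center) / m$trait_scale
  est <- f$coefficients[, "Estimate"]
  expect_equal(unname(est), c(b0_true, b1_true, b2_true), tolerance = 1e-6)
  expect_equal(optimum_temperature(f)$T_opt, opt, tolerance = 1e-6)
})

test_that("balanced fits with no plant effect reduce to OLS", {
  prof <- quiet_profile(plant_sd = 0, resid_sd = 0.4)
  pd <- sim_plant_days(prof, small_design(n_plants = 10), seed = 21)
  f <- fit_quadratic_lmm(pd, "volume")
  dat <- f$data
  ols <- stats::lm(value ~ temp_z + I(temp_z^2), data = dat)
  expect_equal(unname(f$coefficients[, "Estimate"]),
               unname(stats::coef(ols)), tolerance = 1e-8)
})

test_that("fit metadata supports expressing the curve in degC", {
  prof <- quiet_profile()
  pd <- sim_plant_days(prof, small_design(n_plants = 12), seed = 33)
  f <- fit_quadratic_lmm(pd, "volume")
  expect_true(f$converged)
  expect_equal(f$df_method, "normal")
  expect_true(f$meta$temp_scale > 0)
  expect_equal(f$meta$transform, "log")
  expect_true(all(f$varcomp >= 0))
  expect_true(f$r2m <= f$r2c && f$r2c <= 1)
  expect_error(fit_quadratic_lmm(pd[pd$step <= 2, ], "volume"),
               "3 temperature levels")
})

test_that("vertex recovery and coverage behave over seeded replicates", {
  # scaled down from the spec's 500-replicate oracle to 120 replicates;
  # thresholds unchanged (mean vertex error < 0.5 degC, 2-SE coverage in
  # [0.90, 0.99]).
  prof <- quiet_profile()
  d <- small_design(n_plants = 15)
  reps <- 120
  res <- vapply(seq_len(reps), function(r) {
    pd <- sim_plant_days(prof, d, seed = 20000 + r)
    f <- fit_quadratic_lmm(pd, "volume")
    o <- optimum_temperature(f)
    cf <- f$coefficients[, "Estimate"]
    V <- f$vcov_fixed
    g <- c(0, -1 / (2 * cf[3]), cf[2] / (2 * cf[3]^2))  # d x*/d beta
    se_x <- sqrt(drop(t(g) %*% V %*% g))
    se_T <- se_x * f$meta$temp_scale
    c(err = o$T_opt - prof$volume$true_opt,
      cover = abs(o$T_opt - prof$volume$true_opt) <= 2 * se_T)
  }, numeric(2))
  expect_lt(abs(mean(res["err", ])), 0.5)
  expect_gte(mean(res["cover", ]), 0.90)
  expect_lte(mean(res["cover", ]), 0.99)
})

test_that("time x group interaction vanishes when control mirrors experiment", {
  prof <- quiet_profile()
  pd <- sim_plant_days(prof, small_design(n_plants = 8), seed = 10)
  dup <- pd
  dup$group <- "control"
  dup$plant_id <- paste0(dup$plant_id, "_c")
  f <- fit_time_group_interaction(rbind(pd, dup), "volume",
                                  scope = "per_species")
  ix <- grep(":groupexperimental", rownames(f$coefficients))
  expect_equal(unname(f$coefficients[ix, "Estimate"]), c(0, 0),
               tolerance = 1e-8)
})

test_that("a true temperature effect is detected against controls", {
  # power check, scaled down from 500 to 60 replicates (default effect
  # sizes give power near 1, so the 0.8 threshold is safe at 60)
  prof <- quiet_profile(drift_linear = 0.01)
  d <- small_design(n_plants = 15)
  cd <- small_control_design(n_plants = 8)
  hits <- vapply(1:60, function(r) {
    pde <- sim_plant_days(prof, d, seed = 40000 + r)
    sc <- generate_control(prof, cd, seed = 40000 + r)
    pdc <- aggregate_plant_day(impute_concentration(sc$flowers), sc$counts)
    f <- fit_time_group_interaction(rbind(pde, pdc), "volume",
                                    scope = "per_species")
    ix <- grep(":groupexperimental", rownames(f$coefficients))
    any(f$coefficients[ix, "p value"] < 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # single-group input is a design error
  pde <- sim_plant_days(prof, d, seed = 1)
  expect_error(fit_time_group_interaction(pde, "volume"), "both")
})

test_that("flowering-group interactions recover construction and symmetry", {
  prof_lo <- quiet_profile()
  prof_lo$species_name <- "lo1"
  prof_lo$volume$true_opt <- 14
  prof_hi <- quiet_profile()
  prof_hi$species_name <- "hi1"
  prof_hi$volume$true_opt <- 27
  prof_lo2 <- prof_lo; prof_lo2$species_name <- "lo2"
  prof_hi2 <- prof_hi; prof_hi2$species_name <- "hi2"
  d <- small_design(n_plants = 10)
  pd <- do.call(rbind, lapply(list(prof_lo, prof_lo2, prof_hi, prof_hi2),
                              function(p) {
    s <- generate_experiment(p, d, seed = 55)
    aggregate_plant_day(impute_concentration(s$flowers), s$counts)
  }))
  grouping <- c(lo1 = "early", lo2 = "early", hi1 = "late", hi2 = "late")
  f <- fit_flowering_group_model(pd, "volume", grouping)
  # late group has the higher optimum: positive temp x group interaction
  est <- f$coefficients["temp_z:fgrouplate", "Estimate"]
  expect_gt(est, 0)
  expect_lt(f$coefficients["temp_z:fgrouplate", "p value"], 0.05)
  # relabeling symmetry: swapping the groups flips the interaction sign
  swapped <- c(lo1 = "late", lo2 = "late", hi1 = "early", hi2 = "early")
  f2 <- fit_flowering_group_model(pd, "volume", swapped)
  expect_equal(f2$coefficients["temp_z:fgrouplate", "Estimate"], -est,
               tolerance = 1e-6)
  expect_warning(
    fit_flowering_group_model(pd[pd$species != "lo2", ], "volume",
                              grouping),
    "< 2 species")
})

test_that("AIC selection prefers the generating model", {
  make_pd <- function(seed, quadratic) {
    set.seed(seed)
    n_pl <- 10; temps <- seq(10, 31, by = 3)
    g <- expand.grid(plant = seq_len(n_pl), temp = temps)
    b <- rnorm(n_pl, 0, 0.3)
    z <- (g$temp - mean(temps)) / sd(temps)
    lv <- 0.5 + 0.4 * z + (if (quadratic) -0.6 * z^2 else 0) +
      b[g$plant] + rnorm(nrow(g), 0, 0.4)
    data.frame(plant_id = sprintf("p%02d", g$plant), species = "s",
               group = "experimental", step = match(g$temp, temps),
               time_index = 3 * match(g$temp, temps), mean24_temp = g$temp,
               mean_volume = exp(lv))
  }
  pick <- function(seed, quadratic) {
    pd <- make_pd(seed, quadratic)
    fs <- fit_quadratic_lmm(pd, "volume", drop_quadratic = TRUE)
    fq <- fit_quadratic_lmm(pd, "volume")
    aic_select(fs, fq)$chosen
  }
  # scaled down from the spec's replicate counts (200 / 60 runs)
  lin <- vapply(1:200, function(r) pick(60000 + r, FALSE), character(1))
  expect_gt(mean(lin == "simple"), 0.8)
  quad <- vapply(1:60, function(r) pick(70000 + r, TRUE), character(1))
  expect_gt(mean(quad == "quadratic"), 0.95)
  # identical models: delta AIC exactly 0
  pd <- make_pd(1, TRUE)
  fq <- fit_quadratic_lmm(pd, "volume")
  expect_equal(aic_select(fq, fq)$delta_aic, 0)
  other <- fit_quadratic_lmm(make_pd(2, TRUE), "volume")
  expect_error(aic_select(fq, other), "same data")
})

test_that("Nakagawa R2 equals an independent variance decomposition", {
  prof <- quiet_profile()
  pd <- sim_plant_days(prof, small_design(n_plants = 12), seed = 91)
  f <- fit_quadratic_lmm(pd, "volume")
  r2 <- r2_nakagawa(f)
  # oracle: recompute from the lme4 object itself
  mod <- f$model
  vf <- stats::var(stats::predict(mod, re.form = NA))
  vc <- as.data.frame(lme4::VarCorr(mod))
  vr <- sum(vc$vcov[vc$grp != "Residual"])
  s2 <- vc$vcov[vc$grp == "Residual"]
  expect_equal(r2$r2m, vf / (vf + vr + s2), tolerance = 1e-8)
  expect_equal(r2$r2c, (vf + vr) / (vf + vr + s2), tolerance = 1e-8)
  # no random variance: marginal equals conditional
  prof0 <- quiet_profile(plant_sd = 0, resid_sd = 0)
  f0 <- fit_quadratic_lmm(sim_plant_days(prof0, small_design(), seed = 2),
                          "volume")
  expect_equal(f0$r2m, f0$r2c)
})
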