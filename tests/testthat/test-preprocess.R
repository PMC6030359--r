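test_that("sucrose density and per-flower sugar match the published table", {
  # independent oracle: linear interpolation of the standard 20 degC
  # density table for sucrose solutions (% w/w -> g/ml)
  tab_c <- c(0, 10, 20, 30, 40, 50, 60, 70)
  tab_d <- c(0.9982, 1.0381, 1.0810, 1.1270, 1.1764, 1.2295, 1.2864, 1.3472)
  grid <- seq(0, 70, by = 2.5)
  oracle <- stats::approx(tab_c, tab_d, xout = grid)$y
  expect_true(all(abs(sucrose_density(grid) - oracle) / oracle < 0.01))
  expect_equal(sucrose_density(0), 0.9982)
  expect_equal(sugar_per_flower(0, 30), 0)
  expect_equal(sugar_per_flower(1, 0), 0)
  expect_equal(sugar_per_flower(2, 30), 0.676, tolerance = 2e-3)
  # empty flower with unreadable concentration still carries zero sugar
  expect_equal(sugar_per_flower(0, NA), 0)
  expect_error(sugar_per_flower(2, 120), "concentration")
  expect_error(sugar_per_flower(-1, 30), "volume")
})

test_that("imputation fills unreadable concentrations from plant-day mates", {
  fl <- data.frame(plant_id = "p1", species = "s", group = "experimental",
                   step = 1, time_index = 3, mean24_temp = 20,
                   flower_index = 1:3, volume = c(1, 0.01, 2),
                   concentration = c(30, NA, 34),
                   is_empty = c(FALSE, FALSE, FALSE))
  out <- impute_concentration(fl)
  expect_equal(out$concentration[2], 32)
  expect_equal(attr(out, "n_imputed"), 1L)
  expect_identical(out$concentration[c(1, 3)], c(30, 34))
  # no missing values: identity
  fl2 <- fl; fl2$concentration <- c(30, 31, 34)
  out2 <- impute_concentration(fl2)
  expect_equal(out2$concentration, fl2$concentration)
  expect_equal(attr(out2, "n_imputed"), 0L)
  # all unreadable with nonzero volume: flagged, not aborted
  fl3 <- fl; fl3$concentration <- rep(NA_real_, 3)
  out3 <- impute_concentration(fl3)
  expect_true(all(out3$conc_unresolved))
})

test_that("imputation equals the brute-force oracle on random plant-days", {
  set.seed(42)
  for (r in 1:25) {
    n_days <- 40
    rows <- do.call(rbind, lapply(seq_len(n_days), function(i) {
      k <- sample(2:4, 1)
      conc <- runif(k, 10, 60)
      conc[runif(k) < 0.3] <- NA
      data.frame(plant_id = sprintf("p%02d", i), species = "s",
                 group = "experimental", step = sample(1:8, 1),
                 time_index = 3, mean24_temp = 20, flower_index = seq_len(k),
                 volume = runif(k, 0.1, 3), concentration = conc,
                 is_empty = FALSE)
    }))
    out <- impute_concentration(rows)
    key <- paste(rows$plant_id, rows$step)
    for (g in split(seq_len(nrow(rows)), key)) {
      obs <- rows$concentration[g]
      if (all(is.na(obs))) {
        expect_true(all(out$conc_unresolved[g]))
      } else {
        exp_fill <- ifelse(is.na(obs), mean(obs, na.rm = TRUE), obs)
        expect_equal(out$concentration[g], exp_fill)
      }
    }
  }
})

test_that("plant-day aggregation follows the trait definitions", {
  fl <- data.frame(plant_id = "p1", species = "s", group = "experimental",
                   step = 2, time_index = 6, mean24_temp = 22,
                   flower_index = 1:3, volume = c(1, 2, 3),
                   concentration = c(30, 30, 30), is_empty = FALSE)
  cnt <- data.frame(plant_id = "p1", species = "s", group = "experimental",
                    step = 2, time_index = 6, mean24_temp = 22,
                    n_flowers = 40)
  pd <- aggregate_plant_day(impute_concentration(fl), cnt)
  expect_equal(pd$mean_volume, 2)
  expect_equal(pd$mean_concentration, 30)
  expect_equal(pd$sugar_per_plant, pd$sugar_per_flower * 40)
  # product rule: mean sugar 0.5 mg and 40 flowers -> 20 mg per plant
  expect_equal(0.5 * 40, 20)
  # empty flowers: zero volume and sugar, excluded from concentration
  fl$is_empty <- c(FALSE, FALSE, TRUE)
  fl$volume <- c(1, 2, 0)
  fl$concentration <- c(30, 34, NA)
  pd2 <- aggregate_plant_day(impute_concentration(fl), cnt)
  expect_equal(pd2$mean_volume, 1)           # (1 + 2 + 0) / 3
  expect_equal(pd2$mean_concentration, 32)   # empties excluded
  expect_equal(pd2$n_empty_of_sampled, 1)
  s <- sugar_per_flower(c(1, 2), c(30, 34))
  expect_equal(pd2$sugar_per_flower, sum(s) / 3)
})

test_that("aggregation equals a brute-force group-and-average oracle", {
  prof <- quiet_profile(zero_inflation_base = 0.15,
                        zero_inflation_heat_slope = 0.1)
  sim <- generate_experiment(prof, small_design(n_plants = 10), seed = 77)
  fl <- impute_concentration(sim$flowers)
  pd <- aggregate_plant_day(fl, sim$counts)
  key <- paste(fl$plant_id, fl$step)
  pk <- paste(pd$plant_id, pd$step)
  for (g in split(seq_len(nrow(fl)), key)) {
    i <- match(paste(fl$plant_id[g[1]], fl$step[g[1]]), pk)
    expect_equal(pd$mean_volume[i], mean(fl$volume[g]))
    ok <- !fl$is_empty[g] & !is.na(fl$concentration[g])
    if (any(ok))
      expect_equal(pd$mean_concentration[i], mean(fl$concentration[g][ok]))
    # conservation: total sampled volume = n_sampled x mean volume
    expect_equal(sum(fl$volume[g]), pd$n_sampled[i] * pd$mean_volume[i])
  }
})

test_that("transforms follow the log-offset and logit boundary rules", {
  lt <- transform_trait(c(exp(1), 1, 2), "log")
  expect_equal(attr(lt, "offset"), 0)
  expect_equal(as.numeric(lt)[1], 1)
  # zeros present: offset = half the smallest positive value
  lt0 <- transform_trait(c(0, 0.4, 2), "log")
  expect_equal(attr(lt0, "offset"), 0.2)
  expect_equal(as.numeric(lt0)[1], log(0.2))
  expect_error(transform_trait(c(-1, 2), "log"), "non-negative")
  gt <- transform_trait(c(50, 25), "logit")
  expect_equal(as.numeric(gt)[1], 0)
  expect_equal(as.numeric(gt)[2], log(1 / 3), tolerance = 1e-12)
  # boundary percentages are clamped to [eps, 1 - eps], eps = 1/(2N)
  gb <- transform_trait(c(0, 100, 50, 50), "logit")
  expect_equal(attr(gb, "eps"), 1 / 8)
  expect_equal(as.numeric(gb)[1], qlogis(1 / 8))
  expect_error(transform_trait(c(101), "logit"), "\\[0, 100\\]")
  # interior round trip (inside the clamp band): inverse-logit of logit
  # is the identity
  p <- c(20, 35.5, 72.2, 60)
  expect_equal(100 * plogis(as.numeric(transform_trait(p, "logit"))), p,
               tolerance = 1e-12)
})

test_that("standardization is exact, idempotent and invertible", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  z <- standardize(rnorm(50, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  z2 <- standardize(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  # round trip through the stored center/scale
  x <- rnorm(30, 20, 5)
  zx <- standardize(x)
  expect_equal(attr(zx, "center") + attr(zx, "scale") * as.numeric(zx), x,
               tolerance = 1e-10)
  # brute-force oracle
  set.seed(9)
  for (r in 1:20) {
    v <- rnorm(sample(5:50, 1), runif(1, -10, 10), runif(1, 0.5, 4))
    expect_equal(as.numeric(standardize(v)), (v - mean(v)) / sd(v))
  }
  expect_error(standardize(rep(2, 5)), "zero variance")
})

test_that("Shapiro-Wilk wrapper reports and guards degenerate input", {
  set.seed(11)
  p_norm <- replicate(500, shapiro_normality(rnorm(200))$p)
  expect_gte(mean(p_norm > 0.05), 0.94)
  p_exp <- replicate(200, shapiro_normality(rexp(100))$p)
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(shapiro_normality(c(1, 2)), "n >= 3")
  expect_error(shapiro_normality(rep(1, 10)), "identical")
})

test_that("prepare_trait_data standardizes within the declared scope", {
  prof <- quiet_profile()
  pd <- sim_plant_days(prof, small_design(n_plants = 8), seed = 12)
  pd2 <- pd
  pd2$species <- "other"
  pd2$mean_volume <- pd2$mean_volume * 3
  both <- rbind(pd, pd2)
  per <- prepare_trait_data(both, "volume", scope = "per_species")
  for (sp in unique(per$species)) {
    expect_equal(mean(per$value[per$species == sp]), 0, tolerance = 1e-10)
    expect_equal(sd(per$value[per$species == sp]), 1, tolerance = 1e-10)
  }
  pooled <- prepare_trait_data(both, "volume", scope = "pooled")
  expect_equal(mean(pooled$value), 0, tolerance = 1e-10)
  expect_equal(sd(pooled$value), 1, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(sd(pooled$value[pooled$species == "testspec"]),
                                1)))
})
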