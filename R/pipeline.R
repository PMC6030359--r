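# End-to-end wiring: simulate -> preprocess -> fit -> optima -> climate
# comparison (+ control validation and empty-flower ZINB), with a manifest
# recording every surfaced design decision.

#' Pipeline configuration
#'
#' Collects every tunable the pipeline surfaces; all values land in the run
#' manifest so two runs differing in any decision produce differing
#' manifests.
#'
#' @param outdir output directory.
#' @param seed master seed for the synthetic stage.
#' @param profiles named list of [species_profile()]s (default:
#'   [default_species_profiles()]).
#' @param designs named list of [experiment_design()]s keyed like
#'   `profiles` (default: [species_designs()]).
#' @param scenario a [climate_scenario()] or path to a JSON file with
#'   elements `baseline`, `p25`, `p50`, `p75`, `max`.
#' @param levels scenario levels for the comparison table. Requesting
#'   `"p50"` without configured p50 increments is a configuration error.
#' @param truncate_ranges clip optimal ranges to tested temperatures.
#' @param alpha significance level for annotations.
#' @param simulate_controls also generate constant-temperature control
#'   groups and run the time x group validation models.
#' @param measurable_threshold volume (ul) below which concentration is
#'   unreadable.
#' @param stages character vector of stages to run, subset of
#'   `c("simulate", "preprocess", "fit", "optima", "compare", "zinb")` or
#'   `"all"`. Later stages read the earlier stages' files from `outdir`.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            profiles = default_species_profiles(),
                            designs = NULL,
                            scenario = climate_scenario(),
                            levels = c("baseline", "p75", "max"),
                            truncate_ranges = FALSE,
                            alpha = 0.05,
                            simulate_controls = TRUE,
                            measurable_threshold = 0.05,
                            stages = "all") {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if ("p50" %in% levels && is.null(scenario$increments$p50))
    stop("missing increment: level 'p50' requested but the scenario ",
         "defines no p50 increments", call. = FALSE)
  if (is.null(designs)) {
    sd_all <- species_designs()
    designs <- sd_all[intersect(names(profiles), names(sd_all))]
    missing <- setdiff(names(profiles), names(designs))
    for (nm in missing)
      designs[[nm]] <- experiment_design(n_plants = 15, n_steps = 8,
                                         start_day_temp = 20, increment = 3,
                                         light_hours = 14)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 profiles = profiles, designs = designs,
                 scenario = scenario, levels = levels,
                 truncate_ranges = truncate_ranges, alpha = alpha,
                 simulate_controls = simulate_controls,
                 measurable_threshold = measurable_threshold,
                 stages = stages),
            class = "run_config")
}

#' Read a climate scenario from JSON
#'
#' @param path JSON file with `baseline` (named by month number) and any of
#'   `p25`, `p50`, `p75`, `max` (named by season).
#' @return a [climate_scenario()].
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  climate_scenario(baseline = unlist(x$baseline),
                   p25 = if (!is.null(x$p25)) unlist(x$p25) else
                     c(winter = 1.5, spring = 2.1, summer = 2.3),
                   p75 = if (!is.null(x$p75)) unlist(x$p75) else
                     c(winter = 2.4, spring = 2.7, summer = 3.3),
                   max = if (!is.null(x$max)) unlist(x$max) else
                     c(winter = 3.0, spring = 3.7, summer = 5.5),
                   p50 = if (!is.null(x$p50)) unlist(x$p50) else NULL)
}

#' Validate a flower-record table
#'
#' Structural and range checks on a long-format flower table: required
#' columns present, volumes non-negative, concentrations within `[0, 100]`,
#' integral step/flower indices, empty flowers with zero volume, consistent
#' species within plant.
#'
#' @param table data.frame as written by [write_sim()].
#' @return data.frame of issues (`row`, `column`, `rule`, `message`);
#'   zero rows when the table is clean.
#' @export
validate_input <- function(table) {
  issues <- list()
  add <- function(row, column, rule, message)
    issues[[length(issues) + 1L]] <<- data.frame(row = row, column = column,
                                                 rule = rule,
                                                 message = message)
  required <- c("plant_id", "species", "group", "step", "volume",
                "concentration", "mean24_temp")
  for (col in setdiff(required, names(table)))
    add(NA_integer_, col, "missing_column",
        paste0("required column '", col, "' absent"))
  if (length(issues) == 0L) {
    bad <- which(!is.na(table$volume) & table$volume < 0)
    for (i in bad) add(i, "volume", "range", "negative nectar volume")
    bad <- which(!is.na(table$concentration) &
                   (table$concentration < 0 | table$concentration > 100))
    for (i in bad) add(i, "concentration", "range",
                       "concentration outside [0, 100] % w/w")
    bad <- which(!is.na(table$step) & table$step != round(table$step))
    for (i in bad) add(i, "step", "integral", "non-integral step index")
    if (!is.null(table$is_empty)) {
      bad <- which(table$is_empty & table$volume != 0)
      for (i in bad) add(i, "volume", "consistency",
                         "empty flower with nonzero volume")
    }
    if (!is.null(table$n_flowers)) {
      bad <- which(!is.na(table$n_flowers) &
                     (table$n_flowers < 0 |
                        table$n_flowers != round(table$n_flowers)))
      for (i in bad) add(i, "n_flowers", "integral",
                         "flower count must be a non-negative integer")
    }
    sp <- tapply(as.character(table$species), table$plant_id,
                 function(s) length(unique(s)))
    for (pid in names(sp)[sp > 1])
      add(NA_integer_, "species", "consistency",
          paste0("plant '", pid, "' maps to several species"))
  }
  if (length(issues) == 0L)
    return(data.frame(row = integer(), column = character(),
                      rule = character(), message = character()))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[nectartherm] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Executes the requested stages: simulate the chamber experiment for every
#' configured species (plus controls), derive plant-day traits, fit the
#' per-species quadratic mixed models and the flowering-group interaction
#' model, compute optima and 5%-band optimal ranges, compare group optima
#' against the climate scenario, and fit the empty-flower ZINB where empty
#' flowers occur. All tables are written to `outdir` as UTF-8 CSV, along
#' with `manifest.json` capturing the seed, configuration and per-fit
#' convergence. Identical configurations yield identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory tables (`plant_days`,
#'   `species_fits`, `optima`, `climate`, `group_model`, `validation`,
#'   `zinb`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  if (identical(stages, "all"))
    stages <- c("simulate", "preprocess", "fit", "optima", "compare", "zinb")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  warnings_log <- character()

  if ("simulate" %in% stages) {
    pipeline_log("simulate: %d species, seed %d", length(config$profiles),
                 config$seed)
    for (nm in names(config$profiles)) {
      sim <- generate_experiment(config$profiles[[nm]], config$designs[[nm]],
                                 seed = config$seed,
                                 measurable_threshold =
                                   config$measurable_threshold)
      write_sim(sim, config$outdir, stem = nm)
      if (config$simulate_controls) {
        de <- config$designs[[nm]]
        ctrl_design <- experiment_design(
          n_plants = max(6L, de$n_plants %/% 2L), n_steps = de$n_steps,
          start_day_temp = de$start_day_temp, increment = 0,
          light_hours = de$light_hours,
          flowers_sampled = de$flowers_sampled,
          control_mode = "constant_temp",
          control_temp = de$start_day_temp)
        ctrl <- generate_control(config$profiles[[nm]], ctrl_design,
                                 seed = config$seed,
                                 measurable_threshold =
                                   config$measurable_threshold)
        write_sim(ctrl, config$outdir, stem = paste0(nm, "_control"))
      }
    }
  }

  read_stems <- function(suffix) {
    files <- list.files(config$outdir, pattern = paste0(suffix, "\\.csv$"),
                        full.names = TRUE)
    do.call(rbind, lapply(files, read_flower_records))
  }

  if ("preprocess" %in% stages) {
    flowers <- read_stems("_flowers")
    counts <- read_stems("_counts")
    issues <- validate_input(flowers)
    if (nrow(issues) > 0)
      stop("input validation failed: ", nrow(issues), " issue(s); first: ",
           issues$message[1], call. = FALSE)
    flowers <- impute_concentration(flowers)
    pipeline_log("preprocess: %d flower records, %d imputed concentrations",
                 nrow(flowers), attr(flowers, "n_imputed"))
    plant_days <- aggregate_plant_day(flowers, counts)
    utils::write.csv(plant_days, file.path(config$outdir, "plant_days.csv"),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
    out$plant_days <- plant_days
  } else {
    pd_path <- file.path(config$outdir, "plant_days.csv")
    if (file.exists(pd_path)) out$plant_days <- read_flower_records(pd_path)
  }

  traits <- c("volume", "concentration", "sugar_per_flower",
              "sugar_per_plant", "n_flowers")

  if ("fit" %in% stages) {
    pd <- out$plant_days
    exp_pd <- pd[pd$group == "experimental", ]
    fits <- list()
    for (sp in unique(exp_pd$species)) {
      for (tr in traits) {
        key <- paste(sp, tr, sep = ".")
        f <- try(fit_quadratic_lmm(exp_pd, tr, species = sp), silent = TRUE)
        if (inherits(f, "try-error")) {
          warnings_log <- c(warnings_log, paste0(key, ": ",
                                                 trimws(attr(f, "condition")$message)))
          next
        }
        pipeline_log("fit %s: converged=%s R2m=%.2f", key, f$converged, f$r2m)
        fits[[key]] <- f
      }
    }
    out$species_fits <- fits
    grouping <- vapply(config$profiles, function(p)
      assign_flowering_group(p$species_name, p$flowering_month), character(1))
    names(grouping) <- vapply(config$profiles, `[[`, character(1),
                              "species_name")
    if (length(unique(exp_pd$species)) >= 2 &&
        length(unique(grouping[unique(exp_pd$species)])) == 2) {
      out$group_model <- lapply(traits, function(tr)
        withCallingHandlers(
          fit_flowering_group_model(exp_pd, tr, grouping,
                                    drop_quadratic = tr == "concentration"),
          warning = function(w) {
            warnings_log <<- c(warnings_log,
                               paste0("group_model.", tr, ": ",
                                      conditionMessage(w)))
            invokeRestart("muffleWarning")
          }))
      names(out$group_model) <- traits
      gm <- do.call(rbind, lapply(traits, function(tr) {
        f <- out$group_model[[tr]]
        data.frame(trait = tr, term = rownames(f$coefficients),
                   estimate = f$coefficients[, "Estimate"],
                   t = f$coefficients[, "t value"],
                   p = f$coefficients[, "p value"],
                   r2m = f$r2m, r2c = f$r2c)
      }))
      utils::write.csv(gm, file.path(config$outdir,
                                     "table_group_model.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      warnings_log <- c(warnings_log,
                        "group_model: skipped (needs >= 2 species spanning both flowering groups)")
    }
    if (config$simulate_controls && any(pd$group == "control")) {
      val <- list()
      for (sp in unique(pd$species[pd$group == "control"])) {
        sub <- pd[pd$species == sp, ]
        for (tr in traits) {
          f <- try(fit_time_group_interaction(sub, tr,
                                              scope = "per_species"),
                   silent = TRUE)
          if (!inherits(f, "try-error"))
            val[[paste(sp, tr, sep = ".")]] <- f
        }
      }
      val$combined <- NULL
      out$validation <- val
      vt <- do.call(rbind, lapply(names(val), function(k) {
        f <- val[[k]]
        ix <- grep(":groupexperimental", rownames(f$coefficients))
        data.frame(model = k, term = rownames(f$coefficients)[ix],
                   t = f$coefficients[ix, "t value"],
                   p = f$coefficients[ix, "p value"])
      }))
      utils::write.csv(vt, file.path(config$outdir,
                                     "table_interaction.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }

  if ("optima" %in% stages) {
    fits <- out$species_fits
    keep <- !vapply(fits, is.null, logical(1))
    tab <- optima_table(fits[keep], truncate = config$truncate_ranges)
    months <- vapply(config$profiles, `[[`, integer(1), "flowering_month")
    names(months) <- vapply(config$profiles, `[[`, character(1),
                            "species_name")
    tab$flowering_month <- months[tab$species]
    utils::write.csv(tab, file.path(config$outdir, "table_optima.csv"),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
    out$optima <- tab
  }

  if ("compare" %in% stages) {
    if (is.null(out$optima)) {
      op <- file.path(config$outdir, "table_optima.csv")
      if (!file.exists(op))
        stop("compare stage needs the optima stage output", call. = FALSE)
      out$optima <- read_flower_records(op)
    }
    op <- out$optima
    op <- op[op$trait != "concentration" & !is.na(op$T_opt), ]
    t5 <- build_comparison_table(op[, c("species", "flowering_month", "trait",
                              "T_opt")],
                       scenario = config$scenario, levels = config$levels)
    utils::write.csv(t5, file.path(config$outdir, "table_climate.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    out$climate <- t5
  }

  if ("zinb" %in% stages && !is.null(out$plant_days)) {
    pd <- out$plant_days[out$plant_days$group == "experimental", ]
    zi_species <- names(config$profiles)[vapply(config$profiles, function(p)
      p$zero_inflation_base > 0, logical(1))]
    zi_species <- vapply(config$profiles[zi_species], `[[`, character(1),
                         "species_name")
    sub <- pd[pd$species %in% zi_species, ]
    if (nrow(sub) > 0 && any(sub$n_empty_of_sampled > 0)) {
      zf <- fit_zinb_empty(sub$n_empty_of_sampled, sub$mean24_temp,
                           plant_id = sub$plant_id)
      out$zinb <- zf
      if (!is.null(zf$coefficients)) {
        zt <- data.frame(term = rownames(zf$coefficients),
                         estimate = zf$coefficients[, "Estimate"],
                         se = zf$coefficients[, "Std. Error"],
                         z = zf$coefficients[, "z"],
                         p = zf$coefficients[, "p value"])
        utils::write.csv(zt, file.path(config$outdir, "table_zinb.csv"),
                         row.names = FALSE, fileEncoding = "UTF-8")
      }
    }
  }

  manifest <- list(
    package = "nectartherm",
    version = as.character(utils::packageVersion("nectartherm")),
    seed = config$seed,
    stages = stages,
    species = names(config$profiles),
    levels = config$levels,
    truncate_ranges = config$truncate_ranges,
    alpha = config$alpha,
    df_method = "normal",
    standardization = list(per_species_fits = "per_species",
                           group_models = "pooled"),
    log_offset_rule = "half smallest positive observed value",
    logit_boundary_rule = "clamp to [1/(2N), 1 - 1/(2N)]",
    measurable_threshold = config$measurable_threshold,
    simulate_controls = config$simulate_controls,
    convergence = if (!is.null(out$species_fits))
      lapply(out$species_fits, function(f)
        list(converged = f$converged, notes = f$notes)) else NULL,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
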