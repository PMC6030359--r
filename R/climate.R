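# Climate baselines, end-of-century warming increments, and the paired
# t-test comparison of thermal optima against them.

#' Climate scenario: monthly baselines plus seasonal warming increments
#'
#' Default values describe the Aegean study region: long-term (1958-2001)
#' monthly mean temperatures for the flowering months of the study species,
#' and end-of-century seasonal warming increments from the IPCC
#' stabilization scenarios (RCP4.5 for winter/summer; A1B for spring, where
#' RCP4.5 gives no seasonal figure): winter (Dec-Feb) 1.5-2.4 degC with a
#' 3.0 maximum, spring (Mar-May) 2.1-2.7 with a 3.7 maximum, summer
#' (Jun-Aug) 2.3-3.3 with a 5.5 maximum. Median (p50) increments are NOT
#' published; requesting level `"p50"` without supplying `p50` fails
#' loudly rather than inventing a value.
#'
#' @param baseline named numeric vector of monthly mean temperatures (degC),
#'   names = month numbers.
#' @param p25,p75,max named numeric vectors of per-season increments (degC),
#'   names in `c("winter", "spring", "summer")`.
#' @param p50 optional per-season median increments; no default.
#' @return a `climate_scenario` list.
#' @export
climate_scenario <- function(baseline = c(`1` = 9.2, `3` = 11.9, `4` = 15.9,
                                          `5` = 21.3, `6` = 26.2),
                             p25 = c(winter = 1.5, spring = 2.1, summer = 2.3),
                             p75 = c(winter = 2.4, spring = 2.7, summer = 3.3),
                             max = c(winter = 3.0, spring = 3.7, summer = 5.5),
                             p50 = NULL) {
  inc <- list(p25 = p25, p50 = p50, p75 = p75, max = max)
  for (nm in names(inc)) {
    v <- inc[[nm]]
    if (!is.null(v) && any(v < 0))
      stop("warming increments must be >= 0", call. = FALSE)
  }
  structure(list(baseline = baseline, increments = inc),
            class = "climate_scenario")
}

month_season <- function(month) {
  if (month %in% c(12, 1, 2)) "winter"
  else if (month %in% 3:5) "spring"
  else if (month %in% 6:8) "summer"
  else "autumn"
}

#' Flowering-group assignment
#'
#' Species flowering January-April form the early group; May-June the late
#' group. Other months fall outside the study design and raise an error.
#'
#' @param species species label (carried through to the error message).
#' @param flowering_month month 1-12.
#' @return `"early"` or `"late"`.
#' @export
assign_flowering_group <- function(species, flowering_month) {
  if (flowering_month %in% 1:4) "early"
  else if (flowering_month %in% 5:6) "late"
  else stop("unsupported flowering month ", flowering_month, " for ",
            species, ": outside the January-June design", call. = FALSE)
}

#' Reference temperature for a month under a scenario level
#'
#' @param month month 1-12 with a configured baseline.
#' @param level `"baseline"`, `"p25"`, `"p50"`, `"p75"` or `"max"`.
#' @param scenario a [climate_scenario()].
#' @return temperature in degC (baseline + seasonal increment).
#' @export
scenario_temperature <- function(month, level, scenario = climate_scenario()) {
  b <- scenario$baseline[as.character(month)]
  if (is.na(b))
    stop("no baseline configured for month ", month, call. = FALSE)
  if (level == "baseline") return(unname(b))
  inc <- scenario$increments[[level]]
  if (is.null(inc))
    stop("missing increment: level '", level,
         "' is not configured in the scenario (p50 has no published ",
         "default and must be supplied)", call. = FALSE)
  season <- month_season(month)
  if (!season %in% names(inc) || is.na(inc[season]))
    stop("missing increment: no '", level, "' value for season ", season,
         call. = FALSE)
  unname(b + inc[season])
}

signif_band <- function(p) {
  if (is.na(p)) ""
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.1) "."
  else "ns"
}

#' Paired t-test of thermal optima against reference temperatures
#'
#' Tests whether a group of species' optima differ from the matching
#' per-species reference temperatures: differences `d_i = optimum_i -
#' reference_i`, `t = mean(d) / (sd(d) / sqrt(n))` with the sample SD, `df
#' = n - 1`, two-sided p. Species with an undefined optimum are dropped
#' pairwise.
#'
#' @param optima numeric vector of per-species optima (degC); may contain
#'   `NA`.
#' @param references numeric vector of matching reference temperatures.
#' @return list with `n`, `df`, `t`, `p`, `annotation` (significance band:
#'   `ns`, `.` for 0.1-0.05, `*`, `**`, `***`).
#' @export
paired_t_optima <- function(optima, references) {
  stopifnot(length(optima) == length(references))
  keep <- !is.na(optima) & !is.na(references)
  d <- optima[keep] - references[keep]
  n <- length(d)
  if (n < 2) stop("insufficient pairs: need >= 2 complete pairs",
                  call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("undefined t: zero variance of pair differences",
                   call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(n = n, df = n - 1L, t = t, p = p, annotation = signif_band(p))
}

#' Reported thermal optima of the six study species
#'
#' The published per-species optimum temperatures (degC, 24-h means) for
#' nectar volume per flower, sugar content per flower, sugar content per
#' plant and flower number, together with each species' peak flowering
#' month. Concentration is excluded: several species responded linearly and
#' have no optimum. The one missing cell is the lavender sugar content per
#' flower, whose response was linear.
#'
#' @return data.frame with columns `species`, `flowering_month`, `trait`,
#'   `T_opt`.
#' @export
reference_optima <- function() {
  species <- c("R_officinalis", "A_ramosus", "L_stoechas",
               "E_plantagineum", "B_acetabulosa", "T_divaricatum")
  months <- c(1, 3, 4, 5, 6, 6)
  vals <- rbind(
    volume = c(15.7, 12.4, 16.4, 23.1, 25.9, 30.9),
    sugar_per_flower = c(16.0, 12.5, NA, 20.8, 25.7, 28.7),
    sugar_per_plant = c(17.7, 14.7, 15.3, 20.8, 25.4, 22.5),
    n_flowers = c(19.7, 15.9, 18.9, 18.7, 24.7, 20.2))
  out <- do.call(rbind, lapply(rownames(vals), function(tr)
    data.frame(species = species, flowering_month = months, trait = tr,
               T_opt = vals[tr, ])))
  rownames(out) <- NULL
  out
}

#' Full paired-comparison table of optima vs climate
#'
#' For every trait (volume, sugar per flower, sugar per plant, flower
#' number; concentration excluded by design) x flowering group (early,
#' late) x scenario level, runs [paired_t_optima()] of the group's optima
#' against each species' flowering-month reference temperature. Cells whose
#' test cannot be computed (too few pairs, unconfigured level) are reported
#' as annotated missing rows rather than aborting the table.
#'
#' @param optima data.frame with columns `species`, `flowering_month`,
#'   `trait`, `T_opt` (e.g. from [optima_table()] joined to flowering
#'   months, or [reference_optima()]).
#' @param scenario a [climate_scenario()].
#' @param levels scenario levels to tabulate.
#' @return data.frame with columns `trait`, `level`, `group`, `n`, `df`,
#'   `t`, `p`, `annotation`, `note`.
#' @export
build_comparison_table <- function(optima, scenario = climate_scenario(),
                                   levels = c("baseline", "p50", "p75",
                                              "max")) {
  traits <- intersect(c("volume", "sugar_per_flower", "sugar_per_plant",
                        "n_flowers"), unique(optima$trait))
  rows <- list()
  for (tr in traits) {
    sub <- optima[optima$trait == tr, ]
    sub$fgroup <- vapply(seq_len(nrow(sub)), function(i)
      assign_flowering_group(sub$species[i], sub$flowering_month[i]),
      character(1))
    for (lev in levels) {
      for (g in c("early", "late")) {
        gg <- sub[sub$fgroup == g, ]
        res <- try({
          refs <- vapply(gg$flowering_month, scenario_temperature,
                         numeric(1), level = lev, scenario = scenario)
          paired_t_optima(gg$T_opt, refs)
        }, silent = TRUE)
        rows[[length(rows) + 1L]] <- if (inherits(res, "try-error")) {
          data.frame(trait = tr, level = lev, group = g, n = NA_integer_,
                     df = NA_integer_, t = NA_real_, p = NA_real_,
                     annotation = "",
                     note = trimws(attr(res, "condition")$message))
        } else {
          data.frame(trait = tr, level = lev, group = g, n = res$n,
                     df = res$df, t = res$t, p = res$p,
                     annotation = res$annotation, note = "")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
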