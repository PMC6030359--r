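# Quadratic temperature-response mixed models, control-group time x group
# validation models, flowering-group interaction models, AIC comparison and
# Nakagawa R2. Coefficient p-values use the normal approximation (recorded
# as df_method = "normal"); variance components are estimated by REML unless
# a fit is requested with ML for AIC comparability.

new_mixed_fit <- function(trait, scope, coef_table, varcomp, sigma2,
                          fixed_pred, aic, reml, converged, meta, model,
                          data, notes = character()) {
  r2 <- .r2_components(fixed_pred, varcomp, sigma2)
  vcv <- try(suppressWarnings(as.matrix(stats::vcov(model))), silent = TRUE)
  if (inherits(vcv, "try-error")) vcv <- NULL
  structure(
    list(trait = trait, scope = scope, coefficients = coef_table,
         vcov_fixed = vcv,
         varcomp = varcomp, sigma2 = sigma2, fixed_pred = fixed_pred,
         r2m = r2[["r2m"]], r2c = r2[["r2c"]], aic = aic, reml = reml,
         converged = converged, df_method = "normal", meta = meta,
         model = model, data = data, notes = notes,
         observed_value_range = range(data$value),
         observed_tempz_range = if (!is.null(data$temp_z))
           range(data$temp_z) else NULL,
         n_obs = nrow(data),
         n_plants = length(unique(data$plant_id))),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed fit: %s (%s)%s\n", x$trait, x$scope,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  cat(sprintf("Random variances: %s; sigma2 = %.4g\n",
              paste(sprintf("%s=%.4g", names(x$varcomp), x$varcomp),
                    collapse = ", "), x$sigma2))
  cat(sprintf("R2m = %.3f, R2c = %.3f, AIC = %.2f (%s)\n",
              x$r2m, x$r2c, x$aic, if (x$reml) "REML" else "ML"))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

.r2_components <- function(fixed_pred, varcomp, sigma2) {
  vf <- stats::var(fixed_pred)
  vr <- sum(varcomp)
  tot <- vf + vr + sigma2
  c(r2m = vf / tot, r2c = (vf + vr) / tot)
}

.coef_table_lmer <- function(fit) {
  cc <- summary(fit)$coefficients
  p <- 2 * stats::pnorm(-abs(cc[, "t value"]))
  cbind(cc[, c("Estimate", "Std. Error", "t value"), drop = FALSE],
        `p value` = p)
}

.lmer_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  length(msgs) == 0L || all(grepl("singular|boundary", msgs,
                                  ignore.case = TRUE))
}

.varcomp_lmer <- function(fit) {
  vc <- lme4::VarCorr(fit)
  out <- vapply(vc, function(m) m[1, 1], numeric(1))
  names(out) <- names(vc)
  out
}

.fit_lmm <- function(formula, data, trait, scope, meta, reml = TRUE) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(formula, data = data, REML = reml,
                                     control = ctrl))
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  new_mixed_fit(trait, scope,
                coef_table = .coef_table_lmer(fit),
                varcomp = .varcomp_lmer(fit),
                sigma2 = stats::sigma(fit)^2,
                fixed_pred = as.numeric(X %*% beta),
                aic = stats::AIC(fit),
                reml = reml,
                converged = .lmer_converged(fit),
                meta = meta, model = fit, data = data)
}

#' Quadratic temperature-response mixed model for one species
#'
#' Fits `value ~ temp + temp^2` with a per-plant random intercept by REML to
#' the (transformed, per-species standardized) plant-day series of one
#' trait; everything needed to express the fitted parabola in degC is kept
#' in the returned object. Data with exactly zero residual variance (the
#' noiseless simulator limit) degenerate for REML; such fits are detected
#' via an exact ordinary-least-squares interpolation check and returned with
#' the OLS coefficients, zero variance components and the note
#' `"degenerate_noiseless"`.
#'
#' @param plant_days output of [aggregate_plant_day()].
#' @param trait trait name (see [prepare_trait_data()]).
#' @param species optional species to subset to; required when `plant_days`
#'   holds several species.
#' @param reml fit by REML (default) or ML.
#' @param drop_quadratic omit the squared term (the "simple" model of the
#'   AIC comparison).
#' @return a `mixed_fit` object.
#' @export
fit_quadratic_lmm <- function(plant_days, trait, species = NULL,
                              reml = TRUE, drop_quadratic = FALSE) {
  if (!is.null(species)) plant_days <- plant_days[plant_days$species %in% species, ]
  if (length(unique(plant_days$species)) != 1L)
    stop("fit_quadratic_lmm is per-species; pass `species` to subset",
         call. = FALSE)
  pd <- plant_days[plant_days$group != "control", ]
  dat <- prepare_trait_data(pd, trait, scope = "per_species")
  meta <- attr(dat, "meta")
  if (length(unique(dat$mean24_temp)) < 3 && !drop_quadratic)
    stop("design error: quadratic unidentifiable with < 3 temperature levels",
         call. = FALSE)
  if (length(unique(dat$plant_id)) < 2)
    stop("design error: need >= 2 plants for a plant random intercept",
         call. = FALSE)
  form <- if (drop_quadratic) value ~ temp_z + (1 | plant_id)
          else value ~ temp_z + I(temp_z^2) + (1 | plant_id)
  ols_form <- if (drop_quadratic) value ~ temp_z else value ~ temp_z + I(temp_z^2)
  ols <- stats::lm(ols_form, data = dat)
  if (mean(stats::residuals(ols)^2) < 1e-18) {
    cc <- suppressWarnings(summary(ols))$coefficients
    ct <- cbind(cc[, c("Estimate", "Std. Error", "t value"), drop = FALSE],
                `p value` = 2 * stats::pnorm(-abs(cc[, "t value"])))
    return(new_mixed_fit(trait, paste0("species:", dat$species[1]),
                         coef_table = ct,
                         varcomp = c(plant_id = 0), sigma2 = 0,
                         fixed_pred = as.numeric(stats::fitted(ols)),
                         aic = NA_real_, reml = reml, converged = TRUE,
                         meta = meta, model = ols, data = dat,
                         notes = "degenerate_noiseless"))
  }
  .fit_lmm(form, dat, trait, paste0("species:", dat$species[1]), meta,
           reml = reml)
}

#' Time x treatment-group validation model
#'
#' Separates the effect of the manipulated chamber temperatures from the
#' natural drift over the flowering period by contrasting the experimental
#' and control group: both groups share the time trend, so significant
#' `time x group` / `time^2 x group` interactions indicate a genuine
#' temperature effect. Fits
#' `value ~ (time + time^2) * group` with a per-plant random intercept
#' (per species) or additional species and plant-within-species intercepts
#' (combined across species).
#'
#' @param plant_days plant-day table holding both groups.
#' @param trait trait name.
#' @param scope `"per_species"` (single species) or `"combined"`.
#' @return a `mixed_fit`; the interaction rows of `$coefficients` carry the
#'   reported t and p.
#' @export
fit_time_group_interaction <- function(plant_days, trait,
                                       scope = c("per_species", "combined")) {
  scope <- match.arg(scope)
  if (length(unique(plant_days$group)) < 2)
    stop("design error: both experimental and control records required",
         call. = FALSE)
  dat <- prepare_trait_data(plant_days, trait,
                            scope = if (scope == "combined") "pooled"
                                    else "per_species")
  if (scope == "per_species" && length(unique(dat$species)) != 1L)
    stop("per_species scope expects a single species", call. = FALSE)
  dat$group <- factor(dat$group, levels = c("control", "experimental"))
  dat$plant_uid <- interaction(dat$species, dat$plant_id, drop = TRUE)
  form <- if (scope == "combined")
    value ~ (time_z + I(time_z^2)) * group + (1 | species) + (1 | plant_uid)
  else
    value ~ (time_z + I(time_z^2)) * group + (1 | plant_id)
  .fit_lmm(form, dat, trait, paste0("time_group:", scope),
           attr(dat, "meta"))
}

#' Temperature x flowering-group interaction model
#'
#' Tests whether early- and late-flowering species respond differently to
#' temperature: `value ~ (temp + temp^2) * flowering_group` with random
#' intercepts for species and plant-within-species, on the pooled
#' standardization scale so species are comparable.
#'
#' @param plant_days plant-day table across species (experimental group).
#' @param trait trait name.
#' @param grouping named character vector mapping species to `"early"` /
#'   `"late"` (see [assign_flowering_group()]).
#' @param drop_quadratic omit the squared temperature terms (used for the
#'   concentration trait, whose response is linear).
#' @return a `mixed_fit`.
#' @export
fit_flowering_group_model <- function(plant_days, trait, grouping,
                                      drop_quadratic = FALSE) {
  pd <- plant_days[plant_days$group != "control", ]
  dat <- prepare_trait_data(pd, trait, scope = "pooled")
  dat$fgroup <- factor(unname(grouping[as.character(dat$species)]),
                       levels = c("early", "late"))
  if (anyNA(dat$fgroup))
    stop("grouping must cover every species present", call. = FALSE)
  tab <- table(unique(dat[c("species", "fgroup")])$fgroup)
  if (any(tab < 2))
    warning("a flowering group has < 2 species; interaction poorly identified")
  dat$plant_uid <- interaction(dat$species, dat$plant_id, drop = TRUE)
  form <- if (drop_quadratic)
    value ~ temp_z * fgroup + (1 | species) + (1 | plant_uid)
  else
    value ~ (temp_z + I(temp_z^2)) * fgroup + (1 | species) + (1 | plant_uid)
  .fit_lmm(form, dat, trait, "flowering_group", attr(dat, "meta"))
}

#' Compare a simple and a quadratic model by AIC
#'
#' Refits both models by maximum likelihood (AIC on REML fits is not
#' comparable across fixed-effect structures) and returns the winner.
#'
#' @param fit_simple,fit_quadratic `mixed_fit` objects on the same data and
#'   random structure.
#' @return list with `chosen` (`"simple"` or `"quadratic"`), `delta_aic`
#'   (AIC simple - AIC quadratic), and both ML AIC values.
#' @export
aic_select <- function(fit_simple, fit_quadratic) {
  if (fit_simple$n_obs != fit_quadratic$n_obs ||
      !isTRUE(all.equal(sort(fit_simple$data$value),
                        sort(fit_quadratic$data$value))))
    stop("comparison error: fits are not on the same data", call. = FALSE)
  notes <- character()
  ml_aic <- function(f, label) {
    if (inherits(f$model, "merMod")) {
      m <- withCallingHandlers(
        if (lme4::isREML(f$model)) lme4::refitML(f$model) else f$model,
        warning = function(w) {
          notes <<- c(notes, paste0(label, " ML refit: ",
                                    conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      stats::AIC(m)
    } else {
      stats::AIC(f$model)
    }
  }
  a_s <- ml_aic(fit_simple, "simple")
  a_q <- ml_aic(fit_quadratic, "quadratic")
  list(chosen = if (a_q < a_s) "quadratic" else "simple",
       delta_aic = a_s - a_q, aic_simple = a_s, aic_quadratic = a_q,
       notes = notes)
}

#' Marginal and conditional R2 of a mixed fit
#'
#' Variance decomposition for Gaussian mixed models: the marginal R2 is the
#' variance of the fixed-effect predictions over the total (fixed + summed
#' random-intercept variances + residual); the conditional R2 adds the
#' random variances to the numerator.
#'
#' @param fit a `mixed_fit`.
#' @return list with `r2m` and `r2c`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!fit$converged)
    stop("fit did not converge; R2 not defined", call. = FALSE)
  r2 <- .r2_components(fit$fixed_pred, fit$varcomp, fit$sigma2)
  list(r2m = unname(r2["r2m"]), r2c = unname(r2["r2c"]))
}
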