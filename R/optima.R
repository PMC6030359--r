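# Thermal optimum and 5%-band optimal temperature range of a fitted
# quadratic response, with shape classification.

.fit_quad_coefs <- function(fit) {
  cf <- fit$coefficients[, "Estimate"]
  b0 <- unname(cf["(Intercept)"])
  b1 <- unname(cf[grep("^temp_z$", names(cf))])
  b2v <- cf[grep("temp_z\\^2", names(cf))]
  b2 <- if (length(b2v)) unname(b2v[1]) else 0
  if (length(b1) == 0) b1 <- 0
  c(b0 = b0, b1 = b1, b2 = b2)
}

.fit_temp_meta <- function(fit) {
  m <- fit$meta
  if (!is.null(m$by_species))
    stop("fit metadata spans several species; refit per species",
         call. = FALSE)
  list(center = m$temp_center, scale = m$temp_scale)
}

#' Classify the shape of a fitted temperature response
#'
#' Sign rule on the point estimates: negative quadratic coefficient is
#' concave/unimodal (an optimum exists), positive is convex, a quadratic
#' coefficient that is absent or numerically zero leaves a linear trend
#' classified by the sign of the linear coefficient, and both near zero is
#' flat. Shapes are assigned regardless of significance; the quadratic
#' term's p-value rides along as an annotation.
#'
#' @param fit a `mixed_fit` of a quadratic (or simple) temperature model.
#' @param alpha significance level for the annotation (default 0.05).
#' @param tol numerical tolerance below which a coefficient counts as zero.
#' @return list with `shape` (one of `"unimodal_concave"`,
#'   `"unimodal_convex"`, `"linear_increasing"`, `"linear_decreasing"`,
#'   `"flat"`), `p_quadratic` (NA when no quadratic term), `significant`.
#' @export
classify_shape <- function(fit, alpha = 0.05, tol = 1e-10) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!fit$converged)
    stop("fit did not converge; shape undefined", call. = FALSE)
  co <- .fit_quad_coefs(fit)
  p_quad <- {
    i <- grep("temp_z\\^2", rownames(fit$coefficients))
    if (length(i)) fit$coefficients[i[1], "p value"] else NA_real_
  }
  shape <- if (abs(co["b2"]) > tol) {
    if (co["b2"] < 0) "unimodal_concave" else "unimodal_convex"
  } else if (abs(co["b1"]) > tol) {
    if (co["b1"] > 0) "linear_increasing" else "linear_decreasing"
  } else "flat"
  list(shape = shape, p_quadratic = p_quad,
       significant = isTRUE(p_quad < alpha))
}

#' Thermal optimum of a fitted quadratic response
#'
#' Vertex of the fitted parabola on the standardized temperature scale,
#' `x* = -b1 / (2 b2)`, mapped back to degC through the stored
#' standardization. For convex fits the vertex is the minimum and is
#' reported analogously.
#'
#' @param fit a `mixed_fit` with a quadratic temperature term.
#' @return list with `T_opt` (degC), `x_opt` (standardized),
#'   `extrapolated` (`TRUE` when the vertex lies outside the observed
#'   temperature range), `shape`.
#' @export
optimum_temperature <- function(fit) {
  co <- .fit_quad_coefs(fit)
  if (abs(co["b2"]) < 1e-12)
    stop("no optimum: quadratic coefficient is zero (linear response)",
         call. = FALSE)
  tm <- .fit_temp_meta(fit)
  x_opt <- -co["b1"] / (2 * co["b2"])
  rng <- fit$observed_tempz_range
  list(T_opt = unname(destandardize_temperature(x_opt, tm$center, tm$scale)),
       x_opt = unname(x_opt),
       extrapolated = x_opt < rng[1] || x_opt > rng[2],
       shape = if (co["b2"] < 0) "unimodal_concave" else "unimodal_convex")
}

#' 5%-band optimal temperature range
#'
#' The optimal range is the temperature interval over which the fitted
#' curve stays within a band of height 5% of the measured trait-value range
#' below the fitted maximum. With `delta = 0.05 * (max - min)` of the
#' observed trait on the model scale, the interval around the vertex solves
#' the quadratic exactly: `x = x* +/- sqrt(delta / |b2|)`, mapped back to
#' degC. For convex fits the band sits above the minimum (same formula on
#' the negated curve). By default the analytic interval is reported without
#' truncation to the tested temperature range; `truncate = TRUE` clips it.
#'
#' @param fit a `mixed_fit` with a quadratic temperature term.
#' @param observed_min,observed_max observed trait range on the model
#'   (transformed, standardized) scale; defaults to the range of the data
#'   the model was fitted to.
#' @param band fraction of the trait range defining the band height
#'   (default 0.05).
#' @param truncate clip the interval to the observed temperature range.
#' @param alpha significance level for the annotation.
#' @return an `optimal_range` list: `trait`, `species`, `T_opt`, `T_lo`,
#'   `T_hi`, `delta`, `shape`, `p_quadratic`, `significant`,
#'   `extrapolated`, `truncated`.
#' @export
optimal_range <- function(fit, observed_min = NULL, observed_max = NULL,
                          band = 0.05, truncate = FALSE, alpha = 0.05) {
  sh <- classify_shape(fit, alpha = alpha)
  if (!sh$shape %in% c("unimodal_concave", "unimodal_convex"))
    stop("no optimal range: response is ", sh$shape,
         " (optimum undefined for linear shapes)", call. = FALSE)
  if (is.null(observed_min)) observed_min <- fit$observed_value_range[1]
  if (is.null(observed_max)) observed_max <- fit$observed_value_range[2]
  if (observed_max <= observed_min)
    stop("observed trait range must have positive width", call. = FALSE)
  co <- .fit_quad_coefs(fit)
  tm <- .fit_temp_meta(fit)
  opt <- optimum_temperature(fit)
  delta <- band * (observed_max - observed_min)
  half_z <- sqrt(delta / abs(co["b2"]))
  x_lo <- opt$x_opt - half_z
  x_hi <- opt$x_opt + half_z
  if (truncate) {
    rng <- fit$observed_tempz_range
    x_lo <- max(x_lo, rng[1])
    x_hi <- min(x_hi, rng[2])
  }
  structure(
    list(trait = fit$trait,
         species = sub("^species:", "", fit$scope),
         T_opt = opt$T_opt,
         T_lo = unname(destandardize_temperature(x_lo, tm$center, tm$scale)),
         T_hi = unname(destandardize_temperature(x_hi, tm$center, tm$scale)),
         delta = unname(delta),
         shape = sh$shape,
         p_quadratic = sh$p_quadratic,
         significant = sh$significant,
         extrapolated = opt$extrapolated,
         truncated = truncate),
    class = "optimal_range")
}

#' @export
print.optimal_range <- function(x, ...) {
  cat(sprintf("%s / %s: T_opt %.1f degC (%.1f-%.1f), %s%s%s\n",
              x$species, x$trait, x$T_opt, x$T_lo, x$T_hi, x$shape,
              if (x$significant) "" else " (ns)",
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Map a standardized temperature back to degC
#'
#' @param x standardized value(s).
#' @param mean,sd the standardization center (degC) and scale (degC).
#' @return `mean + sd * x`.
#' @export
destandardize_temperature <- function(x, mean, sd) {
  if (!is.numeric(sd) || any(sd <= 0))
    stop("sd must be > 0", call. = FALSE)
  mean + sd * x
}

#' Optima summary table across fits
#'
#' Formats per species x trait optimal ranges as delimited-text-ready rows
#' with `"T_opt (T_lo-T_hi)"` strings rounded to one decimal, the shape
#' symbol and the significance annotation; traits with linear responses get
#' a missing optimum and their shape only.
#'
#' @param fits list of `mixed_fit` objects.
#' @param truncate passed to [optimal_range()].
#' @return data.frame with one row per fit.
#' @export
optima_table <- function(fits, truncate = FALSE) {
  symbol <- c(unimodal_concave = "\u2229", unimodal_convex = "\u222a",
              linear_increasing = "/", linear_decreasing = "\\",
              flat = "-")
  rows <- lapply(fits, function(f) {
    sh <- classify_shape(f)
    base <- data.frame(species = sub("^species:", "", f$scope),
                       trait = f$trait,
                       shape = unname(symbol[sh$shape]),
                       significant = sh$significant,
                       p_quadratic = sh$p_quadratic)
    if (sh$shape %in% c("unimodal_concave", "unimodal_convex")) {
      orng <- optimal_range(f, truncate = truncate)
      base$T_opt <- round(orng$T_opt, 1)
      base$T_lo <- round(orng$T_lo, 1)
      base$T_hi <- round(orng$T_hi, 1)
      base$display <- sprintf("%.1f (%.1f-%.1f)", orng$T_opt, orng$T_lo,
                              orng$T_hi)
      base$extrapolated <- orng$extrapolated
    } else {
      base$T_opt <- NA_real_; base$T_lo <- NA_real_; base$T_hi <- NA_real_
      base$display <- "-"
      base$extrapolated <- NA
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
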