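#' Bottom-water conditions at the core-top calibration locations
#'
#' Environmental records for the nine core-top sampling locations used in
#' the pore-density vs bottom-water-nitrate calibration: nitrate
#' (umol/kg), water depth (m), salinity, oxygen (umol/kg) and temperature
#' (degrees C) at Costa Rica (Quepos Slide), Sagami Bay, and seven
#' Peruvian oxygen-minimum-zone multicorer stations.
#'
#' @return data.frame with columns location, nitrate, water_depth,
#'   salinity, oxygen, temperature.
#' @export
coretop_env <- function() {
  data.frame(
    location = c("Costa Rica (SO206-43-MUC)", "Sagami Bay push core (Japan)",
                 "M77/1-455/MUC-21", "M77/1-565/MUC-60", "M77/1-445/MUC-15",
                 "M77/1-487/MUC-39", "M77/1-459/MUC-25", "M77/1-604/MUC-74",
                 "M77/1-516/MUC-40"),
    nitrate     = c(39.1, 42.2, 34.0, 40.1, 40.8, 38.8, 41.0, 40.8, 36.1),
    water_depth = c(568, 1410, 465, 640, 928, 579, 698, 878, 513),
    salinity    = c(34.69, 34.50, 34.64, 34.56, 34.56, 34.55, 34.57, 34.53,
                    34.60),
    oxygen      = c(9.53, 56.40, 2.42, 8.17, 36.77, 3.70, 12.55, 34.23,
                    2.40),
    temperature = c(7.47, 2.30, 8.12, 6.70, 4.76, 7.21, 6.68, 5.72, 8.05),
    stringsAsFactors = FALSE)
}

#' Species for which the nitrate calibration applies
#' @name calibration_species
#' @export
applicable_species <- c("B. spissa", "B. subadvena")

#' @rdname calibration_species
#' @export
excluded_species <- c("B. subadvena accumeata", "B. argentea")

#' Assemble calibration points
#'
#' @param location,species character vectors.
#' @param pore_density_mean location-mean pore densities, pores/um^2.
#' @param pore_density_sem 1-SEM uncertainties of the means.
#' @param nitrate bottom-water nitrate, umol/kg.
#' @return data.frame of class \code{calibration_points}.
#' @export
calibration_points <- function(location, species, pore_density_mean,
                               pore_density_sem, nitrate) {
  if (any(pore_density_mean <= 0)) stopf("pore densities must be > 0")
  if (any(pore_density_sem < 0)) stopf("pore density SEMs must be >= 0")
  if (any(nitrate < 0)) stopf("nitrate must be >= 0")
  structure(data.frame(location = location, species = species,
                       pore_density_mean = pore_density_mean,
                       pore_density_sem = pore_density_sem,
                       nitrate = nitrate, stringsAsFactors = FALSE),
            class = c("calibration_points", "data.frame"))
}

#' Fit the pore-density to bottom-water-nitrate transfer function
#'
#' Unweighted ordinary least squares of nitrate on location-mean pore
#' density over core-top calibration points. Only the species for which
#' the calibration is valid (\emph{B. spissa}, \emph{B. subadvena}) may
#' enter the fit; the fine-pored \emph{B. subadvena accumeata} and
#' \emph{B. argentea} have distinctly offset pore densities and are
#' rejected.
#'
#' @param points a \code{\link{calibration_points}} data.frame.
#' @return Object of class \code{calibration_model}: slope and intercept
#'   with SEs, coefficient covariance, R-squared, p, n, and the species
#'   whitelist.
#' @export
fit_calibration <- function(points) {
  bad <- setdiff(unique(points$species), applicable_species)
  if (length(bad))
    stopf("calibration restricted to %s; excluded species present: %s",
          paste(applicable_species, collapse = ", "),
          paste(bad, collapse = ", "))
  if (nrow(points) < 3L) stopf("need at least 3 calibration points")
  fit <- ols_fit(points$pore_density_mean, points$nitrate)
  structure(list(slope = fit$slope, slope_se = fit$slope_se,
                 intercept = fit$intercept, intercept_se = fit$intercept_se,
                 coef_cov = fit$coef_cov, r_squared = fit$r_squared,
                 p = fit$p_slope, n = fit$n,
                 residual_sd = fit$residual_sd,
                 pd_mean = mean(points$pore_density_mean),
                 applicable_species = applicable_species,
                 excluded_species = excluded_species,
                 source = "fitted"),
            class = "calibration_model")
}

#' The published transfer-function coefficients
#'
#' The calibration in its published form: nitrate = -3896 (+/- 350) PD +
#' 61 (+/- 1) umol/kg, R-squared 0.93 over 9 core-top points. The
#' coefficient covariance is not published and is taken as zero;
#' prediction SEs from this model therefore omit the (negative)
#' covariance term and are slightly conservative near the calibration
#' mean.
#'
#' @return a \code{calibration_model}.
#' @export
published_calibration <- function() {
  structure(list(slope = -3896, slope_se = 350,
                 intercept = 61, intercept_se = 1,
                 coef_cov = matrix(c(1, 0, 0, 350^2), 2, 2,
                                   dimnames = list(c("intercept", "slope"),
                                                   c("intercept", "slope"))),
                 r_squared = 0.93, p = 1.4e-6, n = 9,
                 residual_sd = NA_real_, pd_mean = NA_real_,
                 applicable_species = applicable_species,
                 excluded_species = excluded_species,
                 source = "published"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model (%s)> NO3 = %.0f (+/- %.0f) PD + %.0f (+/- %.0f) umol/kg, R^2 = %.2f, n = %d\n",
              x$source, x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$r_squared, x$n))
  invisible(x)
}

#' Predict bottom-water nitrate from pore density
#'
#' Evaluates the transfer function at a specimen-set mean pore density
#' and propagates uncertainty to first order: coefficient covariance plus
#' the slope^2 * pd_sem^2 term. Prediction is refused for species outside
#' the calibration's applicability set unless \code{override = TRUE}
#' (which always warns).
#'
#' @param model a \code{calibration_model}.
#' @param pd mean pore density, pores/um^2.
#' @param pd_sem 1-SEM uncertainty of pd.
#' @param species species name.
#' @param override allow excluded species (warns).
#' @param interval if TRUE, additionally return a t-based 95% prediction
#'   interval including residual variance (fitted models only).
#' @return list: nitrate (umol/kg), se, and optionally lower/upper.
#' @export
predict_nitrate <- function(model, pd, pd_sem = 0, species = "B. spissa",
                            override = FALSE, interval = FALSE) {
  if (!inherits(model, "calibration_model")) stopf("not a calibration_model")
  if (!species %in% model$applicable_species) {
    if (!override)
      stopf("calibration not applicable to %s (valid for: %s); the pore density of this species is offset from the transfer function",
            species, paste(model$applicable_species, collapse = ", "))
    warnf("overriding species applicability guard for %s", species)
  }
  est <- model$slope * pd + model$intercept
  v <- model$coef_cov[1, 1] + pd^2 * model$coef_cov[2, 2] +
    2 * pd * model$coef_cov[1, 2] + model$slope^2 * pd_sem^2
  out <- list(nitrate = est, se = sqrt(v))
  if (interval) {
    if (is.na(model$residual_sd))
      stopf("prediction intervals need a fitted model with residual variance")
    vp <- v + model$residual_sd^2
    tq <- qt(0.975, df = model$n - 2)
    out$lower <- est - tq * sqrt(vp)
    out$upper <- est + tq * sqrt(vp)
  }
  out
}

#' Screen environmental covariates against pore density
#'
#' Regresses location-mean pore density on each environmental covariate
#' (oxygen, temperature, salinity, water depth) and on nitrate, joining
#' calibration points to environmental records by location. Flags
#' whether nitrate shows the strongest correlation (largest R-squared),
#' the condition for treating pore density as a nitrate rather than an
#' oxygen/temperature proxy. A covariate with no variance is reported as
#' degenerate without failing the others.
#'
#' @param points a \code{\link{calibration_points}} data.frame.
#' @param env an environmental table as from \code{\link{coretop_env}}.
#' @return list with \code{fits} (named list of regression_result or
#'   degenerate-covariate error message), \code{r_squared} (named
#'   vector) and \code{nitrate_strongest} (logical).
#' @export
covariate_screen <- function(points, env) {
  i <- match(points$location, env$location)
  if (any(is.na(i)))
    stopf("locations missing from environmental table: %s",
          paste(points$location[is.na(i)], collapse = ", "))
  env <- env[i, ]
  covs <- c("nitrate", "oxygen", "temperature", "salinity", "water_depth")
  fits <- lapply(covs, function(v)
    tryCatch(ols_fit(env[[v]], points$pore_density_mean),
             error = function(e) conditionMessage(e)))
  names(fits) <- covs
  r2 <- vapply(fits, function(f)
    if (inherits(f, "regression_result")) f$r_squared else NA_real_, 0)
  list(fits = fits, r_squared = r2,
       nitrate_strongest = is.finite(r2["nitrate"]) &&
         all(r2["nitrate"] > r2[-1], na.rm = TRUE))
}
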