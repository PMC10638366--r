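#' Measure individual pores within an ROI
#'
#' A pore belongs to the measurement region iff its centroid lies inside
#' the ROI mask; an included pore contributes its full area (pixel count
#' times pixel area), so pore areas are never clipped at the ROI
#' boundary. Eccentricity comes from the second central moments of the
#' pore's pixels.
#'
#' @param labelmap a \code{\link{pore_labelmap}}.
#' @param roi a \code{\link{select_roi}} result (or any list with a
#'   logical \code{mask}).
#' @param pixel_size micrometers per pixel.
#' @return data.frame with columns pore_id, area_um2, centroid_row,
#'   centroid_col (0-based pixel coordinates), eccentricity.
#' @export
measure_pores <- function(labelmap, roi, pixel_size) {
  if (!identical(dim(labelmap$labels), dim(roi$mask)))
    stopf("label map and ROI mask are misaligned")
  nr <- nrow(labelmap$labels)
  idx <- which(labelmap$labels > 0L)
  empty <- data.frame(pore_id = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      eccentricity = numeric(0))
  if (length(idx) == 0L) return(empty)
  lab <- labelmap$labels[idx]
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  n <- tabulate(lab)
  cr <- rowsum(rr, lab)[, 1] / n
  ccol <- rowsum(cc, lab)[, 1] / n
  # centroid-in-ROI rule (centroid rounded to nearest pixel)
  crr <- pmin(pmax(round(cr), 1), nr)
  crc <- pmin(pmax(round(ccol), 1), ncol(labelmap$labels))
  inside <- roi$mask[cbind(crr, crc)]
  keep <- which(inside)
  if (length(keep) == 0L) return(empty)
  # second central moments -> eccentricity
  mrr <- rowsum((rr - cr[lab])^2, lab)[, 1] / n
  mcc <- rowsum((cc - ccol[lab])^2, lab)[, 1] / n
  mrc <- rowsum((rr - cr[lab]) * (cc - ccol[lab]), lab)[, 1] / n
  tr <- mrr + mcc
  det_ <- sqrt(pmax((mrr - mcc)^2 + 4 * mrc^2, 0))
  l1 <- (tr + det_) / 2
  l2 <- pmax((tr - det_) / 2, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  data.frame(pore_id = keep,
             area_um2 = n[keep] * pixel_size^2,
             centroid_row = cr[keep] - 1,
             centroid_col = ccol[keep] - 1,
             eccentricity = pmin(ecc[keep], 1 - 1e-12))
}

#' Specimen-level pore parameters
#'
#' Computes the three core pore parameters inside the measurement region:
#' pore density PD = n / area (pores/um^2), mean pore size MPS =
#' arithmetic mean pore area (um^2), and porosity = 100 * total pore area
#' / ROI area (%). The per-specimen identity porosity = 100 * PD * MPS
#' holds by construction to machine precision. MPS is reported missing
#' (NA, with a warning) for poreless specimens rather than 0, so
#' downstream regressions are not corrupted.
#'
#' @param records per-pore table from \code{\link{measure_pores}}.
#' @param roi the \code{\link{select_roi}} result used for measurement.
#' @param specimen_id,location,species specimen metadata; species one of
#'   "B. spissa", "B. subadvena", "B. subadvena accumeata",
#'   "B. argentea", "other".
#' @return one-row data.frame: specimen_id, location, species,
#'   roi_area_um2, n_pores, pore_density, mean_pore_size_um2,
#'   porosity_pct.
#' @export
specimen_params <- function(records, roi, specimen_id = "specimen",
                            location = NA_character_,
                            species = "B. spissa") {
  n <- nrow(records)
  pd <- n / roi$area
  if (n == 0L) {
    warnf("specimen '%s' has no pores: MPS undefined", specimen_id)
    mps <- NA_real_
    porosity <- 0
  } else {
    mps <- mean(records$area_um2)
    porosity <- 100 * pd * mps
  }
  data.frame(specimen_id = specimen_id, location = location,
             species = species, roi_area_um2 = roi$area,
             n_pores = n, pore_density = pd,
             mean_pore_size_um2 = mps, porosity_pct = porosity,
             stringsAsFactors = FALSE)
}

#' Summarize specimens of one location
#'
#' Mean, sample SD (n - 1 denominator) and SEM = SD/sqrt(n) of pore
#' density, mean pore size and porosity across the specimens of a single
#' location. SD and SEM are reported missing for n = 1.
#'
#' @param specimens data.frame of rows from \code{\link{specimen_params}},
#'   all sharing one location.
#' @return one-row data.frame with n and mean/sd/sem per parameter.
#' @export
summarize_location <- function(specimens) {
  if (nrow(specimens) == 0L) stopf("no specimens to summarize")
  loc <- unique(specimens$location)
  if (length(loc) != 1L)
    stopf("specimens span multiple locations: %s", paste(loc, collapse = ", "))
  n <- nrow(specimens)
  one <- function(x) {
    if (n >= 2L) c(mean = mean(x), sd = sd(x), sem = sd(x) / sqrt(n))
    else c(mean = mean(x), sd = NA_real_, sem = NA_real_)
  }
  pd <- one(specimens$pore_density)
  mps <- one(specimens$mean_pore_size_um2)
  por <- one(specimens$porosity_pct)
  data.frame(location = loc, n = n,
             pd_mean = pd["mean"], pd_sd = pd["sd"], pd_sem = pd["sem"],
             mps_mean = mps["mean"], mps_sd = mps["sd"], mps_sem = mps["sem"],
             porosity_mean = por["mean"], porosity_sd = por["sd"],
             porosity_sem = por["sem"],
             row.names = NULL, stringsAsFactors = FALSE)
}
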