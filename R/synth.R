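#' Specification for a synthetic bolivinid SEM specimen
#'
#' Defines the geometry, pore statistics and imaging artifacts of one
#' synthetic specimen. The rendered morphology is a biserial test:
#' chambers alternate left/right of a midline running down from the apex
#' (the oldest, proloculus end), with chamber areas growing geometrically
#' at ratio \code{chamber_growth}, so the ontogenetic chamber order is
#' well defined. Pores are dark ellipses on the brighter shell; pore areas
#' are drawn log-normally from \code{pore_area_mean} and
#' \code{pore_area_cv}, and placement is rejection-sampled so pores never
#' overlap.
#'
#' @param seed integer seed; identical seed and spec give bit-identical
#'   output.
#' @param image_shape integer (rows, cols) of the rendered raster.
#' @param pixel_size physical pixel edge in micrometers per pixel.
#' @param n_chambers number of chambers.
#' @param chamber_growth ratio (> 1) of successive chamber areas.
#' @param first_chamber_area area of the oldest chamber in square
#'   micrometers; sets the absolute scale of the test.
#' @param target_pore_density pores per square micrometer of test area.
#' @param pore_area_mean mean individual pore area, square micrometers.
#' @param pore_area_cv coefficient of variation of pore area (0 gives
#'   identical pores).
#' @param pore_eccentricity_range interval in [0, 1) from which pore
#'   eccentricities are drawn uniformly.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise, on the [0, 1] intensity scale.
#' @param debris_count number of bright debris particles to deposit on the
#'   shell. Debris occludes any pore it touches; occluded pores are
#'   excluded from the visible pore mask and flagged in the ground truth.
#' @param debris_size_range (min, max) debris particle area, square
#'   micrometers.
#' @param curvature_shading logical; multiplicative cosine intensity
#'   falloff toward the lateral test edges, emulating a curved surface.
#' @param shell_level,background_level,pore_contrast rendering intensities
#'   on [0, 1]: shell brightness, carbon-pad background brightness, and
#'   how much darker a pore is than the shell.
#' @param bit_depth 8 or 16; intensities are quantized to this depth.
#'
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L,
                           image_shape = c(1280L, 448L),
                           pixel_size = 0.6,
                           n_chambers = 14L,
                           chamber_growth = 1.1,
                           first_chamber_area = 3800,
                           target_pore_density = 0.004,
                           pore_area_mean = 17.83,
                           pore_area_cv = 0.35,
                           pore_eccentricity_range = c(0.3, 0.8),
                           noise_sigma = 0.03,
                           debris_count = 3L,
                           debris_size_range = c(20, 80),
                           curvature_shading = FALSE,
                           shell_level = 0.75,
                           background_level = 0.15,
                           pore_contrast = 0.45,
                           bit_depth = 16L) {
  spec <- list(seed = as.integer(seed),
               image_shape = as.integer(image_shape),
               pixel_size = pixel_size,
               n_chambers = as.integer(n_chambers),
               chamber_growth = chamber_growth,
               first_chamber_area = first_chamber_area,
               target_pore_density = target_pore_density,
               pore_area_mean = pore_area_mean,
               pore_area_cv = pore_area_cv,
               pore_eccentricity_range = pore_eccentricity_range,
               noise_sigma = noise_sigma,
               debris_count = as.integer(debris_count),
               debris_size_range = debris_size_range,
               curvature_shading = isTRUE(curvature_shading),
               shell_level = shell_level,
               background_level = background_level,
               pore_contrast = pore_contrast,
               bit_depth = as.integer(bit_depth))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$pixel_size <= 0) stopf("pixel_size must be > 0")
  if (any(spec$image_shape < 64L)) stopf("image_shape must be at least 64 x 64")
  if (spec$n_chambers < 1L) stopf("n_chambers must be >= 1")
  if (spec$chamber_growth <= 1) stopf("chamber_growth must be > 1")
  if (spec$first_chamber_area <= 0) stopf("first_chamber_area must be > 0")
  if (spec$target_pore_density < 0) stopf("target_pore_density must be >= 0")
  if (spec$pore_area_mean <= 0) stopf("pore_area_mean must be > 0")
  if (spec$pore_area_cv < 0) stopf("pore_area_cv must be >= 0")
  e <- spec$pore_eccentricity_range
  if (length(e) != 2L || e[1] < 0 || e[2] >= 1 || e[1] > e[2])
    stopf("pore_eccentricity_range must be an interval inside [0, 1)")
  if (spec$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (!spec$bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  invisible(spec)
}

#' Construct a calibrated SEM image object
#'
#' @param pixels numeric matrix of intensities in [0, 1], rows = image
#'   rows.
#' @param pixel_size micrometers per pixel (> 0).
#' @param id specimen identifier string.
#' @param bit_depth declared bit depth (8 or 16).
#' @return An object of class \code{sem_image}.
#' @export
sem_image <- function(pixels, pixel_size, id = "specimen", bit_depth = 16L) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (any(dim(pixels) < 64L)) stopf("image must be at least 64 x 64 pixels")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stopf("intensities must lie in [0, 1] (got range %.3g..%.3g)",
          rng[1], rng[2])
  structure(list(pixels = pixels, pixel_size = pixel_size, id = id,
                 bit_depth = as.integer(bit_depth)),
            class = "sem_image")
}

#' @export
print.sem_image <- function(x, ...) {
  cat(sprintf("<sem_image '%s'> %d x %d px, %.3g um/px, %d-bit\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$bit_depth))
  invisible(x)
}

# --- chamber layout ---------------------------------------------------------

# Biserial layout: ellipse centers alternate left/right of the vertical
# midline, advancing down from the apex, with areas growing geometrically.
# Returns per-chamber centers and semi-axes in pixel units.
layout_chambers <- function(spec) {
  n <- spec$n_chambers
  px2 <- spec$pixel_size^2
  areas_um <- spec$first_chamber_area * spec$chamber_growth^(seq_len(n) - 1)
  areas_px <- areas_um / px2
  q <- 0.78                       # ellipse aspect: ry = q * rx
  rx <- sqrt(areas_px / (pi * q))
  ry <- q * rx
  rows <- numeric(n)
  rows[1] <- ry[1] + 0.03 * spec$image_shape[1]
  if (n > 1)
    for (k in 2:n) rows[k] <- rows[k - 1] + 0.55 * (ry[k - 1] + ry[k])
  mid <- spec$image_shape[2] / 2
  cols <- mid + ifelse(seq_len(n) %% 2 == 0, 1, -1) * 0.52 * rx
  if (rows[n] + ry[n] > spec$image_shape[1] - 4 ||
      any(cols - rx < 4) || any(cols + rx > spec$image_shape[2] - 4))
    stopf("test geometry does not fit the %d x %d canvas; enlarge image_shape",
          spec$image_shape[1], spec$image_shape[2])
  list(row = rows, col = cols, rx = rx, ry = ry)
}

# Chamber label map: silhouette = morphological closing of the ellipse
# union (fills suture gaps); each silhouette pixel is assigned to the
# chamber with minimal normalized elliptical distance.
build_chamber_map <- function(spec, lay) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  n <- spec$n_chambers
  union <- matrix(FALSE, nr, nc)
  for (k in seq_len(n)) {
    r0 <- max(1L, floor(lay$row[k] - lay$ry[k])); r1 <- min(nr, ceiling(lay$row[k] + lay$ry[k]))
    c0 <- max(1L, floor(lay$col[k] - lay$rx[k])); c1 <- min(nc, ceiling(lay$col[k] + lay$rx[k]))
    rr <- r0:r1; cc <- c0:c1
    d <- outer((rr - lay$row[k])^2 / lay$ry[k]^2,
               (cc - lay$col[k])^2 / lay$rx[k]^2, "+")
    union[rr, cc] <- union[rr, cc] | (d <= 1)
  }
  sil <- EBImage::closing(as_ebi(union), EBImage::makeBrush(9, "disc"))
  sil <- from_ebi(EBImage::fillHull(sil)) > 0
  idx <- which(sil)
  pr <- (idx - 1L) %% nr + 1L
  pc <- (idx - 1L) %/% nr + 1L
  best <- rep(1L, length(idx))
  bestd <- rep(Inf, length(idx))
  for (k in seq_len(n)) {
    d <- (pr - lay$row[k])^2 / lay$ry[k]^2 + (pc - lay$col[k])^2 / lay$rx[k]^2
    upd <- d < bestd
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  labels <- matrix(0L, nr, nc)
  labels[idx] <- best
  apex <- c(round(lay$row[1] - lay$ry[1]), round(lay$col[1]))
  chamber_map(labels, ontogeny_order = seq_len(n), apex = apex)
}

#' Construct a chamber map
#'
#' A chamber map labels every on-test pixel with a chamber id (0 =
#' off-test) and carries the ontogenetic rank of each chamber (1 =
#' oldest) plus the apex (proloculus-end) pixel coordinate.
#'
#' @param labels integer matrix of chamber ids, 0 = background.
#' @param ontogeny_order integer vector: \code{ontogeny_order[label]} is
#'   the rank of that chamber, or NULL when ranks are unknown.
#' @param apex (row, col) pixel coordinate of the oldest end, or NULL.
#' @return Object of class \code{chamber_map}.
#' @export
chamber_map <- function(labels, ontogeny_order = NULL, apex = NULL) {
  labs <- sort(unique(labels[labels > 0]))
  if (!is.null(ontogeny_order)) {
    if (length(labs) && !setequal(ontogeny_order[labs],
                                  seq_along(labs)))
      stopf("ontogeny ranks must be a permutation of 1..n_chambers")
  }
  structure(list(labels = labels, ontogeny_order = ontogeny_order,
                 apex = apex),
            class = "chamber_map")
}

# --- pore placement and rasterization --------------------------------------

# Sample one pore geometry: area (um^2, log-normal around the spec mean),
# eccentricity, orientation. Areas are floored at 4 px equivalents so the
# rendered blob is resolvable, and capped at 4x the mean.
sample_pore_geometry <- function(spec) {
  if (spec$pore_area_cv > 0) {
    sdl <- sqrt(log(1 + spec$pore_area_cv^2))
    a <- rlnorm(1, log(spec$pore_area_mean) - sdl^2 / 2, sdl)
  } else a <- spec$pore_area_mean
  a <- min(max(a, 4 * spec$pixel_size^2), 4 * spec$pore_area_mean)
  e <- runif(1, spec$pore_eccentricity_range[1], spec$pore_eccentricity_range[2])
  theta <- runif(1, 0, pi)
  list(area = a, ecc = e, theta = theta)
}

# Rasterize an ellipse as exactly n = round(area / pixel_size^2) pixels:
# the n pixels of smallest elliptical radius around the center (ties by
# raster order). Returns linear pixel indices.
rasterize_pore <- function(center, geom, pixel_size, nr, nc) {
  n_px <- max(1L, as.integer(round(geom$area / pixel_size^2)))
  alpha <- sqrt(geom$area / (pi * sqrt(1 - geom$ecc^2))) / pixel_size  # semi-major, px
  beta <- alpha * sqrt(1 - geom$ecc^2)
  ext <- ceiling(alpha) + 2L
  r0 <- max(1L, center[1] - ext); r1 <- min(nr, center[1] + ext)
  c0 <- max(1L, center[2] - ext); c1 <- min(nc, center[2] + ext)
  rr <- r0:r1; cc <- c0:c1
  dr <- rep(rr - center[1], times = length(cc))
  dc <- rep(cc - center[2], each = length(rr))
  u <- dc * cos(geom$theta) + dr * sin(geom$theta)
  v <- -dc * sin(geom$theta) + dr * cos(geom$theta)
  rho <- (u / alpha)^2 + (v / beta)^2
  if (length(rho) < n_px) return(NULL)
  ord <- order(rho, seq_along(rho))[seq_len(n_px)]
  lin <- rep(rr, times = length(cc)) + (rep(cc, each = length(rr)) - 1L) * nr
  list(idx = lin[ord], n_px = n_px, r_px = alpha)
}

# Place pores in one chamber by rejection sampling: centers uniform in the
# chamber's cell, kept clear of other pores (bounding-circle test) and of
# the silhouette boundary.
place_chamber_pores <- function(spec, cham_idx_lin, nr, n_target, placed,
                                interior_ok, chamber = NA_integer_) {
  centers <- placed$centers
  radii <- placed$radii
  out <- list()
  attempts <- 0L
  max_attempts <- 400L * max(1L, n_target)
  while (length(out) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    lin <- cham_idx_lin[sample.int(length(cham_idx_lin), 1L)]
    if (!interior_ok[lin]) next
    ctr <- c((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
    geom <- sample_pore_geometry(spec)
    alpha_px <- sqrt(geom$area / (pi * sqrt(1 - geom$ecc^2))) / spec$pixel_size
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2
      if (any(d2 < (radii + alpha_px + 2)^2)) next
    }
    out[[length(out) + 1L]] <- list(center = ctr, geom = geom)
    centers <- rbind(centers, ctr)
    radii <- c(radii, alpha_px)
  }
  if (length(out) < n_target)
    stopf("density unattainable: could not place %d non-overlapping pores in chamber %d (placed %d)",
          n_target, chamber, length(out))
  list(pores = out, centers = centers, radii = radii)
}

# --- debris -----------------------------------------------------------------

# One debris particle: union of a short random walk of discs, total area
# within the requested range, placed on the shell.
sample_debris_blob <- function(spec, on_test_lin, nr, nc) {
  target_um <- runif(1, spec$debris_size_range[1], spec$debris_size_range[2])
  target_px <- max(4L, round(target_um / spec$pixel_size^2))
  seed_lin <- on_test_lin[sample.int(length(on_test_lin), 1L)]
  ctr <- c((seed_lin - 1L) %% nr + 1L, (seed_lin - 1L) %/% nr + 1L)
  idx <- integer(0)
  r_disc <- max(2, sqrt(target_px / (pi * 3)))
  pos <- ctr
  for (i in 1:6) {
    rr <- max(1L, round(pos[1] - r_disc)):min(nr, round(pos[1] + r_disc))
    cc <- max(1L, round(pos[2] - r_disc)):min(nc, round(pos[2] + r_disc))
    dr <- rep(rr - pos[1], times = length(cc))
    dc <- rep(cc - pos[2], each = length(rr))
    lin <- rep(rr, times = length(cc)) + (rep(cc, each = length(rr)) - 1L) * nr
    idx <- union(idx, lin[dr^2 + dc^2 <= r_disc^2])
    if (length(idx) >= target_px) break
    pos <- pos + round(runif(2, -r_disc, r_disc))
    pos[1] <- min(max(pos[1], 1), nr); pos[2] <- min(max(pos[2], 1), nc)
  }
  idx
}

# --- main generator ---------------------------------------------------------

#' Generate one synthetic specimen with exact ground truth
#'
#' Renders a biserial bolivinid test as a grayscale SEM-like raster and
#' returns it together with ground truth that exactly describes what was
#' rendered: a per-pore label map, the chamber map with ontogeny order and
#' apex, the debris mask, and per-chamber pore counts and areas. Each pore
#' occupies exactly \code{round(area / pixel_size^2)} pixels, so declared
#' pore areas equal pixel counts times the pixel area, and the specimen
#' identity porosity = 100 * PD * MPS holds to machine precision. Debris
#' particles occlude any pore they touch; occluded pores are removed from
#' the visible pore mask and flagged in \code{true_params$pores}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with elements \code{image} (a \code{\link{sem_image}})
#'   and \code{truth} (pore label map, chamber map, debris mask,
#'   per-pore and per-chamber tables, and specimen-level pd / mps /
#'   porosity computed over the whole test).
#' @export
generate_specimen <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed, generate_specimen_impl(spec))
}

generate_specimen_impl <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px2 <- spec$pixel_size^2
  lay <- layout_chambers(spec)
  cmap <- build_chamber_map(spec, lay)
  on_test <- cmap$labels > 0

  # interior = on-test pixels a safe margin away from the silhouette edge,
  # so pores do not straddle the test boundary
  margin_px <- ceiling(sqrt(4 * spec$pore_area_mean / pi) / spec$pixel_size) + 2
  interior <- from_ebi(EBImage::erode(
    as_ebi(on_test), EBImage::makeBrush(2L * as.integer(margin_px) + 1L, "disc"))) > 0

  chamber_area_um <- label_areas_px(cmap$labels) * px2

  # pore placement, chamber by chamber (oldest first)
  placed <- list(centers = matrix(numeric(0), 0, 2), radii = numeric(0))
  pores <- list()
  pore_chamber <- integer(0)
  for (k in seq_len(spec$n_chambers)) {
    n_k <- round(spec$target_pore_density * chamber_area_um[k])
    if (n_k == 0) next
    cham_lin <- which(cmap$labels == k)
    res <- place_chamber_pores(spec, cham_lin, nr, n_k, placed, interior,
                               chamber = k)
    placed$centers <- res$centers
    placed$radii <- res$radii
    pores <- c(pores, res$pores)
    pore_chamber <- c(pore_chamber, rep(k, n_k))
  }

  # rasterize all pores (exact pixel counts)
  pore_mask <- matrix(0L, nr, nc)
  pore_area_um <- numeric(length(pores))
  for (i in seq_along(pores)) {
    ras <- rasterize_pore(pores[[i]]$center, pores[[i]]$geom,
                          spec$pixel_size, nr, nc)
    pore_mask[ras$idx] <- i
    pore_area_um[i] <- ras$n_px * px2
  }

  # debris: bright particles on the shell; any pore touched is swallowed
  # whole (the particle covers it) and flagged occluded
  debris_mask <- matrix(FALSE, nr, nc)
  occluded <- rep(FALSE, length(pores))
  if (spec$debris_count > 0 && any(on_test)) {
    on_test_lin <- which(on_test)
    for (b in seq_len(spec$debris_count)) {
      idx <- sample_debris_blob(spec, on_test_lin, nr, nc)
      idx <- idx[on_test[idx]]
      hit <- unique(pore_mask[idx])
      hit <- hit[hit > 0]
      for (p in hit) {
        idx <- union(idx, which(pore_mask == p))
        occluded[p] <- TRUE
      }
      debris_mask[idx] <- TRUE
    }
    pore_mask[debris_mask] <- 0L
  }

  # visible pores only, relabeled consecutively
  visible <- which(!occluded)
  vis_mask <- matrix(0L, nr, nc)
  new_id <- integer(length(pores))
  new_id[visible] <- seq_along(visible)
  keep <- pore_mask > 0
  vis_mask[keep] <- new_id[pore_mask[keep]]

  # render
  img <- matrix(spec$background_level, nr, nc)
  img[on_test] <- spec$shell_level
  suture <- on_test & (
    rbind(cmap$labels[-1, ], 0L) != cmap$labels |
    rbind(0L, cmap$labels[-nr, ]) != cmap$labels) &
    cmap$labels > 0
  img[suture] <- spec$shell_level * 0.9
  img[vis_mask > 0] <- spec$shell_level - spec$pore_contrast
  img[debris_mask] <- 0.95
  img <- from_ebi(EBImage::gblur(as_ebi(img), sigma = 0.5))  # soft edges
  if (spec$curvature_shading) {
    mid <- nc / 2
    halfw <- pmax(abs(seq_len(nc) - mid), 1)
    shade <- matrix(rep(0.75 + 0.25 * cos(pmin(abs(seq_len(nc) - mid) /
                                               (0.55 * nc), 1) * pi / 2),
                        each = nr), nr, nc)
    img <- ifelse(on_test, img * shade, img)
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  img <- pmin(pmax(img, 0), 1)
  levels <- 2^spec$bit_depth - 1
  img <- round(img * levels) / levels

  pore_tab <- data.frame(
    pore_id = seq_along(pores),
    chamber = pore_chamber,
    row = vapply(pores, function(p) p$center[1], 0),
    col = vapply(pores, function(p) p$center[2], 0),
    area_um2 = pore_area_um,
    eccentricity = vapply(pores, function(p) p$geom$ecc, 0),
    occluded = occluded)

  vis <- pore_tab[!pore_tab$occluded, ]
  per_chamber <- data.frame(
    chamber = seq_len(spec$n_chambers),
    area_um2 = chamber_area_um,
    n_pores = as.integer(tabulate(vis$chamber, spec$n_chambers)),
    pore_area_um2 = vapply(seq_len(spec$n_chambers), function(k)
      sum(vis$area_um2[vis$chamber == k]), 0))

  test_area <- sum(chamber_area_um)
  pd <- nrow(vis) / test_area
  mps <- if (nrow(vis) > 0) mean(vis$area_um2) else NA_real_
  truth <- list(
    pore_mask = pore_labelmap(vis_mask, provenance = "ground_truth"),
    chamber_map = cmap,
    debris_mask = debris_mask,
    true_params = list(pores = pore_tab, per_chamber = per_chamber),
    test_area_um2 = test_area,
    pd = pd, mps = mps,
    porosity_pct = 100 * sum(vis$area_um2) / test_area)

  id <- sprintf("synthetic-%d", spec$seed)
  list(image = sem_image(img, spec$pixel_size, id = id,
                         bit_depth = spec$bit_depth),
       truth = truth, spec = spec)
}

# --- cohorts ---------------------------------------------------------------

#' Location presets for synthetic cohorts
#'
#' Per-location normal distributions of specimen-level pore density
#' (pores/um^2) and mean pore size (um^2) from which cohort targets are
#' drawn, truncated at physical bounds. Means and SDs follow the
#' location summaries reported for Gulf of Guayaquil, Sea of Okhotsk,
#' the Mexican margin and the Costa Rica / Sagami Bay core-top samples;
#' the default preset uses the across-location means.
#'
#' @return named list of presets, each with pd_mean, pd_sd, mps_mean,
#'   mps_sd.
#' @export
cohort_presets <- function() {
  list(
    guayaquil      = list(pd_mean = 0.0043, pd_sd = 0.0008,
                          mps_mean = 17.13, mps_sd = 4.37),
    okhotsk        = list(pd_mean = 0.0052, pd_sd = 0.0008,
                          mps_mean = 20.67, mps_sd = 3.54),
    mexican_margin = list(pd_mean = 0.0050, pd_sd = 0.0010,
                          mps_mean = 18.00, mps_sd = 3.80),
    coretop        = list(pd_mean = 0.0059, pd_sd = 0.0012,
                          mps_mean = 16.00, mps_sd = 3.50),
    default        = list(pd_mean = 0.0040, pd_sd = 0.0010,
                          mps_mean = 17.83, mps_sd = 3.83))
}

# Truncation bounds: observed physical ranges of specimen parameters.
.pd_bounds <- c(0.0015, 0.009)
.mps_bounds <- c(6, 48)

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Draw per-specimen cohort targets from a location preset
#'
#' @param n number of specimens.
#' @param location_preset one of the names of \code{\link{cohort_presets}}.
#' @param seed integer seed.
#' @return data.frame with columns specimen, pd, mps (truncated-normal
#'   draws from the preset) and first_chamber_area (uniform 3,500-4,100
#'   um^2, giving specimens the natural spread of test sizes).
#' @export
draw_cohort_targets <- function(n, location_preset = "default", seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  presets <- cohort_presets()
  if (!location_preset %in% names(presets))
    stopf("unknown preset '%s' (use one of: %s)", location_preset,
          paste(names(presets), collapse = ", "))
  p <- presets[[location_preset]]
  with_seed(seed, {
    pd <- vapply(seq_len(n), function(i)
      rtruncnorm1(p$pd_mean, p$pd_sd, .pd_bounds[1], .pd_bounds[2]), 0)
    mps <- vapply(seq_len(n), function(i)
      rtruncnorm1(p$mps_mean, p$mps_sd, .mps_bounds[1], .mps_bounds[2]), 0)
    fca <- runif(n, 3500, 4100)
    data.frame(specimen = seq_len(n), pd = pd, mps = mps,
               first_chamber_area = fca)
  })
}

#' Generate a cohort of synthetic specimens
#'
#' Draws per-specimen pore density and mean pore size targets from the
#' preset's truncated normal distributions, then renders one specimen per
#' draw. Fully deterministic for a fixed seed.
#'
#' @param n number of specimens (>= 1).
#' @param location_preset preset name, see \code{\link{cohort_presets}}.
#' @param seed integer seed for the cohort.
#' @param base_spec template \code{\link{synthetic_spec}} whose geometry,
#'   noise and debris settings are reused for every specimen.
#' @return list of per-specimen lists as returned by
#'   \code{\link{generate_specimen}}; the drawn targets are attached as
#'   attribute \code{"targets"}.
#' @export
generate_cohort <- function(n, location_preset = "default", seed = 1L,
                            base_spec = synthetic_spec()) {
  targets <- draw_cohort_targets(n, location_preset, seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- child_seed(seed, i)
    sp$target_pore_density <- targets$pd[i]
    sp$pore_area_mean <- targets$mps[i]
    sp$first_chamber_area <- targets$first_chamber_area[i]
    out[[i]] <- generate_specimen(sp)
    out[[i]]$image$id <- sprintf("%s-%03d", location_preset, i)
  }
  attr(out, "targets") <- targets
  out
}
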