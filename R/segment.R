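#' Construct a pore label map
#'
#' Integer raster aligned to an SEM image: 0 = non-pore, k > 0 = pore k.
#' Labels are kept consecutive.
#'
#' @param labels integer matrix of pore labels.
#' @param provenance one of "classical", "learned", "ground_truth",
#'   "corrected".
#' @return Object of class \code{pore_labelmap}.
#' @export
pore_labelmap <- function(labels,
                          provenance = c("classical", "learned",
                                         "ground_truth", "corrected")) {
  provenance <- match.arg(provenance)
  labels <- relabel_consecutive(labels)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance),
            class = "pore_labelmap")
}

#' @export
print.pore_labelmap <- function(x, ...) {
  cat(sprintf("<pore_labelmap> %d pores, %d x %d px, provenance=%s\n",
              max(0L, max(x$labels)), nrow(x$labels), ncol(x$labels),
              x$provenance))
  invisible(x)
}

#' Number of pores in a label map
#' @param labelmap a \code{\link{pore_labelmap}}.
#' @return integer pore count.
#' @export
n_pores <- function(labelmap) max(0L, max(labelmap$labels))

#' Segmentation configuration
#'
#' @param min_pore_area smallest pore kept, square micrometers. The
#'   default of 1 is well below the smallest mean pore sizes observed for
#'   bolivinids (about 6 um^2) but keeps the tiny-pore failure mode of
#'   very fine-pored species (e.g. \emph{B. argentea}) reproducible by
#'   raising it.
#' @param max_pore_area largest pore kept, square micrometers.
#' @param threshold_method "otsu_global" (Otsu over on-test pixels of the
#'   flattened image) or "otsu_local" (adaptive local mean threshold).
#' @param split_touching logical; split touching pores by watershed on the
#'   distance transform. Off by default: well-preserved flat specimens
#'   have separated pore openings, and watershed can over-split elongated
#'   single pores.
#' @param solidity_min minimum component solidity (area / convex area);
#'   filters ragged noise blobs. 0 disables.
#' @return Object of class \code{seg_config}.
#' @export
seg_config <- function(min_pore_area = 1.0, max_pore_area = 200,
                       threshold_method = c("otsu_global", "otsu_local"),
                       split_touching = FALSE, solidity_min = 0.5) {
  threshold_method <- match.arg(threshold_method)
  if (min_pore_area <= 0 || min_pore_area >= max_pore_area)
    stopf("need 0 < min_pore_area < max_pore_area")
  structure(list(min_pore_area = min_pore_area,
                 max_pore_area = max_pore_area,
                 threshold_method = threshold_method,
                 split_touching = isTRUE(split_touching),
                 solidity_min = solidity_min),
            class = "seg_config")
}

#' Detect the test (specimen) silhouette
#'
#' Isolates the specimen from the dark carbon-pad background: global Otsu
#' threshold, largest bright 8-connected component, holes filled.
#'
#' @param image a \code{\link{sem_image}}.
#' @return logical matrix, TRUE on the test.
#' @export
detect_test_mask <- function(image) {
  px <- image$pixels
  if (diff(range(px)) < 1e-3)
    if (px[1] > 0.5) return(matrix(TRUE, nrow(px), ncol(px)))
    else stopf("no specimen found: image has no contrast")
  thr <- EBImage::otsu(as_ebi(px), range = c(0, 1))
  bright <- px > thr
  lab <- label_components(bright)
  if (max(lab) == 0L) stopf("no specimen found: nothing above threshold")
  areas <- label_areas_px(lab)
  mask <- lab == which.max(areas)
  mask <- from_ebi(EBImage::fillHull(as_ebi(mask))) > 0
  if (!any(mask)) stopf("no specimen found")
  mask
}

# Illumination flattening: subtract a large-kernel Gaussian background
# estimate, leaving local contrast. The estimate is mask-weighted
# (normalized convolution) so the dark off-test background does not bleed
# a bright halo across the silhouette edge. Sigma ~ 40 px exceeds any
# pore scale; capped so the kernel fits small frames.
flatten_illumination <- function(px, mask = NULL, sigma = 40) {
  sigma <- min(sigma, (min(dim(px)) - 3) / 7)
  if (is.null(mask)) {
    bg <- from_ebi(EBImage::gblur(as_ebi(px), sigma = sigma))
  } else {
    m <- mask * 1
    bg <- from_ebi(EBImage::gblur(as_ebi(px * m), sigma = sigma)) /
      pmax(from_ebi(EBImage::gblur(as_ebi(m), sigma = sigma)), 1e-6)
  }
  px - bg
}

# Solidity (area / convex hull area) of one component given its pixel
# coordinates; 8-connected blobs of < 3 px are fully solid by convention.
component_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(1)
  # pixel-corner cloud so single-row/col components get a real hull area
  xs <- c(cols - 0.5, cols + 0.5, cols + 0.5, cols - 0.5)
  ys <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  min(1, n / hull_area)
}

# Shared post-processing: opening -> optional watershed split -> area and
# solidity filters -> consecutive 8-connected labels.
postprocess_pore_mask <- function(binary, pixel_size, config) {
  if (!any(binary)) {
    return(pore_labelmap(matrix(0L, nrow(binary), ncol(binary)),
                         provenance = "classical"))
  }
  # open only when the smallest admissible pore survives the 3x3 kernel;
  # below that, isolated noise specks are handled by the area filter
  if (config$min_pore_area / pixel_size^2 >= 9)
    opened <- from_ebi(EBImage::opening(as_ebi(binary),
                                        EBImage::makeBrush(3, "box"))) > 0
  else opened <- binary
  if (config$split_touching && any(opened)) {
    dm <- EBImage::distmap(as_ebi(opened))
    # minimum seed separation ~ diameter of the smallest admissible pore
    tol <- max(1, sqrt(config$min_pore_area / pi) / pixel_size)
    lab <- from_ebi(EBImage::watershed(dm, tolerance = tol))
  } else {
    lab <- label_components(opened)
  }
  filter_components(lab, pixel_size, config)
}

filter_components <- function(lab, pixel_size, config) {
  storage.mode(lab) <- "integer"
  if (max(lab) > 0L) {
    px2 <- pixel_size^2
    areas <- label_areas_px(lab) * px2
    keep <- areas >= config$min_pore_area & areas <= config$max_pore_area
    if (config$solidity_min > 0 && any(keep)) {
      nr <- nrow(lab)
      idx <- which(lab > 0)
      by_lab <- split(idx, lab[idx])
      for (l in which(keep)) {
        pix <- by_lab[[as.character(l)]]
        sol <- component_solidity((pix - 1L) %% nr + 1L,
                                  (pix - 1L) %/% nr + 1L)
        if (sol < config$solidity_min) keep[l] <- FALSE
      }
    }
    lab[lab > 0L & !keep[pmax(lab, 1L)]] <- 0L
  }
  pore_labelmap(lab, provenance = "classical")
}

#' Segment pores by the classical operator chain
#'
#' Deterministic reference segmentation: illumination flattening
#' (large-kernel Gaussian background subtraction), thresholding of dark
#' pixels within the detected test mask (global Otsu over on-test pixels,
#' or an adaptive local-mean threshold), morphological opening, optional
#' watershed splitting of touching pores, then area and solidity filters
#' and 8-connected labeling.
#'
#' @param image a \code{\link{sem_image}}.
#' @param config a \code{\link{seg_config}}.
#' @param test_mask optional precomputed silhouette (logical matrix);
#'   detected when NULL.
#' @return a \code{\link{pore_labelmap}} with provenance "classical".
#' @export
segment_pores_classical <- function(image, config = seg_config(),
                                    test_mask = NULL) {
  if (!inherits(config, "seg_config")) stopf("config must be a seg_config")
  if (is.null(test_mask)) test_mask <- detect_test_mask(image)
  flat <- flatten_illumination(image$pixels, mask = test_mask)
  if (config$threshold_method == "otsu_global") {
    vals <- flat[test_mask]
    v01 <- (flat - min(vals)) / max(diff(range(vals)), 1e-12)
    thr <- EBImage::otsu(as_ebi(matrix(pmin(pmax(v01[test_mask], 0), 1))),
                         range = c(0, 1))
    # refine to the midpoint of the two class means: for a two-level
    # scene with blurred edges this tracks the half-contrast contour,
    # recovering pore areas without the systematic erosion of the raw
    # Otsu cut
    iv <- v01[test_mask]
    lo <- iv[iv < thr]; hi <- iv[iv >= thr]
    if (length(lo) && length(hi)) thr <- (mean(lo) + mean(hi)) / 2
    binary <- test_mask & (v01 < thr)
    # contrast guard: pore openings are far darker than the shell; if the
    # candidate dark class is nearly as bright as the rest of the test
    # (ratio above 0.75, invariant to intensity rescaling) the split is
    # only shell texture (sutures, shading) and the specimen is poreless
    if (any(binary)) {
      dark <- mean(image$pixels[binary])
      rest <- image$pixels[test_mask & !binary]
      if (!length(rest) || dark / mean(rest) > 0.75)
        binary[] <- FALSE
    }
  } else {
    # local mean threshold: pore pixels sit below the local average
    local_mean <- from_ebi(EBImage::gblur(as_ebi(image$pixels), sigma = 8))
    binary <- test_mask & (image$pixels < local_mean - 0.08)
  }
  postprocess_pore_mask(binary, image$pixel_size, config)
}

#' Remove artifact pixels from a pore segmentation
#'
#' Emulates the manual-correction step in which unwanted particles on the
#' test surface are erased from the automated segmentation: artifact
#' pixels are removed from the pore foreground, components are relabeled
#' and re-filtered. The pore count can only stay equal or decrease.
#'
#' @param labelmap a \code{\link{pore_labelmap}}.
#' @param artifact_mask logical matrix of artifact pixels, aligned to the
#'   label map.
#' @param pixel_size micrometers per pixel (for re-filtering).
#' @param config a \code{\link{seg_config}}.
#' @return corrected \code{\link{pore_labelmap}} (provenance
#'   "corrected").
#' @export
remove_artifacts <- function(labelmap, artifact_mask, pixel_size,
                             config = seg_config()) {
  if (!identical(dim(labelmap$labels), dim(artifact_mask)))
    stopf("artifact mask shape %s does not match label map %s",
          paste(dim(artifact_mask), collapse = "x"),
          paste(dim(labelmap$labels), collapse = "x"))
  fg <- labelmap$labels > 0L & !artifact_mask
  lab <- label_components(fg)
  out <- filter_components(lab, pixel_size, config)
  out$provenance <- "corrected"
  out
}
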