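# Multiscale filter-bank features for pixel classification: intensity,
# Gaussian scale space, difference-of-Gaussians (band-pass, pore-scale),
# local standard deviation, gradient magnitude. Returns an n_pixels x
# n_features matrix in raster order.
pixel_features <- function(px) {
  g1 <- from_ebi(EBImage::gblur(as_ebi(px), 1))
  g2 <- from_ebi(EBImage::gblur(as_ebi(px), 2))
  g4 <- from_ebi(EBImage::gblur(as_ebi(px), 4))
  g8 <- from_ebi(EBImage::gblur(as_ebi(px), 8))
  dog <- g2 - g8
  m2 <- from_ebi(EBImage::gblur(as_ebi(px^2), 2))
  lsd <- sqrt(pmax(m2 - g2^2, 0))
  nr <- nrow(px); nc <- ncol(px)
  gr <- (rbind(px[-1, ], px[nr, ]) - rbind(px[1, ], px[-nr, ])) / 2
  gc <- (cbind(px[, -1], px[, nc]) - cbind(px[, 1], px[, -nc])) / 2
  grad <- sqrt(gr^2 + gc^2)
  cbind(int = as.vector(px), g1 = as.vector(g1), g2 = as.vector(g2),
        g4 = as.vector(g4), g8 = as.vector(g8), dog = as.vector(dog),
        lsd = as.vector(lsd), grad = as.vector(grad))
}

#' Train the pore-recognition pixel classifier
#'
#' Trains a shallow pixel-classification network for binary
#' pore/non-pore semantic segmentation: each pixel is described by a
#' multiscale filter-bank feature vector (Gaussian scale space,
#' difference-of-Gaussians, local variance, gradient magnitude) and
#' classified by a single-hidden-layer neural network. Training pixels
#' are sampled from each image, stratified between pore and non-pore
#' classes. One epoch is one warm-started optimization round; the
#' training loss after each epoch is recorded in the manifest.
#'
#' @param pairs list of lists with elements \code{image} (a
#'   \code{\link{sem_image}}) and \code{labels} (a
#'   \code{\link{pore_labelmap}} giving the ground-truth pores).
#' @param epochs number of training rounds; 0 returns an untrained model
#'   with a warning.
#' @param seed integer seed controlling pixel sampling and weight
#'   initialization; training is deterministic given the seed.
#' @param hidden number of hidden units.
#' @param pixels_per_image training pixels sampled from each image.
#' @return Object of class \code{pore_model}: the fitted network, the
#'   feature normalization, the pixel size trained at, and a
#'   \code{training_manifest} (image ids, epochs, seed, loss curve).
#' @export
train_pore_model <- function(pairs, epochs = 10L, seed = 1L, hidden = 8L,
                             pixels_per_image = 1500L) {
  if (length(pairs) < 8L && epochs > 0L)
    stopf("need at least 8 training pairs (got %d)", length(pairs))
  psz <- unique(vapply(pairs, function(p) p$image$pixel_size, 0))
  if (length(psz) != 1L)
    stopf("training images must share one pixel size (got: %s)",
          paste(signif(psz, 3), collapse = ", "))
  shapes <- vapply(pairs, function(p)
    !identical(dim(p$image$pixels), dim(p$labels$labels)), TRUE)
  if (any(shapes)) stopf("image/label raster shapes mismatch in pair %d",
                         which(shapes)[1])

  model <- structure(list(fit = NULL, center = NULL, scale = NULL,
                          pixel_size = psz, trained = FALSE,
                          training_manifest = list(
                            image_ids = vapply(pairs, function(p) p$image$id, ""),
                            epochs = as.integer(epochs),
                            seed = as.integer(seed),
                            loss_curve = numeric(0))),
                     class = "pore_model")
  if (epochs <= 0L) {
    warnf("epochs = 0: returning untrained model")
    return(model)
  }

  with_seed(seed, {
    xs <- vector("list", length(pairs))
    ys <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      feats <- pixel_features(pairs[[i]]$image$pixels)
      lab <- as.vector(pairs[[i]]$labels$labels) > 0L
      pos <- which(lab); neg <- which(!lab)
      n_pos <- min(length(pos), pixels_per_image %/% 2L)
      n_neg <- min(length(neg), pixels_per_image - n_pos)
      sel <- c(if (n_pos > 0) pos[sample.int(length(pos), n_pos)],
               neg[sample.int(length(neg), n_neg)])
      xs[[i]] <- feats[sel, , drop = FALSE]
      ys[[i]] <- as.numeric(lab[sel])
    }
    x <- do.call(rbind, xs)
    y <- unlist(ys)
    ctr <- colMeans(x)
    scl <- pmax(apply(x, 2, sd), 1e-8)
    xz <- sweep(sweep(x, 2, ctr), 2, scl, "/")

    n_w <- (ncol(xz) + 1L) * hidden + hidden + 1L
    wts <- runif(n_w, -0.5, 0.5)
    loss <- numeric(epochs)
    fit <- NULL
    for (e in seq_len(epochs)) {
      fit <- nnet::nnet(xz, y, size = hidden, Wts = wts, entropy = TRUE,
                        maxit = 30L, decay = 1e-4, trace = FALSE,
                        MaxNWts = 5000L)
      wts <- fit$wts
      loss[e] <- fit$value
    }
    model$fit <- fit
    model$center <- ctr
    model$scale <- scl
    model$trained <- TRUE
    model$training_manifest$loss_curve <- loss
  })
  model
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> %s, trained at %.3g um/px on %d images, %d epochs\n",
              if (x$trained) "trained" else "UNTRAINED", x$pixel_size,
              length(x$training_manifest$image_ids),
              x$training_manifest$epochs))
  invisible(x)
}

#' Segment pores with a trained pixel-classification model
#'
#' Computes the per-pixel pore probability map, thresholds it at 0.5
#' (ties to background), restricts to the detected test mask, and applies
#' the same post-processing chain as the classical path (opening,
#' optional watershed split, area/solidity filters, labeling). Inference
#' is deterministic.
#'
#' @param image a \code{\link{sem_image}}.
#' @param model a \code{\link{train_pore_model}} result.
#' @param config a \code{\link{seg_config}}.
#' @return a \code{\link{pore_labelmap}} with provenance "learned".
#' @export
segment_pores_learned <- function(image, model, config = seg_config()) {
  if (!inherits(model, "pore_model")) stopf("model must be a pore_model")
  if (!isTRUE(model$trained)) {
    warnf("model is untrained; returning empty segmentation")
    return(pore_labelmap(matrix(0L, nrow(image$pixels), ncol(image$pixels)),
                         provenance = "learned"))
  }
  if (abs(image$pixel_size - model$pixel_size) > 1e-9 * model$pixel_size)
    warnf("image pixel size (%.3g) differs from training scale (%.3g)",
          image$pixel_size, model$pixel_size)
  feats <- pixel_features(image$pixels)
  xz <- sweep(sweep(feats, 2, model$center), 2, model$scale, "/")
  prob <- as.vector(predict(model$fit, xz))
  binary <- matrix(prob > 0.5, nrow(image$pixels), ncol(image$pixels))
  tm <- tryCatch(detect_test_mask(image), error = function(e) NULL)
  if (is.null(tm)) {
    out <- pore_labelmap(matrix(0L, nrow(image$pixels), ncol(image$pixels)),
                         provenance = "learned")
    return(out)
  }
  binary <- binary & tm
  out <- postprocess_pore_mask(binary, image$pixel_size, config)
  out$provenance <- "learned"
  out
}
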