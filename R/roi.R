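#' Order chambers ontogenetically
#'
#' Returns chamber labels in ontogeny order (oldest first). When the
#' chamber map carries explicit ranks they are passed through; otherwise
#' chambers are ranked by increasing centroid distance from the apex
#' (proloculus-end) coordinate.
#'
#' @param chambers a \code{\link{chamber_map}}.
#' @return integer vector of chamber labels, oldest first.
#' @export
order_chambers <- function(chambers) {
  labs <- sort(unique(chambers$labels[chambers$labels > 0]))
  if (length(labs) == 0L) stopf("empty chamber map")
  if (!is.null(chambers$ontogeny_order))
    return(labs[order(chambers$ontogeny_order[labs])])
  if (is.null(chambers$apex))
    stopf("chamber map has neither ontogeny ranks nor an apex coordinate")
  nr <- nrow(chambers$labels)
  d <- vapply(labs, function(l) {
    idx <- which(chambers$labels == l)
    rr <- mean((idx - 1L) %% nr + 1L)
    cc <- mean((idx - 1L) %/% nr + 1L)
    sqrt((rr - chambers$apex[1])^2 + (cc - chambers$apex[2])^2)
  }, 0)
  labs[order(d)]
}

#' Select the size-normalized measurement region
#'
#' Accumulates whole chambers from the oldest until the cumulative area
#' reaches the lower edge of the window (50,000 um^2 by default). The
#' selection is the smallest such prefix; specimens whose total area is
#' below the lower bound are rejected, as are specimens whose smallest
#' sufficient prefix overshoots the upper bound (chambers are never
#' split).
#'
#' @param chambers a \code{\link{chamber_map}}.
#' @param order chamber labels oldest-first, from
#'   \code{\link{order_chambers}}.
#' @param window (lower, upper) area window in square micrometers.
#' @param pixel_size micrometers per pixel.
#' @return Object of class \code{roi_selection}: included ranks, the ROI
#'   mask, and its area in square micrometers.
#' @export
select_roi <- function(chambers, order = order_chambers(chambers),
                       window = c(50000, 70000), pixel_size) {
  if (length(window) != 2L || window[1] >= window[2])
    stopf("window must be (lower, upper) with lower < upper")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  px2 <- pixel_size^2
  areas <- vapply(order, function(l) sum(chambers$labels == l) * px2, 0)
  total <- sum(areas)
  if (total < window[1])
    stopf("specimen too small: total chamber area %.0f um^2 < %.0f um^2",
          total, window[1])
  cum <- cumsum(areas)
  k <- which(cum >= window[1])[1]
  if (cum[k] > window[2])
    stopf("window unattainable: smallest sufficient prefix covers %.0f um^2 > %.0f um^2",
          cum[k], window[2])
  included <- order[seq_len(k)]
  mask <- matrix(chambers$labels %in% included,
                 nrow(chambers$labels), ncol(chambers$labels))
  structure(list(chamber_ranks_included = seq_len(k),
                 chambers_included = included,
                 mask = mask, area = cum[k]),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> %d oldest chambers, %.0f um^2\n",
              length(x$chamber_ranks_included), x$area))
  invisible(x)
}
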