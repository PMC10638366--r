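#' @import stats
#' @import utils
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed range R requires of set.seed().
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# matrix (row = image row) <-> EBImage orientation (first dim = x)
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

# Connected-component labeling of a logical matrix, 8-connected,
# labels 1..k in EBImage raster order.
label_components <- function(mask) {
  storage.mode(mask) <- "double"
  from_ebi(EBImage::bwlabel(as_ebi(mask)))
}

# Relabel a nonnegative integer matrix so positive labels are consecutive
# 1..k, preserving order of first appearance by original label value.
relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0L) return(lab)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- lab
  out[lab > 0] <- lut[lab[lab > 0]]
  out
}

# Per-label pixel counts of a label matrix (named by label).
label_areas_px <- function(lab) {
  pos <- lab[lab > 0]
  if (length(pos) == 0L) return(integer(0))
  tabulate(pos, nbins = max(pos))
}
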