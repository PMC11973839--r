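#' Construct a 17-segment polar-map geometry
#'
#' The default reproduces the standard AHA layout: rings at normalized radii
#' 0.25, 0.5, 0.75, 1 with 6 basal, 6 mid and 4 apical sectors plus the
#' apical cap (segment 17), angle measured counterclockwise from 12 o'clock,
#' and the apical ring rotated by 45 degrees so its four sectors straddle
#' the vertical and horizontal axes.
#'
#' Boundary pixels are assigned half-open: a pixel exactly on a radial
#' boundary belongs to the outer ring, and one exactly on an angular
#' boundary to the counterclockwise-later sector, so the segments always
#' partition the disc.
#'
#' @param boundaries increasing outer radial edges of the rings, innermost
#'   first, ending at 1.
#' @param counts integer sectors per ring, basal (outermost) ring first;
#'   must sum to 17.
#' @param offsets per-ring angular offset in degrees, basal first.
#' @return a [SegmentGeometry-class] object.
#' @examples
#' geo <- segmentGeometry()
#' @export
segmentGeometry <- function(boundaries = c(0.25, 0.5, 0.75, 1),
                            counts = c(6L, 6L, 4L, 1L),
                            offsets = c(0, 0, 45, 0)) {
  new("SegmentGeometry", boundaries = as.numeric(boundaries),
      counts = as.integer(counts), offsets = as.numeric(offsets))
}

# per-pixel segment labels (1..17) over a disc; NA outside the mask.
# rings are numbered basal-first to match `counts`/`offsets`.
.segmentLabels <- function(geometry, mask, center, radius) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("disc mask is empty")
  dy <- idx[, 1] - center[1]           # down the rows
  dx <- idx[, 2] - center[2]           # along the columns
  rn <- sqrt(dx^2 + dy^2) / radius
  # angle from 12 o'clock, counterclockwise, in [0, 360)
  ang <- (atan2(-dx, -dy) / pi * 180 + 180) %% 360
  b <- geometry@boundaries
  nr <- length(b)
  # ring from the apex outward; clamp rn == 1 into the outermost ring
  ringIn <- pmin(findInterval(rn, b), nr - 1L) + 1L
  ring <- nr - ringIn + 1L                       # basal-first index
  base <- c(0L, cumsum(geometry@counts))[ring]
  n <- geometry@counts[ring]
  off <- geometry@offsets[ring]
  sector <- floor(((ang - off) %% 360) / (360 / n)) + 1L
  lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
  lab[idx] <- base + as.integer(sector)
  lab
}

#' Pixel mask of one AHA segment
#'
#' Returns the logical grid selecting the pixels of segment
#' `segment` (1-17) inside a polar map's disc. Across segments 1-17 the
#' masks partition the disc.
#'
#' @param geometry a [SegmentGeometry-class].
#' @param map a [PolarMap-class].
#' @param segment integer segment index in 1..17.
#' @return logical matrix of the map's dimensions.
#' @export
setMethod("segmentMask", signature("SegmentGeometry", "PolarMap"),
  function(geometry, map, segment) {
    segment <- as.integer(segment)
    if (length(segment) != 1L || is.na(segment) ||
        segment < 1L || segment > 17L)
      stop("segment index must be a single integer in 1..17")
    lab <- .segmentLabels(geometry, map@mask, map@center, map@radius)
    out <- !is.na(lab) & lab == segment
    if (!any(out))
      stop("segment ", segment,
           " contains no pixels at this resolution")
    out
  })

#' @describeIn segmentMask-SegmentGeometry-PolarMap-method kind accessor
#' @export
setMethod("mapKind", "PolarMap", function(map) map@kind)

setMethod("show", "SegmentGeometry", function(object) {
  cat("SegmentGeometry:", sum(object@counts), "segments in",
      length(object@counts), "rings\n")
  cat("  radial boundaries:", paste(object@boundaries, collapse = ", "),
      "\n")
  cat("  sectors per ring (basal first):",
      paste(object@counts, collapse = ", "), "\n")
})

setMethod("show", "PolarMap", function(object) {
  v <- object@grid[object@mask]
  cat(sprintf("PolarMap (%s): %d x %d raster, %d in-disc pixels\n",
              object@kind, nrow(object@grid), ncol(object@grid),
              sum(object@mask)))
  cat(sprintf("  flow range %.3f - %.3f mL/g/min\n", min(v), max(v)))
})
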