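#' Segmentation parameters
#'
#' @param normPercentiles (low, high) intensity percentiles used for
#'   normalization; defaults 1 and 99.8.
#' @param threshold foreground threshold on the normalized image.
#' @param minRadiusPx,maxRadiusPx equivalent-radius gates in pixels.
#' @param borderPolicy \code{"exclude"} (default) removes droplets touching
#'   the field edge; \code{"keep"} retains them.
#' @param splitMinDistancePx minimum separation of watershed seeds when
#'   splitting touching droplets.
#' @param smoothSigmaPx Gaussian pre-smoothing of the normalized image
#'   (0 disables); suppresses photon-noise holes in the foreground.
#' @return list of validated parameters.
#' @export
segmentationParams <- function(normPercentiles = c(1, 99.8), threshold = 0.5,
                               minRadiusPx = 2, maxRadiusPx = 40,
                               borderPolicy = c("exclude", "keep"),
                               splitMinDistancePx = 5, smoothSigmaPx = 1) {
  stopifnot(length(normPercentiles) == 2L,
            normPercentiles[1] >= 0, normPercentiles[2] <= 100,
            normPercentiles[1] < normPercentiles[2],
            threshold > 0, threshold < 1,
            minRadiusPx > 0, maxRadiusPx >= minRadiusPx,
            splitMinDistancePx >= 1, smoothSigmaPx >= 0)
  list(normPercentiles = normPercentiles, threshold = threshold,
       minRadiusPx = minRadiusPx, maxRadiusPx = maxRadiusPx,
       borderPolicy = match.arg(borderPolicy),
       splitMinDistancePx = splitMinDistancePx,
       smoothSigmaPx = smoothSigmaPx)
}

#' Percentile-normalize an image
#'
#' Maps the low/high intensity percentiles to 0/1 and clips:
#' \code{clip((I - p_low) / (p_high - p_low), 0, 1)}. Affine-invariant, so
#' global gain/offset changes do not alter downstream masks.
#'
#' @param image numeric matrix, nonnegative.
#' @param low,high percentiles in [0, 100]; defaults 1 and 99.8.
#' @return matrix with values in [0, 1].
#' @export
normalizePercentile <- function(image, low = 1, high = 99.8) {
  stopifnot(is.matrix(image), low >= 0, high <= 100, low < high)
  p <- quantile(image, c(low, high) / 100, names = FALSE)
  if (p[2] <= p[1])
    stop("degenerate contrast: low and high percentiles coincide")
  pmin(pmax((image - p[1]) / (p[2] - p[1]), 0), 1)
}

#' Segment droplets in a red-channel image
#'
#' Classical pipeline: percentile normalization, optional Gaussian
#' smoothing, fixed threshold, hole filling, then distance-transform
#' watershed to split touching droplets. Regions outside the radius gates
#' are removed, border droplets handled per policy, and surviving labels
#' renumbered 1..K by decreasing area.
#'
#' @param image numeric matrix (red channel, one day).
#' @param params from \code{\link{segmentationParams}}.
#' @param pixelSizeUm pixel size used for radii in micrometers.
#' @return A \linkS4class{LabelMask}.
#' @export
segmentDroplets <- function(image, params = segmentationParams(),
                            pixelSizeUm = 123 / 512) {
  norm <- normalizePercentile(image, params$normPercentiles[1],
                              params$normPercentiles[2])
  if (params$smoothSigmaPx > 0)
    norm <- EBImage::gblur(norm, sigma = params$smoothSigmaPx)
  bw <- norm > params$threshold
  if (!any(bw))
    return(.labelMask(matrix(0L, nrow(image), ncol(image)), pixelSizeUm))
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = 1,
                            ext = params$splitMinDistancePx)
  lab <- matrix(as.integer(lab), nrow(image))

  # radius gates
  area <- tabulate(lab[lab > 0L])
  rad <- sqrt(area / pi)
  drop <- which(rad < params$minRadiusPx | rad > params$maxRadiusPx)
  # border policy
  if (params$borderPolicy == "exclude") {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, edge[edge > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L

  # renumber by decreasing area
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    area <- tabulate(lab, nbins = max(ids))[ids]
    remap <- integer(max(ids))
    remap[ids[order(area, decreasing = TRUE)]] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  .labelMask(lab, pixelSizeUm)
}

# Build a LabelMask with per-label centroid and equivalent radius.
.labelMask <- function(lab, pixelSizeUm) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rw <- (idx - 1L) %% nrow(lab) + 1L
    cl <- (idx - 1L) %/% nrow(lab) + 1L
    area <- as.vector(rowsum(rep(1, length(l)), l))
    props <- data.frame(
      label = ids, area_px = area,
      row = as.vector(rowsum(rw, l)) / area,
      col = as.vector(rowsum(cl, l)) / area,
      radius_px = sqrt(area / pi))
    props$radius_um <- props$radius_px * pixelSizeUm
  } else {
    props <- data.frame(label = integer(0), area_px = numeric(0),
                        row = numeric(0), col = numeric(0),
                        radius_px = numeric(0), radius_um = numeric(0))
  }
  new("LabelMask", labels = lab, props = props, pixelSizeUm = pixelSizeUm)
}

#' Continuous-phase mask
#'
#' Set complement of the union of all droplet labels: every pixel belongs
#' to exactly one of droplet or continuous phase.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return logical matrix, TRUE on continuous-phase pixels.
#' @export
invertMask <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  maskLabels(mask) == 0L
}

#' Segment every day of a field series
#'
#' @param field a \linkS4class{FieldSeries}; the red channel is segmented.
#' @param params from \code{\link{segmentationParams}}.
#' @return list of \linkS4class{LabelMask}, one per day.
#' @export
segmentSeries <- function(field, params = segmentationParams()) {
  lapply(seq_len(nDays(field)), function(d)
    segmentDroplets(getFrame(field, d, "red"), params, pixelSizeUm(field)))
}
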