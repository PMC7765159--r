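#' @import methods
#' @importFrom stats quantile rnorm rpois runif lm anova coef predict pt median sd setNames complete.cases residuals
#' @importFrom utils read.csv write.csv head
NULL

CHANNELS <- c("red", "green", "blue")

#' Multi-day, three-channel confocal field series
#'
#' Container for a time series of three-channel 2-D images of one field of
#' view: red = non-oxidized lipid (ex 640 nm), green = oxidized lipid
#' (ex 561 nm), blue = oxidized protein autofluorescence (ex 488 nm).
#' Pixel values are nonnegative integer photon counts.
#'
#' @slot intensities numeric array \code{[day, channel, row, col]} of
#'   nonnegative integer photon counts.
#' @slot dayTimes numeric vector of acquisition times in days, strictly
#'   increasing, one per day index.
#' @slot pixelSizeUm physical pixel size in micrometers.
#' @slot channels character vector naming the channel axis
#'   (\code{"red"}, \code{"green"}, \code{"blue"}).
#' @exportClass FieldSeries
setClass("FieldSeries",
  representation(
    intensities = "array",
    dayTimes    = "numeric",
    pixelSizeUm = "numeric",
    channels    = "character"
  )
)

setValidity("FieldSeries", function(object) {
  msg <- character(0)
  d <- dim(object@intensities)
  if (length(d) != 4L)
    msg <- c(msg, "intensities must be a 4-d array [day, channel, row, col]")
  else {
    if (d[2] != 3L) msg <- c(msg, "exactly three channels are required")
    if (d[1] != length(object@dayTimes))
      msg <- c(msg, "day axis length must match dayTimes")
  }
  if (!identical(object@channels, CHANNELS))
    msg <- c(msg, "channels must be c('red', 'green', 'blue')")
  if (length(object@dayTimes) > 1L && any(diff(object@dayTimes) <= 0))
    msg <- c(msg, "dayTimes must be strictly increasing")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldSeries
#'
#' @param intensities array \code{[day, channel, row, col]}.
#' @param dayTimes acquisition times in days.
#' @param pixelSizeUm pixel size in micrometers.
#' @return A \linkS4class{FieldSeries}.
#' @export
FieldSeries <- function(intensities, dayTimes, pixelSizeUm) {
  new("FieldSeries", intensities = intensities, dayTimes = as.numeric(dayTimes),
      pixelSizeUm = pixelSizeUm, channels = CHANNELS)
}

#' Per-day droplet label mask
#'
#' Integer labeling of one field image: 0 is continuous (aqueous) phase,
#' k > 0 the pixels of droplet k. Labels are numbered 1..K by decreasing
#' area. Per-label centroid (sub-pixel, 1-based row/col) and equivalent-disk
#' radius are tabulated in \code{props}.
#'
#' @slot labels integer matrix of region labels.
#' @slot props data.frame with columns \code{label}, \code{area_px},
#'   \code{row}, \code{col}, \code{radius_px}, \code{radius_um}.
#' @slot pixelSizeUm pixel size in micrometers.
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", props = "data.frame",
                 pixelSizeUm = "numeric")
)

setValidity("LabelMask", function(object) {
  msg <- character(0)
  lab <- object@labels
  if (any(lab < 0)) msg <- c(msg, "labels must be nonnegative")
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (!identical(ids, sort(object@props$label)))
    msg <- c(msg, "props must list exactly the positive labels present")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FieldSeries", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("FieldSeries: %d day(s) x 3 channels, %d x %d px (%.4g um/px)\n",
              d[1], d[3], d[4], object@pixelSizeUm))
  cat("  day times:", paste(object@dayTimes, collapse = ", "), "\n")
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d droplet(s)\n",
              nrow(object@labels), ncol(object@labels), nrow(object@props)))
})

#' @rdname FieldSeries-accessors
#' @export
setGeneric("nDays", function(x) standardGeneric("nDays"))
#' @rdname FieldSeries-accessors
#' @export
setGeneric("dayTimes", function(x) standardGeneric("dayTimes"))
#' @rdname FieldSeries-accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname FieldSeries-accessors
#' @export
setGeneric("getFrame", function(x, day, channel) standardGeneric("getFrame"))
#' @rdname LabelMask-accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname LabelMask-accessors
#' @export
setGeneric("maskProps", function(x) standardGeneric("maskProps"))
#' @rdname LabelMask-accessors
#' @export
setGeneric("nDroplets", function(x) standardGeneric("nDroplets"))

#' Accessors for FieldSeries
#'
#' @param x a \linkS4class{FieldSeries}.
#' @param day day index (1-based).
#' @param channel one of \code{"red"}, \code{"green"}, \code{"blue"}.
#' @name FieldSeries-accessors
NULL

#' @rdname FieldSeries-accessors
setMethod("nDays", "FieldSeries", function(x) dim(x@intensities)[1])
#' @rdname FieldSeries-accessors
setMethod("dayTimes", "FieldSeries", function(x) x@dayTimes)
#' @rdname FieldSeries-accessors
setMethod("pixelSizeUm", "FieldSeries", function(x) x@pixelSizeUm)
#' @rdname FieldSeries-accessors
setMethod("getFrame", "FieldSeries", function(x, day, channel) {
  ch <- match.arg(channel, CHANNELS)
  m <- x@intensities[day, match(ch, CHANNELS), , ]
  matrix(m, nrow = dim(x@intensities)[3])
})

#' Accessors for LabelMask
#'
#' @param x a \linkS4class{LabelMask}.
#' @name LabelMask-accessors
NULL

#' @rdname LabelMask-accessors
setMethod("maskLabels", "LabelMask", function(x) x@labels)
#' @rdname LabelMask-accessors
setMethod("maskProps", "LabelMask", function(x) x@props)
#' @rdname LabelMask-accessors
setMethod("nDroplets", "LabelMask", function(x) nrow(x@props))
#' @rdname LabelMask-accessors
setMethod("pixelSizeUm", "LabelMask", function(x) x@pixelSizeUm)
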