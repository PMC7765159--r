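#' Per-droplet channel means for one day
#'
#' Arithmetic mean of each channel over exactly the labeled pixels of each
#' trajectory present that day.
#'
#' @param field a \linkS4class{FieldSeries}.
#' @param day day index.
#' @param mask the day's \linkS4class{LabelMask}.
#' @param spots labeled spot table from \code{\link{assignLabels}}.
#' @param subtractBackground named (red, green, blue) constants subtracted
#'   from the means (clamped at 0); default none, reporting raw
#'   photons/pixel.
#' @return data.frame with \code{trajectory}, \code{day}, \code{label},
#'   \code{n_px}, \code{I_R}, \code{I_G}, \code{I_B}.
#' @export
dropletMeans <- function(field, day, mask, spots,
                         subtractBackground = c(red = 0, green = 0, blue = 0)) {
  L <- maskLabels(mask)
  sel <- spots[spots$frame == day & spots$label > 0L, , drop = FALSE]
  out <- data.frame(trajectory = integer(0), day = integer(0),
                    label = integer(0), n_px = integer(0),
                    I_R = numeric(0), I_G = numeric(0), I_B = numeric(0))
  if (!nrow(sel)) return(out)
  fg <- which(L > 0L)
  l <- L[fg]
  ids <- sort(unique(l))
  cnt <- as.vector(rowsum(rep(1L, length(l)), l))
  sums <- matrix(vapply(CHANNELS, function(ch)
    as.vector(rowsum(getFrame(field, day, ch)[fg], l)),
    numeric(length(ids))), ncol = 3L)
  ridx <- match(sel$label, ids)
  bg <- if (is.null(names(subtractBackground)))
    rep_len(subtractBackground, 3L) else unname(subtractBackground[CHANNELS])
  data.frame(
    trajectory = sel$track, day = day, label = sel$label,
    n_px = cnt[ridx],
    I_R = pmax(sums[ridx, 1] / cnt[ridx] - bg[1], 0),
    I_G = pmax(sums[ridx, 2] / cnt[ridx] - bg[2], 0),
    I_B = pmax(sums[ridx, 3] / cnt[ridx] - bg[3], 0),
    row.names = NULL)
}

#' Lipid oxidation ratio
#'
#' \code{R = I_G / (I_G + I_R)}: the green (oxidized lipid) mean divided by
#' the summed green and red means; 0 is non-oxidized, 1 fully shifted.
#' Undefined (NA) when both channels are zero. Invariant under a common
#' positive gain on both channels.
#'
#' @param I_G,I_R nonnegative mean intensities (vectorized).
#' @return the ratio in [0, 1], NA where I_G + I_R = 0.
#' @export
oxidationRatio <- function(I_G, I_R) {
  if (any(I_G < 0, na.rm = TRUE) || any(I_R < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  s <- I_G + I_R
  ifelse(s > 0, I_G / s, NA_real_)
}

#' Mean blue intensity of the continuous phase
#'
#' Single per-field number: the mean of the blue channel over the
#' complement of the droplet mask.
#'
#' @param blueImage blue-channel matrix for one day.
#' @param mask the day's \linkS4class{LabelMask}.
#' @param subtractBackground constant subtracted from the mean.
#' @return scalar mean (NA if the field is fully covered by droplets).
#' @export
aqueousMean <- function(blueImage, mask, subtractBackground = 0) {
  stopifnot(all(dim(blueImage) == dim(maskLabels(mask))))
  aq <- invertMask(mask)
  if (!any(aq)) return(NA_real_)
  max(mean(blueImage[aq]) - subtractBackground, 0)
}

#' Assemble per-droplet and per-field oxidation time series
#'
#' Combines all days into one tidy droplet table (channel means and lipid
#' ratio per trajectory-day; gap days are simply absent) and a field table
#' (aqueous blue mean and droplet-pixel fraction per day).
#'
#' @param field a \linkS4class{FieldSeries}.
#' @param masks list of \linkS4class{LabelMask}, one per day.
#' @param assigned result of \code{\link{assignLabels}}.
#' @param group formulation label attached to every trajectory.
#' @param subtractBackground named (red, green, blue) constants; default
#'   none (raw photons/pixel).
#' @return list with \code{droplets} (trajectory, group, day, t, n_px,
#'   I_R, I_G, I_B, ratio, radius_um), \code{field} (day, t,
#'   aqueous_blue, droplet_fraction) and \code{trajectories} (the
#'   per-track summary with group attached).
#' @export
assembleTimeSeries <- function(field, masks, assigned, group = "A",
                               subtractBackground = c(red = 0, green = 0,
                                                      blue = 0)) {
  if (nDays(field) != length(masks))
    stop("field and masks cover different numbers of days")
  bg <- if (is.null(names(subtractBackground)))
    rep_len(subtractBackground, 3L) else unname(subtractBackground[CHANNELS])
  days <- seq_len(nDays(field))
  drop <- do.call(rbind, lapply(days, function(d)
    dropletMeans(field, d, masks[[d]], assigned$spots, subtractBackground)))
  if (is.null(drop))
    drop <- data.frame(trajectory = integer(0), day = integer(0),
                       label = integer(0), n_px = integer(0),
                       I_R = numeric(0), I_G = numeric(0), I_B = numeric(0))
  drop$t <- dayTimes(field)[drop$day]
  drop$ratio <- oxidationRatio(drop$I_G, drop$I_R)
  traj <- assigned$trajectories
  drop$group <- rep(group, nrow(drop))
  drop$radius_um <- traj$radius_um[match(drop$trajectory, traj$trajectory)]
  fld <- data.frame(
    day = days, t = dayTimes(field),
    aqueous_blue = vapply(days, function(d)
      aqueousMean(getFrame(field, d, "blue"), masks[[d]], bg[3]), 0),
    droplet_fraction = vapply(days, function(d)
      mean(maskLabels(masks[[d]]) > 0L), 0))
  traj$group <- rep(group, nrow(traj))
  list(droplets = drop[, c("trajectory", "group", "day", "t", "label",
                           "n_px", "I_R", "I_G", "I_B", "ratio",
                           "radius_um")],
       field = fld, trajectories = traj)
}
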