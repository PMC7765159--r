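#' Tracking parameters
#'
#' Defaults follow the established LoG + simple-LAP configuration for
#' slowly drifting droplets: blob diameter 14 px, linking and gap-closing
#' maximum distances 15 px, maximum frame gap 2, and a spot-count filter
#' retaining tracks with at least 10 spots (strictly above 9.9).
#'
#' @param blobDiameterPx estimated droplet diameter in pixels.
#' @param useMedianFilter apply a 3x3 median filter before detection.
#' @param subpixel quadratic sub-pixel refinement of maxima.
#' @param linkingMaxDistancePx maximum frame-to-frame displacement.
#' @param gapMaxDistancePx maximum displacement across a closed gap.
#' @param gapMaxFrameGap maximum number of skipped frames a gap may span.
#' @param minSpotsPerTrack spot-count filter threshold.
#' @param altCostFactor,altCostPercentile birth/death alternative cost =
#'   factor x this percentile of admissible link costs.
#' @param adaptiveFloorFrac adaptive response floor for spot detection, as
#'   a fraction of the frame's maximum LoG response; separates true blob
#'   maxima from faint side-lobe artifacts while keeping no absolute
#'   threshold. 0 retains every positive-response maximum.
#' @return list of validated parameters.
#' @export
trackingParams <- function(blobDiameterPx = 14, useMedianFilter = TRUE,
                           subpixel = TRUE, linkingMaxDistancePx = 15,
                           gapMaxDistancePx = 15, gapMaxFrameGap = 2,
                           minSpotsPerTrack = 10, altCostFactor = 1.05,
                           altCostPercentile = 1,
                           adaptiveFloorFrac = 0.02) {
  stopifnot(blobDiameterPx > 0, linkingMaxDistancePx > 0,
            gapMaxDistancePx > 0, gapMaxFrameGap >= 0,
            minSpotsPerTrack >= 1, altCostFactor > 0,
            altCostPercentile > 0, altCostPercentile <= 1,
            adaptiveFloorFrac >= 0, adaptiveFloorFrac < 1)
  list(blobDiameterPx = blobDiameterPx, useMedianFilter = useMedianFilter,
       subpixel = subpixel, linkingMaxDistancePx = linkingMaxDistancePx,
       gapMaxDistancePx = gapMaxDistancePx, gapMaxFrameGap = gapMaxFrameGap,
       minSpotsPerTrack = minSpotsPerTrack, altCostFactor = altCostFactor,
       altCostPercentile = altCostPercentile,
       adaptiveFloorFrac = adaptiveFloorFrac)
}

# Scale-normalized, zero-mean LoG kernel; negated so bright blobs respond
# positively. sigma = d / (2 sqrt(2)) maximizes the response for a disk of
# diameter d.
.logKernel <- function(sigma) {
  h <- ceiling(3.5 * sigma)
  x <- (-h):h
  d2 <- outer(x^2, x^2, `+`)
  k <- (d2 - 2 * sigma^2) / sigma^2 * exp(-d2 / (2 * sigma^2))
  -(k - mean(k))
}

.localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(cbind(row = integer(0), col = integer(0)))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  # positive response only; the tiny relative floor absorbs FFT round-off
  # in exactly flat regions and is not a detection threshold
  ok <- core > max(m) * 1e-9
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & (core >= m[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
}

.quadOffset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  off <- ifelse(den == 0, 0, 0.5 * (fm - fp) / den)
  pmin(pmax(off, -0.5), 0.5)
}

#' Detect droplet spots with a LoG filter
#'
#' Percentile-normalizes the image, optionally median-filters it, applies
#' a Laplacian-of-Gaussian filter at scale \code{sigma = d / (2 sqrt(2))},
#' and returns all positive-response local maxima with quadratic
#' sub-pixel refinement. Maxima closer than d/2 are suppressed, keeping
#' the stronger.
#'
#' @param image numeric matrix (red channel).
#' @param params from \code{\link{trackingParams}}.
#' @return data.frame with \code{row}, \code{col} (sub-pixel, 1-based) and
#'   \code{response}.
#' @export
detectSpots <- function(image, params = trackingParams()) {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0))
  if (max(image) == min(image)) return(empty)
  norm <- normalizePercentile(image)
  if (params$useMedianFilter)
    norm <- EBImage::medianFilter(norm, size = 1L)
  sigma <- params$blobDiameterPx / (2 * sqrt(2))
  resp <- EBImage::filter2(norm, .logKernel(sigma), boundary = "replicate")
  resp <- matrix(as.numeric(resp), nrow(image))
  mx <- .localMaxima(resp)
  if (!nrow(mx)) return(empty)
  r <- mx[, "row"]; cc <- mx[, "col"]
  val <- resp[cbind(r, cc)]
  if (params$adaptiveFloorFrac > 0) {
    keepF <- val > params$adaptiveFloorFrac * max(resp)
    if (!any(keepF)) return(empty)
    r <- r[keepF]; cc <- cc[keepF]; val <- val[keepF]
  }
  row <- as.numeric(r); col <- as.numeric(cc)
  if (params$subpixel) {
    row <- row + .quadOffset(resp[cbind(r - 1L, cc)], val,
                             resp[cbind(r + 1L, cc)])
    col <- col + .quadOffset(resp[cbind(r, cc - 1L)], val,
                             resp[cbind(r, cc + 1L)])
  }
  # non-maximum suppression at radius d/2
  ord <- order(val, decreasing = TRUE)
  keep <- logical(length(ord))
  minD2 <- (params$blobDiameterPx / 2)^2
  for (i in ord) {
    k <- which(keep)
    if (!length(k) ||
        all((row[k] - row[i])^2 + (col[k] - col[i])^2 >= minD2))
      keep[i] <- TRUE
  }
  data.frame(row = row[keep], col = col[keep], response = val[keep])
}

# Exact square linear assignment (Jonker-Volgenant shortest augmenting
# path with potentials). Returns the column assigned to each row.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)                 # p[j + 1] = row matched to column j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedIdx <- which(used)
      u[p[usedIdx]] <- u[p[usedIdx]] + delta
      v[usedIdx] <- v[usedIdx] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  match[p[-1L]] <- seq_len(n)
  match
}

.BIG <- 1e12

# Jaqaman-style augmented LAP for one frame pair: rows = source spots +
# birth dummies, cols = target spots + death dummies. Returns for each
# source spot the linked target index (NA if it dies).
.linkFramePair <- function(d2, maxDist, factor, pctl) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  adm <- d2 <= maxDist^2
  if (!any(adm)) return(rep(NA_integer_, n1))
  alt <- factor * quantile(d2[adm], pctl, names = FALSE)
  if (alt <= 0) alt <- .Machine$double.eps
  n <- n1 + n2
  M <- matrix(.BIG, n, n)
  M[seq_len(n1), seq_len(n2)] <- ifelse(adm, d2, .BIG)
  M[cbind(seq_len(n1), n2 + seq_len(n1))] <- alt
  M[cbind(n1 + seq_len(n2), seq_len(n2))] <- alt
  M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  sol <- .solveAssignment(M)
  link <- sol[seq_len(n1)]
  link[link > n2] <- NA_integer_
  bad <- which(!is.na(link))
  bad <- bad[!adm[cbind(bad, link[bad])]]
  link[bad] <- NA_integer_
  link
}

#' Link spots across frames into tracks
#'
#' Stage 1 links consecutive frames by solving a linear assignment with
#' squared-displacement costs; links farther than the maximum linking
#' distance are inadmissible and birth/death alternatives are priced at
#' \code{altCostFactor} times the \code{altCostPercentile} quantile of
#' admissible costs. Stage 2 joins track-segment ends to later starts
#' within the frame-gap and distance limits by a second assignment with
#' the same cost rule (gap closing).
#'
#' @param spotsByDay list of spot data.frames (from
#'   \code{\link{detectSpots}}), one per frame in increasing time order.
#' @param params from \code{\link{trackingParams}}.
#' @return data.frame with \code{track}, \code{frame}, \code{row},
#'   \code{col}, \code{response}; one row per detected spot.
#' @export
linkTracks <- function(spotsByDay, params = trackingParams()) {
  D <- length(spotsByDay)
  spots <- do.call(rbind, lapply(seq_len(D), function(f) {
    s <- spotsByDay[[f]]
    if (!nrow(s)) return(NULL)
    data.frame(frame = f, row = s$row, col = s$col, response = s$response)
  }))
  if (is.null(spots))
    return(data.frame(track = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0),
                      response = numeric(0)))
  spots$track <- NA_integer_
  nextId <- 1L
  idx <- split(seq_len(nrow(spots)), spots$frame)
  frames <- as.integer(names(idx))
  # seed tracks in the first occupied frame
  first <- idx[[1]]
  spots$track[first] <- seq_along(first)
  nextId <- length(first) + 1L
  for (k in seq_len(length(frames) - 1L)) {
    a <- idx[[k]]; b <- idx[[as.character(frames[k + 1L])]]
    link <- rep(NA_integer_, length(a))
    if (length(a) && length(b) && frames[k + 1L] == frames[k] + 1L) {
      d2 <- outer(spots$row[a], spots$row[b], `-`)^2 +
        outer(spots$col[a], spots$col[b], `-`)^2
      d2 <- matrix(d2, length(a))
      link <- .linkFramePair(d2, params$linkingMaxDistancePx,
                             params$altCostFactor, params$altCostPercentile)
    }
    linked <- !is.na(link)
    spots$track[b[link[linked]]] <- spots$track[a[linked]]
    new <- is.na(spots$track[b])
    if (any(new)) {
      spots$track[b[new]] <- nextId + seq_len(sum(new)) - 1L
      nextId <- nextId + sum(new)
    }
  }

  # stage 2: gap closing between segment ends and starts
  segs <- split(seq_len(nrow(spots)), spots$track)
  S <- length(segs)
  if (S > 1L && params$gapMaxFrameGap > 0) {
    endIdx <- vapply(segs, function(s) s[which.max(spots$frame[s])], 0L)
    startIdx <- vapply(segs, function(s) s[which.min(spots$frame[s])], 0L)
    dt <- outer(spots$frame[startIdx], spots$frame[endIdx], `-`)  # [start, end]
    d2 <- outer(spots$row[startIdx], spots$row[endIdx], `-`)^2 +
      outer(spots$col[startIdx], spots$col[endIdx], `-`)^2
    adm <- t(dt >= 2L & dt <= params$gapMaxFrameGap + 1L &
               d2 <= params$gapMaxDistancePx^2)     # [end, start]
    d2 <- t(d2)
    if (any(adm)) {
      alt <- params$altCostFactor *
        quantile(d2[adm], params$altCostPercentile, names = FALSE)
      if (alt <= 0) alt <- .Machine$double.eps
      M <- matrix(.BIG, 2L * S, 2L * S)
      M[seq_len(S), seq_len(S)][adm] <- d2[adm]
      M[cbind(seq_len(S), S + seq_len(S))] <- alt
      M[cbind(S + seq_len(S), seq_len(S))] <- alt
      M[S + seq_len(S), S + seq_len(S)] <- 0
      sol <- .solveAssignment(M)
      join <- sol[seq_len(S)]          # end of segment i joins start of join[i]
      join[join > S] <- NA_integer_
      bad <- which(!is.na(join))
      bad <- bad[!adm[cbind(bad, join[bad])]]
      join[bad] <- NA_integer_
      # merge chains: relabel each joined segment to its root's track id
      parent <- rep(NA_integer_, S)
      parent[join[!is.na(join)]] <- which(!is.na(join))
      root <- function(s) { while (!is.na(parent[s])) s <- parent[s]; s }
      ids <- as.integer(names(segs))
      for (s in seq_len(S)) {
        r <- root(s)
        if (r != s) spots$track[segs[[s]]] <- ids[r]
      }
    }
  }
  spots$track <- match(spots$track, sort(unique(spots$track)))
  rownames(spots) <- NULL
  spots[order(spots$track, spots$frame),
        c("track", "frame", "row", "col", "response")]
}

#' Filter tracks by spot count
#'
#' Retains tracks with at least \code{minSpotsPerTrack} spots; with the
#' default of 10 on a 10-day grid this keeps only droplets detected on
#' every day.
#'
#' @param tracks data.frame from \code{\link{linkTracks}}.
#' @param params from \code{\link{trackingParams}}.
#' @return filtered track data.frame.
#' @export
filterTracks <- function(tracks, params = trackingParams()) {
  if (!nrow(tracks)) return(tracks)
  n <- table(tracks$track)
  keep <- as.integer(names(n)[n >= params$minSpotsPerTrack])
  out <- tracks[tracks$track %in% keep, , drop = FALSE]
  out$track <- match(out$track, sort(unique(out$track)))
  rownames(out) <- NULL
  out
}

#' Assign segmentation labels to trajectories
#'
#' Each spot receives the label of the mask pixel containing its rounded
#' position; spots on continuous phase get label 0 (a gap that day). When
#' two trajectories claim one label on the same day, the spot nearer the
#' label centroid wins and the loser gets a gap.
#'
#' @param tracks data.frame from \code{\link{linkTracks}} /
#'   \code{\link{filterTracks}}.
#' @param masks list of \linkS4class{LabelMask}, one per frame; must cover
#'   all frames referenced by \code{tracks}.
#' @return list with \code{spots} (tracks plus \code{label},
#'   \code{radius_px}, \code{radius_um}) and \code{trajectories}
#'   (per-track summary: n_spots, n_labeled, mean radius).
#' @export
assignLabels <- function(tracks, masks) {
  if (nrow(tracks) && max(tracks$frame) > length(masks))
    stop("tracks reference frames beyond the supplied masks")
  lab <- integer(nrow(tracks))
  rad_px <- rad_um <- rep(NA_real_, nrow(tracks))
  for (f in unique(tracks$frame)) {
    m <- masks[[f]]
    L <- maskLabels(m)
    sel <- which(tracks$frame == f)
    r <- pmin(pmax(round(tracks$row[sel]), 1L), nrow(L))
    cc <- pmin(pmax(round(tracks$col[sel]), 1L), ncol(L))
    l <- L[cbind(r, cc)]
    # conflict resolution: nearest centroid keeps the label
    pr <- maskProps(m)
    for (dup in unique(l[duplicated(l) & l > 0L])) {
      cand <- sel[l == dup]
      ctr <- pr[pr$label == dup, ]
      d2 <- (tracks$row[cand] - ctr$row)^2 + (tracks$col[cand] - ctr$col)^2
      l[l == dup & sel %in% cand[-which.min(d2)]] <- 0L
    }
    lab[sel] <- l
    got <- l > 0L
    ridx <- match(l[got], pr$label)
    rad_px[sel[got]] <- pr$radius_px[ridx]
    rad_um[sel[got]] <- pr$radius_um[ridx]
  }
  spots <- cbind(tracks, label = lab, radius_px = rad_px, radius_um = rad_um)
  if (nrow(spots)) {
    byTrack <- split(seq_len(nrow(spots)), spots$track)
    trajectories <- data.frame(
      trajectory = as.integer(names(byTrack)),
      n_spots = lengths(byTrack),
      n_labeled = vapply(byTrack, function(s) sum(spots$label[s] > 0L), 0L),
      radius_px = vapply(byTrack, function(s)
        mean(spots$radius_px[s], na.rm = TRUE), 0),
      radius_um = vapply(byTrack, function(s)
        mean(spots$radius_um[s], na.rm = TRUE), 0),
      row.names = NULL)
  } else {
    trajectories <- data.frame(trajectory = integer(0), n_spots = integer(0),
                               n_labeled = integer(0), radius_px = numeric(0),
                               radius_um = numeric(0))
  }
  list(spots = spots, trajectories = trajectories)
}
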