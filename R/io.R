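#' Write a field series as multi-page TIFF plus sidecar metadata
#'
#' Pages are ordered day-major, channel-minor (red, green, blue within
#' each day), 16-bit unsigned. A YAML sidecar (same path with
#' \code{.yml} appended) records pixel size, day times and channel roles
#' so the series round-trips bit-exactly.
#'
#' @param field a \linkS4class{FieldSeries}; counts above 65535 are
#'   clamped.
#' @param path output TIFF path.
#' @return the TIFF path, invisibly.
#' @export
writeFieldSeries <- function(field, path) {
  pages <- list()
  for (d in seq_len(nDays(field)))
    for (ch in CHANNELS)
      pages[[length(pages) + 1L]] <-
        pmin(getFrame(field, d, ch), 65535) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  # numbers are serialized as full-precision strings so the series
  # round-trips bit-exactly
  meta <- list(pixel_size_um = formatC(pixelSizeUm(field), digits = 17,
                                       format = "g"),
               day_times = formatC(dayTimes(field), digits = 17,
                                   format = "g"),
               channels = as.list(CHANNELS),
               page_order = "day-major, channel-minor")
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a field series written by \code{\link{writeFieldSeries}}
#'
#' @param path TIFF path; \code{<path>.yml} must exist.
#' @return A \linkS4class{FieldSeries}.
#' @export
readFieldSeries <- function(path) {
  metaPath <- paste0(path, ".yml")
  if (!file.exists(metaPath))
    stop("missing sidecar metadata file: ", metaPath)
  meta <- yaml::read_yaml(metaPath)
  roles <- unlist(meta$channels)
  if (!identical(roles, CHANNELS))
    stop("unknown channel role(s) in metadata: ",
         paste(setdiff(roles, CHANNELS), collapse = ", "))
  days <- as.numeric(meta$day_times)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L * length(days))
    stop(sprintf("page count mismatch: found %d pages, expected %d (%d days x 3 channels)",
                 length(pages), 3L * length(days), length(days)))
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(days), 3L, nr, nc))
  k <- 1L
  for (d in seq_along(days)) for (ch in 1:3) {
    arr[d, ch, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  FieldSeries(arr, days, as.numeric(meta$pixel_size_um))
}

#' Analyze one field series end to end
#'
#' Runs segmentation, spot detection, LAP linking with gap closing, the
#' spot-count filter, label assignment, quantification and per-droplet
#' Gompertz fitting on one field, returning every intermediate table.
#'
#' @param field a \linkS4class{FieldSeries}.
#' @param group formulation label attached to the field's droplets.
#' @param segParams,trackParams stage parameters.
#' @param subtractBackground named (red, green, blue) constants removed
#'   from mean intensities (default none: raw photons/pixel).
#' @param minPoints minimum time points per Gompertz fit.
#' @return list with \code{masks}, \code{tracks} (filtered),
#'   \code{rawTracks}, \code{assigned}, \code{timeseries}, \code{rates}.
#' @export
analyzeField <- function(field, group = "A",
                         segParams = segmentationParams(),
                         trackParams = trackingParams(),
                         subtractBackground = c(red = 0, green = 0, blue = 0),
                         minPoints = 4L) {
  masks <- segmentSeries(field, segParams)
  spotsByDay <- lapply(seq_len(nDays(field)), function(d)
    detectSpots(getFrame(field, d, "red"), trackParams))
  rawTracks <- linkTracks(spotsByDay, trackParams)
  tracks <- filterTracks(rawTracks, trackParams)
  assigned <- assignLabels(tracks, masks)
  ts <- assembleTimeSeries(field, masks, assigned, group = group,
                           subtractBackground = subtractBackground)
  rates <- buildRateTable(ts, minPoints = minPoints)
  list(masks = masks, tracks = tracks, rawTracks = rawTracks,
       assigned = assigned, timeseries = ts, rates = rates)
}

#' Run the full multi-field oxidation pipeline
#'
#' Segments, tracks, quantifies and fits every supplied field, pools the
#' per-droplet rates, and runs the ANCOVA plus within-group regressions
#' on c_lip and c_prot. When \code{outDir} is given, all tables are
#' written as CSV (droplet time series, field time series, rates,
#' statistics report) together with an exclusion log (filtered tracks,
#' non-converged fits).
#'
#' @param fields list of \linkS4class{FieldSeries}, or
#'   \linkS4class{OxScenario}s to simulate first (one field per group).
#' @param groups formulation label per field (defaults to field names or
#'   "A", "B", ...).
#' @param outDir optional output directory.
#' @param seed seed used when simulating scenarios.
#' @param alpha significance level of the report.
#' @param ... passed on to \code{\link{analyzeField}}.
#' @return list with \code{perField} results, pooled \code{rates},
#'   \code{ancova} (per response, where estimable), \code{slopes},
#'   \code{report}, and the per-field \code{fieldSeries} tables.
#' @export
runPipeline <- function(fields, groups = NULL, outDir = NULL, seed = 1L,
                        alpha = 0.05, ...) {
  if (is(fields, "OxScenario") || is(fields, "FieldSeries"))
    fields <- list(fields)
  truths <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    if (is(fields[[i]], "OxScenario")) {
      sim <- generateField(fields[[i]], seed = seed + i - 1L)
      fields[[i]] <- sim$field
      truths[[i]] <- sim$truth
    }
  }
  if (is.null(groups)) {
    groups <- names(fields)
    if (is.null(groups)) groups <- LETTERS[seq_along(fields)]
  }
  perField <- lapply(seq_along(fields), function(i)
    analyzeField(fields[[i]], group = groups[i], ...))
  names(perField) <- make.unique(groups)
  rates <- do.call(rbind, lapply(seq_along(perField), function(i) {
    r <- perField[[i]]$rates
    if (nrow(r)) cbind(field = i, r) else cbind(r, field = integer(0))
  }))
  rownames(rates) <- NULL
  # make pooled trajectory ids unique across fields
  if (nrow(rates))
    rates$trajectory <- paste(rates$field, rates$trajectory, sep = ".")

  results <- list()
  for (resp in c("c_lip", "c_prot")) {
    a <- tryCatch(rateAncova(rates, resp, alpha = alpha),
                  error = function(e) NULL)
    if (!is.null(a)) results[[paste0("ancova_", resp)]] <- a
    for (g in unique(rates$group)) {
      s <- tryCatch(withinGroupRegression(rates, resp, g),
                    error = function(e) NULL)
      if (!is.null(s)) results[[paste0("slope_", resp, "_", g)]] <- s
    }
  }
  report <- summarizeTests(results, alpha = alpha)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    addField <- function(i, x)
      if (nrow(x)) cbind(field = i, x) else x
    drops <- do.call(rbind, lapply(seq_along(perField), function(i)
      addField(i, perField[[i]]$timeseries$droplets)))
    flds <- do.call(rbind, lapply(seq_along(perField), function(i)
      addField(i, cbind(group = rep(groups[i],
                                    nrow(perField[[i]]$timeseries$field)),
                        perField[[i]]$timeseries$field))))
    write.csv(drops, file.path(outDir, "droplet_timeseries.csv"),
              row.names = FALSE)
    write.csv(flds, file.path(outDir, "field_timeseries.csv"),
              row.names = FALSE)
    write.csv(rates, file.path(outDir, "rates.csv"), row.names = FALSE)
    write.csv(report, file.path(outDir, "statistics.csv"),
              row.names = FALSE)
    excl <- do.call(rbind, lapply(seq_along(perField), function(i) {
      p <- perField[[i]]
      data.frame(field = i, group = groups[i],
                 raw_tracks = length(unique(p$rawTracks$track)),
                 retained_tracks = length(unique(p$tracks$track)),
                 nonconverged_lipid = sum(!p$rates$converged_lip),
                 nonconverged_protein = sum(!p$rates$converged_prot))
    }))
    write.csv(excl, file.path(outDir, "exclusions.csv"), row.names = FALSE)
  }
  list(perField = perField, rates = rates,
       ancova = results[grep("^ancova", names(results))],
       slopes = results[grep("^slope", names(results))],
       report = report, truths = truths)
}
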