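#' Synthetic oxidation-imaging scenario
#'
#' Describes a ground-truthed synthetic acquisition: field geometry, day
#' grid, droplet population, per-group Gompertz kinetics for the lipid
#' conversion (red to green) and the interface protein signal, an aqueous
#' (continuous-phase) protein kinetic, photon backgrounds, inter-day drift
#' and optional per-day dropout. All pixel values are Poisson photon counts
#' around the configured expectations.
#'
#' Kinetics tables have one row per formulation group and columns
#' \code{group, a, a_sd, b, b_sd, c, c_sd, beta}: droplet parameters are
#' drawn from normal distributions truncated to be positive, and the true
#' growth rate of a droplet of radius r is \code{c + beta / r} (beta in
#' day^-1 um, the size-coupling slope).
#'
#' @slot fieldPx pixels per side. @slot fieldUm field width, um.
#' @slot days acquisition times (days), strictly increasing.
#' @slot nDroplets number of droplets. @slot radiusRangeUm (min, max), um.
#' @slot lipidKinetics,proteinKinetics per-group kinetics tables (above);
#'   lipid a is the asymptotic oxidized fraction, protein a is in
#'   photons/pixel.
#' @slot aqueousKinetics numeric (a, b, c) for the continuous-phase blue
#'   signal (photons/pixel above background).
#' @slot lipidTotalIntensity expected total (red+green) droplet brightness,
#'   photons/pixel. @slot background named (red, green, blue) means.
#' @slot driftPxPerDay maximum center displacement per day, px.
#' @slot dropoutProb per interior-day probability a droplet is undetectable.
#' @slot dropoutMaxDays cap on undetectable days per droplet (Inf = none).
#' @slot ringWidthPx 0 paints interface protein over the whole disk
#'   (canonical); > 0 restricts it to a rim of that width.
#' @slot seed default random seed.
#' @exportClass OxScenario
setClass("OxScenario",
  representation(
    fieldPx = "integer", fieldUm = "numeric", days = "numeric",
    nDroplets = "integer", radiusRangeUm = "numeric",
    lipidKinetics = "data.frame", proteinKinetics = "data.frame",
    aqueousKinetics = "numeric", lipidTotalIntensity = "numeric",
    background = "numeric", driftPxPerDay = "numeric",
    dropoutProb = "numeric", dropoutMaxDays = "numeric",
    ringWidthPx = "numeric", seed = "integer"
  )
)

.kinCols <- c("group", "a", "a_sd", "b", "b_sd", "c", "c_sd", "beta")

setValidity("OxScenario", function(object) {
  msg <- character(0)
  if (object@fieldPx <= 0L) msg <- c(msg, "fieldPx must be positive")
  if (object@fieldUm <= 0) msg <- c(msg, "fieldUm must be positive")
  if (length(object@days) < 1L ||
      (length(object@days) > 1L && any(diff(object@days) <= 0)))
    msg <- c(msg, "days must be non-empty and strictly increasing")
  if (object@nDroplets < 0L) msg <- c(msg, "nDroplets must be >= 0")
  rr <- object@radiusRangeUm
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] < rr[1])
    msg <- c(msg, "radiusRangeUm must be (min, max) with 0 < min <= max")
  for (nm in c("lipidKinetics", "proteinKinetics")) {
    k <- slot(object, nm)
    if (!all(.kinCols %in% names(k)))
      msg <- c(msg, sprintf("%s must have columns %s", nm,
                            paste(.kinCols, collapse = ", ")))
    else if (any(k$a < 0 | k$b < 0 | k$c < 0))
      msg <- c(msg, sprintf("%s kinetic means must be >= 0", nm))
  }
  if (length(object@aqueousKinetics) != 3L || any(object@aqueousKinetics < 0))
    msg <- c(msg, "aqueousKinetics must be nonnegative (a, b, c)")
  if (!identical(names(object@background), CHANNELS) ||
      any(object@background < 0))
    msg <- c(msg, "background must be named nonnegative (red, green, blue)")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    msg <- c(msg, "dropoutProb must be in [0, 1]")
  if (object@driftPxPerDay < 0) msg <- c(msg, "driftPxPerDay must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OxScenario", function(object) {
  cat(sprintf(
    "OxScenario: %d droplet(s) in %d px (%.3g um), days %s, groups %s\n",
    object@nDroplets, object@fieldPx, object@fieldUm,
    paste(range(object@days), collapse = ".."),
    paste(object@lipidKinetics$group, collapse = ", ")))
})

.kinTable <- function(x) {
  stopifnot(is.data.frame(x))
  for (nm in setdiff(.kinCols, names(x)))
    x[[nm]] <- if (nm == "group") as.character(seq_len(nrow(x))) else 0
  x[, .kinCols]
}

#' Construct a synthetic scenario
#'
#' @param fieldPx,fieldUm field geometry (defaults 512 px, 123 um).
#' @param days acquisition times in days (default 1..10).
#' @param nDroplets droplet count.
#' @param radiusRangeUm uniform radius range in um.
#' @param lipidKinetics,proteinKinetics per-group kinetics tables; see
#'   \linkS4class{OxScenario}. Missing columns default to 0.
#' @param aqueousKinetics (a, b, c) of the continuous-phase blue kinetic.
#' @param lipidTotalIntensity per-droplet total lipid brightness
#'   (photons/pixel).
#' @param background named (red, green, blue) background means.
#' @param driftPxPerDay,dropoutProb,ringWidthPx,seed see
#'   \linkS4class{OxScenario}.
#' @return An \linkS4class{OxScenario}.
#' @export
scenarioConfig <- function(fieldPx = 512L, fieldUm = 123, days = 1:10,
                           nDroplets = 120L, radiusRangeUm = c(1.5, 2.5),
                           lipidKinetics = data.frame(group = "A", a = 0.88,
                             a_sd = 0.02, b = 3.5, b_sd = 0.3, c = 0.5,
                             c_sd = 0.02, beta = 0),
                           proteinKinetics = data.frame(group = "A", a = 6.4,
                             a_sd = 0.6, b = 34, b_sd = 3, c = 0.39,
                             c_sd = 0.03, beta = 0.5),
                           aqueousKinetics = c(a = 5, b = 34, c = 0.63),
                           lipidTotalIntensity = 150,
                           background = c(red = 2, green = 2, blue = 1.5),
                           driftPxPerDay = 2, dropoutProb = 0,
                           dropoutMaxDays = Inf, ringWidthPx = 0, seed = 1L) {
  new("OxScenario", fieldPx = as.integer(fieldPx), fieldUm = fieldUm,
      days = as.numeric(days), nDroplets = as.integer(nDroplets),
      radiusRangeUm = as.numeric(radiusRangeUm),
      lipidKinetics = .kinTable(lipidKinetics),
      proteinKinetics = .kinTable(proteinKinetics),
      aqueousKinetics = unname(aqueousKinetics),
      lipidTotalIntensity = lipidTotalIntensity,
      background = background[CHANNELS],
      driftPxPerDay = driftPxPerDay, dropoutProb = dropoutProb,
      dropoutMaxDays = dropoutMaxDays, ringWidthPx = ringWidthPx,
      seed = as.integer(seed))
}

#' Formulation presets
#'
#' Single-group scenarios emulating the three analyzed mayonnaise
#' formulations: "I" soybean oil (slow lipid oxidation, near-flat interface
#' protein signal), "II" soybean oil + ascorbic acid (slowest lipid
#' oxidation, strong early protein rise, lipid rate weakly coupled to
#' droplet size), "III" stripped soybean oil (fastest lipid oxidation,
#' delayed but large protein rise). Protein rates carry a size-coupling
#' slope of 0.5 day^-1 um in all presets.
#'
#' @param sample one of "I", "II", "III".
#' @param ... overrides passed to \code{\link{scenarioConfig}}.
#' @return An \linkS4class{OxScenario}.
#' @export
scenarioPreset <- function(sample = c("I", "II", "III"), ...) {
  sample <- match.arg(sample)
  lip <- switch(sample,
    I   = data.frame(group = "I", a = 0.45, a_sd = 0.02, b = 3.5, b_sd = 0.3,
                     c = 0.32, c_sd = 0.02, beta = 0),
    II  = data.frame(group = "II", a = 0.35, a_sd = 0.02, b = 3.5, b_sd = 0.3,
                     c = 0.30, c_sd = 0.02, beta = 0.12),
    III = data.frame(group = "III", a = 0.88, a_sd = 0.02, b = 3.5, b_sd = 0.3,
                     c = 0.50, c_sd = 0.02, beta = 0))
  prot <- switch(sample,
    I   = data.frame(group = "I", a = 1.2, a_sd = 0.12, b = 2.0, b_sd = 0.2,
                     c = 0.095, c_sd = 0.03, beta = 0.5),
    II  = data.frame(group = "II", a = 4.32, a_sd = 0.4, b = 3.26, b_sd = 0.33,
                     c = 0.545, c_sd = 0.03, beta = 0.5),
    III = data.frame(group = "III", a = 6.4, a_sd = 0.6, b = 34, b_sd = 3,
                     c = 0.372, c_sd = 0.03, beta = 0.5))
  aq <- switch(sample,
    I   = c(0.4, 1.0, 0.30),
    II  = c(3.5, 3.3, 0.80),
    III = c(5.0, 34, 0.63))
  scenarioConfig(lipidKinetics = lip, proteinKinetics = prot,
                 aqueousKinetics = aq, ...)
}

# Fractional pixel coverage of a disk, 4x supersampled. Returns the local
# block and its row/col index ranges.
.diskCoverage <- function(rowC, colC, rPx, fieldPx, ss = 4L) {
  r0 <- max(1L, floor(rowC - rPx - 1)); r1 <- min(fieldPx, ceiling(rowC + rPx + 1))
  c0 <- max(1L, floor(colC - rPx - 1)); c1 <- min(fieldPx, ceiling(colC + rPx + 1))
  rows <- r0:r1; cols <- c0:c1
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  subr <- rep(rows, each = ss) + offs
  subc <- rep(cols, each = ss) + offs
  inside <- outer((subr - rowC)^2, (subc - colC)^2, `+`) <= rPx^2
  cov <- rowsum(inside + 0, rep(seq_along(rows), each = ss))
  cov <- t(rowsum(t(cov), rep(seq_along(cols), each = ss))) / (ss * ss)
  list(cov = cov, rows = rows, cols = cols)
}

.truncNorm <- function(n, mean, sd, lower = 1e-4) {
  pmax(rnorm(n, mean, sd), lower)
}

#' Evaluate the Gompertz growth curve
#'
#' \code{f(t) = a * exp(-b * exp(-c * t))}: a is the asymptote, b the
#' displacement along the time axis, c the growth rate (day^-1).
#'
#' @param a,b,c curve parameters. @param t time, days.
#' @return f(t).
#' @export
gompertzEval <- function(a, b, c, t) a * exp(-b * exp(-c * t))

#' Generate a ground-truthed synthetic field series
#'
#' Places non-overlapping disk droplets by rejection sampling, draws
#' per-droplet Gompertz kinetics from the scenario's group tables, renders
#' each day's three channels (red+green conserve the total lipid
#' fluorophore; blue is the interface signal inside droplets and the
#' aqueous kinetic outside) with anti-aliased rims, drifts centers between
#' days and applies Poisson photon noise.
#'
#' @param scenario an \linkS4class{OxScenario}.
#' @param noise if FALSE, render noise-free expectations (rounded to
#'   integer photon counts).
#' @param seed overrides the scenario seed.
#' @return list with \code{field} (\linkS4class{FieldSeries}),
#'   \code{truth} (one row per droplet: id, group, radius, true Gompertz
#'   parameters with size coupling applied) and \code{centers}
#'   (droplet_id, day, t, row, col, present).
#' @export
generateField <- function(scenario, noise = TRUE, seed = NULL) {
  stopifnot(is(scenario, "OxScenario"))
  validObject(scenario)
  set.seed(if (is.null(seed)) scenario@seed else seed)
  n <- scenario@nDroplets
  fp <- scenario@fieldPx
  pxUm <- scenario@fieldUm / fp
  days <- scenario@days
  D <- length(days)
  lipK <- scenario@lipidKinetics
  protK <- scenario@proteinKinetics
  groups <- lipK$group

  # radii and group assignment
  radiusUm <- runif(n, scenario@radiusRangeUm[1], scenario@radiusRangeUm[2])
  radiusPx <- radiusUm / pxUm
  grp <- groups[(seq_len(n) - 1L) %% length(groups) + 1L]

  # rejection-sampled non-overlapping placement (2 px edge gap)
  ord <- order(radiusPx, decreasing = TRUE)
  rowC <- colC <- numeric(n)
  placed <- integer(0)
  attempts <- 0L; maxAttempts <- 200L * max(n, 1L)
  for (i in ord) {
    m <- radiusPx[i] + 1.5
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(sprintf(
          "droplet placement failed: field too crowded (placed %d of %d)",
          length(placed), n))
      rr <- runif(1, m, fp + 1 - m); cc <- runif(1, m, fp + 1 - m)
      if (!length(placed)) { ok <- TRUE } else {
        d2 <- (rowC[placed] - rr)^2 + (colC[placed] - cc)^2
        ok <- all(d2 > (radiusPx[placed] + radiusPx[i] + 2)^2)
      }
      if (ok) { rowC[i] <- rr; colC[i] <- cc; placed <- c(placed, i); break }
    }
  }

  drawKin <- function(tab) {
    idx <- match(grp, tab$group)
    cbind(a = .truncNorm(n, tab$a[idx], tab$a_sd[idx]),
          b = .truncNorm(n, tab$b[idx], tab$b_sd[idx]),
          c = .truncNorm(n, tab$c[idx], tab$c_sd[idx]) +
            tab$beta[idx] / radiusUm)
  }
  lip <- drawKin(lipK)
  prot <- drawKin(protK)

  # per-day centers (random-walk drift, clamped inside field) and presence
  centerR <- matrix(rowC, n, D); centerC <- matrix(colC, n, D)
  if (D > 1L) for (d in 2:D) {
    theta <- runif(n, 0, 2 * pi)
    step <- runif(n, 0, scenario@driftPxPerDay)
    centerR[, d] <- centerR[, d - 1] + step * sin(theta)
    centerC[, d] <- centerC[, d - 1] + step * cos(theta)
    lo <- radiusPx + 1.5
    centerR[, d] <- pmin(pmax(centerR[, d], lo), fp + 1 - lo)
    centerC[, d] <- pmin(pmax(centerC[, d], lo), fp + 1 - lo)
  }
  present <- matrix(TRUE, n, D)
  if (scenario@dropoutProb > 0 && D > 2L && n > 0L) {
    present[, 2:(D - 1L)] <-
      matrix(runif(n * (D - 2L)) >= scenario@dropoutProb, n)
    if (is.finite(scenario@dropoutMaxDays)) for (i in seq_len(n)) {
      out <- which(!present[i, ])
      if (length(out) > scenario@dropoutMaxDays) {
        keepOut <- sample(out, scenario@dropoutMaxDays)
        present[i, ] <- TRUE
        present[i, keepOut] <- FALSE
      }
    }
  }

  bg <- scenario@background
  aqk <- scenario@aqueousKinetics
  L <- scenario@lipidTotalIntensity
  arr <- array(0, dim = c(D, 3L, fp, fp))
  for (d in seq_len(D)) {
    t <- days[d]
    aq <- gompertzEval(aqk[1], aqk[2], aqk[3], t) + bg["blue"]
    red <- matrix(bg["red"], fp, fp)
    green <- matrix(bg["green"], fp, fp)
    blue <- matrix(aq, fp, fp)
    for (i in seq_len(n)) {
      if (!present[i, d]) next
      cv <- .diskCoverage(centerR[i, d], centerC[i, d], radiusPx[i], fp)
      g <- gompertzEval(lip[i, "a"], lip[i, "b"], lip[i, "c"], t)
      red[cv$rows, cv$cols] <- red[cv$rows, cv$cols] + cv$cov * L * (1 - g)
      green[cv$rows, cv$cols] <- green[cv$rows, cv$cols] + cv$cov * L * g
      inner <- gompertzEval(prot[i, "a"], prot[i, "b"], prot[i, "c"], t) +
        bg["blue"]
      pcov <- cv$cov
      if (scenario@ringWidthPx > 0) {
        rIn <- max(radiusPx[i] - scenario@ringWidthPx, 0)
        pcov <- cv$cov - .diskCoverage(centerR[i, d], centerC[i, d], rIn, fp)$cov
      }
      blue[cv$rows, cv$cols] <- blue[cv$rows, cv$cols] + pcov * (inner - aq)
    }
    for (ch in 1:3) {
      m <- switch(ch, red, green, blue)
      arr[d, ch, , ] <- if (noise) rpois(fp * fp, pmax(m, 0)) else round(m)
    }
  }

  truth <- data.frame(
    droplet_id = seq_len(n), group = grp, radius_um = radiusUm,
    radius_px = radiusPx,
    a_lip = lip[, "a"], b_lip = lip[, "b"], c_lip = lip[, "c"],
    a_prot = prot[, "a"], b_prot = prot[, "b"], c_prot = prot[, "c"],
    days_present = apply(present, 1, sum),
    stringsAsFactors = FALSE)
  centers <- data.frame(
    droplet_id = rep(seq_len(n), times = D),
    day = rep(seq_len(D), each = n),
    t = rep(days, each = n),
    row = as.vector(centerR), col = as.vector(centerC),
    present = as.vector(present))
  if (n == 0L) centers <- centers[0, ]
  list(field = FieldSeries(arr, days, pxUm), truth = truth,
       centers = centers)
}

#' Write / read droplet ground truth
#'
#' One CSV row per droplet with all true parameters; round-trips.
#'
#' @param truth ground-truth data.frame from \code{\link{generateField}}.
#' @param path CSV path.
#' @return \code{readGroundTruth} returns the data.frame.
#' @export
writeGroundTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
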