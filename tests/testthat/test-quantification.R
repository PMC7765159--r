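miniField <- function(red, green, blue) {
  n <- nrow(red)
  arr <- array(0, dim = c(1, 3, n, n))
  arr[1, 1, , ] <- red; arr[1, 2, , ] <- green; arr[1, 3, , ] <- blue
  FieldSeries(arr, 1, 0.24)
}

test_that("droplet means are the arithmetic mean over labeled pixels", {
  lab <- matrix(0L, 16, 16)
  lab[4:8, 4:8] <- 1L
  lab[12, 3:4] <- 2L
  m <- dropOx:::.labelMask(lab, 0.24)
  red <- matrix(0, 16, 16); red[lab == 1L] <- 100
  blue <- matrix(0, 16, 16); blue[12, 3] <- 2; blue[12, 4] <- 4
  fld <- miniField(red, matrix(0, 16, 16), blue)
  spots <- data.frame(track = c(1L, 2L), frame = 1L, row = c(6, 12),
                      col = c(6, 3.6), response = 1, label = c(1L, 2L))
  out <- dropletMeans(fld, 1, m, spots)
  expect_equal(out$I_R[out$label == 1L], 100)
  expect_equal(out$I_G[out$label == 1L], 0)
  expect_equal(out$I_B[out$label == 2L], 3)
  expect_equal(out$n_px, c(25L, 2L))
})

test_that("the oxidation ratio is correct, bounded and gain-invariant", {
  expect_equal(oxidationRatio(0, 50), 0)
  expect_equal(oxidationRatio(50, 0), 1)
  expect_equal(oxidationRatio(30, 70), 0.30)
  expect_true(is.na(oxidationRatio(0, 0)))
  expect_error(oxidationRatio(-1, 5), "nonnegative")
  set.seed(21)
  g <- runif(50, 0, 100); r <- runif(50, 0, 100); k <- runif(50, 0.1, 9)
  expect_equal(oxidationRatio(k * g, k * r), oxidationRatio(g, r))
  expect_true(all(oxidationRatio(g, r) >= 0 & oxidationRatio(g, r) <= 1))
})

test_that("the aqueous mean reads the exact mask complement", {
  lab <- matrix(0L, 10, 10); lab[1:4, 1:4] <- 1L
  m <- dropOx:::.labelMask(lab, 0.24)
  expect_equal(aqueousMean(matrix(0, 10, 10), m), 0)
  blue <- matrix(5, 10, 10); blue[lab == 1L] <- 99
  expect_equal(aqueousMean(blue, m), 5)
  full <- dropOx:::.labelMask(matrix(1L, 10, 10), 0.24)
  expect_true(is.na(aqueousMean(blue, full)))
})

test_that("droplet and aqueous means recombine exactly to the field mean", {
  sim <- noisyScene()
  blue <- getFrame(sim$field, 3, "blue")
  m <- segmentDroplets(getFrame(sim$field, 3, "red"),
                       pixelSizeUm = pixelSizeUm(sim$field))
  nFg <- sum(maskLabels(m) > 0L); nBg <- length(blue) - nFg
  fgMean <- mean(blue[maskLabels(m) > 0L])
  aqMean <- aqueousMean(blue, m)
  expect_equal((fgMean * nFg + aqMean * nBg) / length(blue), mean(blue),
               tolerance = 1e-12)
})

test_that("quantified means match generator expectations within 2%", {
  sim <- noisyScene()
  res <- analyzeField(sim$field, group = "A",
                      subtractBackground = fixtureBackground)
  d <- res$timeseries$droplets
  big <- d[d$n_px >= 200 & d$day == 1, ]
  expect_gt(nrow(big), 5)
  for (i in seq_len(nrow(big))) {
    ctr <- sim$centers[sim$centers$day == 1, ]
    tr <- res$tracks[res$tracks$track == big$trajectory[i] &
                       res$tracks$frame == 1, ]
    id <- ctr$droplet_id[which.min((ctr$row - tr$row)^2 +
                                     (ctr$col - tr$col)^2)]
    tru <- sim$truth[sim$truth$droplet_id == id, ]
    g <- gompertzEval(tru$a_lip, tru$b_lip, tru$c_lip, 1)
    expect_equal(big$I_R[i] + big$I_G[i], 150, tolerance = 0.02)
    expect_equal(big$ratio[i], g, tolerance = 0.05)
  }
})

test_that("lipid totals are conserved through the pipeline without noise", {
  sim <- staticScene()
  res <- analyzeField(sim$field, group = "A",
                      subtractBackground = fixtureBackground)
  d <- res$timeseries$droplets
  tot <- d$I_R + d$I_G
  dev <- tapply(tot, d$trajectory, function(x) diff(range(x)) / mean(x))
  expect_lt(max(dev), 0.01)
})

test_that("time-series assembly keeps one row per trajectory-day", {
  sim <- cleanScene()
  res <- analyzeField(sim$field, group = "G1")
  d <- res$timeseries$droplets
  expect_equal(nrow(d), length(unique(d$trajectory)) * 10)
  expect_true(all(table(d$trajectory) == 10))
  expect_true(all(d$group == "G1"))
  expect_equal(nrow(res$timeseries$field), 10)
  expect_true(all(res$timeseries$field$droplet_fraction > 0))
})
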