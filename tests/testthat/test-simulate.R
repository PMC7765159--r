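test_that("an empty scene renders pure background with empty ground truth", {
  sc <- scenarioConfig(fieldPx = 64L, fieldUm = 15.4, nDroplets = 0L,
                       days = 1:3, seed = 1L)
  sim <- generateField(sc, noise = FALSE)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$centers), 0L)
  expect_equal(nDays(sim$field), 3L)
  # red and green are exactly the configured backgrounds everywhere
  expect_true(all(getFrame(sim$field, 1, "red") == 2))
  expect_true(all(getFrame(sim$field, 2, "green") == 2))
  # blue is background plus the continuous-phase kinetic, uniform
  b <- getFrame(sim$field, 3, "blue")
  expect_equal(length(unique(as.vector(b))), 1L)
})

test_that("generation is deterministic in the seed", {
  sc <- scenarioConfig(fieldPx = 96L, fieldUm = 23, nDroplets = 5L,
                       days = 1:3, seed = 9L)
  a <- generateField(sc)
  b <- generateField(sc)
  expect_identical(a$field@intensities, b$field@intensities)
  expect_identical(a$truth, b$truth)
  d <- generateField(sc, seed = 10L)
  expect_false(identical(a$field@intensities, d$field@intensities))
})

test_that("noise-free lipid ratio follows the configured Gompertz curve", {
  # a = 1, b = 3, c = 0.5 at t = 10: g = exp(-3 exp(-5)) = 0.98002
  sc <- scenarioConfig(
    fieldPx = 96L, fieldUm = 23, nDroplets = 1L, days = c(1, 10),
    lipidKinetics = data.frame(group = "A", a = 1, a_sd = 0, b = 3,
                               b_sd = 0, c = 0.5, c_sd = 0, beta = 0),
    driftPxPerDay = 0, seed = 2L)
  sim <- generateField(sc, noise = FALSE)
  ctr <- sim$centers[sim$centers$day == 2, ]
  rows <- round(ctr$row) + (-1:1); cols <- round(ctr$col) + (-1:1)
  red <- getFrame(sim$field, 2, "red")[rows, cols] - 2
  green <- getFrame(sim$field, 2, "green")[rows, cols] - 2
  ratio <- mean(green) / (mean(green) + mean(red))
  expect_equal(ratio, exp(-3 * exp(-5)), tolerance = 0.005)
  expect_equal(exp(-3 * exp(-5)), 0.979989, tolerance = 1e-6)
})

test_that("red + green is conserved across days without noise", {
  sim <- cleanScene()
  tot <- sapply(seq_len(nDays(sim$field)), function(d)
    sum(getFrame(sim$field, d, "red") + getFrame(sim$field, d, "green")))
  expect_lt(max(abs(tot - mean(tot))) / mean(tot), 1e-3)
})

test_that("Poisson means converge to expectations on large droplets", {
  sc <- scenarioConfig(fieldPx = 128L, fieldUm = 30.75, nDroplets = 1L,
                       radiusRangeUm = c(2.4, 2.4), days = c(1, 5),
                       driftPxPerDay = 0, seed = 33L)
  sim <- generateField(sc)
  ctr <- sim$centers[sim$centers$day == 1, ]
  rPx <- sim$truth$radius_px
  expect_gt(pi * rPx^2, 200)   # interior large enough for 2% convergence
  rr <- seq_len(128); d2 <- outer((rr - ctr$row)^2, (rr - ctr$col)^2, `+`)
  interior <- d2 <= (rPx - 1.5)^2
  tot <- getFrame(sim$field, 1, "red")[interior] +
    getFrame(sim$field, 1, "green")[interior]
  expect_equal(mean(tot), 150 + 4, tolerance = 0.02)
  blue <- getFrame(sim$field, 1, "blue")[interior]
  expTruth <- sim$truth$a_prot * exp(-sim$truth$b_prot *
                                       exp(-sim$truth$c_prot * 1)) + 1.5
  expect_equal(mean(blue), expTruth, tolerance = 0.02)
})

test_that("impossible packing fails with the achieved count", {
  sc <- scenarioConfig(fieldPx = 48L, fieldUm = 11.5, nDroplets = 40L,
                       days = 1:2, seed = 3L)
  expect_error(generateField(sc), "placement failed.*placed")
})

test_that("invalid configurations are rejected", {
  expect_error(scenarioConfig(days = c(3, 1)), "strictly increasing")
  expect_error(scenarioConfig(dropoutProb = 1.5), "dropoutProb")
  expect_error(scenarioConfig(radiusRangeUm = c(-1, 2)), "radiusRangeUm")
})

test_that("dropoutMaxDays caps missing days and spares first and last day", {
  sc <- scenarioConfig(fieldPx = 256L, fieldUm = 61.5, nDroplets = 15L,
                       dropoutProb = 0.4, dropoutMaxDays = 1, seed = 5L)
  sim <- generateField(sc, noise = FALSE)
  perDroplet <- tapply(sim$centers$present, sim$centers$droplet_id, sum)
  expect_true(all(perDroplet >= 9))
  expect_true(any(perDroplet == 9))
  edge <- sim$centers$day %in% c(1, 10)
  expect_true(all(sim$centers$present[edge]))
})

test_that("ground truth round-trips through CSV", {
  sim <- cleanScene()
  path <- withr::local_tempfile(fileext = ".csv")
  writeGroundTruth(sim$truth, path)
  back <- readGroundTruth(path)
  expect_equal(back, sim$truth)
  expect_equal(nrow(back), 20L)
  # empty truth: header-only file
  writeGroundTruth(sim$truth[0, ], path)
  expect_equal(nrow(readGroundTruth(path)), 0L)
  expect_equal(names(readGroundTruth(path)), names(sim$truth))
})
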