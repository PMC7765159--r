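test_that("the assignment solver matches brute-force enumeration", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n)
    sol <- dropOx:::.solveAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]),
                 bruteAssignmentCost(cost), tolerance = 1e-12)
  }
})

test_that("frame-pair linking is optimal for the augmented objective", {
  set.seed(8)
  tp <- trackingParams()
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    a <- matrix(runif(n1 * 2, 0, 40), n1)
    b <- matrix(runif(n2 * 2, 0, 40), n2)
    d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
    adm <- d2 <= tp$linkingMaxDistancePx^2
    if (!any(adm)) next
    alt <- tp$altCostFactor *
      quantile(d2[adm], tp$altCostPercentile, names = FALSE)
    link <- dropOx:::.linkFramePair(d2, tp$linkingMaxDistancePx,
                                    tp$altCostFactor, tp$altCostPercentile)
    expect_equal(achievedLinkCost(d2, link, alt),
                 bruteLinkCost(d2, tp$linkingMaxDistancePx, alt),
                 tolerance = 1e-9)
  }
})

test_that("LoG detection localizes disks to sub-pixel accuracy", {
  expect_equal(nrow(detectSpots(matrix(5, 64, 64))), 0L)
  img <- paintDisks(256L, rbind(c(100, 200)), 7)
  s <- detectSpots(img)
  expect_equal(nrow(s), 1L)
  expect_lt(sqrt((s$row - 100)^2 + (s$col - 200)^2), 0.5)
})

test_that("all droplets in a field are detected near their true centers", {
  # radii close to the configured blob diameter (14 px ~ 1.7 um radius)
  sc <- scenarioConfig(fieldPx = 256L, fieldUm = 61.5, nDroplets = 20L,
                       radiusRangeUm = c(1.6, 1.8), seed = 55L)
  sim <- generateField(sc, noise = FALSE)
  s <- detectSpots(getFrame(sim$field, 1, "red"))
  ctr <- sim$centers[sim$centers$day == 1, ]
  expect_equal(nrow(s), nrow(ctr))
  # one-to-one match within 1 px (greedy nearest is enough at this spacing)
  d <- sqrt(outer(s$row, ctr$row, `-`)^2 + outer(s$col, ctr$col, `-`)^2)
  expect_true(all(apply(d, 2, min) < 1))
  expect_equal(sort(apply(d, 2, which.min)), seq_len(nrow(s)))
})

test_that("drifting droplets are tracked without identity switches", {
  sim <- cleanScene()
  tp <- trackingParams()
  spotsByDay <- lapply(1:10, function(d)
    detectSpots(getFrame(sim$field, d, "red"), tp))
  tr <- linkTracks(spotsByDay, tp)
  expect_equal(length(unique(tr$track)), 20L)
  ctr <- sim$centers
  truthOf <- vapply(seq_len(nrow(tr)), function(i) {
    cd <- ctr[ctr$day == tr$frame[i], ]
    cd$droplet_id[which.min((cd$row - tr$row[i])^2 + (cd$col - tr$col[i])^2)]
  }, 0)
  expect_true(all(tapply(truthOf, tr$track, function(x)
    length(unique(x))) == 1))
  expect_true(all(table(tr$track) == 10))
})

test_that("a one-day dropout is closed into a single track", {
  set.seed(12)
  base <- cbind(row = c(50, 120), col = c(60, 130))
  centerList <- lapply(1:10, function(f) {
    m <- base + (f - 1) * 1.5
    if (f == 5) m <- m[2, , drop = FALSE]   # droplet 1 invisible on day 5
    m
  })
  tr <- linkTracks(spotsFromCenters(centerList))
  expect_equal(length(unique(tr$track)), 2L)
  lens <- table(tr$track)
  expect_setequal(as.integer(lens), c(9L, 10L))
  gappy <- names(lens)[lens == 9]
  expect_equal(setdiff(1:10, tr$frame[tr$track == gappy]), 5)
})

test_that("well-separated droplets never swap identities", {
  centerList <- lapply(1:10, function(f) rbind(
    c(50 + 4 * f, 100), c(50 + 4 * (10 - f), 200)))   # opposing drifts
  tr <- linkTracks(spotsFromCenters(centerList))
  expect_equal(length(unique(tr$track)), 2L)
  expect_true(all(tapply(tr$col, tr$track, function(x)
    length(unique(x)) == 1)))
})

test_that("the spot-count filter keeps only full-duration tracks", {
  tr <- data.frame(track = rep(1:2, c(10, 9)), frame = c(1:10, 1:9),
                   row = 1, col = 1, response = 1)
  out <- filterTracks(tr)
  expect_equal(unique(out$track), 1L)
  expect_equal(nrow(filterTracks(tr[0, ])), 0L)
})

test_that("labels are assigned to spots with conflict resolution", {
  lab <- matrix(0L, 32, 32)
  lab[10:14, 10:14] <- 1L
  m <- dropOx:::.labelMask(lab, 0.24)
  # spot at the centroid gets the label; continuous-phase spot gets a gap
  tr <- data.frame(track = c(1L, 2L), frame = 1L,
                   row = c(12, 25), col = c(12, 25), response = 1)
  res <- assignLabels(tr, list(m))
  expect_equal(res$spots$label, c(1L, 0L))
  expect_equal(res$trajectories$n_labeled, c(1L, 0L))
  expect_equal(res$spots$radius_um[1], sqrt(25 / pi) * 0.24)
  # two spots on one label: nearer centroid wins, loser gets a gap
  tr2 <- data.frame(track = c(1L, 2L), frame = 1L,
                    row = c(12.2, 13.9), col = c(12, 13.5), response = 1)
  res2 <- assignLabels(tr2, list(m))
  expect_equal(res2$spots$label, c(1L, 0L))
  expect_error(assignLabels(data.frame(track = 1L, frame = 2L, row = 1,
                                       col = 1, response = 1), list(m)),
               "frames beyond")
})
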