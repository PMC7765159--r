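mkRates <- function(y, group, invr) {
  data.frame(trajectory = seq_along(y), group = group, radius_um = 1 / invr,
             inv_radius = invr, c_lip = y, c_prot = y)
}

test_that("ANCOVA matches the brute-force extra-sum-of-squares oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(c(6L, 12L, 20L), 1)
    g <- rep(c("A", "B"), length.out = n)
    x <- runif(n, 0.4, 0.7)
    y <- 0.3 + 0.1 * (g == "B") + 0.5 * x + rnorm(n, 0, 0.05)
    res <- rateAncova(mkRates(y, g, x), "c_lip")
    oracle <- bruteAncova(y, g, x)
    expect_equal(res$F, oracle$F, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
    expect_equal(res$beta, as.numeric(oracle$beta), tolerance = 1e-10)
  }
})

test_that("ANCOVA is invariant to group relabeling", {
  set.seed(42)
  g <- rep(c("A", "B", "C"), each = 10)
  x <- runif(30, 0.4, 0.7)
  y <- 0.3 + 0.2 * (g == "C") + rnorm(30, 0, 0.05)
  r1 <- rateAncova(mkRates(y, g, x), "c_lip")
  swap <- c(A = "Z", B = "Q", C = "M")[g]
  r2 <- rateAncova(mkRates(y, swap, x), "c_lip")
  expect_equal(r1$F, r2$F)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$beta, r2$beta)
})

test_that("ANCOVA rejects degenerate designs", {
  expect_error(rateAncova(mkRates(1:6 / 10, rep("A", 6), runif(6)), "c_lip"),
               "two formulation groups")
  expect_error(rateAncova(mkRates(1:6 / 10, rep(c("A", "B"), 3),
                                  rep(0.5, 6)), "c_lip"),
               "degenerate covariate")
})

test_that("a strong injected formulation effect is detected", {
  set.seed(43)
  g <- rep(c("A", "B"), each = 25)
  x <- runif(50, 0.4, 0.7)
  y <- 0.3 + 0.3 * (g == "B") + rnorm(50, 0, 0.02)
  expect_lt(rateAncova(mkRates(y, g, x), "c_lip")$p, 1e-4)
})

test_that("within-group regression recovers slopes and is exact on lines", {
  x <- seq(0.4, 0.7, length.out = 10)
  r <- mkRates(0.2 + 0.5 * x, "A", x)
  s <- suppressWarnings(withinGroupRegression(r, "c_prot", "A"))
  expect_equal(s$slope, 0.5, tolerance = 1e-10)
  expect_equal(s$intercept, 0.2, tolerance = 1e-10)
  expect_lt(s$p, 1e-12)
  set.seed(44)
  x <- runif(400, 1 / 2.5, 1 / 1.5)
  y <- 0.2 + 0.5 * x + rnorm(400, 0, 0.05)
  s2 <- withinGroupRegression(mkRates(y, "A", x), "c_prot", "A")
  expect_equal(s2$slope, 0.5, tolerance = 0.1)
  expect_error(withinGroupRegression(mkRates(1:2 / 10, "A", c(0.5, 0.6)),
                                     "c_lip", "A"), "at least 3")
})

test_that("the report table collects tests with significance flags", {
  expect_equal(nrow(summarizeTests(list())), 0L)
  set.seed(45)
  g <- rep(c("A", "B"), each = 20)
  x <- runif(40, 0.4, 0.7)
  y <- 0.3 + 0.3 * (g == "B") + 0.5 * x + rnorm(40, 0, 0.02)
  r <- mkRates(y, g, x)
  tab <- summarizeTests(rateAncova(r, "c_lip"),
                        withinGroupRegression(r, "c_lip", "A"),
                        withinGroupRegression(r, "c_lip", "B"),
                        withinGroupRegression(r, "c_prot", "A"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$test[1], "ancova_formulation")
  expect_true(tab$significant[1])
  expect_true(all(c("statistic", "p", "n") %in% names(tab)))
})
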