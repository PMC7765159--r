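# Shared desk-scale fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# Homogeneous per-group kinetics: all droplets share one brightness
# trajectory, so the global percentile threshold treats them alike on
# every day (droplet-to-droplet brightness spread is a documented
# limitation of the fixed-threshold segmenter, tested separately).
homogKinetics <- function() list(
  lipid = data.frame(group = "A", a = 0.88, a_sd = 0, b = 3.5, b_sd = 0,
                     c = 0.5, c_sd = 0, beta = 0),
  protein = data.frame(group = "A", a = 6.4, a_sd = 0, b = 34, b_sd = 0,
                       c = 0.39, c_sd = 0, beta = 0))

# 20 non-overlapping droplets, noise-free, quarter-size field
cleanScene <- function() fixture("cleanScene", function() {
  k <- homogKinetics()
  sc <- scenarioConfig(fieldPx = 256L, fieldUm = 61.5, nDroplets = 20L,
                       driftPxPerDay = 2, lipidKinetics = k$lipid,
                       proteinKinetics = k$protein, seed = 101L)
  generateField(sc, noise = FALSE)
})

# Same scene with Poisson noise
noisyScene <- function() fixture("noisyScene", function() {
  k <- homogKinetics()
  sc <- scenarioConfig(fieldPx = 256L, fieldUm = 61.5, nDroplets = 20L,
                       driftPxPerDay = 2, lipidKinetics = k$lipid,
                       proteinKinetics = k$protein, seed = 101L)
  generateField(sc, noise = TRUE)
})

# Static conversion scene: no drift, no noise, homogeneous kinetics -- the
# droplet pixel set is identical on every day, isolating red/green
# conversion conservation from rim re-discretization and from the
# brightness-dependent thresholding of heterogeneous droplets.
staticScene <- function() fixture("staticScene", function() {
  k <- homogKinetics()
  sc <- scenarioConfig(fieldPx = 256L, fieldUm = 61.5, nDroplets = 20L,
                       driftPxPerDay = 0, lipidKinetics = k$lipid,
                       proteinKinetics = k$protein, seed = 101L)
  generateField(sc, noise = FALSE)
})

fixtureBackground <- c(red = 2, green = 2, blue = 1.5)
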