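test_that("landscape config rejects invalid inputs with diagnostics", {
  vars <- data.frame(name = c("a", "b"), corLength = 2, mean = 0, sd = 1)
  expect_error(landscapeConfig(4, 32, vars), "at least 8 x 8")
  expect_error(
    landscapeConfig(16, 16, data.frame(name = c("a", "a"),
                                       corLength = 2, mean = 0, sd = 1)),
    "unique")
  badC <- matrix(c(1, 2, 2, 1), 2)  # correlation 2: not PSD
  expect_error(landscapeConfig(16, 16, vars, crossCorrelation = badC),
               "positive semi-definite")
  expect_error(landscapeConfig(16, 16, vars,
                               crossCorrelation = matrix(c(1, .2, .3, 1), 2)),
               "symmetric")
})

test_that("perfectly correlated variables yield identical layers", {
  vars <- data.frame(name = c("a", "b"), corLength = c(3, 3),
                     mean = 5, sd = 2)
  cfg <- landscapeConfig(32, 32, vars,
                         crossCorrelation = matrix(1, 2, 2), seed = 7)
  g <- generateLandscape(cfg)
  v <- gridValues(g)
  expect_lt(max(abs(v[, "a"] - v[, "b"])), 1e-8)
})

test_that("uncorrelated layers show near-zero sample correlation", {
  # short correlation length keeps the effective sample size high enough
  # that |cor| < 0.2 is a ~5-sigma bound
  vars <- data.frame(name = c("a", "b"), corLength = 2, mean = 0, sd = 1)
  for (s in 1:5) {
    g <- generateLandscape(landscapeConfig(128, 128, vars, seed = s))
    r <- cor(gridValues(g)[, 1], gridValues(g)[, 2])
    expect_gt(r, -0.2); expect_lt(r, 0.2)
  }
})

test_that("generation is a pure function of the config (seed included)", {
  vars <- data.frame(name = c("a", "b"), corLength = c(2, 5),
                     mean = c(1, -1), sd = c(0.5, 3))
  cfg <- landscapeConfig(16, 24, vars,
                         crossCorrelation = matrix(c(1, .4, .4, 1), 2),
                         seed = 99)
  expect_identical(gridValues(generateLandscape(cfg)),
                   gridValues(generateLandscape(cfg)))
})

test_that("realized marginals match the specification", {
  vars <- data.frame(name = c("dd5", "MAP", "PET"), corLength = c(0, 4, 8),
                     mean = c(900, 600, 1100), sd = c(150, 220, 90))
  g <- generateLandscape(landscapeConfig(64, 64, vars, seed = 2))
  v <- gridValues(g)
  for (j in 1:3) {
    expect_lt(abs(mean(v[, j]) - vars$mean[j]), 0.1 * abs(vars$mean[j]))
    expect_lt(abs(sd(v[, j]) - vars$sd[j]), 0.1 * vars$sd[j])
  }
})

test_that("suitability surface follows the Gaussian-product closed form", {
  # one cell pinned at the optimum, one at optimum + tolerance
  vals <- matrix(c(2, 3, 5, 5), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  g <- ClimateGrid(vals, 2, 1)
  niche <- nicheSpec(c(v1 = 2, v2 = 5), tolerance = c(v1 = 1, v2 = 1),
                     weight = c(v1 = 1, v2 = 0), maxSuitability = 1)
  s <- surfaceValues(suitabilitySurface(g, niche))
  expect_equal(s[1], 1)                 # at joint optimum
  expect_equal(s[2], exp(-0.5))         # one tolerance away on v1
  flat <- nicheSpec(c(v1 = 0, v2 = 0), weight = c(v1 = 0, v2 = 0),
                    maxSuitability = 0.7)
  expect_equal(surfaceValues(suitabilitySurface(g, flat)), rep(0.7, 2))
})

test_that("suitability rejects unknown variables, naming the grid's", {
  g <- tinyGrid()
  expect_error(
    suitabilitySurface(g, nicheSpec(c(zz = 0))),
    "zz.*v1.*v2")
})

test_that("suitability stays in [0, 1] for random parameterizations", {
  g <- tinyGrid(16, 16, seed = 4)
  set.seed(10)
  for (k in 1:20) {
    opts <- rnorm(2, 0, 3)
    niche <- nicheSpec(c(v1 = opts[1], v2 = opts[2]),
                       tolerance = runif(1, 0.1, 2),
                       weight = runif(2, 0, 3),
                       maxSuitability = runif(1, 0.05, 1))
    s <- surfaceValues(suitabilitySurface(g, niche))
    expect_gte(min(s), 0); expect_lte(max(s), 1)
  }
})

test_that("occurrence sampling honours counts and degenerate niches", {
  g <- tinyGrid(8, 8)
  flat1 <- nicheSpec(c(v1 = 0), weight = c(v1 = 0), maxSuitability = 1)
  occ <- sampleOccurrences(g, flat1, samplingSpec(50, 0, "NC", seed = 3))
  expect_equal(nPresence(occ), 50)
  expect_equal(nAbsence(occ), 0)
  expect_true(all(as.data.frame(occ)$cluster == "NC"))
  # suitability identically one: absences impossible
  expect_error(sampleOccurrences(g, flat1, samplingSpec(0, 5, seed = 3)),
               "identically one")
  occA <- sampleOccurrences(g, nicheSpec(c(v1 = 0), tolerance = 1),
                            samplingSpec(0, 10, seed = 4))
  expect_equal(nPresence(occA), 0); expect_equal(nAbsence(occA), 10)
  # optimum so remote that suitability underflows to zero everywhere
  far <- nicheSpec(c(v1 = 1e6), tolerance = 1e-3)
  expect_error(sampleOccurrences(g, far, samplingSpec(5, 0, seed = 1)),
               "identically zero")
  expect_identical(
    as.data.frame(sampleOccurrences(g, flat1, samplingSpec(20, 0, seed = 8))),
    as.data.frame(sampleOccurrences(g, flat1, samplingSpec(20, 0, seed = 8))))
})

test_that("presences concentrate nearer the optimum than absences", {
  closer <- 0
  for (s in 1:100) {
    g <- generateLandscape(landscapeConfig(16, 16, data.frame(
      name = c("v1", "v2"), corLength = 2, mean = 0, sd = 1), seed = s))
    niche <- nicheSpec(c(v1 = 0.5, v2 = 0), tolerance = 0.3,
                       weight = c(v1 = 1, v2 = 0), maxSuitability = 0.95)
    adm <- extractFeatures(g, sampleOccurrences(
      g, niche, samplingSpec(30, 30, seed = s + 1000)))
    v1 <- features(adm)[, "v1"]; y <- presenceLabels(adm)
    closer <- closer +
      (abs(mean(v1[y == 1]) - 0.5) < abs(mean(v1[y == 0]) - 0.5))
  }
  expect_gte(closer, 95)
})

test_that("realized acceptance rate rises with maximum suitability", {
  levels <- c(0.2, 0.5, 0.9)
  rates <- matrix(0, 20, 3)
  for (s in 1:20) for (j in 1:3) {
    g <- generateLandscape(landscapeConfig(16, 16, data.frame(
      name = "v1", corLength = 2, mean = 0, sd = 1), seed = s))
    niche <- nicheSpec(c(v1 = 0), tolerance = 1, maxSuitability = levels[j])
    occ <- sampleOccurrences(g, niche, samplingSpec(40, 0, seed = s))
    rates[s, j] <- attr(occ, "acceptanceRate")["presence"]
  }
  m <- colMeans(rates)
  expect_lt(m[1], m[2]); expect_lt(m[2], m[3])
})

test_that("two-cluster scenario bookkeeping and divergence-0 symmetry", {
  sc <- makeTwoClusterScenario(0, width = 32, height = 32,
                               nPresence = 40, nAbsence = 60, seed = 5)
  expect_equal(nPresence(sc$occ), 80)
  expect_equal(nAbsence(sc$occ), 60)
  expect_equal(nrow(as.data.frame(sc$occ)),
               nPresence(sc$occNC) + nPresence(sc$occSC) + 60)
  expect_identical(sc$nicheNC, sc$nicheSC)  # divergence 0: one shared niche
  expect_error(makeTwoClusterScenario(-1), "nonnegative")
})

test_that("strongly diverged clusters occupy disjoint climate ranges", {
  disjoint <- 0
  for (s in 1:100) {
    sc <- makeTwoClusterScenario(6, width = 32, height = 32,
                                 nPresence = 30, nAbsence = 10, seed = s)
    adm <- extractFeatures(sc$grid, sc$occ)
    v1 <- features(adm)[, "v1"]
    cl <- as.data.frame(sc$occ)$cluster
    rNC <- range(v1[cl == "NC"]); rSC <- range(v1[cl == "SC"])
    disjoint <- disjoint + (rNC[2] < rSC[1] || rSC[2] < rNC[1])
  }
  expect_gte(disjoint, 95)
})
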