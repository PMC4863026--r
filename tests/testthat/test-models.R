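test_that("the registry knows the native methods and rejects strangers", {
  expect_true(all(c("GLM", "GAM", "CTA", "RF", "ANN", "SRE") %in% sdmMethods()))
  expect_error(modelSpec("MAXENT"), "unknown model method")
  expect_error(modelSpec("SRE", list(bogus = 1)), "unknown hyperparameter")
})

test_that("custom methods can be registered behind the same contract", {
  registerSDMMethod("V1LOGISTIC",
                    fit = function(x, y, h) NULL,
                    predict = function(fit, x, h) plogis(x[, "v1"]))
  adm <- separableDesign(60)
  m <- fitModel(modelSpec("V1LOGISTIC"), adm)
  expect_equal(predictModel(m, features(adm)), plogis(features(adm)[, "v1"]))
})

test_that("GLM separates a linearly separable toy set perfectly", {
  adm <- separableDesign(100)
  m <- fitModel(modelSpec("GLM", seed = 1), adm)
  pred <- predictModel(m, adm)
  expect_equal(mean((pred >= 0.5) == (presenceLabels(adm) == 1L)), 1)
})

test_that("intercept-only GLM on balanced classes predicts one half", {
  x <- cbind(v1 = rep(1, 40))            # constant feature
  adm <- admFromMatrix(x, rep(c(1L, 0L), 20))
  m <- fitModel(modelSpec("GLM"), adm)
  expect_equal(predictModel(m, x), rep(0.5, 40), tolerance = 1e-8)
})

test_that("SRE envelope matches its by-hand definition at quantile 0", {
  xp <- cbind(v1 = seq(2, 8, length.out = 20))
  adm <- admFromMatrix(xp, rep(1L, 20))  # presence-only fit
  m <- fitModel(modelSpec("SRE", list(quantile = 0)), adm)
  test <- cbind(v1 = c(1.9, 2, 5, 8, 8.1))
  expect_equal(predictModel(m, test), c(0, 1, 1, 1, 0))
})

test_that("SRE membership equals a direct per-variable interval check", {
  set.seed(42)
  for (rep in 1:10) {
    x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("v1", "v2")))
    y <- rep(c(1L, 0L), 15)
    q <- 0.05
    m <- fitModel(modelSpec("SRE", list(quantile = q)), admFromMatrix(x, y))
    xt <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("v1", "v2")))
    xp <- x[y == 1L, , drop = FALSE]
    inside <- rep(TRUE, 20)
    for (j in 1:2) {
      lo <- quantile(xp[, j], q, type = 7); hi <- quantile(xp[, j], 1 - q, type = 7)
      inside <- inside & xt[, j] >= lo & xt[, j] <= hi
    }
    expect_identical(predictModel(m, xt), as.numeric(inside))
  }
})

test_that("stochastic learners are deterministic given seed and data", {
  d <- nicheDesign(200, seed = 9)
  for (method in c("RF", "ANN")) {
    m1 <- fitModel(modelSpec(method, seed = 77), d$adm)
    m2 <- fitModel(modelSpec(method, seed = 77), d$adm)
    expect_identical(predictModel(m1, d$adm), predictModel(m2, d$adm))
  }
})

test_that("training-row order does not change any method's predictions", {
  d <- nicheDesign(200, seed = 5)
  set.seed(1); perm <- sample(nrow(features(d$adm)))
  shuffled <- d$adm[perm]
  probe <- features(d$adm)[1:50, ]
  for (method in c("GLM", "GAM", "CTA", "RF", "ANN", "SRE")) {
    m1 <- fitModel(modelSpec(method, seed = 3), d$adm)
    m2 <- fitModel(modelSpec(method, seed = 3), shuffled)
    expect_equal(predictModel(m1, probe), predictModel(m2, probe),
                 tolerance = 1e-10)
  }
})

test_that("predictions are a row-wise map in [0, 1]", {
  d <- nicheDesign(150, seed = 11)
  probe <- features(d$adm)
  set.seed(2); perm <- sample(nrow(probe))
  for (method in c("GLM", "CTA", "RF", "ANN", "SRE")) {
    m <- fitModel(modelSpec(method, seed = 4), d$adm)
    p <- predictModel(m, probe)
    expect_length(p, nrow(probe))
    expect_gte(min(p), 0); expect_lte(max(p), 1)
    expect_equal(predictModel(m, probe[perm, ]), p[perm])
    if (method == "SRE") expect_true(all(p %in% c(0, 1)))
  }
})

test_that("contract failures carry actionable messages", {
  d <- nicheDesign(100, seed = 13)
  onlyPres <- d$adm[presenceLabels(d$adm) == 1L]
  expect_error(fitModel(modelSpec("GLM"), onlyPres),
               "GLM requires both classes.*0 absences")
  m <- fitModel(modelSpec("GLM"), d$adm)
  probe <- features(d$adm)[, "v1", drop = FALSE]
  expect_error(predictModel(m, probe), "missing training variable.*v2")
})
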