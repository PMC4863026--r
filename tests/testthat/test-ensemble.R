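test_that("stratified split yields exact per-class counts and a partition", {
  adm <- admFromMatrix(cbind(v1 = rnorm(100)), rep(c(1L, 0L), 50))
  sp <- splitData(adm, 0.8, seed = 1)
  expect_equal(nrow(features(sp$train)), 80)
  expect_equal(nrow(features(sp$test)), 20)
  expect_equal(sum(presenceLabels(sp$train)), 40)
  expect_equal(sum(presenceLabels(sp$test)), 10)
  expect_setequal(c(sp$train@recordId, sp$test@recordId), 1:100)
  expect_length(intersect(sp$train@recordId, sp$test@recordId), 0)

  sp2 <- splitData(adm[1:10], 0.5, seed = 2)
  expect_equal(nrow(features(sp2$train)), 5)
  expect_equal(nrow(features(sp2$test)), 5)

  spA <- splitData(adm, 0.8, seed = 7); spB <- splitData(adm, 0.8, seed = 7)
  expect_identical(spA$train@recordId, spB$train@recordId)
  tiny <- admFromMatrix(cbind(v1 = rnorm(3)), c(1L, 0L, 0L))
  expect_error(splitData(tiny, 0.8), "at least 2 records per class")
})

test_that("TSS arithmetic matches hand-computed confusion matrices", {
  # perfect correspondence
  ev <- evaluateTSS(c(.9, .8, .2, .1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(ev$tss, 1)
  # uninformative: everything classified presence at 0.5
  ev0 <- evaluateTSS(rep(0.5, 20), rep(c(1, 0), 10), threshold = 0.5)
  expect_equal(ev0$sensitivity, 1)
  expect_equal(ev0$specificity, 0)
  expect_equal(ev0$tss, 0)
  # TP=40, FN=10, TN=45, FP=5 -> sens .8, spec .9, tss .7
  pred <- c(rep(.9, 40), rep(.1, 10), rep(.1, 45), rep(.9, 5))
  lab <- c(rep(1, 50), rep(0, 50))
  ev2 <- evaluateTSS(pred, lab, threshold = 0.5)
  expect_equal(ev2$sensitivity, 0.8)
  expect_equal(ev2$specificity, 0.9)
  expect_equal(ev2$tss, 0.7)
  expect_equal(ev2$tss, ev2$sensitivity + ev2$specificity - 1)
  expect_error(evaluateTSS(c(.1, .2), c(1, 1)), "both classes")
})

test_that("the TSS identity holds exactly for random evaluations", {
  set.seed(21)
  for (k in 1:20) {
    pred <- runif(60); lab <- rbinom(60, 1, 0.5)
    if (length(unique(lab)) < 2) next
    ev <- evaluateTSS(pred, lab)
    expect_identical(ev$tss, ev$sensitivity + ev$specificity - 1)
    expect_gte(ev$tss, -1); expect_lte(ev$tss, 1)
  }
})

test_that("threshold maximization finds a separating cut, lowest on ties", {
  ev <- evaluateTSS(c(.9, .7, .3, .1), c(1, 1, 0, 0))
  expect_equal(ev$tss, 1)
  expect_equal(ev$threshold, 0.7)   # lowest threshold achieving max TSS
})

test_that("singleton and identical-member ensembles reduce to the member", {
  d <- nicheDesign(200, seed = 31)
  e1 <- buildEnsemble(d$adm, "GLM", nRuns = 1, gate = 0, seed = 8)
  member <- e1@members[[1]]
  probe <- features(d$adm)[1:40, ]
  expect_equal(predictEnsemble(e1, probe), predictModel(member, probe))
  # two members with identical predictions average to either
  info <- memberInfo(e1)[c(1, 1), ]
  eDup <- EnsembleModel(list(member, member), info, gate = 0)
  expect_equal(predictEnsemble(eDup, probe), predictModel(member, probe))
})

test_that("gate excludes weak members and the TSS-weighted mean is exact", {
  registerSDMMethod("CONST1", function(x, y, h) NULL,
                    function(f, x, h) rep(1, nrow(x)))
  registerSDMMethod("CONST0", function(x, y, h) NULL,
                    function(f, x, h) rep(0, nrow(x)))
  adm <- separableDesign(40)
  m1 <- fitModel(modelSpec("CONST1"), adm)
  m0 <- fitModel(modelSpec("CONST0"), adm)
  info <- data.frame(method = c("CONST1", "CONST0"), run = 1L,
                     sensitivity = 1, specificity = 1,
                     tss = c(0.9, 0.3), threshold = 0.5, nTest = 10L)
  e <- EnsembleModel(list(m1, m0), info, gate = 0.6)
  expect_equal(includedMembers(e), 1L)      # only tss 0.9 passes 0.6
  probe <- features(adm)[1:5, ]
  expect_equal(predictEnsemble(e, probe), rep(1, 5))
  # both pass a zero gate; tss-weighted mean of preds {1, 0} w {0.8, 0.7}
  info$tss <- c(0.8, 0.7)
  eW <- EnsembleModel(list(m1, m0), info, gate = 0.6, aggregation = "tss")
  expect_equal(predictEnsemble(eW, probe), rep(8 / 15, 5), tolerance = 1e-12)
})

test_that("the ensemble surface is bounded by member surfaces", {
  d <- nicheDesign(240, seed = 41)
  e <- buildEnsemble(d$adm, c("GLM", "CTA", "SRE"), nRuns = 2, gate = -1,
                     seed = 19)
  s <- surfaceValues(predictSurface(e, d$grid))
  mem <- sapply(seq_along(e@members),
                function(i) surfaceValues(predictModel(e@members[[i]], d$grid)))
  expect_true(all(s >= apply(mem, 1, min) - 1e-12))
  expect_true(all(s <= apply(mem, 1, max) + 1e-12))
  expect_gte(min(s), 0); expect_lte(max(s), 1)
})

test_that("raising the gate never adds members; emptying it errors", {
  d <- nicheDesign(200, seed = 51)
  e <- buildEnsemble(d$adm, c("GLM", "CTA", "SRE"), nRuns = 3, gate = -1,
                     seed = 23)
  prev <- includedMembers(e)
  for (g in c(0, 0.2, 0.4, 0.6)) {
    eg <- tryCatch(applyGate(e, g), error = function(e) NULL)
    if (is.null(eg)) break
    expect_true(all(includedMembers(eg) %in% prev))
    prev <- includedMembers(eg)
  }
  expect_error(applyGate(e, 1.5), "empty ensemble")
  # noise labels cannot pass a 0.6 gate
  set.seed(3)
  noise <- admFromMatrix(cbind(v1 = rnorm(200), v2 = rnorm(200)),
                         rbinom(200, 1, 0.5))
  expect_error(buildEnsemble(noise, "GLM", nRuns = 2, gate = 0.6, seed = 2),
               "empty ensemble.*TSS")
})

test_that("committee averaging is no worse than the median member", {
  wins <- 0; nSeeds <- 30
  for (s in seq_len(nSeeds)) {
    d <- nicheDesign(300, seed = 100 + s)
    sp <- splitData(d$adm, 0.7, seed = s)
    e <- buildEnsemble(sp$train, c("GLM", "CTA", "SRE"), nRuns = 2,
                       gate = -1, seed = s)
    hold <- sp$test
    tssOf <- function(p) evaluateTSS(p, presenceLabels(hold))$tss
    eTss <- tssOf(predictEnsemble(e, hold))
    mTss <- vapply(e@members, function(m) tssOf(predictModel(m, hold)), 0)
    wins <- wins + (eTss >= median(mTss))
  }
  expect_gte(wins, 0.8 * nSeeds)
})

test_that("the member report records every fit with its evaluation", {
  d <- nicheDesign(200, seed = 61)
  e <- buildEnsemble(d$adm, c("GLM", "SRE"), nRuns = 3, gate = -1, seed = 5)
  rep_ <- ensembleReport(e)
  expect_equal(nrow(rep_), 6)
  expect_setequal(unique(rep_$method), c("GLM", "SRE"))
  expect_equal(rep_$tss, rep_$sensitivity + rep_$specificity - 1)
  path <- tempfile(fileext = ".csv")
  ensembleReport(e, path)
  expect_equal(read.csv(path)$tss, rep_$tss, tolerance = 1e-12)
})
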