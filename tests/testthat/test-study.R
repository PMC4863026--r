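scenarioOcc <- function() {
  # 30 NC presences, 10 SC presences, 50 shared absences at arbitrary coords
  bindOccurrences(
    OccurrenceSet(runif(30, 0, 8), runif(30, 0, 8), 1L, "NC"),
    OccurrenceSet(runif(10, 0, 8), runif(10, 0, 8), 1L, "SC"),
    OccurrenceSet(runif(50, 0, 8), runif(50, 0, 8), 0L, "none"))
}

test_that("partitions pair cluster presences with all shared absences", {
  set.seed(2); occ <- scenarioOcc()
  parts <- assemblePartitions(occ, c("NC", "SC"), seed = 9)
  expect_equal(nrow(as.data.frame(parts$NC)), 30 + 50)
  expect_equal(nrow(as.data.frame(parts$SC)), 10 + 50)
  # EP: all 40 presences + absences subsampled to the presence count
  ep <- as.data.frame(parts$EP)
  expect_equal(sum(ep$presence == 1), 40)
  expect_equal(sum(ep$presence == 0), 40)
  parts2 <- assemblePartitions(occ, c("NC", "SC"), seed = 9)
  expect_identical(as.data.frame(parts2$EP), ep)
  expect_error(assemblePartitions(occ, c("NC", "ZZ")),
               "cluster 'ZZ' has no presence records")
})

test_that("EP keeps all absences when presences outnumber them", {
  occ <- bindOccurrences(
    OccurrenceSet(runif(20), runif(20), 1L, "NC"),
    OccurrenceSet(runif(5), runif(5), 0L, "none"))
  ep <- as.data.frame(assemblePartitions(occ, "NC")$EP)
  expect_equal(sum(ep$presence == 0), 5)
})

test_that("stage seeds derive deterministically from the master seed", {
  expect_identical(seedForStage(7, "simulate"), seedForStage(7, "simulate"))
  expect_false(seedForStage(7, "simulate") == seedForStage(7, "ensemble:NC"))
  expect_false(seedForStage(7, "simulate") == seedForStage(8, "simulate"))
  expect_true(seedForStage(2^31 - 1, "x") < 2^31)
})

test_that("runStudy emits every advertised artefact", {
  out <- file.path(tempdir(), "study-a")
  cfg <- studyConfig(
    scenario = list(divergence = 4, width = 32, height = 32,
                    nPresence = 80, nAbsence = 160),
    methods = c("GLM", "SRE"), nRuns = 2, seed = 5, outDir = out)
  res <- runStudy(cfg)
  files <- c("members_NC.csv", "members_SC.csv", "members_EP.csv",
             "surface_NC.txt", "surface_SC.txt", "surface_EP.txt",
             "overlap.csv", "overlap.json", "importance.csv",
             "contrast.csv", "climate_summaries.csv", "manifest.json")
  for (f in files) expect_true(file.exists(file.path(out, f)), label = f)
  expect_equal(nrow(res$overlap), 3)            # EP-NC, EP-SC, NC-SC
  expect_equal(sort(unique(res$importance$partition)),
               c("EP", "NC", "SC"))
  expect_equal(nrow(memberInfo(res$ensembles$NC)), 4)  # 2 methods x 2 runs
  # members CSV mirrors the in-memory report
  tab <- read.csv(file.path(out, "members_NC.csv"))
  expect_equal(tab$tss, memberInfo(res$ensembles$NC)$tss)
})

test_that("a study re-run from its manifest is byte-identical", {
  outA <- file.path(tempdir(), "study-b")
  cfg <- studyConfig(
    scenario = list(divergence = 2, width = 32, height = 32,
                    nPresence = 60, nAbsence = 120),
    methods = c("GLM", "SRE"), nRuns = 2, seed = 11, outDir = outA)
  runStudy(cfg)
  outB <- file.path(tempdir(), "study-b-rerun")
  runStudyFromManifest(file.path(outA, "manifest.json"), outDir = outB)
  for (f in list.files(outA, pattern = "\\.(csv|txt)$")) {
    expect_identical(unname(tools::md5sum(file.path(outB, f))),
                     unname(tools::md5sum(file.path(outA, f))),
                     label = f)
  }
})

test_that("config validation catches incoherent requests", {
  expect_error(studyConfig(scenario = NULL), "config error")
  expect_error(studyConfig(aggregation = "mode"))
  expect_error(studyConfig(trainFraction = 1.2))
})

test_that("the pooled ensemble overlaps each cluster at least as much as they overlap each other", {
  ok <- 0
  for (s in 1:3) {
    sc <- makeTwoClusterScenario(4, seed = s)   # reference study conditions
    parts <- assemblePartitions(sc$occ, c("NC", "SC"),
                                seed = seedForStage(s, "ep"))
    surfaces <- lapply(parts, function(p) {
      adm <- extractFeatures(sc$grid, p)
      # gate 0.4: the pooled partition's bimodal presence pool caps what
      # single low-capacity members can score, and this check is about
      # overlap geometry, not gate semantics
      predictSurface(buildEnsemble(adm, c("GLM", "CTA", "SRE"),
                                   nRuns = 2, gate = 0.4, seed = s),
                     sc$grid)
    })
    tab <- pairwiseOverlap(surfaces)
    dOf <- function(a, b)
      tab$d[(tab$surfaceX == a & tab$surfaceY == b) |
              (tab$surfaceX == b & tab$surfaceY == a)]
    ok <- ok + (min(dOf("EP", "NC"), dOf("EP", "SC")) >= dOf("NC", "SC") - 0.05)
  }
  expect_equal(ok, 3)
})
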