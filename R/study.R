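# End-to-end comparison of per-cluster ensembles: partition assembly, one
# ensemble per partition, pairwise overlap, importance and climate
# contrasts, all driven by a single config and reproducible from the
# emitted manifest.

#' Assemble per-cluster modeling partitions
#'
#' Follows the regional-ensemble design: each cluster's partition pairs
#' that cluster's presences with **all** absences; the whole-population
#' partition (`"EP"`) pairs all presences with a seeded absence subsample
#' of equal size (absences are subsampled down to the presence count when
#' they exceed it, giving the balanced whole-range design).
#'
#' @param occ an [OccurrenceSet-class] whose presence records carry
#'   cluster labels.
#' @param clusters cluster labels to partition on (default: all labels
#'   among presences except `"none"`).
#' @param seed seed for the EP absence subsample.
#' @param epLabel name of the pooled partition (default `"EP"`).
#' @return Named list of [OccurrenceSet-class] partitions: one per cluster
#'   plus the pooled partition.
#' @export
assemblePartitions <- function(occ, clusters = NULL, seed = 1L,
                               epLabel = "EP") {
  stopifnot(is(occ, "OccurrenceSet"))
  r <- occ@records
  if (is.null(clusters))
    clusters <- setdiff(sort(unique(r$cluster[r$presence == 1L])), "none")
  if (!length(clusters)) stop("no cluster labels among presence records")
  absAll <- absences(occ)
  out <- list()
  for (cl in clusters) {
    pres <- r$presence == 1L & r$cluster == cl
    if (!any(pres))
      stop(sprintf("cluster '%s' has no presence records", cl))
    out[[cl]] <- new("OccurrenceSet",
                     records = rbind(r[pres, , drop = FALSE], absAll@records))
  }
  presAll <- presences(occ)
  nP <- nrow(presAll@records); nA <- nrow(absAll@records)
  set.seed(seed)
  keep <- if (nA > nP) sort(sample.int(nA, nP)) else seq_len(nA)
  out[[epLabel]] <- new("OccurrenceSet",
                        records = rbind(presAll@records,
                                        absAll@records[keep, , drop = FALSE]))
  out
}

#' Configure a full comparative study
#'
#' Either a synthetic two-cluster scenario (`scenario` = list of arguments
#' for [makeTwoClusterScenario()], minus the seed) or real inputs
#' (`gridPath`/`gridFormat` + `occurrencePath`). Every downstream stage
#' draws its seed from `seed` via [seedForStage()].
#'
#' @param scenario list of [makeTwoClusterScenario()] arguments, or `NULL`
#'   when reading data from files.
#' @param gridPath,gridFormat,occurrencePath real-data inputs (used when
#'   `scenario` is `NULL`).
#' @param clusters cluster labels to compare (default `c("NC", "SC")`).
#' @param methods model acronyms for every ensemble.
#' @param nRuns repeated splits per ensemble.
#' @param gate TSS gate.
#' @param aggregation `"mean"` or `"tss"`.
#' @param iVariant `"hellinger"` or `"printed"`.
#' @param nReps permutation-importance repetitions.
#' @param trainFraction training fraction per split.
#' @param seed master seed.
#' @param outDir output directory.
#' @param writeTiff also write TIFF copies of the surfaces.
#' @return A validated `StudyConfig` (classed list).
#' @export
studyConfig <- function(scenario = list(divergence = 4),
                        gridPath = NULL, gridFormat = "textgrid",
                        occurrencePath = NULL,
                        clusters = c("NC", "SC"),
                        methods = c("GLM", "CTA", "SRE"),
                        nRuns = 5L, gate = 0.6,
                        aggregation = "mean",
                        iVariant = "hellinger",
                        nReps = 3L, trainFraction = 0.8,
                        seed = 1L, outDir = "study-out",
                        writeTiff = FALSE) {
  if (is.null(scenario) && (is.null(gridPath) || is.null(occurrencePath)))
    stop("config error: provide either a scenario or gridPath + occurrencePath")
  if (!is.null(scenario)) scenario$seed <- NULL
  if (length(clusters) < 1L)
    stop("config error: at least one cluster label required")
  stopifnot(aggregation %in% c("mean", "tss"),
            iVariant %in% c("hellinger", "printed"),
            nRuns >= 1L, nReps >= 1L,
            trainFraction > 0, trainFraction < 1)
  structure(list(scenario = scenario, gridPath = gridPath,
                 gridFormat = gridFormat, occurrencePath = occurrencePath,
                 clusters = clusters, methods = methods,
                 nRuns = as.integer(nRuns), gate = gate,
                 aggregation = aggregation, iVariant = iVariant,
                 nReps = as.integer(nReps), trainFraction = trainFraction,
                 seed = as.integer(seed), outDir = outDir,
                 writeTiff = isTRUE(writeTiff)),
            class = "StudyConfig")
}

#' Run the full comparative study
#'
#' Stages: (1) simulate or load the climate grid and occurrences;
#' (2) assemble partitions (each cluster + the pooled population);
#' (3) build one TSS-gated ensemble per partition and write its member
#' report (CSV) and prediction surface (textgrid, optionally TIFF);
#' (4) pairwise Schoener's D / Hellinger I overlap across the ensemble
#' surfaces (CSV + JSON); (5) ensemble permutation importance per
#' partition (CSV); (6) per-variable rank-sum climate contrasts between
#' clusters (CSV + five-number summaries); (7) a JSON manifest recording
#' the full configuration and derived stage seeds, from which
#' [runStudyFromManifest()] reproduces every table byte-identically.
#'
#' Any stage failure aborts with the stage name.
#'
#' @param config a [studyConfig()].
#' @return Invisibly, a list with the in-memory results (`grid`, `occ`,
#'   `ensembles`, `surfaces`, `overlap`, `importance`, `contrast`,
#'   `summaries`, `manifest`).
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("study stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inputs <- stage("inputs", {
    if (!is.null(config$scenario)) {
      sc <- do.call(makeTwoClusterScenario,
                    c(config$scenario,
                      list(seed = seedForStage(config$seed, "simulate"))))
      list(grid = sc$grid, occ = sc$occ)
    } else {
      list(grid = readGrid(config$gridPath, config$gridFormat),
           occ = readOccurrences(config$occurrencePath))
    }
  })

  partitions <- stage("partitions",
    assemblePartitions(inputs$occ, config$clusters,
                       seed = seedForStage(config$seed, "ep-subsample")))

  ensembles <- list(); surfaces <- list()
  for (p in names(partitions)) {
    ensembles[[p]] <- stage(paste0("ensemble:", p), {
      adm <- extractFeatures(inputs$grid, partitions[[p]])
      buildEnsemble(adm, config$methods, nRuns = config$nRuns,
                    gate = config$gate, aggregation = config$aggregation,
                    trainFraction = config$trainFraction,
                    seed = seedForStage(config$seed, paste0("ensemble:", p)))
    })
    ensembleReport(ensembles[[p]],
                   file.path(config$outDir, paste0("members_", p, ".csv")))
    surfaces[[p]] <- stage(paste0("surface:", p),
                           predictSurface(ensembles[[p]], inputs$grid))
    writeSurfaceGrid(surfaces[[p]],
                     file.path(config$outDir, paste0("surface_", p, ".txt")))
  }

  overlap <- stage("overlap", pairwiseOverlap(surfaces, config$iVariant))
  write.csv(overlap, file.path(config$outDir, "overlap.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(overlap, file.path(config$outDir, "overlap.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "rows")

  importance <- stage("importance", {
    rows <- list()
    for (p in names(partitions)) {
      adm <- extractFeatures(inputs$grid, partitions[[p]])
      imp <- ensembleImportance(
        ensembles[[p]], adm, nReps = config$nReps,
        seed = seedForStage(config$seed, paste0("importance:", p)))
      rows[[p]] <- data.frame(partition = p,
                              variable = names(imp$aggregate),
                              importance = unname(imp$aggregate),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  write.csv(importance, file.path(config$outDir, "importance.csv"),
            row.names = FALSE, quote = FALSE)

  contrast <- stage("contrast",
                    climateContrast(inputs$occ, inputs$grid))
  write.csv(contrast, file.path(config$outDir, "contrast.csv"),
            row.names = FALSE, quote = FALSE)
  summaries <- stage("summaries",
                     summarizePresenceClimate(inputs$occ, inputs$grid))
  write.csv(summaries, file.path(config$outDir, "climate_summaries.csv"),
            row.names = FALSE, quote = FALSE)

  if (config$writeTiff)
    for (p in names(surfaces))
      writeSurfaceGrid(surfaces[[p]],
                       file.path(config$outDir, paste0("surface_", p, ".tif")),
                       format = "tiff")

  manifest <- stage("manifest", {
    mf <- unclass(config)
    mf$stageSeeds <- c(
      list(simulate = seedForStage(config$seed, "simulate"),
           epSubsample = seedForStage(config$seed, "ep-subsample")),
      setNames(lapply(names(partitions), function(p)
        seedForStage(config$seed, paste0("ensemble:", p))),
        paste0("ensemble.", names(partitions))))
    mf$memberCounts <- lapply(ensembles, function(e)
      c(total = nrow(memberInfo(e)), included = sum(memberInfo(e)$included)))
    jsonlite::write_json(mf, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    mf
  })

  invisible(list(grid = inputs$grid, occ = inputs$occ,
                 ensembles = ensembles, surfaces = surfaces,
                 overlap = overlap, importance = importance,
                 contrast = contrast, summaries = summaries,
                 manifest = manifest))
}

#' Re-run a study from its manifest
#'
#' Reconstructs the [studyConfig()] recorded in a `manifest.json` and
#' re-runs [runStudy()]; because every stage seed derives from the recorded
#' master seed, all emitted CSV tables are byte-identical to the original
#' run.
#'
#' @param manifestPath path to a `manifest.json` written by [runStudy()].
#' @param outDir output directory (default: the manifest's own).
#' @return As [runStudy()].
#' @export
runStudyFromManifest <- function(manifestPath, outDir = NULL) {
  mf <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  cfg <- studyConfig(
    scenario = if (is.null(mf$scenario)) NULL else as.list(mf$scenario),
    gridPath = mf$gridPath, gridFormat = mf$gridFormat %||% "textgrid",
    occurrencePath = mf$occurrencePath,
    clusters = mf$clusters, methods = mf$methods, nRuns = mf$nRuns,
    gate = mf$gate, aggregation = mf$aggregation, iVariant = mf$iVariant,
    nReps = mf$nReps, trainFraction = mf$trainFraction, seed = mf$seed,
    outDir = outDir %||% mf$outDir, writeTiff = isTRUE(mf$writeTiff))
  runStudy(cfg)
}

#' Write a prediction surface as a single-variable grid file
#'
#' @param surface a [PredictionSurface-class].
#' @param path output path.
#' @param format `"textgrid"` or `"tiff"`.
#' @param name variable name to record (default `"suitability"`).
#' @return `path`, invisibly.
#' @export
writeSurfaceGrid <- function(surface, path, format = c("textgrid", "tiff"),
                             name = "suitability") {
  stopifnot(is(surface, "PredictionSurface"))
  g <- ClimateGrid(matrix(surface@values, ncol = 1,
                          dimnames = list(NULL, name)),
                   surface@dims[1L], surface@dims[2L],
                   origin = surface@origin, cellsize = surface@cellsize)
  writeGrid(g, path, format = match.arg(format))
}

#' Read a prediction surface written by [writeSurfaceGrid()]
#'
#' @param path grid file path.
#' @param format `"textgrid"` or `"tiff"`.
#' @return A [PredictionSurface-class].
#' @export
readSurfaceGrid <- function(path, format = c("textgrid", "tiff")) {
  g <- readGrid(path, match.arg(format))
  .surfaceLike(g, g@values[, 1L])
}
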