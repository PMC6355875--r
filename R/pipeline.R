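#' Assemble a pipeline configuration
#'
#' Declarative configuration for [runPipeline()], either built in code
#' or read from JSON.  Defaults mirror the package's standard screening
#' settings: 4-descriptor filters, Tanimoto pruning at 0.8, a +-2 sigma
#' applicability domain, MBI report borders (-3, 3, 6, 9, 10, 13) and
#' the 3.3 / 3.9 / 3.5 / 5.0 Angstrom geometry thresholds with
#' 2-of-crucial, 7-of-important voting across all structures.
#'
#' @param outDir output directory for all artifacts.
#' @param trainTable path to a training descriptor CSV
#'   ([readDescriptorTable()] format); ignored when \code{synthetic} is
#'   given.
#' @param screenTable optional path of a descriptor CSV to score; with a
#'   synthetic preset, a held-out synthetic test set is generated
#'   instead.
#' @param synthetic optional [syntheticSpec()] (or list of its
#'   arguments) -- the self-contained preset.
#' @param ise list of [iseConfig()] arguments.
#' @param borders MBI report borders.
#' @param geometry optional list with \code{receptor}, \code{poses}
#'   (named list of SDF paths, one per molecule or structure) and
#'   \code{criteria} (config path), plus optional \code{required} votes.
#' @param seed master seed; stage seeds derive from it.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir,
                           trainTable = NULL,
                           screenTable = NULL,
                           synthetic = NULL,
                           ise = list(),
                           borders = c(-3, 3, 6, 9, 10, 13),
                           geometry = NULL,
                           seed = 1L) {
  if (is.null(synthetic) && is.null(trainTable))
    stop("either a training table or a synthetic preset is required")
  if (!is.null(synthetic) && !inherits(synthetic, "SyntheticSpec"))
    synthetic <- do.call(syntheticSpec, as.list(synthetic))
  cfg <- list(outDir = outDir, trainTable = trainTable,
              screenTable = screenTable, synthetic = synthetic,
              ise = ise, borders = as.numeric(borders),
              geometry = geometry, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

# md5 manifest of a stage's inputs, used for skip-if-unchanged.
.stageFingerprint <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  unlist(lapply(paths, function(p) unname(tools::md5sum(p))))
}

#' Run the screening pipeline
#'
#' Executes the stages train -> score -> report (-> geometry filter)
#' with per-stage logging.  A stage is skipped when its outputs already
#' exist and the checksums of its inputs are unchanged since they were
#' produced; a failing stage aborts with its name and removes its
#' partial outputs.  The resolved configuration is written next to the
#' artifacts, and reruns with an unchanged configuration are
#' byte-identical.
#'
#' @param config a [pipelineConfig()] or the path of a JSON file of its
#'   arguments.
#' @param verbose log stage progress (default TRUE).
#' @return Invisibly, a list of artifact paths plus the summary, also
#'   written to \code{summary.json}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) {
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipelineConfig, args)
  }
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[iseScreen] ", sprintf(...))
  out <- config$outDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  for (p in c(config$trainTable, config$screenTable,
              config$geometry$receptor, unlist(config$geometry$poses),
              config$geometry$criteria)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }

  manifestPath <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else list()
  resolved <- unclass(config)
  resolved$synthetic <- if (!is.null(config$synthetic)) unclass(config$synthetic)
  jsonlite::write_json(resolved, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  runStage <- function(name, inputs, outputs, fun) {
    fp <- .stageFingerprint(inputs)
    if (all(file.exists(outputs)) && identical(manifest[[name]], fp) &&
        length(fp) == length(inputs)) {
      say("stage %s: up to date, skipped", name)
      return(invisible(NULL))
    }
    say("stage %s: running", name)
    ok <- FALSE
    on.exit(if (!ok) unlink(outputs), add = TRUE)
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    ok <- TRUE
    manifest[[name]] <<- fp
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
    invisible(NULL)
  }

  # -- inputs ----------------------------------------------------------------
  trainCsv <- file.path(out, "train.csv")
  screenCsv <- if (!is.null(config$screenTable)) config$screenTable
               else file.path(out, "screen.csv")
  if (!is.null(config$synthetic)) {
    runStage("simulate", inputs = list(file.path(out, "config.json")),
             outputs = c(trainCsv, if (is.null(config$screenTable)) screenCsv),
             fun = function() {
      writeDescriptorTable(genDescriptorDataset(config$synthetic), trainCsv)
      if (is.null(config$screenTable)) {
        testSpec <- config$synthetic
        testSpec$seed <- config$synthetic$seed + 1L
        writeDescriptorTable(genDescriptorDataset(testSpec), screenCsv)
      }
    })
  } else {
    trainCsv <- config$trainTable
    if (is.null(config$screenTable)) screenCsv <- trainCsv
  }

  # -- train -----------------------------------------------------------------
  modelPath <- file.path(out, "model.json")
  runStage("train", inputs = list(trainCsv), outputs = modelPath,
           fun = function() {
    iseArgs <- config$ise
    if (is.null(iseArgs$seed)) iseArgs$seed <- config$seed
    model <- buildModel(readDescriptorTable(trainCsv),
                        do.call(iseConfig, iseArgs), verbose = verbose)
    saveModel(model, modelPath)
  })

  # -- score -----------------------------------------------------------------
  scorePath <- file.path(out, "scores.csv")
  runStage("score", inputs = list(modelPath, screenCsv), outputs = scorePath,
           fun = function() {
    tab <- readDescriptorTable(screenCsv)
    sc <- mbiScore(loadModel(modelPath), tab)
    sc$label <- moleculeLabels(tab)
    utils::write.csv(sc, scorePath, row.names = FALSE, quote = FALSE)
  })

  # -- report ----------------------------------------------------------------
  reportPath <- file.path(out, "report.csv")
  summaryPath <- file.path(out, "summary.json")
  runStage("report", inputs = list(scorePath), outputs = reportPath,
           fun = function() {
    sc <- utils::read.csv(scorePath, stringsAsFactors = FALSE)
    if (all(c("active", "inactive") %in% sc$label)) {
      rep <- thresholdReport(sc$mbi, sc$label, borders = config$borders)
      utils::write.csv(formatThresholdReport(rep), reportPath,
                       row.names = FALSE, quote = FALSE)
    } else {
      utils::write.csv(data.frame(note = "no labeled classes to evaluate"),
                       reportPath, row.names = FALSE)
    }
  })

  # -- geometry filter (optional) -------------------------------------------
  verdictPath <- NULL
  if (!is.null(config$geometry)) {
    g <- config$geometry
    verdictPath <- file.path(out, "verdicts.csv")
    runStage("geometry",
             inputs = c(list(g$receptor, g$criteria), as.list(unlist(g$poses))),
             outputs = verdictPath, fun = function() {
      receptor <- readReceptor(g$receptor)
      protein <- receptor[!receptor$het, , drop = FALSE]
      criteria <- readGeometryCriteria(g$criteria)
      vd <- lapply(g$poses, function(pp)
        moleculeDockVerdict(readPoses(pp), protein, criteria))
      utils::write.csv(data.frame(
        id = names(g$poses) %||% basename(unlist(g$poses)),
        accepted = vapply(vd, `[[`, logical(1), "accepted"),
        pose = vapply(vd, `[[`, character(1), "pose"),
        energy = vapply(vd, `[[`, numeric(1), "energy")),
        verdictPath, row.names = FALSE, quote = FALSE)
    })
  }

  sc <- utils::read.csv(scorePath, stringsAsFactors = FALSE)
  summary <- list(
    nFilters = length(loadModel(modelPath)),
    nScored = nrow(sc),
    mbiRange = range(sc$mbi),
    artifacts = list(model = modelPath, scores = scorePath,
                     report = reportPath, verdicts = verdictPath)
  )
  if (all(c("active", "inactive") %in% sc$label))
    summary$auc <- rocAndEnrichment(sc$mbi, sc$label)$auc
  jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  say("done: %d filters, %d molecules scored", summary$nFilters, summary$nScored)
  invisible(summary)
}
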