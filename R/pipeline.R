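# One-call orchestration of the full analysis with a YAML config, stage
# isolation and a machine-readable report bundle.

#' @importFrom yaml read_yaml as.yaml
#' @importFrom utils packageVersion head
NULL

pipelineDefaults <- function() {
  list(
    inputs = list(substitutions = NULL, substitutionsFormat = "tsv",
                  indels = NULL, rearrangements = NULL, reference = NULL,
                  genes = NULL, islands = NULL, expression = NULL),
    nmf = list(kmin = 2L, kmax = 8L, runs = 100L, seed = 17L,
               extractRuns = 20L),
    kataegis = list(minSize = 6L, imdThreshold = 1000L, macroGap = 1e6),
    doublets = list(sims = 1000L, seed = 7L),
    indels = list(mhMin = 2L, maxUnit = 6L),
    transcription = list(nBins = 8L),
    outDir = NULL)
}

## Polynomial rolling hash (mod 2^31 - 1) of the normalized config, for
## provenance lines.
configHash <- function(config) {
  config$outDir <- NULL  # analytic parameters only
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate and normalize an analysis configuration
#'
#' Fills defaults, rejects unknown keys and out-of-range values, and
#' returns the normalized configuration (idempotent:
#' \code{validateConfig(validateConfig(x))} equals
#' \code{validateConfig(x)}).
#'
#' @param config Path to a YAML file, or a configuration list.
#' @return Normalized configuration list of class \code{AnalysisConfig}.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  class(config) <- NULL
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (sect in names(defaults)) {
    if (sect == "outDir") next
    bad <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
    if (length(bad))
      stopf("unknown key(s) in %s: %s", sect, paste(bad, collapse = ", "))
    defaults[[sect]][names(config[[sect]])] <- config[[sect]]
  }
  if (!is.null(config$outDir)) defaults$outDir <- config$outDir
  with(defaults, {
    if (nmf$kmin < 1L || nmf$kmax < nmf$kmin) stopf("invalid NMF k range")
    if (nmf$runs < 10L) stopf("nmf runs must be >= 10")
    if (kataegis$minSize < 2L) stopf("kataegis minSize must be >= 2")
    if (kataegis$imdThreshold < 1) stopf("kataegis imdThreshold must be positive")
    if (doublets$sims < 100L) stopf("doublet sims must be >= 100")
    if (indels$mhMin < 1L) stopf("indel mhMin must be >= 1")
  })
  structure(defaults, class = "AnalysisConfig")
}

writeWithProvenance <- function(df, path, config, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mutforge %s | config %s%s",
                     as.character(utils::packageVersion("mutforge")),
                     configHash(unclass(config)),
                     if (is.null(note)) "" else paste0(" | ", note)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the full mutational-process analysis
#'
#' Executes, in order: spectrum construction, NMF signature extraction
#' with rank selection, sample clustering, kataegis detection, the doublet
#' Monte Carlo test, transcription analyses and indel classification —
#' each stage only when its inputs are configured, and with
#' partial-failure isolation: a failing stage contributes an error record
#' while later independent stages still run.  All stochastic stages are
#' seeded from the config, so a rerun with identical config and inputs
#' reproduces every output.
#'
#' @param config An \code{AnalysisConfig} (or anything accepted by
#'   [validateConfig()]).
#' @return A \code{ReportBundle} list: per-stage results, \code{skipped}
#'   and \code{errors} records, and a \code{log} with package version,
#'   config hash and seeds.  Results are additionally written as TSV to
#'   \code{outDir} when configured.
#' @export
runPipeline <- function(config = list()) {
  config <- validateConfig(config)
  inp <- config$inputs
  if (is.null(inp$substitutions))
    stopf("config error in stage 'spectrum': inputs$substitutions is required")
  if (is.null(inp$reference))
    stopf("config error in stage 'spectrum': inputs$reference is required")
  bundle <- list(skipped = character(0), errors = list(),
                 log = list(version = as.character(packageVersion("mutforge")),
                            configHash = configHash(unclass(config)),
                            config = unclass(config)))
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(df, name, note = NULL) {
    if (!is.null(outDir))
      writeWithProvenance(df, file.path(outDir, name), config, note)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  genome <- stage("load", readReference(inp$reference))
  subs <- stage("load", readSubstitutions(inp$substitutions,
                                          format = inp$substitutionsFormat,
                                          genome = genome))
  if (is.null(genome) || is.null(subs))
    stopf("input loading failed: %s",
          paste(unlist(bundle$errors), collapse = "; "))
  indelTab <- if (!is.null(inp$indels)) stage("load", readIndels(inp$indels))
  rearrTab <- if (!is.null(inp$rearrangements))
    stage("load", readRearrangements(inp$rearrangements))
  genes <- if (!is.null(inp$genes)) stage("load", readGenes(inp$genes))
  islands <- if (!is.null(inp$islands))
    stage("load", readCpgIslands(inp$islands))
  expr <- if (!is.null(inp$expression))
    stage("load", readExpression(inp$expression, genes))
  catalogs <- splitCatalogs(subs, indelTab, rearrTab)

  bundle$spectrum <- stage("spectrum", {
    sm <- buildSpectrumMatrix(catalogs, genome)
    emit(data.frame(channel = channelLabels(), spectrumCounts(sm),
                    check.names = FALSE), "spectrum.tsv")
    sm
  })

  if (!is.null(bundle$spectrum) && length(catalogs) >= 3L) {
    bundle$rankSelection <- stage("signatures", {
      kmax <- min(config$nmf$kmax, length(catalogs) - 1L)
      selectRank(bundle$spectrum, kRange = config$nmf$kmin:kmax,
                 nRuns = config$nmf$runs, seed = config$nmf$seed)
    })
    bundle$signatureSet <- stage("signatures", {
      k <- chosenK(bundle$rankSelection)
      ss <- extractSignatures(bundle$spectrum, k,
                              nRuns = config$nmf$extractRuns,
                              seed = config$nmf$seed)
      emit(selectionTable(bundle$rankSelection), "model_selection.tsv",
           sprintf("seed %d", config$nmf$seed))
      emit(data.frame(channel = channelLabels(), signatures(ss),
                      check.names = FALSE), "signatures.tsv")
      emit(data.frame(signature = rownames(exposures(ss)), exposures(ss),
                      check.names = FALSE), "exposures.tsv")
      ss
    })
    bundle$sampleClustering <- stage("clustering",
                                     clusterSamples(bundle$signatureSet))
  } else {
    bundle$skipped <- c(bundle$skipped,
                        "signatures: fewer than 3 samples")
  }

  bundle$kataegis <- stage("kataegis", {
    res <- lapply(catalogs, function(cat) {
      calls <- callKataegis(rainfall(cat),
                            minSize = config$kataegis$minSize,
                            imdThreshold = config$kataegis$imdThreshold,
                            macroGap = config$kataegis$macroGap)
      if (nrow(rearrangements(cat)) && nrow(calls$clusters))
        calls$colocalization <-
          rearrangementColocalization(calls, rearrangements(cat),
                                      chromLengths(genome))
      calls
    })
    tab <- do.call(rbind, lapply(names(res), function(sm) {
      cl <- res[[sm]]$clusters
      if (!nrow(cl)) return(NULL)
      cbind(sample = sm, cl[setdiff(names(cl), "members")])
    }))
    emit(if (is.null(tab)) data.frame() else tab, "kataegis.tsv",
         sprintf("minSize %d imd %d", config$kataegis$minSize,
                 config$kataegis$imdThreshold))
    res
  })

  bundle$doublets <- stage("doublets", {
    seeds <- deriveSeeds(config$doublets$seed, length(catalogs))
    res <- lapply(seq_along(catalogs), function(i) {
      runs <- findAdjacentRuns(catalogs[[i]])
      mc <- monteCarloAdjacencyTest(catalogs[[i]], chromLengths(genome),
                                    nSims = config$doublets$sims,
                                    seed = seeds[i])
      mc$simCounts <- NULL
      list(runs = runs, monteCarlo = mc,
           spectrum = doubletSpectrum(runs$doublets))
    })
    names(res) <- names(catalogs)
    emit(do.call(rbind, lapply(names(res), function(sm)
      data.frame(sample = sm, observed = res[[sm]]$monteCarlo$observed,
                 fold = res[[sm]]$monteCarlo$fold,
                 p = res[[sm]]$monteCarlo$p))),
      "doublets.tsv", sprintf("sims %d seed %d", config$doublets$sims,
                              config$doublets$seed))
    res
  })

  if (!is.null(genes)) {
    bundle$transcription <- stage("transcription", {
      pooled <- do.call(rbind, lapply(catalogs, function(cat)
        assignStrand(cat, genes)))
      bias <- lapply(setNames(nm = SUB_CLASSES), function(cp)
        strandBiasTest(pooled, cp, genome, genes))
      out <- list(strandBias = bias)
      if (!is.null(expr)) {
        out$expression <- expressionPrevalence(catalogs, genes, expr,
                                               nBins = config$transcription$nBins)
        out$tss <- tssProfile(catalogs, genes)
      }
      emit(do.call(rbind, lapply(names(bias), function(cp)
        data.frame(class = cp, transcribed = bias[[cp]]$transcribed,
                   untranscribed = bias[[cp]]$untranscribed,
                   expected = bias[[cp]]$expected, p = bias[[cp]]$p))),
        "strand_bias.tsv")
      out
    })
  } else {
    bundle$skipped <- c(bundle$skipped, "transcription: no gene annotation")
  }

  if (!is.null(indelTab) && nrow(indelTab)) {
    bundle$indelClassification <- stage("indels", {
      cls <- classifyIndels(indelTab, genome,
                            mhMin = config$indels$mhMin,
                            maxUnit = config$indels$maxUnit)
      emit(cls, "indel_classification.tsv",
           sprintf("mhMin %d maxUnit %d", config$indels$mhMin,
                   config$indels$maxUnit))
      cls
    })
  } else {
    bundle$skipped <- c(bundle$skipped, "indels: no indel input")
  }

  if (!is.null(islands)) {
    bundle$cpgIslandOR <- stage("cpg",
                                cpgIslandOddsRatio(catalogs, genome, islands))
  }

  class(bundle) <- "ReportBundle"
  bundle
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("mutforge ReportBundle (version", x$log$version, ", config",
      x$log$configHash, ")\n")
  stages <- setdiff(names(x), c("skipped", "errors", "log"))
  cat(" stages run:", paste(stages, collapse = ", "), "\n")
  if (length(x$skipped)) cat(" skipped:", paste(x$skipped, collapse = "; "), "\n")
  if (length(x$errors))
    cat(" errors:", paste(names(x$errors), unlist(x$errors), sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}
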