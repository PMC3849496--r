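#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the documented defaults
#' (top-k 50, negative-similarity threshold 0.4, validation check every
#' 2000 iterations, 3 folds, 25 percent validation holdout,
#' borderline-favouring negative sampling).
#'
#' @param dir run directory: inputs are resolved and artifacts written
#'   here.
#' @param ontology,annotations input paths; default to the files
#'   \code{simulate} writes into \code{dir}.
#' @param sources character vector of source paths; files ending in
#'   \code{_edges.tsv} are read as binary edge lists, all others as
#'   gene-by-feature matrices. Defaults to the \code{source*} files in
#'   \code{dir}.
#' @param k,threshold,alpha,sigma,checkInterval,patience,minDelta,
#'   maxIterations,strategy,nFolds,valFraction learning and evaluation
#'   parameters (see \code{\link{trainConfig}},
#'   \code{\link{samplingConfig}}, \code{\link{crossValidate}}).
#' @param nGenes,nTerms,nSources,signal,noise simulation sizes used by
#'   the \code{simulate} subcommand.
#' @param terms optional term subset for learn/reconstruct/predict.
#' @param seed integer seed for every source of randomness.
#' @param force overwrite existing per-term artifacts instead of
#'   resuming past them.
#' @return a list of class "runConfig".
#' @export
runConfig <- function(dir = ".", ontology = NULL, annotations = NULL,
                      sources = NULL, k = 50, threshold = 0.4,
                      alpha = 0.1, sigma = 1, checkInterval = 2000L,
                      patience = 3L, minDelta = 1e-4,
                      maxIterations = 20000L,
                      strategy = "favor_borderline", nFolds = 3L,
                      valFraction = 0.25, nGenes = 300L, nTerms = 20L,
                      nSources = 4L, signal = 1, noise = 1,
                      terms = NULL, seed = 1L, force = FALSE) {
  structure(list(dir = dir, ontology = ontology,
                 annotations = annotations, sources = sources, k = k,
                 threshold = threshold, alpha = alpha, sigma = sigma,
                 checkInterval = as.integer(checkInterval),
                 patience = as.integer(patience), minDelta = minDelta,
                 maxIterations = as.integer(maxIterations),
                 strategy = strategy, nFolds = as.integer(nFolds),
                 valFraction = valFraction,
                 nGenes = as.integer(nGenes),
                 nTerms = as.integer(nTerms),
                 nSources = as.integer(nSources), signal = signal,
                 noise = noise, terms = terms, seed = as.integer(seed),
                 force = isTRUE(force)),
            class = "runConfig")
}

.log <- function(cfg, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(line, "\n", sep = "", file = stderr())
  cat(line, "\n", sep = "",
      file = file.path(cfg$dir, "run.log"), append = TRUE)
}

.snapshotConfig <- function(cfg, subcommand) {
  snap <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(snap,
                   file.path(cfg$dir,
                             paste0("config_", subcommand, ".yaml")))
}

.requireFile <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  path
}

.safeName <- function(term) gsub("[^A-Za-z0-9._-]", "_", term)

.loadInputs <- function(cfg) {
  ontPath <- cfg$ontology %||% file.path(cfg$dir, "ontology.tsv")
  annPath <- cfg$annotations %||% file.path(cfg$dir, "annotations.tsv")
  .requireFile(ontPath)
  .requireFile(annPath)
  dag <- if (grepl("\\.obo$", ontPath)) readOBO(ontPath) else
    readOntologyTSV(ontPath)
  raw <- if (grepl("\\.gaf$", annPath)) readGAF(annPath) else
    readAnnotationsTSV(annPath)
  list(dag = dag, annot = upPropagate(raw, dag))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the prediction pipeline
#'
#' Subcommands: \code{simulate} (write a synthetic benchmark into the
#' run directory), \code{build-nets} (per-source association networks),
#' \code{integrate} (equal-weight sum, sparsified), \code{learn}
#' (per-term similarity models), \code{reconstruct} (per-term
#' networks), \code{predict} (per-term propagation scores),
#' \code{evaluate} (cross-validated per-term AUC with and without
#' learning, plus the comparison summary). Every invocation writes a
#' resolved-config snapshot and appends to \code{run.log}; with a fixed
#' seed the full pipeline is byte-reproducible. Per-term artifacts are
#' skipped when they already exist unless \code{force}.
#'
#' @param subcommand one of the subcommands above.
#' @param cfg a \code{\link{runConfig}}.
#' @return invisibly, a subcommand-specific result (e.g. the evaluation
#'   summary for \code{evaluate}).
#' @export
runPipeline <- function(subcommand = c("simulate", "build-nets",
                                       "integrate", "learn",
                                       "reconstruct", "predict",
                                       "evaluate"),
                        cfg = runConfig()) {
  subcommand <- match.arg(subcommand)
  dir.create(cfg$dir, recursive = TRUE, showWarnings = FALSE)
  .snapshotConfig(cfg, subcommand)
  .log(cfg, "subcommand ", subcommand, " (seed ", cfg$seed, ")")
  set.seed(cfg$seed)
  switch(subcommand,
         "simulate"    = .cmdSimulate(cfg),
         "build-nets"  = .cmdBuildNets(cfg),
         "integrate"   = .cmdIntegrate(cfg),
         "learn"       = .cmdLearn(cfg),
         "reconstruct" = .cmdReconstruct(cfg),
         "predict"     = .cmdPredict(cfg),
         "evaluate"    = .cmdEvaluate(cfg))
}

.cmdSimulate <- function(cfg) {
  bench <- generateBenchmark(nGenes = cfg$nGenes, nTerms = cfg$nTerms,
                             nSources = cfg$nSources,
                             signal = cfg$signal, noise = cfg$noise,
                             seed = cfg$seed)
  writeBenchmark(bench, cfg$dir)
  .log(cfg, "wrote benchmark: ", length(bench@genes), " genes, ",
       length(bench@dag@terms), " terms, ", length(bench@sources),
       " sources")
  invisible(bench)
}

.findSources <- function(cfg) {
  src <- cfg$sources %||%
    list.files(cfg$dir, "^source[0-9]+_.*\\.tsv$", full.names = TRUE)
  if (!length(src)) stop("no source files found")
  for (s in src) .requireFile(s)
  src
}

.cmdBuildNets <- function(cfg) {
  src <- .findSources(cfg)
  outDir <- file.path(cfg$dir, "networks")
  dir.create(outDir, showWarnings = FALSE)
  paths <- character(0)
  for (s in src) {
    out <- file.path(outDir, paste0("net_", basename(s)))
    if (file.exists(out) && !cfg$force) {
      .log(cfg, "skip existing ", out)
    } else {
      net <- if (grepl("_edges\\.tsv$", s)) {
        binaryNetwork(utils::read.table(s, sep = "\t",
                                        colClasses = "character"))
      } else pccNetwork(readDataMatrixTSV(s))
      writeEdgeListTSV(net, out)
      .log(cfg, "built ", out, " (", length(genes(net)), " genes)")
    }
    paths <- c(paths, out)
  }
  invisible(paths)
}

.cmdIntegrate <- function(cfg) {
  netDir <- file.path(cfg$dir, "networks")
  files <- list.files(netDir, "^net_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no per-source networks in ", netDir,
                           "; run build-nets first")
  nets <- lapply(files, readEdgeListTSV)
  combined <- sparsifyTopK(integrateEqual(nets), cfg$k)
  out <- file.path(cfg$dir, "combined.tsv")
  writeEdgeListTSV(combined, out)
  .log(cfg, "integrated ", length(files), " networks -> ", out)
  invisible(combined)
}

.pipelineState <- function(cfg) {
  inp <- .loadInputs(cfg)
  comb <- .requireFile(file.path(cfg$dir, "combined.tsv"))
  genesPath <- file.path(cfg$dir, "genes.txt")
  universe <- if (file.exists(genesPath)) readLines(genesPath) else NULL
  network <- readEdgeListTSV(comb, geneIds = universe)
  trainGenes <- intersect(network@genes, names(inp$annot@assignments))
  c(inp, list(network = network, trainGenes = trainGenes))
}

.learnableTerms <- function(cfg, st) {
  tc <- table(unlist(st$annot@assignments[st$trainGenes],
                     use.names = FALSE))
  terms <- setdiff(names(tc)[tc >= 2L], st$dag@root)
  if (!is.null(cfg$terms)) terms <- intersect(terms, cfg$terms)
  terms
}

.cmdLearn <- function(cfg) {
  st <- .pipelineState(cfg)
  terms <- .learnableTerms(cfg, st)
  modelDir <- file.path(cfg$dir, "models")
  dir.create(modelDir, showWarnings = FALSE)
  ic <- informationContent(st$annot, st$dag)
  pairSim <- geneSimilarityMatrix(st$trainGenes, st$annot, ic, st$dag)
  fmapAll <- featureMap(st$network, st$trainGenes)
  fmapTrain <- new("FeatureMap", trainingGenes = st$trainGenes,
                   phi = fmapAll@phi[st$trainGenes, , drop = FALSE])
  tcfg <- trainConfig(alpha = cfg$alpha,
                      checkInterval = cfg$checkInterval,
                      patience = cfg$patience, minDelta = cfg$minDelta,
                      maxIterations = cfg$maxIterations,
                      sigma = cfg$sigma, k = cfg$k)
  scfg <- samplingConfig(strategy = cfg$strategy,
                         threshold = cfg$threshold)
  posByTerm <- lapply(stats::setNames(terms, terms), function(tm)
    st$trainGenes[vapply(st$annot@assignments[st$trainGenes],
                         function(x) tm %in% x, logical(1))])
  for (tm in terms) {
    out <- file.path(modelDir, paste0(.safeName(tm), ".model"))
    if (file.exists(out) && !cfg$force) {
      .log(cfg, "skip existing model for ", tm)
      next
    }
    ok <- tryCatch({
      valGenes <- .drawValidation(tm, posByTerm[[tm]], st$trainGenes,
                                  st$annot, st$dag, cfg$valFraction)
      model <- trainCategory(fmapTrain, st$annot, st$dag, pairSim, tm,
                             valGenes, config = tcfg, sampling = scfg)
      writeSimilarityModel(model, out)
      .log(cfg, "learned ", tm, ": ", model@iterationsRun,
           " iterations, best validation AUC ",
           format(model@bestValidationAUC, digits = 4))
      TRUE
    }, error = function(e) {
      .log(cfg, "FAILED ", tm, ": ", conditionMessage(e))
      FALSE
    })
  }
  invisible(modelDir)
}

.cmdReconstruct <- function(cfg) {
  st <- .pipelineState(cfg)
  modelDir <- file.path(cfg$dir, "models")
  files <- list.files(modelDir, "\\.model$", full.names = TRUE)
  if (!length(files)) stop("no models in ", modelDir,
                           "; run learn first")
  outDir <- file.path(cfg$dir, "reconstructed")
  dir.create(outDir, showWarnings = FALSE)
  for (mf in files) {
    model <- readSimilarityModel(mf)
    if (!is.null(cfg$terms) && !(model@category %in% cfg$terms)) next
    out <- file.path(outDir,
                     paste0(.safeName(model@category), ".tsv"))
    if (file.exists(out) && !cfg$force) {
      .log(cfg, "skip existing network for ", model@category)
      next
    }
    fmapAll <- featureMap(st$network, model@trainingGenes)
    net <- reconstructNetwork(model, fmapAll, k = cfg$k)
    writeEdgeListTSV(net, out)
    .log(cfg, "reconstructed ", model@category)
  }
  invisible(outDir)
}

.cmdPredict <- function(cfg) {
  st <- .pipelineState(cfg)
  netDir <- file.path(cfg$dir, "reconstructed")
  files <- list.files(netDir, "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no reconstructed networks in ", netDir,
                           "; run reconstruct first")
  outDir <- file.path(cfg$dir, "predictions")
  dir.create(outDir, showWarnings = FALSE)
  terms <- .learnableTerms(cfg, st)
  byName <- stats::setNames(files,
                            sub("\\.tsv$", "", basename(files)))
  for (tm in terms) {
    nf <- byName[.safeName(tm)]
    if (is.na(nf)) next
    out <- file.path(outDir, paste0(.safeName(tm), ".tsv"))
    if (file.exists(out) && !cfg$force) next
    ok <- tryCatch({
      net <- readEdgeListTSV(nf, geneIds = st$network@genes)
      y <- buildLabelVector(tm, st$annot, st$dag, st$network@genes,
                            labelGenes = st$trainGenes)
      res <- propagateLabels(net, y, sigma = cfg$sigma, category = tm)
      writePredictionsTSV(res, out)
      .log(cfg, "predicted ", tm)
      TRUE
    }, error = function(e) {
      .log(cfg, "FAILED ", tm, ": ", conditionMessage(e))
      FALSE
    })
  }
  invisible(outDir)
}

.cmdEvaluate <- function(cfg) {
  st <- .pipelineState(cfg)
  tcfg <- trainConfig(alpha = cfg$alpha,
                      checkInterval = cfg$checkInterval,
                      patience = cfg$patience, minDelta = cfg$minDelta,
                      maxIterations = cfg$maxIterations,
                      sigma = cfg$sigma, k = cfg$k)
  scfg <- samplingConfig(strategy = cfg$strategy,
                         threshold = cfg$threshold)
  .log(cfg, "cross-validating with learning enabled")
  repPA <- crossValidate(st$network, st$annot, st$dag,
                         terms = cfg$terms, nFolds = cfg$nFolds,
                         valFraction = cfg$valFraction,
                         learning = "pa", config = tcfg,
                         sampling = scfg, seed = cfg$seed)
  .log(cfg, "cross-validating with learning disabled")
  repNone <- crossValidate(st$network, st$annot, st$dag,
                           terms = cfg$terms, nFolds = cfg$nFolds,
                           valFraction = cfg$valFraction,
                           learning = "none", config = tcfg,
                           sampling = scfg, seed = cfg$seed)
  writeEvaluationReport(repNone, file.path(cfg$dir,
                                           "evaluation_fixed.tsv"))
  summary <- writeEvaluationReport(repPA,
                                   file.path(cfg$dir,
                                             "evaluation_learned.tsv"),
                                   baseline = repNone)
  .log(cfg, "mean AUC learned ",
       format(mean(repPA$perTerm$meanAUC), digits = 4),
       " vs fixed ",
       format(mean(repNone$perTerm$meanAUC), digits = 4))
  invisible(list(learned = repPA, fixed = repNone, summary = summary))
}
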