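#' Rank-based AUC with ties averaged
#'
#' Area under the ROC curve computed from mid-ranks, equivalent to the
#' Mann-Whitney U statistic: ties contribute one half.
#'
#' @param scoreVec real-valued scores.
#' @param labels logical (or 0/1) vector, TRUE for positives; both
#'   classes must be present.
#' @return the AUC in [0, 1].
#' @export
aucScore <- function(scoreVec, labels) {
  labels <- as.logical(labels)
  if (length(scoreVec) != length(labels))
    stop("scores and labels differ in length")
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scoreVec)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Two-sided Wilcoxon signed-rank comparison of paired per-term AUCs
#'
#' Zero differences are dropped (the standard signed-rank convention);
#' when every difference is zero the p-value is 1 by convention.
#'
#' @param aucA,aucB equal-length per-term AUC vectors, paired by term.
#' @return the two-sided p-value.
#' @export
wilcoxonSignedRank <- function(aucA, aucB) {
  stopifnot(length(aucA) == length(aucB))
  d <- aucA - aucB
  d <- d[d != 0]
  if (length(d) == 0L) {
    message("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided")$p.value)
}

#' Floored AUC difference per term
#'
#' Delta-AUC = max(a, 0.5) - max(b, 0.5): both methods are floored at the
#' random-guessing level 0.5 before differencing, so below-chance scores
#' do not inflate the contrast.
#'
#' @param aucA,aucB paired per-term AUC vectors.
#' @return per-term differences, named like \code{aucA}.
#' @export
deltaAUC <- function(aucA, aucB) {
  stopifnot(length(aucA) == length(aucB))
  pmax(aucA, 0.5) - pmax(aucB, 0.5)
}

#' Mean AUC by positive-count bin
#'
#' Groups evaluated terms into inclusive positive-count ranges (default
#' [3-10], [11-30], [31-100] and the overlapping overall bin [3-100])
#' and reports the mean AUC and its standard error per bin. Empty bins
#' are absent from the result.
#'
#' @param report an evaluation report from \code{\link{crossValidate}},
#'   or any data.frame with columns \code{nPositives} and
#'   \code{meanAUC}.
#' @param bins list of inclusive (lo, hi) ranges.
#' @return data.frame with columns bin, nTerms, meanAUC, se.
#' @export
binByPositives <- function(report,
                           bins = list(c(3, 10), c(11, 30),
                                       c(31, 100), c(3, 100))) {
  df <- if (inherits(report, "evaluationReport")) report$perTerm else
    as.data.frame(report)
  out <- lapply(bins, function(b) {
    sel <- df$nPositives >= b[1] & df$nPositives <= b[2]
    if (!any(sel)) return(NULL)
    x <- df$meanAUC[sel]
    data.frame(bin = paste0("[", b[1], "-", b[2], "]"),
               nTerms = sum(sel), meanAUC = mean(x),
               se = stats::sd(x) / sqrt(length(x)))
  })
  do.call(rbind, out)
}

# stratified fold assignment: rarest terms first, their positives dealt
# round-robin over folds; leftover genes fill the smallest folds
.assignFolds <- function(geneIds, posByTerm, nFolds) {
  fold <- stats::setNames(rep(NA_integer_, length(geneIds)), geneIds)
  for (term in names(sort(vapply(posByTerm, length, integer(1))))) {
    pos <- posByTerm[[term]]
    counts <- tabulate(fold[pos][!is.na(fold[pos])], nFolds)
    for (g in sample(pos[is.na(fold[pos])])) {
      f <- which.min(counts)
      fold[g] <- f
      counts[f] <- counts[f] + 1L
    }
  }
  left <- names(fold)[is.na(fold)]
  sizes <- tabulate(fold[!is.na(fold)], nFolds)
  for (g in sample(left)) {
    f <- which.min(sizes)
    fold[g] <- f
    sizes[f] <- sizes[f] + 1L
  }
  fold
}

# restrict an annotation set to a gene subset (closure is preserved)
.restrictAnnotations <- function(annot, geneIds) {
  new("AnnotationSet",
      assignments = annot@assignments[intersect(names(annot@assignments),
                                                geneIds)],
      closed = annot@closed)
}

#' Cross-validated per-term AUC evaluation
#'
#' Splits the annotated genes into \code{nFolds} stratified folds. Per
#' fold, the test genes' annotations are withheld; a 25\% validation
#' subset (stratified per term) is withheld from the remaining training
#' genes to drive early stopping; the learn / reconstruct / propagate
#' pipeline is run per term; and the test genes are ranked. Per-term
#' AUCs are averaged over folds.
#'
#' Three learning modes support the improvement comparison:
#' \code{"pa"} runs the Passive-Aggressive similarity learner;
#' \code{"identity"} keeps W at the identity but still reconstructs
#' (the untrained bilinear baseline); \code{"none"} propagates on the
#' input network directly (the fixed-network baseline).
#'
#' @param network integrated, sparsified \linkS4class{WeightedNetwork}
#'   over all genes.
#' @param annot closed \linkS4class{AnnotationSet} (the visible
#'   annotations; its genes form the CV pool).
#' @param dag \linkS4class{OntologyDAG}.
#' @param terms terms to evaluate; default: all non-root terms with at
#'   least \code{nFolds} positives. Terms that cannot receive one
#'   positive per fold are excluded with a warning.
#' @param nFolds number of folds (default 3).
#' @param valFraction validation fraction of each fold's training
#'   portion (default 0.25).
#' @param learning one of "pa", "identity", "none".
#' @param config a \code{\link{trainConfig}} (its \code{k} and
#'   \code{sigma} also drive reconstruction and propagation).
#' @param sampling a \code{\link{samplingConfig}}.
#' @param seed integer seed; fixes fold assignment, validation splits
#'   and the triplet stream.
#' @param verbose print per-fold progress.
#' @return an object of class "evaluationReport": a list with
#'   \code{perTerm} (term, nPositives, per-fold AUCs, meanAUC),
#'   \code{foldAssignments}, \code{learning}, \code{nFolds}.
#' @export
crossValidate <- function(network, annot, dag, terms = NULL,
                          nFolds = 3L, valFraction = 0.25,
                          learning = c("pa", "identity", "none"),
                          config = trainConfig(),
                          sampling = samplingConfig(),
                          seed = 1L, verbose = FALSE) {
  learning <- match.arg(learning)
  stopifnot(is(network, "WeightedNetwork"), is(annot, "AnnotationSet"))
  if (!annot@closed) stop("annotations must be closed")
  set.seed(seed)
  pool <- intersect(names(annot@assignments), network@genes)
  if (length(pool) < nFolds) stop("too few annotated genes for ",
                                  nFolds, " folds")
  termCounts <- table(unlist(annot@assignments[pool], use.names = FALSE))
  if (is.null(terms)) {
    terms <- setdiff(names(termCounts)[termCounts >= nFolds], dag@root)
  }
  .checkTerms(dag, terms)
  posByTerm <- lapply(stats::setNames(terms, terms), function(tm)
    pool[vapply(annot@assignments[pool], function(x) tm %in% x,
                logical(1))])

  small <- names(posByTerm)[lengths(posByTerm) < nFolds]
  if (length(small)) {
    warning("excluding term(s) with fewer than ", nFolds,
            " positives: ", paste(small, collapse = ", "))
    posByTerm <- posByTerm[setdiff(names(posByTerm), small)]
  }
  # AUC also needs negatives in every test fold; drop near-universal terms
  negCounts <- vapply(names(posByTerm), function(tm) {
    desc <- termDescendants(dag, tm, include.self = TRUE)
    sum(vapply(annot@assignments[pool], function(x)
      !any(x %in% desc), logical(1)))
  }, integer(1))
  wide <- names(posByTerm)[negCounts < nFolds]
  if (length(wide)) {
    warning("excluding term(s) with fewer than ", nFolds,
            " negatives: ", paste(wide, collapse = ", "))
    posByTerm <- posByTerm[setdiff(names(posByTerm), wide)]
  }
  fold <- .assignFolds(pool, posByTerm, nFolds)
  strat <- vapply(posByTerm, function(p)
    all(tabulate(fold[p], nFolds) >= 1L), logical(1))
  if (any(!strat)) {
    warning("excluding unstratifiable term(s): ",
            paste(names(posByTerm)[!strat], collapse = ", "))
    posByTerm <- posByTerm[strat]
  }
  terms <- names(posByTerm)
  if (!length(terms)) stop("no evaluable terms remain")

  aucMat <- matrix(NA_real_, length(terms), nFolds,
                   dimnames = list(terms, paste0("fold", seq_len(nFolds))))
  for (f in seq_len(nFolds)) {
    testGenes <- pool[fold[pool] == f]
    trainGenes <- setdiff(pool, testGenes)
    annotTrain <- .restrictAnnotations(annot, trainGenes)
    if (verbose) message("fold ", f, ": ", length(trainGenes),
                         " train / ", length(testGenes), " test genes")
    if (learning == "none") {
      for (tm in terms) {
        y <- buildLabelVector(tm, annotTrain, dag, network@genes,
                              labelGenes = trainGenes)
        res <- propagateLabels(network, y, sigma = config$sigma,
                               category = tm)
        aucMat[tm, f] <- .testAUC(res, tm, annot, dag, testGenes)
      }
      next
    }
    fmapAll <- featureMap(network, trainGenes)
    if (learning == "identity") {
      netI <- reconstructNetwork(diag(length(trainGenes)), fmapAll,
                                 k = config$k)
      for (tm in terms) {
        y <- buildLabelVector(tm, annotTrain, dag, network@genes,
                              labelGenes = trainGenes)
        res <- propagateLabels(netI, y, sigma = config$sigma,
                               category = tm)
        aucMat[tm, f] <- .testAUC(res, tm, annot, dag, testGenes)
      }
      next
    }
    # learning == "pa"
    icTrain <- informationContent(annotTrain, dag)
    pairSim <- geneSimilarityMatrix(trainGenes, annotTrain, icTrain, dag)
    phiTrainRows <- fmapAll@phi[trainGenes, , drop = FALSE]
    fmapTrain <- new("FeatureMap", trainingGenes = trainGenes,
                     phi = phiTrainRows)
    for (tm in terms) {
      valGenes <- .drawValidation(tm, posByTerm[[tm]], trainGenes,
                                  annotTrain, dag, valFraction)
      model <- trainCategory(fmapTrain, annotTrain, dag, pairSim, tm,
                             valGenes, config = config,
                             sampling = sampling)
      netC <- reconstructNetwork(model, fmapAll, k = config$k)
      y <- buildLabelVector(tm, annotTrain, dag, network@genes,
                            labelGenes = trainGenes)
      res <- propagateLabels(netC, y, sigma = config$sigma,
                             category = tm)
      aucMat[tm, f] <- .testAUC(res, tm, annot, dag, testGenes)
      if (verbose) message("  ", tm, ": AUC ",
                           format(aucMat[tm, f], digits = 3),
                           " (", model@iterationsRun, " iterations)")
    }
  }
  perTerm <- data.frame(term = terms,
                        nPositives = lengths(posByTerm)[terms],
                        aucMat,
                        meanAUC = rowMeans(aucMat, na.rm = TRUE),
                        row.names = NULL)
  structure(list(perTerm = perTerm, foldAssignments = fold,
                 learning = learning, nFolds = nFolds),
            class = "evaluationReport")
}

# stratified 25% validation holdout from the fold's training portion:
# a share of the term's positives and of its eligible negatives
.drawValidation <- function(term, posAll, trainGenes, annotTrain, dag,
                            valFraction) {
  pos <- intersect(posAll, trainGenes)
  desc <- termDescendants(dag, term, include.self = TRUE)
  neg <- trainGenes[vapply(annotTrain@assignments[trainGenes],
                           function(x) is.null(x) || !any(x %in% desc),
                           logical(1))]
  nvp <- floor(length(pos) * valFraction)
  if (length(pos) - nvp < 2L) nvp <- max(length(pos) - 2L, 0L)
  nvn <- floor(length(neg) * valFraction)
  c(if (nvp > 0) sample(pos, nvp),
    if (nvn > 0) sample(neg, nvn))
}

#' Write an evaluation report
#'
#' The per-term table goes to TSV (term, n_positives, per-fold AUCs,
#' mean AUC); a JSON summary holds the positive-count bins and, when a
#' baseline report is supplied, the Wilcoxon signed-rank p-value and the
#' extremes of the floored AUC differences.
#'
#' @param report an evaluation report from \code{\link{crossValidate}}.
#' @param path output TSV path; the JSON summary goes to
#'   \code{paste0(path, ".summary.json")}.
#' @param baseline optional second report (same terms) to compare
#'   against.
#' @return invisibly, the summary list.
#' @export
writeEvaluationReport <- function(report, path, baseline = NULL) {
  df <- report$perTerm
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "nPositives"
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(learning = report$learning,
                  nFolds = report$nFolds,
                  nTerms = nrow(report$perTerm),
                  meanAUC = mean(report$perTerm$meanAUC),
                  bins = binByPositives(report))
  if (!is.null(baseline)) {
    stopifnot(identical(report$perTerm$term, baseline$perTerm$term))
    a <- report$perTerm$meanAUC
    b <- baseline$perTerm$meanAUC
    dd <- deltaAUC(a, b)
    summary$comparison <- list(
      baselineLearning = baseline$learning,
      baselineMeanAUC = mean(b),
      wilcoxonP = wilcoxonSignedRank(a, b),
      nImproved = sum(a > b),
      deltaAUCMax = max(dd),
      deltaAUCMin = min(dd))
  }
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
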