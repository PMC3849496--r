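#' Label vector for one category
#'
#' Training genes annotated to the category get +1; training genes
#' annotated neither to the category nor to any of its descendants get
#' -1; every other gene receives the class-imbalance prior
#' (d+ - d-) / (d+ + d-), with d+ and d- the positive and negative
#' training counts. Annotations must be closed so that a gene annotated
#' only below the category is counted positive, not negative.
#'
#' @param category term identifier.
#' @param annot closed \linkS4class{AnnotationSet} of the training genes.
#' @param dag \linkS4class{OntologyDAG}.
#' @param geneUniverse all n genes, in network order.
#' @param labelGenes genes whose annotation status may be used (the
#'   training set); defaults to all annotated genes.
#' @return named numeric vector y over \code{geneUniverse}, entries in
#'   [-1, 1].
#' @export
buildLabelVector <- function(category, annot, dag, geneUniverse,
                             labelGenes = names(annot@assignments)) {
  .checkTerms(dag, category)
  if (!annot@closed) stop("annotations must be closed")
  labelGenes <- intersect(labelGenes, geneUniverse)
  desc <- termDescendants(dag, category, include.self = TRUE)
  ts <- annot@assignments[labelGenes]
  pos <- labelGenes[vapply(ts, function(x)
    !is.null(x) && category %in% x, logical(1))]
  neg <- labelGenes[vapply(ts, function(x)
    is.null(x) || !any(x %in% desc), logical(1))]
  if (length(pos) == 0L)
    stop("category ", category, " has no positive training gene")
  dpos <- length(pos)
  dneg <- length(neg)
  prior <- if (dpos + dneg > 0) (dpos - dneg) / (dpos + dneg) else 0
  y <- stats::setNames(rep(prior, length(geneUniverse)), geneUniverse)
  y[pos] <- 1
  y[neg] <- -1
  y
}

#' Propagate labels over an association network
#'
#' Solves the semi-supervised objective
#' sum_i (y_i - f_i)^2 + sigma * sum_ij a'_ij (f_i - f_j)^2, whose
#' minimiser is f = (I + sigma L)^{-1} y with L = D - A' the graph
#' Laplacian. The system is solved by a sparse symmetric
#' positive-definite factorisation, never by forming the inverse.
#' Isolated genes keep f_i = y_i; all scores stay within
#' [min(y), max(y)].
#'
#' @param network symmetric non-negative \linkS4class{WeightedNetwork}.
#' @param y label vector (see \code{\link{buildLabelVector}}), aligned
#'   with or named by the network's genes.
#' @param sigma non-negative smoothing trade-off (default 1).
#' @param category optional category label carried into the result.
#' @return a \linkS4class{PropagationResult}.
#' @export
propagateLabels <- function(network, y, sigma = 1,
                            category = NA_character_) {
  stopifnot(is(network, "WeightedNetwork"), sigma >= 0)
  A <- network@adj
  if (min(A) < 0) stop("negative edge weights")
  if (!isSymmetric(A, tol = 0)) stop("network must be symmetric")
  if (!is.null(names(y))) {
    if (!setequal(names(y), network@genes))
      stop("label vector names do not match network genes")
    y <- y[network@genes]
  } else if (length(y) != length(network@genes))
    stop("label vector length does not match network size")
  n <- length(y)
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  M <- Matrix::Diagonal(n) + sigma * L
  f <- as.numeric(Matrix::solve(M, y))
  res <- as.numeric(M %*% f - y)
  if (sqrt(sum(res^2)) > 1e-8 * max(sqrt(sum(y^2)), 1e-12))
    stop("propagation solve did not reach the required residual")
  new("PropagationResult", genes = network@genes, f = f,
      y = as.numeric(y), sigma = sigma, category = category)
}

#' Threshold propagation scores into calls
#'
#' Ranking (AUC) is threshold-free; this helper is provided for callers
#' that need hard positive/negative calls from the scores.
#'
#' @param result a \linkS4class{PropagationResult}.
#' @param cutoff score cutoff (default 0).
#' @return named logical vector of calls.
#' @export
thresholdCalls <- function(result, cutoff = 0) {
  stats::setNames(result@f > cutoff, result@genes)
}

#' Write propagation predictions as TSV
#'
#' Columns: gene, term, score, status (train-positive / train-negative /
#' predicted).
#'
#' @param result a \linkS4class{PropagationResult}.
#' @param path output file path.
#' @export
writePredictionsTSV <- function(result, path) {
  status <- ifelse(result@y == 1, "train-positive",
                   ifelse(result@y == -1, "train-negative", "predicted"))
  df <- data.frame(gene = result@genes, term = result@category,
                   score = format(result@f, digits = 17, trim = TRUE),
                   status = status)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
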