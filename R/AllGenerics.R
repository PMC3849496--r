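#' Accessors for similearn classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x an object of the documented classes.
#' @return \code{genes}: character vector of gene identifiers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname accessors
#' @export
setGeneric("ontologyRoot", function(x) standardGeneric("ontologyRoot"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("icValues", function(x) standardGeneric("icValues"))

#' @rdname accessors
#' @export
setGeneric("maxIC", function(x) standardGeneric("maxIC"))

#' @rdname accessors
#' @export
setGeneric("trainingGenes", function(x) standardGeneric("trainingGenes"))

#' @rdname accessors
#' @export
setGeneric("featureVectors", function(x) standardGeneric("featureVectors"))

#' @rdname accessors
#' @export
setGeneric("modelMatrix", function(x) standardGeneric("modelMatrix"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("ontologyTerms", "OntologyDAG", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("ontologyRoot", "OntologyDAG", function(x) x@root)

#' @rdname accessors
#' @export
setMethod("genes", "AnnotationSet", function(x) names(x@assignments))

#' @rdname accessors
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("isClosed", "AnnotationSet", function(x) x@closed)

#' @rdname accessors
#' @export
setMethod("icValues", "InformationContentTable", function(x) x@ic)

#' @rdname accessors
#' @export
setMethod("maxIC", "InformationContentTable", function(x) x@maxIC)

#' @rdname accessors
#' @export
setMethod("genes", "WeightedNetwork", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("adjacency", "WeightedNetwork", function(x) x@adj)

#' @rdname accessors
#' @export
setMethod("genes", "FeatureMap", function(x) rownames(x@phi))

#' @rdname accessors
#' @export
setMethod("trainingGenes", "FeatureMap", function(x) x@trainingGenes)

#' @rdname accessors
#' @export
setMethod("featureVectors", "FeatureMap", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("modelMatrix", "SimilarityModel", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("trainingGenes", "SimilarityModel", function(x) x@trainingGenes)

#' @rdname accessors
#' @export
setMethod("genes", "PropagationResult", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("scores", "PropagationResult", function(x) {
  stats::setNames(x@f, x@genes)
})

#' @rdname accessors
#' @export
setMethod("genes", "SyntheticBenchmark", function(x) x@genes)

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms, root",
      object@root, "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  nt <- length(unique(unlist(object@assignments)))
  cat("AnnotationSet:", length(object@assignments), "genes,",
      nt, "terms,", if (object@closed) "closed" else "not closed", "\n")
})

setMethod("show", "InformationContentTable", function(object) {
  cat("InformationContentTable:", length(object@ic), "terms, max IC",
      format(object@maxIC, digits = 4), "nats over",
      object@nGenes, "genes\n")
})

setMethod("show", "WeightedNetwork", function(object) {
  ne <- Matrix::nnzero(object@adj) / 2
  cat("WeightedNetwork:", length(object@genes), "genes,",
      ne, "edges\n")
})

setMethod("show", "FeatureMap", function(object) {
  cat("FeatureMap:", nrow(object@phi), "genes x",
      ncol(object@phi), "training-gene coordinates\n")
})

setMethod("show", "SimilarityModel", function(object) {
  cat("SimilarityModel for", object@category, "- d =",
      length(object@trainingGenes),
      if (object@trained) "(trained)" else "(identity / untrained)", "\n")
  if (!is.na(object@bestValidationAUC))
    cat("  iterations:", object@iterationsRun,
        " best validation AUC:",
        format(object@bestValidationAUC, digits = 4), "\n")
})

setMethod("show", "PropagationResult", function(object) {
  cat("PropagationResult for", object@category, "-",
      length(object@genes), "genes, sigma =", object@sigma, "\n")
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat("SyntheticBenchmark:", length(object@genes), "genes,",
      length(object@dag@terms), "terms,", length(object@sources),
      "sources, seed", object@seed, "\n")
})
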