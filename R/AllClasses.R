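#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal t colSums rowSums
#' @importFrom Matrix drop0 nnzero diag isSymmetric solve which
#' @importFrom Matrix tcrossprod crossprod
#' @importFrom Matrix "diag<-"
NULL

#' OntologyDAG: a rooted acyclic term hierarchy
#'
#' Holds a rooted directed acyclic graph of ontology terms linked child to
#' parent (the \code{is_a} relation). Ancestor sets (each term counting as
#' its own ancestor) are precomputed at construction; they drive annotation
#' up-propagation, most-informative-common-ancestor lookup and descendant
#' exclusion when negatives are sampled.
#'
#' @slot terms character vector of term identifiers, topologically ordered
#'   (parents before children).
#' @slot parents named list, term -> character vector of direct parents.
#'   The root has none.
#' @slot root the single term with no parents.
#' @slot ancestors named list, term -> all ancestors including the term
#'   itself.
#'
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  representation(
    terms     = "character",
    parents   = "list",
    root      = "character",
    ancestors = "list"
  )
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  if (length(object@root) != 1L)
    msgs <- c(msgs, "exactly one root term required")
  if (length(object@parents[[object@root]]) != 0L)
    msgs <- c(msgs, "root must have no parents")
  bad <- setdiff(unique(unlist(object@parents)), object@terms)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown parent term(s): ",
                           paste(bad, collapse = ", ")))
  # every term reaches root (ancestors computed by construction guarantee
  # acyclicity; verify reachability)
  reach <- vapply(object@terms, function(t)
    object@root %in% object@ancestors[[t]], logical(1))
  if (!all(reach))
    msgs <- c(msgs, paste0("term(s) not reaching root: ",
                           paste(object@terms[!reach], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: gene-to-term assignments
#'
#' @slot assignments named list, gene -> character vector of annotated
#'   terms.
#' @slot closed TRUE when the set is closed under the ontology's ancestor
#'   relation (every annotated term carries all its ancestors).
#'
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(
    assignments = "list",
    closed      = "logical"
  ),
  prototype(closed = FALSE)
)

setValidity("AnnotationSet", function(object) {
  if (length(object@assignments) &&
      is.null(names(object@assignments)))
    return("assignments must be a named (by gene) list")
  TRUE
})

#' InformationContentTable: per-term information content
#'
#' IC(t) = -log P(t), with P(t) the fraction of annotated genes carrying t
#' in a closed annotation corpus. Terms annotating zero genes are absent
#' rather than infinite. \code{maxIC} is the corpus maximum, used to
#' normalise Resnik similarities into [0, 1].
#'
#' @slot ic named numeric, term -> IC in nats.
#' @slot maxIC corpus maximum IC (0 when only the root is annotated).
#' @slot nGenes number of annotated genes (the probability denominator).
#'
#' @exportClass InformationContentTable
setClass("InformationContentTable",
  representation(
    ic     = "numeric",
    maxIC  = "numeric",
    nGenes = "integer"
  )
)

setValidity("InformationContentTable", function(object) {
  if (any(object@ic < -1e-12)) return("negative IC value")
  if (length(object@maxIC) != 1L || object@maxIC < 0)
    return("maxIC must be a single non-negative number")
  TRUE
})

#' WeightedNetwork: a non-negative weighted gene graph
#'
#' @slot genes ordered gene identifiers (the node set).
#' @slot adj sparse symmetric adjacency with zero diagonal; entry (i, j)
#'   is the association weight a_ij >= 0.
#'
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
  representation(
    genes = "character",
    adj   = "Matrix"
  )
)

setValidity("WeightedNetwork", function(object) {
  n <- length(object@genes)
  if (!all(dim(object@adj) == c(n, n)))
    return("adjacency dimensions must match the gene list")
  if (anyDuplicated(object@genes))
    return("duplicate gene identifiers")
  if (n > 0 && min(object@adj) < 0)
    return("negative edge weight")
  if (any(diag(object@adj) != 0))
    return("self-loops are not allowed")
  if (!isSymmetric(object@adj, tol = 0))
    return("adjacency must be symmetric")
  TRUE
})

#' FeatureMap: genes as vectors of association weights to training genes
#'
#' Represents each gene g_l by the column vector of its network weights to
#' the d annotated training genes, Phi(g_l) = (a_{l,1}, ..., a_{l,d})^T.
#' Rows of \code{phi} are genes, columns the d training-gene coordinates.
#'
#' @slot trainingGenes the d annotated genes defining the coordinates.
#' @slot phi sparse n x d matrix of feature vectors (rows named by gene).
#'
#' @exportClass FeatureMap
setClass("FeatureMap",
  representation(
    trainingGenes = "character",
    phi           = "Matrix"
  )
)

setValidity("FeatureMap", function(object) {
  if (anyDuplicated(object@trainingGenes))
    return("duplicate training genes")
  if (ncol(object@phi) != length(object@trainingGenes))
    return("phi must have one column per training gene")
  if (is.null(rownames(object@phi)))
    return("phi rows must be named by gene")
  TRUE
})

#' SimilarityModel: a learned per-category bilinear similarity
#'
#' The bilinear similarity S_W(g_i, g_j) = Phi(g_i)^T W Phi(g_j) for one
#' functional category, with W a d x d parameter matrix initialised to the
#' identity and updated by Passive-Aggressive steps over training triplets.
#'
#' @slot W d x d parameter matrix.
#' @slot trainingGenes the d genes defining the feature coordinates.
#' @slot category the functional category (ontology term) this W serves.
#' @slot alpha aggressiveness parameter used in training.
#' @slot iterationsRun number of triplet iterations performed.
#' @slot bestValidationAUC best validation AUC observed (NA when untrained).
#' @slot trained FALSE when training was impossible (too few positives) or
#'   never improved on the identity initialisation.
#'
#' @exportClass SimilarityModel
setClass("SimilarityModel",
  representation(
    W                 = "matrix",
    trainingGenes     = "character",
    category          = "character",
    alpha             = "numeric",
    iterationsRun     = "integer",
    bestValidationAUC = "numeric",
    trained           = "logical"
  ),
  prototype(alpha = 0.1, iterationsRun = 0L,
            bestValidationAUC = NA_real_, trained = FALSE)
)

setValidity("SimilarityModel", function(object) {
  d <- length(object@trainingGenes)
  if (!all(dim(object@W) == c(d, d)))
    return("W must be d x d with d the number of training genes")
  if (!all(is.finite(object@W)))
    return("W must be finite")
  if (object@iterationsRun < 0L)
    return("iterationsRun must be non-negative")
  TRUE
})

#' PropagationResult: per-gene scores for one category
#'
#' The solution f of (I + sigma L) f = y on an association network, used to
#' rank genes for the category. Scores stay inside [min(y), max(y)].
#'
#' @slot genes gene identifiers, aligned with \code{f}.
#' @slot f real-valued scores.
#' @slot y the label/prior vector the scores were propagated from.
#' @slot sigma the smoothing trade-off used.
#' @slot category the functional category scored.
#'
#' @exportClass PropagationResult
setClass("PropagationResult",
  representation(
    genes    = "character",
    f        = "numeric",
    y        = "numeric",
    sigma    = "numeric",
    category = "character"
  )
)

setValidity("PropagationResult", function(object) {
  if (length(object@f) != length(object@genes))
    return("f must align with genes")
  if (length(object@y) != length(object@genes))
    return("y must align with genes")
  if (object@sigma < 0) return("sigma must be non-negative")
  TRUE
})

#' SyntheticBenchmark: a self-contained synthetic study
#'
#' Bundles a generated ontology, closed multi-label annotations with a
#' hidden truth split, and heterogeneous data sources in which co-annotated
#' genes carry correlated signal. Regeneration from the same seed and
#' parameters is bit-identical.
#'
#' @slot dag the generated OntologyDAG.
#' @slot annotations visible (closed) AnnotationSet.
#' @slot truth hidden gene -> term assignments (named list), removed from
#'   the visible annotations.
#' @slot sources list of gene x feature matrices; entries of class
#'   \code{data.frame} with columns gene_a/gene_b are binary edge lists.
#' @slot genes the gene universe.
#' @slot seed the generating seed.
#'
#' @exportClass SyntheticBenchmark
setClass("SyntheticBenchmark",
  representation(
    dag         = "OntologyDAG",
    annotations = "AnnotationSet",
    truth       = "list",
    sources     = "list",
    genes       = "character",
    seed        = "integer"
  )
)
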