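#' Generate a random rooted ontology DAG
#'
#' Builds a random tree over the requested number of terms (every term's
#' first parent is drawn among earlier terms, so the graph is acyclic by
#' construction) and then adds extra parent links up to
#' \code{maxParents} per term, giving diamond-style multiple
#' inheritance.
#'
#' @param nTerms total number of terms including the root (>= 2).
#' @param maxParents maximum number of parents per non-root term
#'   (1 gives a tree).
#' @param extraParentProb probability that a term receives each extra
#'   parent link beyond the first.
#' @param seed integer seed; the DAG is bit-identical for a fixed seed.
#' @return an \linkS4class{OntologyDAG} with root "T0000".
#' @export
generateOntology <- function(nTerms, maxParents = 2L,
                             extraParentProb = 0.3, seed = 1L) {
  stopifnot(nTerms >= 2, maxParents >= 1)
  set.seed(seed)
  ids <- sprintf("T%04d", seq_len(nTerms) - 1L)
  parents <- stats::setNames(vector("list", nTerms), ids)
  parents[[1]] <- character(0)
  for (i in 2:nTerms) {
    pool <- ids[seq_len(i - 1L)]
    p <- sample(pool, 1L)
    nExtra <- min(maxParents - 1L, length(pool) - 1L)
    if (nExtra > 0) {
      extra <- pool[pool != p]
      extra <- extra[stats::runif(length(extra)) < extraParentProb]
      p <- c(p, utils::head(extra, nExtra))
    }
    parents[[i]] <- p
  }
  ontologyDAG(parents)
}

#' Generate multi-label, imbalanced, ancestor-closed annotations
#'
#' Leaf terms receive power-law popularity weights (rank^-imbalance;
#' imbalance 0 gives roughly equal term sizes). Each gene draws a small
#' number of leaf terms from that distribution and the assignments are
#' up-propagated. A configurable fraction of (gene, leaf-term) pairs is
#' then moved to a hidden truth set: those assignments are removed from
#' the visible annotations (the gene keeps whatever closure its
#' remaining leaves imply), emulating genes whose function is not yet
#' annotated.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param nGenes number of genes.
#' @param meanTermsPerGene mean number of leaf terms per gene (>= 1).
#' @param imbalance power-law exponent of the leaf-term popularity.
#' @param truthFraction fraction of (gene, leaf-term) assignments
#'   hidden as prediction truth.
#' @param seed integer seed.
#' @return list with elements \code{annotations} (closed, visible
#'   \linkS4class{AnnotationSet}), \code{truth} (named list gene ->
#'   hidden leaf terms), and \code{genes} (the full gene universe,
#'   including genes left unannotated).
#' @export
generateAnnotations <- function(dag, nGenes, meanTermsPerGene = 2,
                                imbalance = 1, truthFraction = 0.1,
                                seed = 1L) {
  stopifnot(nGenes >= 1, meanTermsPerGene >= 1, truthFraction >= 0,
            truthFraction < 1)
  set.seed(seed)
  geneIds <- sprintf("g%04d", seq_len(nGenes))
  kids <- table(factor(unlist(dag@parents, use.names = FALSE),
                       levels = dag@terms))
  leaves <- dag@terms[kids == 0L]
  wt <- seq_along(leaves)^(-imbalance)
  leafSets <- lapply(geneIds, function(g) {
    nt <- min(1L + stats::rpois(1L, meanTermsPerGene - 1),
              length(leaves))
    sample(leaves, nt, prob = wt)
  })
  names(leafSets) <- geneIds

  # hide a fraction of the (gene, leaf term) pairs as prediction truth
  pairGene <- rep(geneIds, lengths(leafSets))
  pairTerm <- unlist(leafSets, use.names = FALSE)
  hide <- stats::runif(length(pairGene)) < truthFraction
  truth <- split(pairTerm[hide], pairGene[hide])
  visible <- leafSets
  for (g in names(truth))
    visible[[g]] <- setdiff(visible[[g]], truth[[g]])
  visible <- visible[lengths(visible) > 0L]

  annot <- upPropagate(annotationSet(visible), dag)
  list(annotations = annot, truth = truth, genes = geneIds)
}

#' Generate heterogeneous noisy data sources with planted structure
#'
#' Gaussian latent-factor model: per source, every leaf term gets an
#' independent standard-normal loading vector, and a gene's feature row
#' is \code{signal} times the sum of its terms' loadings plus
#' \code{noise} times independent Gaussian noise. Genes sharing leaf
#' terms therefore show within-term feature correlation that grows with
#' signal/noise; unannotated genes are pure noise. The last source is
#' emitted as a binary interaction edge list by keeping the top-quantile
#' latent-affinity gene pairs.
#'
#' @param annot \linkS4class{AnnotationSet} carrying the (full) leaf
#'   memberships the sources should encode.
#' @param dag the \linkS4class{OntologyDAG} (identifies leaf terms).
#' @param geneIds gene universe (defaults to the annotated genes).
#' @param nSources number of sources (>= 1); the last is the binary
#'   interaction list when \code{nSources} > 1.
#' @param signal latent-structure strength (>= 0).
#' @param noise independent noise scale (> 0).
#' @param nFeatures features per real-valued source.
#' @param edgeQuantile affinity quantile above which a binary edge is
#'   drawn (default 0.98: the top 2 percent of pairs).
#' @param seed integer seed.
#' @return list of sources: numeric gene-by-feature matrices, plus one
#'   data.frame with columns gene_a, gene_b for the binary source.
#' @export
generateSources <- function(annot, dag, geneIds = NULL, nSources = 4L,
                            signal = 1, noise = 1, nFeatures = 20L,
                            edgeQuantile = 0.98, seed = 1L) {
  stopifnot(signal >= 0, noise > 0, nSources >= 1)
  set.seed(seed)
  if (is.null(geneIds)) geneIds <- names(annot@assignments)
  kids <- table(factor(unlist(dag@parents, use.names = FALSE),
                       levels = dag@terms))
  leaves <- dag@terms[kids == 0L]
  membership <- lapply(annot@assignments[geneIds], intersect, leaves)
  names(membership) <- geneIds

  latent <- function(m) {
    loadings <- matrix(stats::rnorm(length(leaves) * m), length(leaves),
                       m, dimnames = list(leaves, NULL))
    base <- t(vapply(membership, function(ts) {
      if (length(ts)) colSums(loadings[ts, , drop = FALSE]) else
        numeric(m)
    }, numeric(m)))
    signal * base +
      noise * matrix(stats::rnorm(length(geneIds) * m),
                     length(geneIds), m)
  }
  nReal <- if (nSources > 1L) nSources - 1L else nSources
  sources <- lapply(seq_len(nReal), function(s) {
    x <- latent(nFeatures)
    dimnames(x) <- list(geneIds,
                        sprintf("src%d_f%02d", s, seq_len(nFeatures)))
    x
  })
  if (nSources > 1L) {
    aff <- latent(nFeatures)
    A <- tcrossprod(aff)
    ut <- upper.tri(A)
    cut <- stats::quantile(A[ut], edgeQuantile)
    idx <- which(ut & A > cut, arr.ind = TRUE)
    sources[[nSources]] <- data.frame(
      gene_a = geneIds[idx[, 1]], gene_b = geneIds[idx[, 2]])
  }
  sources
}

#' Generate a complete synthetic benchmark
#'
#' Bundles \code{\link{generateOntology}},
#' \code{\link{generateAnnotations}} and \code{\link{generateSources}}
#' into one seeded, bit-reproducible study: a small GO-like DAG,
#' multi-label up-propagated annotations with strong class imbalance, a
#' hidden truth split, and several heterogeneous noisy sources in which
#' co-annotated genes carry correlated signal. The sources encode the
#' full (pre-split) annotations, so hidden-truth genes remain
#' discoverable from the data — the prediction task the pipeline is
#' evaluated on.
#'
#' @param nGenes,nTerms,nSources problem size (defaults 300 genes, 20
#'   terms, 4 sources).
#' @param signal,noise latent-structure strength and noise scale
#'   (defaults 1 and 1: moderate noise).
#' @param meanTermsPerGene,imbalance,truthFraction annotation shape; see
#'   \code{\link{generateAnnotations}}.
#' @param maxParents,extraParentProb DAG shape; see
#'   \code{\link{generateOntology}}.
#' @param nFeatures features per real-valued source.
#' @param seed integer seed (sub-generators run on seed, seed+1,
#'   seed+2).
#' @return a \linkS4class{SyntheticBenchmark}.
#' @export
generateBenchmark <- function(nGenes = 300L, nTerms = 20L,
                              nSources = 4L, signal = 1, noise = 1,
                              meanTermsPerGene = 2, imbalance = 1,
                              truthFraction = 0.1, maxParents = 2L,
                              extraParentProb = 0.3, nFeatures = 20L,
                              seed = 1L) {
  seed <- as.integer(seed)
  dag <- generateOntology(nTerms, maxParents, extraParentProb,
                          seed = seed)
  ann <- generateAnnotations(dag, nGenes, meanTermsPerGene, imbalance,
                             truthFraction, seed = seed + 1L)
  # sources encode the full membership, hidden truth included
  fullLeaf <- ann$annotations@assignments
  for (g in names(ann$truth))
    fullLeaf[[g]] <- unique(c(fullLeaf[[g]], ann$truth[[g]]))
  fullAnnot <- upPropagate(annotationSet(fullLeaf), dag)
  sources <- generateSources(fullAnnot, dag, geneIds = ann$genes,
                             nSources = nSources, signal = signal,
                             noise = noise, nFeatures = nFeatures,
                             seed = seed + 2L)
  new("SyntheticBenchmark", dag = dag, annotations = ann$annotations,
      truth = ann$truth, sources = sources, genes = ann$genes,
      seed = seed)
}

#' Integrated association network of a synthetic benchmark
#'
#' Builds one positive-PCC network per real-valued source and a binary
#' network from the interaction list, integrates them with equal
#' weights and sparsifies to the union of per-node top-k edges.
#'
#' @param bench a \linkS4class{SyntheticBenchmark}.
#' @param k per-node top-k sparsification (default 50).
#' @return a \linkS4class{WeightedNetwork} over the benchmark genes.
#' @export
benchmarkNetwork <- function(bench, k = 50) {
  nets <- lapply(bench@sources, function(s) {
    if (is.data.frame(s)) binaryNetwork(s, geneIds = bench@genes)
    else pccNetwork(s)
  })
  sparsifyTopK(integrateEqual(nets), k)
}

#' Write a benchmark to disk in the package's file dialects
#'
#' Emits ontology.obo (and ontology.tsv), annotations.gaf (and
#' annotations.tsv), one data-matrix TSV per real-valued source, the
#' binary source as an edge-list TSV, truth.tsv and genes.txt — the
#' same formats the package readers consume, so round-tripping a
#' benchmark exercises every parser.
#'
#' @param bench a \linkS4class{SyntheticBenchmark}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeOBO(bench@dag, file.path(dir, "ontology.obo"))
  writeOntologyTSV(bench@dag, file.path(dir, "ontology.tsv"))
  .writeGAF(bench@annotations, file.path(dir, "annotations.gaf"))
  writeAnnotationsTSV(bench@annotations, file.path(dir,
                                                   "annotations.tsv"))
  si <- 0L
  for (s in bench@sources) {
    si <- si + 1L
    if (is.data.frame(s)) {
      utils::write.table(s, file.path(dir,
                                      sprintf("source%d_edges.tsv", si)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    } else {
      writeDataMatrixTSV(s, file.path(dir,
                                      sprintf("source%d_matrix.tsv", si)))
    }
  }
  truthGene <- rep(names(bench@truth), lengths(bench@truth))
  truthTerm <- unlist(bench@truth, use.names = FALSE)
  utils::write.table(data.frame(truthGene, truthTerm),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(bench@genes, file.path(dir, "genes.txt"))
  invisible(dir)
}

.writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag@terms) {
    writeLines(c("[Term]", paste0("id: ", t),
                 paste0("name: synthetic term ", t),
                 paste0("is_a: ", dag@parents[[t]]), ""), con)
  }
  invisible(path)
}

.writeGAF <- function(annot, path) {
  gene <- rep(names(annot@assignments), lengths(annot@assignments))
  term <- unlist(annot@assignments, use.names = FALSE)
  df <- data.frame(db = "SYN", id = gene, symbol = gene, qualifier = "",
                   term = term, ref = "SYN:0000001", evidence = "IEA",
                   with = "", aspect = "P", name = gene, syn = "",
                   type = "gene", taxon = "taxon:0000", date = "20260101",
                   assigned = "similearn")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
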