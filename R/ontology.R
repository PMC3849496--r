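#' Construct an ontology DAG from child-parent links
#'
#' Builds a rooted DAG from a parent relation. The term order is
#' topological (parents before children), cycles are rejected, and the
#' ancestor closure of every term is precomputed.
#'
#' @param parents either a named list (term -> character vector of direct
#'   parents; the root maps to \code{character(0)}), or a two-column
#'   data.frame of (child, parent) links.
#' @return an \linkS4class{OntologyDAG}.
#' @examples
#' dag <- ontologyDAG(data.frame(child  = c("A", "B", "C"),
#'                               parent = c("root", "root", "A")))
#' termAncestors(dag, "C")
#' @export
ontologyDAG <- function(parents) {
  if (is.data.frame(parents)) {
    stopifnot(ncol(parents) >= 2)
    child  <- as.character(parents[[1]])
    parent <- as.character(parents[[2]])
    terms  <- union(child, parent)
    plist  <- lapply(stats::setNames(terms, terms), function(t)
      unique(parent[child == t]))
  } else {
    if (is.null(names(parents)))
      stop("'parents' list must be named by term")
    plist <- lapply(parents, function(p) unique(as.character(p)))
    terms <- union(names(plist), unlist(plist, use.names = FALSE))
    for (t in setdiff(terms, names(plist))) plist[[t]] <- character(0)
  }
  roots <- names(plist)[vapply(plist, length, integer(1)) == 0L]
  if (length(roots) != 1L)
    stop("the term hierarchy must have exactly one root; found: ",
         paste(roots, collapse = ", "))

  # Kahn topological sort; a leftover node means a cycle
  indeg <- vapply(plist, length, integer(1))
  nkids <- lapply(plist, function(p) character(0))
  for (t in names(plist)) for (p in plist[[t]])
    nkids[[p]] <- c(nkids[[p]], t)
  order <- character(0)
  queue <- roots
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (k in nkids[[t]]) {
      indeg_left[[k]] <- indeg_left[[k]] - 1L
      if (indeg_left[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != length(plist))
    stop("cycle detected among terms: ",
         paste(setdiff(names(plist), order), collapse = ", "))

  anc <- vector("list", length(order))
  names(anc) <- order
  for (t in order)
    anc[[t]] <- unique(c(t, unlist(anc[plist[[t]]], use.names = FALSE)))

  new("OntologyDAG", terms = order, parents = plist[order],
      root = roots, ancestors = anc)
}

#' Ancestors and descendants of a term
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param term a term identifier.
#' @param include.self include the term itself (default TRUE; a term is
#'   its own ancestor for MICA purposes).
#' @return character vector of term identifiers.
#' @export
termAncestors <- function(dag, term, include.self = TRUE) {
  .checkTerms(dag, term)
  a <- dag@ancestors[[term]]
  if (include.self) a else setdiff(a, term)
}

#' @rdname termAncestors
#' @export
termDescendants <- function(dag, term, include.self = TRUE) {
  .checkTerms(dag, term)
  d <- dag@terms[vapply(dag@ancestors, function(a) term %in% a,
                        logical(1))]
  if (include.self) d else setdiff(d, term)
}

.checkTerms <- function(dag, terms) {
  bad <- setdiff(terms, dag@terms)
  if (length(bad))
    stop("unknown term identifier(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Construct an annotation set
#'
#' @param assignments named list, gene -> character vector of terms.
#' @param closed whether the set is already ancestor-closed.
#' @return an \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(assignments, closed = FALSE) {
  assignments <- lapply(assignments, function(x)
    sort(unique(as.character(x))))
  new("AnnotationSet", assignments = assignments, closed = closed)
}

#' Up-propagate annotations through the ontology
#'
#' Closes a gene-to-term annotation set under the ancestor relation: a
#' gene assigned to a term is also assigned to all ancestors of that term.
#' The operation is idempotent and only ever adds assignments.
#'
#' @param annot an \linkS4class{AnnotationSet}.
#' @param dag the \linkS4class{OntologyDAG} the terms live in.
#' @return a closed \linkS4class{AnnotationSet}.
#' @export
upPropagate <- function(annot, dag) {
  stopifnot(is(annot, "AnnotationSet"), is(dag, "OntologyDAG"))
  .checkTerms(dag, unique(unlist(annot@assignments, use.names = FALSE)))
  closed <- lapply(annot@assignments, function(ts)
    sort(unique(unlist(dag@ancestors[ts], use.names = FALSE))))
  new("AnnotationSet", assignments = closed, closed = TRUE)
}

#' Per-term information content from a closed annotation corpus
#'
#' IC(t) = -log( n(t) / n(root) ), with n(t) the number of genes
#' annotated to term t. Annotations must be closed so that parent counts
#' dominate child counts, making IC monotone non-decreasing away from the
#' root. Terms annotating zero genes are omitted from the table rather
#' than assigned infinite IC.
#'
#' @param annot a closed \linkS4class{AnnotationSet} with at least one
#'   annotated gene.
#' @param dag the \linkS4class{OntologyDAG}.
#' @return an \linkS4class{InformationContentTable} (IC in nats).
#' @export
informationContent <- function(annot, dag) {
  stopifnot(is(annot, "AnnotationSet"), is(dag, "OntologyDAG"))
  if (!annot@closed)
    stop("annotations must be up-propagated (closed) before computing IC")
  if (length(annot@assignments) == 0L)
    stop("empty annotation corpus")
  counts <- table(factor(unlist(annot@assignments, use.names = FALSE),
                         levels = dag@terms))
  nroot <- as.integer(counts[[dag@root]])
  if (nroot == 0L)
    stop("no gene reaches the root: corpus is empty or not closed")
  present <- counts > 0L
  ic <- -log(as.numeric(counts[present]) / nroot)
  names(ic) <- names(counts)[present]
  ic[dag@root] <- 0  # exactly zero, not -log(1) with rounding noise
  new("InformationContentTable", ic = ic, maxIC = max(ic),
      nGenes = nroot)
}

#' Resnik similarity between two ontology terms
#'
#' The information content of the most informative common ancestor (MICA)
#' of the two terms, normalised to [0, 1] by the corpus maximum IC. Each
#' term counts as its own ancestor, so \code{resnikSimilarity(t, t)} is
#' \code{ic(t)/maxIC}.
#'
#' @param t1,t2 term identifiers present in both the DAG and the IC table.
#' @param ic an \linkS4class{InformationContentTable}.
#' @param dag the \linkS4class{OntologyDAG}.
#' @return a similarity in [0, 1].
#' @export
resnikSimilarity <- function(t1, t2, ic, dag) {
  .checkTerms(dag, c(t1, t2))
  bad <- setdiff(c(t1, t2), names(ic@ic))
  if (length(bad))
    stop("term(s) absent from the IC table (zero-annotation): ",
         paste(bad, collapse = ", "))
  common <- intersect(dag@ancestors[[t1]], dag@ancestors[[t2]])
  common <- intersect(common, names(ic@ic))
  if (length(common) == 0L)
    stop("internal error: no common ancestor in a rooted DAG")
  if (ic@maxIC == 0) return(0)
  max(ic@ic[common]) / ic@maxIC
}

#' Best-match-average semantic similarity between two genes
#'
#' For each term annotated to gene A, takes the best Resnik match among
#' gene B's terms, and vice versa; the similarity is the mean over the
#' union of both directional best-match lists (|T_A| + |T_B| addends).
#' Symmetric and bounded in [0, 1].
#'
#' @param geneA,geneB gene identifiers, both annotated.
#' @param annot an \linkS4class{AnnotationSet}.
#' @param ic an \linkS4class{InformationContentTable}.
#' @param dag the \linkS4class{OntologyDAG}.
#' @return a similarity in [0, 1].
#' @export
geneSimilarityBMA <- function(geneA, geneB, annot, ic, dag) {
  ta <- .annotatedTerms(annot, geneA, ic)
  tb <- .annotatedTerms(annot, geneB, ic)
  S <- termSimilarityMatrix(union(ta, tb), ic, dag)
  .bmaFromMatrix(S, ta, tb)
}

.annotatedTerms <- function(annot, gene, ic) {
  ts <- annot@assignments[[gene]]
  if (is.null(ts) || length(ts) == 0L)
    stop("gene has no annotations: ", gene)
  ts <- intersect(ts, names(ic@ic))
  if (length(ts) == 0L)
    stop("gene has no corpus-annotated terms: ", gene)
  ts
}

.bmaFromMatrix <- function(S, ta, tb) {
  sub <- S[ta, tb, drop = FALSE]
  (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
    (length(ta) + length(tb))
}

#' Pairwise normalised Resnik similarities for a set of terms
#'
#' @param terms term identifiers present in the IC table.
#' @param ic an \linkS4class{InformationContentTable}.
#' @param dag the \linkS4class{OntologyDAG}.
#' @return a symmetric matrix of similarities in [0, 1].
#' @export
termSimilarityMatrix <- function(terms, ic, dag) {
  terms <- unique(terms)
  m <- length(terms)
  S <- matrix(0, m, m, dimnames = list(terms, terms))
  if (ic@maxIC == 0) return(S)
  anc <- lapply(dag@ancestors[terms], intersect, names(ic@ic))
  for (i in seq_len(m)) {
    for (j in i:m) {
      common <- intersect(anc[[i]], anc[[j]])
      s <- if (length(common)) max(ic@ic[common]) / ic@maxIC else 0
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  S
}

#' All-pairs best-match-average gene similarity matrix
#'
#' Computes \code{\link{geneSimilarityBMA}} for every pair of the given
#' genes, sharing one term-similarity matrix across pairs. Triplet
#' sampling consumes this cache since the same pairs recur over many
#' iterations.
#'
#' @param geneIds genes to compare (all must be annotated).
#' @param annot an \linkS4class{AnnotationSet}.
#' @param ic an \linkS4class{InformationContentTable}.
#' @param dag the \linkS4class{OntologyDAG}.
#' @return symmetric matrix of similarities in [0, 1]; the diagonal holds
#'   each gene's self-similarity.
#' @export
geneSimilarityMatrix <- function(geneIds, annot, ic, dag) {
  tl <- lapply(stats::setNames(geneIds, geneIds), function(g)
    .annotatedTerms(annot, g, ic))
  S <- termSimilarityMatrix(unique(unlist(tl, use.names = FALSE)), ic, dag)
  n <- length(geneIds)
  R <- matrix(0, n, n, dimnames = list(geneIds, geneIds))
  for (i in seq_len(n)) {
    for (j in i:n) {
      r <- .bmaFromMatrix(S, tl[[i]], tl[[j]])
      R[i, j] <- r
      R[j, i] <- r
    }
  }
  R
}

#' Read an ontology from OBO or a child-parent TSV
#'
#' The OBO reader keeps \code{is_a} edges only; \code{relationship:}
#' lines (e.g. part_of) are counted and reported via a message. Obsolete
#' terms are dropped. The TSV dialect is two columns, child then parent,
#' no header.
#'
#' @param path file path.
#' @return an \linkS4class{OntologyDAG}.
#' @export
readOBO <- function(path) {
  lines <- readLines(path)
  termStarts <- grep("^\\[Term\\]\\s*$", lines)
  if (length(termStarts) == 0L)
    stop("no [Term] stanzas found in ", path)
  stanzaEnds <- c(grep("^\\[", lines), length(lines) + 1L)
  ids <- character(0)
  isa <- list()
  nRel <- 0L
  for (s in termStarts) {
    e <- min(stanzaEnds[stanzaEnds > s]) - 1L
    block <- lines[s:e]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE)[1])
    id <- sub("\\s*!.*$", "", id)
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    par <- sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE))
    par <- sub("\\s*!.*$", "", par)
    nRel <- nRel + sum(grepl("^relationship:", block))
    ids <- c(ids, id)
    isa[[id]] <- par
  }
  if (nRel > 0L)
    message("readOBO: ignored ", nRel,
            " non-is_a relationship line(s) (e.g. part_of)")
  # keep only edges to non-obsolete terms
  isa <- lapply(isa, intersect, ids)
  ontologyDAG(isa)
}

#' @rdname readOBO
#' @export
readOntologyTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("child", "parent"))
  ontologyDAG(df)
}

#' Read gene annotations from GAF 2.x or a two-column TSV
#'
#' The GAF reader uses column 2 (gene identifier) and column 5 (term),
#' skips comment lines and drops rows whose qualifier (column 4) contains
#' \code{NOT}. The TSV dialect is gene then term, no header.
#'
#' @param path file path.
#' @param closed mark the result as already ancestor-closed.
#' @return an \linkS4class{AnnotationSet}.
#' @export
readGAF <- function(path, closed = FALSE) {
  lines <- grep("^!", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f)
    length(f) >= 5L && !grepl("NOT", f[4]), logical(1))
  fields <- fields[keep]
  gene <- vapply(fields, `[[`, character(1), 2L)
  term <- vapply(fields, `[[`, character(1), 5L)
  annotationSet(split(term, gene), closed = closed)
}

#' @rdname readGAF
#' @export
readAnnotationsTSV <- function(path, closed = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("gene", "term"))
  annotationSet(split(df$term, df$gene), closed = closed)
}

#' Write annotations as a two-column TSV
#'
#' @param annot an \linkS4class{AnnotationSet}.
#' @param path output file path.
#' @export
writeAnnotationsTSV <- function(annot, path) {
  gene <- rep(names(annot@assignments),
              lengths(annot@assignments))
  term <- unlist(annot@assignments, use.names = FALSE)
  utils::write.table(data.frame(gene, term), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an ontology as a child-parent TSV
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param path output file path.
#' @export
writeOntologyTSV <- function(dag, path) {
  child  <- rep(names(dag@parents), lengths(dag@parents))
  parent <- unlist(dag@parents, use.names = FALSE)
  utils::write.table(data.frame(child, parent), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
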