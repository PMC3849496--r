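#' Construct a WeightedNetwork from a (possibly dense) adjacency
#'
#' @param adj square numeric matrix or Matrix, symmetric, non-negative;
#'   the diagonal is zeroed.
#' @param geneIds gene identifiers; defaults to the adjacency rownames.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
weightedNetwork <- function(adj, geneIds = rownames(adj)) {
  if (is.null(geneIds))
    stop("gene identifiers required (rownames or 'geneIds')")
  adj <- Matrix::Matrix(adj, sparse = TRUE)
  diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  dimnames(adj) <- list(geneIds, geneIds)
  new("WeightedNetwork", genes = as.character(geneIds),
      adj = methods::as(adj, "generalMatrix"))
}

#' Association network from positive Pearson correlations
#'
#' Edge weight a_ij = max(cor(x_i, x_j), 0): pairwise Pearson correlation
#' of the gene feature rows, with negative correlations set to zero and
#' no self-edges. Genes with constant rows get zero edges (a warning
#' names how many).
#'
#' @param data numeric gene-by-feature matrix with gene rownames, at
#'   least two feature columns.
#' @return a \linkS4class{WeightedNetwork} with weights in [0, 1].
#' @export
pccNetwork <- function(data) {
  data <- as.matrix(data)
  if (is.null(rownames(data))) stop("data must have gene rownames")
  if (ncol(data) < 2L) stop("need at least two features per gene")
  sds <- apply(data, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat))
    warning(sum(flat), " constant gene row(s): their edges are set to 0")
  C <- suppressWarnings(stats::cor(t(data)))
  C[!is.finite(C)] <- 0
  C[flat, ] <- 0
  C[, flat] <- 0
  C[C < 0] <- 0
  diag(C) <- 0
  weightedNetwork(C, rownames(data))
}

#' Binary interaction network from an edge list
#'
#' Every listed undirected pair gets weight 1; duplicates (including
#' reversed duplicates) collapse to a single edge, and self-loop rows are
#' dropped with a warning.
#'
#' @param edges data.frame whose first two columns are gene identifiers
#'   (an optional third weight column is ignored: weights are 1).
#' @param geneIds the gene universe; defaults to the genes seen in the
#'   edge list.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
binaryNetwork <- function(edges, geneIds = NULL) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (is.null(geneIds)) geneIds <- sort(unique(c(a, b)))
  bad <- setdiff(c(a, b), geneIds)
  if (length(bad))
    stop("edge references unknown gene(s): ", paste(bad, collapse = ", "))
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  n <- length(geneIds)
  i <- match(a, geneIds); j <- match(b, geneIds)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n), use.last.ij = TRUE)
  adj@x[] <- 1  # duplicates collapse to weight 1
  weightedNetwork(adj, geneIds)
}

#' Equal-weight integration of several networks
#'
#' The combined network is the elementwise sum of the individual
#' adjacencies, all sources weighted equally. Gene universes are aligned
#' by identifier; a gene absent from a source contributes a zero row
#' there.
#'
#' @param networks non-empty list of \linkS4class{WeightedNetwork}s.
#' @return a \linkS4class{WeightedNetwork} over the union gene universe.
#' @export
integrateEqual <- function(networks) {
  if (!length(networks)) stop("no networks to integrate")
  stopifnot(all(vapply(networks, is, logical(1), "WeightedNetwork")))
  universe <- sort(unique(unlist(lapply(networks, genes))))
  n <- length(universe)
  total <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, n))
  for (net in networks) {
    idx <- match(net@genes, universe)
    part <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, n))
    part[idx, idx] <- net@adj
    total <- total + part
  }
  weightedNetwork(total, universe)
}

#' Sparsify a network to the union of per-node top-k edges
#'
#' An edge survives iff it ranks among the k largest-weight incident
#' edges of at least one endpoint, so the result stays symmetric and
#' every node of input degree >= k keeps at least k incident edges. Ties
#' break by (weight descending, partner identifier ascending) for
#' reproducibility. Idempotent at fixed k and monotone in k.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param k number of strongest connections kept per node (default 50).
#' @return a sparsified \linkS4class{WeightedNetwork}.
#' @export
sparsifyTopK <- function(network, k = 50) {
  stopifnot(is(network, "WeightedNetwork"), k >= 1)
  adj <- methods::as(network@adj, "TsparseMatrix")
  keepRow <- adj@i < adj@j  # upper triangle, 0-based
  ei <- adj@i[keepRow] + 1L
  ej <- adj@j[keepRow] + 1L
  ex <- adj@x[keepRow]
  live <- ex > 0
  ei <- ei[live]; ej <- ej[live]; ex <- ex[live]
  # union of per-node top-k: rank each edge within both endpoints' lists
  node    <- c(ei, ej)
  partner <- c(ej, ei)
  w       <- c(ex, ex)
  eid     <- rep(seq_along(ex), 2L)
  ord <- order(node, -w, network@genes[partner], method = "radix")
  rankInNode <- sequence(rle(node[ord])$lengths)
  keep <- sort(unique(eid[ord][rankInNode <= k]))
  n <- length(network@genes)
  adj2 <- Matrix::sparseMatrix(i = c(ei[keep], ej[keep]),
                               j = c(ej[keep], ei[keep]),
                               x = rep(ex[keep], 2), dims = c(n, n))
  weightedNetwork(adj2, network@genes)
}

#' Feature map: genes as weight vectors over the training genes
#'
#' Applies the feature representation Phi(g_l) = (a_{l,1}, ..., a_{l,d}),
#' the row of network weights from gene g_l to the d annotated training
#' genes. A training gene's own coordinate is zero (no self-loops), and
#' an isolated gene maps to the zero vector.
#'
#' @param network a (typically sparsified) \linkS4class{WeightedNetwork}.
#' @param trainGenes the d training genes, a subset of the network's
#'   genes, no duplicates.
#' @return a \linkS4class{FeatureMap} over all network genes.
#' @export
featureMap <- function(network, trainGenes) {
  stopifnot(is(network, "WeightedNetwork"))
  trainGenes <- as.character(trainGenes)
  if (anyDuplicated(trainGenes)) stop("duplicate training genes")
  bad <- setdiff(trainGenes, network@genes)
  if (length(bad))
    stop("training gene(s) not in network: ", paste(bad, collapse = ", "))
  phi <- network@adj[, match(trainGenes, network@genes), drop = FALSE]
  dimnames(phi) <- list(network@genes, trainGenes)
  new("FeatureMap", trainingGenes = trainGenes,
      phi = methods::as(phi, "generalMatrix"))
}

#' Read / write edge-list TSV networks
#'
#' Dialect: gene_a<TAB>gene_b<TAB>weight, undirected, no header; the
#' weight column is optional on read (default 1).
#'
#' @param path file path.
#' @param geneIds optional gene universe for the read network.
#' @return \code{readEdgeListTSV}: a \linkS4class{WeightedNetwork}.
#' @export
readEdgeListTSV <- function(path, geneIds = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  if (is.null(geneIds)) geneIds <- sort(unique(c(a, b)))
  n <- length(geneIds)
  i <- match(a, geneIds); j <- match(b, geneIds)
  if (anyNA(i) || anyNA(j)) stop("edge references gene outside universe")
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                              dims = c(n, n), use.last.ij = TRUE)
  weightedNetwork(adj, geneIds)
}

#' @rdname readEdgeListTSV
#' @param network a \linkS4class{WeightedNetwork} to write.
#' @export
writeEdgeListTSV <- function(network, path) {
  adj <- methods::as(network@adj, "TsparseMatrix")
  keep <- adj@i < adj@j
  df <- data.frame(a = network@genes[adj@i[keep] + 1L],
                   b = network@genes[adj@j[keep] + 1L],
                   w = format(adj@x[keep], digits = 17, trim = TRUE,
                              scientific = FALSE))
  df <- df[order(df$a, df$b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-feature data matrix TSV
#'
#' Dialect: header row of feature names, first column gene identifiers.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
readDataMatrixTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @rdname readDataMatrixTSV
#' @param mat numeric matrix with gene rownames to write.
#' @export
writeDataMatrixTSV <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
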