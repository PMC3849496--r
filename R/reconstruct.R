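#' Reconstruct a per-category association network from a learned W
#'
#' Scores every gene pair with the learned bilinear similarity and uses
#' the symmetrised score a'_ij = (S_W(g_i, g_j) + S_W(g_j, g_i)) / 2 as
#' the new edge weight. Because W is unconstrained, negative scores can
#' occur; they are clamped to zero before the union-top-k sparsification
#' (the downstream Laplacian needs non-negative weights). At desk scale
#' the full score matrix is formed blockwise as Phi W Phi^T.
#'
#' @param model a \linkS4class{SimilarityModel} (or bare d x d matrix W
#'   plus \code{trainingGenes} implied by the feature map).
#' @param fmap \linkS4class{FeatureMap} over all n genes, with the same
#'   d training-gene coordinates the model was trained on.
#' @param k per-node top-k sparsification (default 50).
#' @return a symmetric, sparsified \linkS4class{WeightedNetwork}.
#' @export
reconstructNetwork <- function(model, fmap, k = 50) {
  stopifnot(is(fmap, "FeatureMap"))
  W <- if (is(model, "SimilarityModel")) model@W else as.matrix(model)
  if (is(model, "SimilarityModel") &&
      !identical(model@trainingGenes, fmap@trainingGenes))
    stop("model and feature map use different training-gene coordinates")
  if (nrow(W) != ncol(fmap@phi))
    stop("model dimension (", nrow(W),
         ") does not match feature dimension (", ncol(fmap@phi), ")")
  phi <- as.matrix(fmap@phi)
  .reconstructFromW(phi, W, k, rownames(phi))
}

# dense blockwise reconstruction on a bare matrix
.reconstructFromW <- function(phi, W, k, geneIds,
                              blockSize = 2048L) {
  n <- nrow(phi)
  right <- W %*% t(phi)       # d x n: right factor, formed once
  rows <- split(seq_len(n), ceiling(seq_len(n) / blockSize))
  S <- do.call(rbind, lapply(rows, function(idx)
    phi[idx, , drop = FALSE] %*% right))
  A <- (S + t(S)) / 2
  A[A < 0] <- 0
  diag(A) <- 0
  net <- weightedNetwork(A, geneIds)
  sparsifyTopK(net, k)
}
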