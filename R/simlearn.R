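#' Training configuration for the Passive-Aggressive similarity learner
#'
#' @param alpha aggressiveness: the cap on the PA step size tau. Small
#'   values change W conservatively; default 0.1.
#' @param checkInterval iterations between validation-AUC checks
#'   (default 2000).
#' @param patience consecutive non-improving checks before training
#'   stops (default 3).
#' @param minDelta minimum validation-AUC gain that counts as an
#'   improvement (default 1e-4).
#' @param maxIterations hard cap on triplet iterations.
#' @param sigma propagation trade-off used when scoring the validation
#'   set (default 1).
#' @param k top-k sparsification applied to validation reconstructions
#'   (default 50).
#' @param seed optional integer seed for the triplet stream.
#' @return a list of class "trainConfig".
#' @export
trainConfig <- function(alpha = 0.1, checkInterval = 2000L,
                        patience = 3L, minDelta = 1e-4,
                        maxIterations = 20000L, sigma = 1, k = 50,
                        seed = NULL) {
  stopifnot(alpha > 0, checkInterval >= 1, patience >= 1,
            maxIterations >= 0, sigma >= 0, k >= 1)
  if (maxIterations > 0 && maxIterations < checkInterval)
    stop("maxIterations must be >= checkInterval (or 0)")
  structure(list(alpha = alpha, checkInterval = as.integer(checkInterval),
                 patience = as.integer(patience), minDelta = minDelta,
                 maxIterations = as.integer(maxIterations),
                 sigma = sigma, k = k, seed = seed),
            class = "trainConfig")
}

#' Bilinear similarity score
#'
#' S_W(g_i, g_j) = Phi(g_i)^T W Phi(g_j). The computation touches only
#' the non-zero coordinates of the two feature vectors, so its cost is
#' O(nnz_i x nnz_j) independent of d.
#'
#' @param model a \linkS4class{SimilarityModel}, or a bare d x d matrix W.
#' @param phiI,phiJ feature vectors of length d.
#' @return the real-valued similarity score.
#' @export
bilinearScore <- function(model, phiI, phiJ) {
  W <- if (is(model, "SimilarityModel")) model@W else model
  phiI <- as.numeric(phiI); phiJ <- as.numeric(phiJ)
  if (length(phiI) != nrow(W) || length(phiJ) != ncol(W))
    stop("feature vector length does not match model dimension d = ",
         nrow(W))
  ia <- which(phiI != 0)
  jb <- which(phiJ != 0)
  if (!length(ia) || !length(jb)) return(0)
  drop(phiI[ia] %*% (W[ia, jb, drop = FALSE] %*% phiJ[jb]))
}

#' Triplet hinge loss
#'
#' l_W(g, g+, g-) = max(1 - S_W(g, g+) + S_W(g, g-), 0): zero exactly
#' when the positive pair beats the negative pair by the unit safety
#' margin.
#'
#' @inheritParams bilinearScore
#' @param phi,phiPlus,phiMinus feature vectors of the anchor, positive
#'   and negative genes.
#' @return a non-negative loss.
#' @export
hingeLoss <- function(model, phi, phiPlus, phiMinus) {
  max(1 - bilinearScore(model, phi, phiPlus) +
        bilinearScore(model, phi, phiMinus), 0)
}

#' One Passive-Aggressive update
#'
#' For a margin-violating triplet, updates W <- W + tau V with
#' V = Phi(g) (Phi(g+) - Phi(g-))^T and
#' tau = min(alpha, loss / ||V||_Frob^2). When tau is not clamped by
#' alpha, the updated W satisfies the margin with equality, so the
#' triplet's hinge loss becomes exactly zero. Zero-loss triplets leave W
#' untouched (the passive case), as does a degenerate V with zero norm
#' (logged via warning).
#'
#' @param model a \linkS4class{SimilarityModel}.
#' @inheritParams hingeLoss
#' @param alpha aggressiveness cap; defaults to the model's.
#' @return the updated \linkS4class{SimilarityModel} (with
#'   \code{iterationsRun} incremented).
#' @export
paUpdate <- function(model, phi, phiPlus, phiMinus,
                     alpha = model@alpha) {
  stopifnot(is(model, "SimilarityModel"))
  phi <- as.numeric(phi)
  delta <- as.numeric(phiPlus) - as.numeric(phiMinus)
  upd <- .paStep(model@W, phi, delta, alpha)
  if (is.null(upd$W)) {
    if (upd$degenerate)
      warning("degenerate triplet (||V|| = 0) skipped")
    W <- model@W
  } else W <- upd$W
  methods::initialize(model, W = W,
                      iterationsRun = model@iterationsRun + 1L)
}

# core PA step on a bare matrix; returns W = NULL when no update applies
.paStep <- function(W, phi, delta, alpha) {
  ia <- which(phi != 0)
  jd <- which(delta != 0)
  if (!length(ia) || !length(jd)) {
    loss <- 1  # scores are both zero
    return(list(W = NULL, loss = loss, tau = 0, degenerate = TRUE))
  }
  sv <- phi[ia]
  M <- W[ia, jd, drop = FALSE]
  diffScore <- sum(sv * (M %*% delta[jd]))
  loss <- 1 - diffScore
  if (loss <= 0) return(list(W = NULL, loss = 0, tau = 0,
                             degenerate = FALSE))
  vnorm2 <- sum(sv^2) * sum(delta[jd]^2)
  if (vnorm2 == 0) return(list(W = NULL, loss = loss, tau = 0,
                               degenerate = TRUE))
  tau <- min(alpha, loss / vnorm2)
  W[ia, jd] <- M + tau * outer(sv, delta[jd])
  list(W = W, loss = loss, tau = tau, degenerate = FALSE)
}

#' Train a per-category bilinear similarity model
#'
#' Iterates triplet sampling, hinge loss and Passive-Aggressive updates
#' starting from W = I. Every \code{checkInterval} iterations the current
#' W is scored on the held-out validation genes by the full
#' reconstruct-then-propagate path (reconstruct a network over the
#' feature map's genes with the current W, propagate labels from the
#' triplet-training genes, rank the validation genes); the W with the
#' best validation AUC seen is returned. Training stops when
#' \code{patience} consecutive checks fail to improve the best AUC by
#' more than \code{minDelta} ("saturation"). If no check ever beats the
#' identity-W baseline the identity matrix is returned, reproducing the
#' immediate-stop behaviour on categories the bilinear model cannot
#' help. Categories with fewer than two positives (or no eligible
#' negatives) yield an untrained identity model.
#'
#' @param fmap \linkS4class{FeatureMap} over the training-plus-validation
#'   genes, whose coordinates are the d annotated training genes.
#' @param annot closed \linkS4class{AnnotationSet}.
#' @param dag \linkS4class{OntologyDAG}.
#' @param pairSim gene-pair similarity matrix over the annotated
#'   training genes (see \code{\link{geneSimilarityMatrix}}).
#' @param category term to learn a similarity for.
#' @param valGenes validation genes; disjoint from the genes that
#'   generate triplets.
#' @param config a \code{\link{trainConfig}}.
#' @param sampling a \code{\link{samplingConfig}}.
#' @return a \linkS4class{SimilarityModel}.
#' @export
trainCategory <- function(fmap, annot, dag, pairSim, category, valGenes,
                          config = trainConfig(),
                          sampling = samplingConfig()) {
  stopifnot(is(fmap, "FeatureMap"))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- length(fmap@trainingGenes)
  identityModel <- new("SimilarityModel", W = diag(d),
                       trainingGenes = fmap@trainingGenes,
                       category = category, alpha = config$alpha,
                       iterationsRun = 0L,
                       bestValidationAUC = NA_real_, trained = FALSE)
  tripGenes <- setdiff(rownames(pairSim), valGenes)

  sampler <- tryCatch(
    newTripletSampler(category, annot, dag, pairSim, sampling,
                      candidates = tripGenes),
    categoryTooSmall = function(e) NULL)
  if (is.null(sampler) || config$maxIterations == 0L)
    return(identityModel)

  phiD <- as.matrix(fmap@phi)
  valAUC <- function(W) {
    net <- .reconstructFromW(phiD, W, config$k, rownames(phiD))
    y <- buildLabelVector(category, annot, dag,
                          geneUniverse = rownames(phiD),
                          labelGenes = tripGenes)
    res <- propagateLabels(net, y, sigma = config$sigma)
    .testAUC(res, category, annot, dag, valGenes)
  }
  baseAUC <- valAUC(identityModel@W)
  if (is.na(baseAUC)) return(identityModel)  # validation set unusable

  W <- diag(d)
  bestW <- W
  bestAUC <- baseAUC
  bestIter <- 0L
  stale <- 0L
  iter <- 0L
  repeat {
    batch <- tryCatch(sampler(config$checkInterval),
                      categoryTooSmall = function(e) NULL)
    if (is.null(batch)) break
    gi <- match(batch$g, rownames(phiD))
    gp <- match(batch$g_plus, rownames(phiD))
    gm <- match(batch$g_minus, rownames(phiD))
    for (t in seq_len(nrow(batch))) {
      upd <- .paStep(W, phiD[gi[t], ], phiD[gp[t], ] - phiD[gm[t], ],
                     config$alpha)
      if (!is.null(upd$W)) W <- upd$W
    }
    iter <- iter + nrow(batch)
    auc <- valAUC(W)
    if (!is.na(auc) && auc > bestAUC + config$minDelta) {
      bestAUC <- auc
      bestW <- W
      bestIter <- iter
      stale <- 0L
    } else stale <- stale + 1L
    # a first check that already degrades on the identity baseline stops
    # training immediately; the identity W is returned
    if (iter == config$checkInterval && !is.na(auc) && auc < baseAUC)
      break
    if (stale >= config$patience || iter >= config$maxIterations) break
  }
  trained <- bestIter > 0L
  methods::initialize(identityModel, W = bestW,
                      iterationsRun = iter,
                      bestValidationAUC = bestAUC, trained = trained)
}

# AUC of propagation scores over heldGenes for one category: positives
# carry the category; negatives lack it and all its descendants; genes
# matching neither rule are excluded from the ranking
.testAUC <- function(res, category, annot, dag, heldGenes) {
  desc <- termDescendants(dag, category, include.self = TRUE)
  ts <- annot@assignments[heldGenes]
  pos <- vapply(ts, function(x) !is.null(x) && category %in% x,
                logical(1))
  neg <- vapply(ts, function(x) is.null(x) || !any(x %in% desc),
                logical(1))
  use <- pos | neg
  if (!any(pos) || !any(neg)) return(NA_real_)
  s <- scores(res)[heldGenes]
  aucScore(s[use], pos[use])
}

#' Save / load a similarity model as plain text
#'
#' One file per category: a small header (category, alpha, iteration
#' count, best validation AUC, trained flag, d), the training-gene
#' order, then the d rows of W at full precision ("%.17g"), so the
#' round-trip is lossless.
#'
#' @param model a \linkS4class{SimilarityModel}.
#' @param path output file path.
#' @export
writeSimilarityModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- length(model@trainingGenes)
  writeLines(c(
    paste0("category\t", model@category),
    paste0("alpha\t", sprintf("%.17g", model@alpha)),
    paste0("iterations\t", model@iterationsRun),
    paste0("best_validation_auc\t",
           sprintf("%.17g", model@bestValidationAUC)),
    paste0("trained\t", as.integer(model@trained)),
    paste0("d\t", d),
    paste(model@trainingGenes, collapse = "\t")), con)
  writeLines(apply(model@W, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname writeSimilarityModel
#' @return \code{readSimilarityModel}: the restored
#'   \linkS4class{SimilarityModel}.
#' @export
readSimilarityModel <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\t", fixed = TRUE)
  stopifnot(hdr[[6]][1] == "d")
  d <- as.integer(hdr[[6]][2])
  tg <- strsplit(lines[7], "\t", fixed = TRUE)[[1]]
  stopifnot(length(tg) == d, length(lines) == 7L + d)
  W <- do.call(rbind, lapply(lines[7L + seq_len(d)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  new("SimilarityModel", W = W, trainingGenes = tg,
      category = hdr[[1]][2],
      alpha = as.numeric(hdr[[2]][2]),
      iterationsRun = as.integer(hdr[[3]][2]),
      bestValidationAUC = if (hdr[[4]][2] == "NA") NA_real_ else
        as.numeric(hdr[[4]][2]),
      trained = hdr[[5]][2] == "1")
}
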