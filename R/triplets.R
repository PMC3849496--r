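#' Sampling configuration for training triplets
#'
#' Three strategies for drawing the negative gene g- of a triplet
#' (g, g+, g-): \code{uniform} treats all eligible negatives equally;
#' \code{favor_dissimilar} draws a negative with probability (1 - r)/z,
#' preferring genes semantically far from the anchor; and
#' \code{favor_borderline} draws with probability r/z, preferring
#' negatives whose similarity to the anchor sits near the eligibility
#' threshold. r is the best-match-average semantic similarity and z the
#' normalising sum.
#'
#' @param strategy one of "favor_borderline", "uniform",
#'   "favor_dissimilar".
#' @param threshold negative-eligibility similarity threshold in (0, 1);
#'   default 0.4 (genes with r below it count as not functionally
#'   related).
#' @param maxRedraws bounded number of anchor redraws when a drawn
#'   anchor has no eligible negative.
#' @param seed optional integer seed applied by \code{sampleTriplets}.
#' @return a list of class "samplingConfig".
#' @export
samplingConfig <- function(strategy = c("favor_borderline", "uniform",
                                        "favor_dissimilar"),
                           threshold = 0.4, maxRedraws = 50L,
                           seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(threshold > 0, threshold < 1, maxRedraws >= 1)
  structure(list(strategy = strategy, threshold = threshold,
                 maxRedraws = as.integer(maxRedraws), seed = seed),
            class = "samplingConfig")
}

.categoryTooSmall <- function(msg) {
  stop(structure(class = c("categoryTooSmall", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Eligible negative genes for a category and anchor
#'
#' A gene is an eligible negative for anchor g under category C when it
#' (i) is annotated neither with C nor with any descendant term of C,
#' and (ii) has semantic similarity r(g, .) below the threshold.
#'
#' @param category term identifier of the category C.
#' @param g anchor gene.
#' @param annot closed \linkS4class{AnnotationSet}.
#' @param dag \linkS4class{OntologyDAG}.
#' @param pairSim symmetric gene-pair similarity matrix (from
#'   \code{\link{geneSimilarityMatrix}}), rows/cols named by gene.
#' @param threshold eligibility threshold on r (default 0.4).
#' @param candidates genes to consider; defaults to the rows of
#'   \code{pairSim}.
#' @return character vector of eligible negative genes.
#' @export
eligibleNegatives <- function(category, g, annot, dag, pairSim,
                              threshold = 0.4, candidates = NULL) {
  .checkTerms(dag, category)
  if (!annot@closed) stop("annotations must be closed")
  if (is.null(candidates)) candidates <- rownames(pairSim)
  desc <- termDescendants(dag, category, include.self = TRUE)
  lacksC <- vapply(annot@assignments[candidates], function(ts)
    !any(ts %in% desc), logical(1))
  lacksC[is.na(lacksC)] <- TRUE  # unannotated candidates lack C trivially
  pool <- candidates[lacksC]
  pool <- pool[pool != g]
  pool[pairSim[g, pool] < threshold]
}

#' Build a triplet sampler for one category
#'
#' Precomputes the positive set and, lazily per anchor, the eligible
#' negatives with their strategy weights, then returns a function that
#' draws triplets. The anchor g and positive partner g+ are drawn
#' uniformly without replacement from the category's positives; g- is
#' drawn from the anchor's eligible negatives with the configured
#' weights. Raises a "categoryTooSmall" condition when fewer than two
#' positives exist or no anchor with eligible negatives can be found
#' within the redraw bound.
#'
#' @inheritParams eligibleNegatives
#' @param config a \code{\link{samplingConfig}}.
#' @param candidates training genes the triplets may use (anchors,
#'   positives and negatives all come from here).
#' @return a function(n) returning a data.frame with columns g, g_plus,
#'   g_minus.
#' @export
newTripletSampler <- function(category, annot, dag, pairSim, config,
                              candidates = NULL) {
  if (is.null(candidates)) candidates <- rownames(pairSim)
  desc <- termDescendants(dag, category, include.self = TRUE)
  hasC <- vapply(annot@assignments[candidates], function(ts)
    !is.null(ts) && category %in% ts, logical(1))
  positives <- candidates[hasC]
  if (length(positives) < 2L)
    .categoryTooSmall(paste0("category ", category, " has ",
                             length(positives), " positive(s); need >= 2"))
  negCache <- new.env(parent = emptyenv())
  anchorState <- function(g) {
    if (!is.null(negCache[[g]])) return(negCache[[g]])
    negs <- eligibleNegatives(category, g, annot, dag, pairSim,
                              config$threshold, candidates)
    r <- pairSim[g, negs]
    wt <- switch(config$strategy,
                 uniform          = rep(1, length(negs)),
                 favor_dissimilar = 1 - r,
                 favor_borderline = r)
    ok <- length(negs) > 0L && sum(wt) > 0
    st <- list(negs = negs, wt = wt, ok = ok)
    negCache[[g]] <- st
    st
  }
  function(n = 1L) {
    g <- g_plus <- g_minus <- character(n)
    for (t in seq_len(n)) {
      st <- NULL
      for (attempt in seq_len(config$maxRedraws)) {
        pair <- positives[sample.int(length(positives), 2L)]
        st <- anchorState(pair[1])
        if (st$ok) break
        st <- NULL
      }
      if (is.null(st))
        .categoryTooSmall(paste0("no eligible negatives found for ",
                                 "category ", category, " within ",
                                 config$maxRedraws, " anchor redraws"))
      g[t] <- pair[1]
      g_plus[t] <- pair[2]
      g_minus[t] <- if (length(st$negs) == 1L) st$negs else
        st$negs[sample.int(length(st$negs), 1L, prob = st$wt)]
    }
    data.frame(g = g, g_plus = g_plus, g_minus = g_minus,
               category = category)
  }
}

#' Draw training triplets for a category
#'
#' Convenience wrapper over \code{\link{newTripletSampler}}. With a seed
#' in the config the stream is reproducible.
#'
#' @inheritParams newTripletSampler
#' @param n number of triplets to draw.
#' @return data.frame with columns g, g_plus, g_minus, category.
#' @export
sampleTriplets <- function(category, annot, dag, pairSim, config,
                           n = 1L, candidates = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sampler <- newTripletSampler(category, annot, dag, pairSim, config,
                               candidates)
  sampler(n)
}
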