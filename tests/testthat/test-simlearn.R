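newModel <- function(W, geneIds = paste0("g", seq_len(nrow(W))),
                     category = "C") {
  new("SimilarityModel", W = W, trainingGenes = geneIds,
      category = category)
}

test_that("bilinear score with identity W is the plain dot product", {
  d <- 6
  m <- newModel(diag(d))
  ea <- replace(numeric(d), 2, 1)
  eb <- replace(numeric(d), 5, 1)
  expect_identical(bilinearScore(m, ea, ea), 1)
  expect_identical(bilinearScore(m, ea, eb), 0)
  set.seed(1)
  u <- rnorm(d); v <- rnorm(d)
  expect_equal(bilinearScore(m, u, v), sum(u * v))
})

test_that("sparse bilinear score equals the dense oracle", {
  set.seed(10)
  for (rep in 1:20) {
    d <- 50
    W <- matrix(rnorm(d * d), d, d)
    u <- rnorm(d); v <- rnorm(d)
    u[sample(d, 35)] <- 0
    v[sample(d, 35)] <- 0
    dense <- drop(t(u) %*% W %*% v)
    expect_equal(bilinearScore(newModel(W), u, v), dense,
                 tolerance = 1e-12)
  }
  expect_error(bilinearScore(newModel(diag(3)), rnorm(4), rnorm(3)),
               "dimension")
})

test_that("hinge loss follows max(1 - S+ + S-, 0)", {
  d <- 4
  set.seed(2)
  W <- matrix(rnorm(16), 4, 4)
  m <- newModel(W)
  g <- runif(d); gp <- runif(d); gm <- runif(d)
  dense <- max(1 - drop(t(g) %*% W %*% gp) + drop(t(g) %*% W %*% gm), 0)
  expect_equal(hingeLoss(m, g, gp, gm), dense)

  # margin exactly 1 -> loss 0; equal scores -> loss 1
  mI <- newModel(diag(2))
  expect_identical(hingeLoss(mI, c(1, 0), c(1, 0), c(0, 0)), 0)
  expect_identical(hingeLoss(mI, c(1, 0), c(0, 1), c(0, 1)), 1)
})

test_that("the PA update is passive on zero-loss triplets", {
  set.seed(3)
  d <- 5
  m <- newModel(diag(d))
  g <- replace(numeric(d), 1, 1)
  gp <- replace(numeric(d), 1, 2)   # S+ = 2, S- = 0, margin 2 > 1
  gm <- replace(numeric(d), 3, 1)
  expect_identical(hingeLoss(m, g, gp, gm), 0)
  m2 <- paUpdate(m, g, gp, gm)
  expect_identical(modelMatrix(m2), modelMatrix(m))  # bit-identical W
})

test_that("an unclamped PA update zeroes the triplet's hinge loss", {
  set.seed(4)
  for (rep in 1:25) {
    d <- 12
    m <- newModel(diag(d), category = "C")
    g <- runif(d) * rbinom(d, 1, 0.5)
    gp <- runif(d) * rbinom(d, 1, 0.5)
    gm <- runif(d) * rbinom(d, 1, 0.5)
    if (sum(g) == 0 || all(gp == gm)) next
    loss <- hingeLoss(m, g, gp, gm)
    if (loss == 0) next
    vnorm2 <- sum(g^2) * sum((gp - gm)^2)
    alphaBig <- loss / vnorm2 + 1    # guarantee tau is unclamped
    m2 <- paUpdate(m, g, gp, gm, alpha = alphaBig)
    expect_lt(hingeLoss(m2, g, gp, gm), 1e-9)
    # post-update margin is exactly 1
    expect_equal(bilinearScore(m2, g, gp) - bilinearScore(m2, g, gm),
                 1, tolerance = 1e-9)
  }
})

test_that("a clamped PA update takes tau = alpha and leaves residual loss", {
  d <- 6
  set.seed(5)
  g <- runif(d); gp <- runif(d); gm <- runif(d)
  m <- newModel(diag(d))
  loss <- hingeLoss(m, g, gp, gm)
  skip_if(loss == 0, "fixture produced a satisfied triplet")
  vnorm2 <- sum(g^2) * sum((gp - gm)^2)
  alpha <- 0.5 * loss / vnorm2      # forces the clamp
  m2 <- paUpdate(m, g, gp, gm, alpha = alpha)
  expect_equal(modelMatrix(m2),
               modelMatrix(m) + alpha * outer(g, gp - gm),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(hingeLoss(m2, g, gp, gm), loss - alpha * vnorm2,
               tolerance = 1e-9)
})

test_that("degenerate triplets (||V|| = 0) skip the update with a warning", {
  d <- 4
  m <- newModel(diag(d))
  gp <- c(1, 0, 0, 0); gm <- c(0, 1, 0, 0)
  expect_warning(m2 <- paUpdate(m, numeric(d), gp, gm), "degenerate")
  expect_identical(modelMatrix(m2), modelMatrix(m))
  expect_warning(m3 <- paUpdate(m, c(1, 0, 0, 0), gp, gp), "degenerate")
  expect_identical(modelMatrix(m3), modelMatrix(m))
})

trainFixture <- function(nGenes = 80, signal = 3, seed = 21) {
  bench <- generateBenchmark(nGenes = nGenes, nTerms = 10,
                             nSources = 3, signal = signal,
                             truthFraction = 0, seed = seed)
  net <- benchmarkNetwork(bench, k = 15)
  ann <- bench@annotations
  dag <- bench@dag
  ic <- informationContent(ann, dag)
  annGenes <- intersect(genes(net), genes(ann))
  pairSim <- geneSimilarityMatrix(annGenes, ann, ic, dag)
  fmapAll <- featureMap(net, annGenes)
  fmap <- new("FeatureMap", trainingGenes = annGenes,
              phi = featureVectors(fmapAll)[annGenes, , drop = FALSE])
  counts <- table(unlist(annotations(ann)[annGenes]))
  negs <- vapply(names(counts), function(tm)
    sum(!vapply(annotations(ann)[annGenes], function(x) tm %in% x,
                logical(1))), integer(1))
  usable <- names(counts)[counts >= 8 & negs >= 8 &
                            names(counts) != ontologyRoot(dag)]
  list(bench = bench, net = net, ann = ann, dag = dag,
       pairSim = pairSim, fmap = fmap, term = usable[1],
       annGenes = annGenes)
}

test_that("training returns an untrained identity model when impossible", {
  # a category with a single positive cannot form triplets
  dag <- diamondDAG()
  ann <- upPropagate(annotationSet(list(
    p1 = "L", n1 = "A", n2 = "A", n3 = "B", n4 = "root")), dag)
  ic <- informationContent(ann, dag)
  ps <- geneSimilarityMatrix(genes(ann), ann, ic, dag)
  set.seed(12)
  net <- randomNetwork(5)
  dimnames(net@adj) <- list(genes(ann), genes(ann))
  net@genes <- genes(ann)
  fmap <- featureMap(net, genes(ann))
  m <- trainCategory(fmap, ann, dag, ps, "L",
                     valGenes = character(0),
                     config = trainConfig(checkInterval = 50,
                                          maxIterations = 100, k = 5))
  expect_false(m@trained)
  expect_identical(modelMatrix(m), diag(5))
  expect_identical(m@iterationsRun, 0L)

  fx <- trainFixture()
  d <- length(fx$annGenes)

  # maxIterations = 0 returns the identity initialisation untouched
  m0 <- trainCategory(fx$fmap, fx$ann, fx$dag, fx$pairSim, fx$term,
                      valGenes = character(0),
                      config = trainConfig(checkInterval = 50,
                                           maxIterations = 0, k = 15))
  expect_identical(modelMatrix(m0), diag(d))
})

test_that("training is deterministic given a seed and can beat identity", {
  fx <- trainFixture()
  pos <- fx$annGenes[vapply(annotations(fx$ann)[fx$annGenes],
                            function(x) fx$term %in% x, logical(1))]
  neg <- setdiff(fx$annGenes, pos)
  set.seed(33)
  valGenes <- c(sample(pos, max(1, floor(length(pos) * 0.25))),
                sample(neg, floor(length(neg) * 0.25)))
  cfg <- trainConfig(checkInterval = 300, maxIterations = 1500,
                     k = 15, seed = 55)
  m1 <- trainCategory(fx$fmap, fx$ann, fx$dag, fx$pairSim, fx$term,
                      valGenes, config = cfg)
  m2 <- trainCategory(fx$fmap, fx$ann, fx$dag, fx$pairSim, fx$term,
                      valGenes, config = cfg)
  expect_identical(modelMatrix(m1), modelMatrix(m2))
  expect_identical(m1@iterationsRun, m2@iterationsRun)
  expect_identical(m1@bestValidationAUC, m2@bestValidationAUC)
  # the selected W never validates worse than the identity baseline
  d <- length(fx$annGenes)
  idAUC <- local({
    netI <- reconstructNetwork(diag(d),
                               featureMap(fx$net, fx$annGenes), k = 15)
    y <- buildLabelVector(fx$term, fx$ann, fx$dag, genes(netI),
                          labelGenes = setdiff(fx$annGenes, valGenes))
    res <- propagateLabels(netI, y, sigma = 1)
    similearn:::.testAUC(res, fx$term, fx$ann, fx$dag, valGenes)
  })
  expect_gte(m1@bestValidationAUC, idAUC)
})

test_that("similarity models round-trip losslessly through disk", {
  set.seed(8)
  d <- 7
  W <- matrix(rnorm(d * d), d, d)
  m <- new("SimilarityModel", W = W,
           trainingGenes = paste0("gene", 1:d), category = "T0005",
           alpha = 0.1, iterationsRun = 1234L,
           bestValidationAUC = 0.87654321, trained = TRUE)
  path <- withr::local_tempfile(fileext = ".model")
  writeSimilarityModel(m, path)
  back <- readSimilarityModel(path)
  expect_identical(modelMatrix(back), modelMatrix(m))
  expect_identical(trainingGenes(back), trainingGenes(m))
  expect_identical(back@category, m@category)
  expect_identical(back@iterationsRun, m@iterationsRun)
  expect_identical(back@bestValidationAUC, m@bestValidationAUC)
  expect_identical(back@trained, m@trained)
})
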