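test_that("positive-PCC network matches a direct correlation oracle", {
  set.seed(42)
  X <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("f", 1:6)))
  X["g2", ] <- X["g1", ]          # identical rows
  X["g3", ] <- -X["g1", ]         # perfectly anti-correlated
  net <- pccNetwork(X)
  A <- as.matrix(adjacency(net))
  expect_equal(A["g1", "g2"], 1)
  expect_identical(A["g1", "g3"], 0)  # negative PCC clamped to zero
  oracle <- cor(t(X)); oracle[oracle < 0] <- 0; diag(oracle) <- 0
  expect_equal(A, oracle, ignore_attr = TRUE)
  expect_true(all(A >= 0 & A <= 1))
  expect_identical(diag(A), setNames(rep(0, 4), rownames(X)))
})

test_that("constant gene rows get zero edges with a warning", {
  X <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  X[2, ] <- 7
  expect_warning(net <- pccNetwork(X), "constant")
  expect_true(all(adjacency(net)[2, ] == 0))
})

test_that("binary networks collapse duplicates and drop self-loops", {
  expect_equal(length(genes(binaryNetwork(
    data.frame(a = character(0), b = character(0))))), 0L)

  edges <- data.frame(a = c("x", "y", "x"), b = c("y", "x", "y"))
  net <- binaryNetwork(edges)
  expect_equal(Matrix::nnzero(adjacency(net)), 2)  # one undirected edge
  expect_equal(adjacency(net)["x", "y"], 1)

  expect_warning(net2 <- binaryNetwork(data.frame(a = c("x", "z"),
                                                  b = c("x", "y"),
                                                  w = 1)),
                 "self-loop")
  expect_equal(adjacency(net2)["z", "y"], 1)
  expect_true(all(diag(adjacency(net2)) == 0))

  # 5-edge toy list against a hand-built adjacency
  el <- data.frame(a = c("a", "a", "b", "c", "d"),
                   b = c("b", "c", "c", "d", "e"))
  H <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  H["a", "b"] <- H["a", "c"] <- H["b", "c"] <- H["c", "d"] <-
    H["d", "e"] <- 1
  H <- pmax(H, t(H))
  expect_equal(as.matrix(adjacency(binaryNetwork(el))), H,
               ignore_attr = TRUE)
})

test_that("equal-weight integration sums adjacencies over the gene union", {
  set.seed(7)
  n1 <- randomNetwork(6)
  expect_equal(as.matrix(adjacency(integrateEqual(list(n1)))),
               as.matrix(adjacency(n1)), ignore_attr = TRUE)

  # dense-addition oracle over three overlapping toy networks
  nets <- lapply(1:3, function(i) randomNetwork(6))
  combined <- integrateEqual(nets)
  dense <- Reduce(`+`, lapply(nets, function(x) as.matrix(adjacency(x))))
  expect_equal(as.matrix(adjacency(combined)), dense,
               ignore_attr = TRUE)
  expect_true(min(adjacency(combined)) >= 0)
  expect_error(integrateEqual(list()), "no networks")
})

test_that("integration aligns differing gene universes by identifier", {
  a <- weightedNetwork(matrix(c(0, 1, 1, 0), 2, 2,
                              dimnames = list(c("g1", "g2"),
                                              c("g1", "g2"))))
  b <- weightedNetwork(matrix(c(0, 2, 2, 0), 2, 2,
                              dimnames = list(c("g2", "g3"),
                                              c("g2", "g3"))))
  comb <- integrateEqual(list(a, b))
  expect_setequal(genes(comb), c("g1", "g2", "g3"))
  A <- as.matrix(adjacency(comb))
  expect_equal(A["g1", "g2"], 1)
  expect_equal(A["g2", "g3"], 2)
  expect_equal(A["g1", "g3"], 0)
})

test_that("top-k sparsification keeps the union of per-node top-k", {
  # a node of degree <= k keeps all its edges: star with 10 leaves, k=3
  star <- data.frame(a = rep("hub", 10), b = paste0("leaf", 1:10))
  net <- binaryNetwork(star)
  kept <- sparsifyTopK(net, 3)
  expect_equal(Matrix::nnzero(adjacency(kept)) / 2, 10)

  # brute-force union-of-top-k oracle on random graphs
  bruteTopK <- function(A, genes, k) {
    keep <- matrix(FALSE, nrow(A), ncol(A))
    for (i in seq_len(nrow(A))) {
      nz <- which(A[i, ] > 0)
      ord <- nz[order(-A[i, nz], genes[nz])]
      keep[i, head(ord, k)] <- TRUE
    }
    out <- A * (keep | t(keep))
    out
  }
  set.seed(11)
  for (rep in 1:5) {
    net <- randomNetwork(20, density = 0.6)
    k <- 5
    got <- as.matrix(adjacency(sparsifyTopK(net, k)))
    want <- bruteTopK(as.matrix(adjacency(net)), genes(net), k)
    expect_equal(got, want, ignore_attr = TRUE)
    # every node with input degree >= k retains >= k incident edges
    degIn <- colSums(as.matrix(adjacency(net)) > 0)
    degOut <- colSums(got > 0)
    expect_true(all(degOut[degIn >= k] >= k))
  }
})

test_that("sparsification is idempotent at fixed k and monotone in k", {
  set.seed(3)
  net <- randomNetwork(15, density = 0.7)
  s5 <- sparsifyTopK(net, 5)
  expect_equal(as.matrix(adjacency(sparsifyTopK(s5, 5))),
               as.matrix(adjacency(s5)), ignore_attr = TRUE)
  s8 <- sparsifyTopK(net, 8)
  kept5 <- as.matrix(adjacency(s5)) > 0
  kept8 <- as.matrix(adjacency(s8)) > 0
  expect_true(all(kept8[kept5]))
})

test_that("feature map restricts adjacency rows to training columns", {
  set.seed(9)
  net <- randomNetwork(6)
  train <- genes(net)[c(2, 4, 5, 6)]
  fm <- featureMap(net, train)
  expect_identical(trainingGenes(fm), train)
  dense <- as.matrix(adjacency(net))[, train]
  expect_equal(as.matrix(featureVectors(fm)), dense,
               ignore_attr = TRUE)
  # a training gene's own coordinate is zero
  for (tg in train)
    expect_identical(as.numeric(featureVectors(fm)[tg, tg]), 0)
  expect_error(featureMap(net, c(train, train[1])), "duplicate")
  expect_error(featureMap(net, "absent"), "absent")
})

test_that("an isolated gene has an all-zero feature vector", {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                       c("a", "b", "c")))
  A["a", "b"] <- A["b", "a"] <- 0.7
  net <- weightedNetwork(A)
  fm <- featureMap(net, c("a", "b"))
  expect_identical(as.numeric(featureVectors(fm)["c", ]), c(0, 0))
  expect_identical(as.numeric(featureVectors(fm)["a", ]), c(0, 0.7))
})

test_that("edge-list and data-matrix TSVs round-trip losslessly", {
  set.seed(21)
  net <- randomNetwork(8)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeListTSV(net, path)
  back <- readEdgeListTSV(path, geneIds = genes(net))
  expect_equal(as.matrix(adjacency(back)), as.matrix(adjacency(net)),
               ignore_attr = TRUE)

  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("f", 1:4)))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  writeDataMatrixTSV(X, mpath)
  expect_equal(readDataMatrixTSV(mpath), X)
})
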