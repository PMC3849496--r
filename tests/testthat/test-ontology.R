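test_that("up-propagation closes annotations over ancestors", {
  dag <- ontologyDAG(data.frame(child  = c("A", "L"),
                                parent = c("root", "A")))
  ann <- upPropagate(annotationSet(list(g1 = "L")), dag)
  expect_setequal(annotations(ann)$g1, c("L", "A", "root"))
  expect_true(isClosed(ann))
})

test_that("up-propagation is idempotent and only adds annotations", {
  dag <- diamondDAG()
  raw <- annotationSet(list(g1 = c("C"), g2 = c("A", "B"), g3 = "root"))
  once <- upPropagate(raw, dag)
  twice <- upPropagate(once, dag)
  expect_identical(annotations(once), annotations(twice))
  for (g in genes(raw))
    expect_true(all(annotations(raw)[[g]] %in% annotations(once)[[g]]))
})

test_that("diamond closure matches brute-force ancestor enumeration", {
  dag <- diamondDAG()
  ann <- upPropagate(annotationSet(list(g = "L")), dag)
  expect_identical(sort(annotations(ann)$g), bruteAncestors(dag, "L"))
  expect_length(annotations(ann)$g, 5L)
})

test_that("up-propagation rejects unknown terms by name", {
  dag <- diamondDAG()
  expect_error(upPropagate(annotationSet(list(g1 = "NOPE")), dag),
               "NOPE")
})

test_that("DAG construction rejects cycles and multiple roots", {
  expect_error(ontologyDAG(data.frame(child = c("A", "B"),
                                      parent = c("B", "A"))),
               "root")
  expect_error(ontologyDAG(list(root = character(0),
                                A = "B", B = "A")),
               "cycle")
  expect_error(ontologyDAG(data.frame(child = c("A", "B"),
                                      parent = c("r1", "r2"))),
               "exactly one root")
})

test_that("information content matches hand counts on the toy corpus", {
  dag <- diamondDAG()
  ann <- diamondAnnotations(dag)
  ic <- informationContent(ann, dag)
  v <- icValues(ic)
  expect_identical(unname(v["root"]), 0)           # P(root) = 1
  expect_equal(unname(v["A"]), log(2))             # 4 of 8 genes
  expect_equal(unname(v["C"]), log(4))             # 2 of 8 genes
  expect_equal(unname(v["L"]), log(8))             # 1 of 8 genes
  expect_equal(maxIC(ic), log(8))
})

test_that("IC is monotone non-decreasing along parent links", {
  for (seed in 1:5) {
    dag <- generateOntology(15, seed = seed)
    ann <- generateAnnotations(dag, 40, truthFraction = 0,
                               seed = seed)$annotations
    ic <- icValues(informationContent(ann, dag))
    for (tm in names(ic))
      for (p in dag@parents[[tm]])
        if (p %in% names(ic))
          expect_gte(ic[[tm]], ic[[p]])
  }
})

test_that("IC requires a closed, non-empty corpus", {
  dag <- diamondDAG()
  expect_error(informationContent(annotationSet(list(g1 = "A")), dag),
               "closed")
  expect_error(
    informationContent(annotationSet(list(), closed = TRUE), dag),
    "empty")
})

test_that("zero-annotation terms are absent from the IC table", {
  dag <- diamondDAG()
  ann <- upPropagate(annotationSet(list(g1 = "A", g2 = "root")), dag)
  ic <- informationContent(ann, dag)
  expect_false("L" %in% names(icValues(ic)))
  expect_false(any(is.infinite(icValues(ic))))
})

test_that("Resnik similarity is the normalised MICA information content", {
  dag <- diamondDAG()
  ann <- diamondAnnotations(dag)
  ic <- informationContent(ann, dag)
  # a term is its own MICA
  expect_equal(resnikSimilarity("C", "C", ic, dag),
               icValues(ic)[["C"]] / maxIC(ic))
  # terms meeting only at root score zero
  expect_identical(resnikSimilarity("A", "B", ic, dag), 0)
  # diamond: common ancestors of C and L include A, B, C; brute-force max
  common <- intersect(bruteAncestors(dag, "C"), bruteAncestors(dag, "L"))
  expect_equal(resnikSimilarity("C", "L", ic, dag),
               max(icValues(ic)[common]) / maxIC(ic))
})

test_that("best-match-average gene similarity matches an all-pairs oracle", {
  dag <- diamondDAG()
  ann <- diamondAnnotations(dag)
  ic <- informationContent(ann, dag)

  # identical single-term annotation: the self-match score
  single <- annotationSet(list(gx = "C", gy = "C"))
  expect_equal(geneSimilarityBMA("gx", "gy", single, ic, dag),
               resnikSimilarity("C", "C", ic, dag))
  # disjoint terms meeting only at root
  expect_identical(geneSimilarityBMA("g3", "g5", ann, ic, dag), 0)

  # all-pairs brute force on genes with 5 and 4 closed terms
  bmaOracle <- function(ta, tb) {
    S <- outer(ta, tb, Vectorize(function(x, y)
      resnikSimilarity(x, y, ic, dag)))
    (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) /
      (length(ta) + length(tb))
  }
  got <- geneSimilarityBMA("g1", "g2", ann, ic, dag)
  expect_equal(got, bmaOracle(annotations(ann)$g1, annotations(ann)$g2))
  expect_error(geneSimilarityBMA("g1", "gX", ann, ic, dag), "gX")
})

test_that("Resnik and BMA are symmetric and bounded on random DAGs", {
  for (seed in 1:5) {
    dag <- generateOntology(12, seed = seed)
    ann <- generateAnnotations(dag, 25, truthFraction = 0,
                               seed = seed)$annotations
    ic <- informationContent(ann, dag)
    ts <- names(icValues(ic))
    S <- termSimilarityMatrix(ts, ic, dag)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(S, t(S))
    R <- geneSimilarityMatrix(genes(ann), ann, ic, dag)
    expect_true(all(R >= 0 & R <= 1))
    expect_equal(R, t(R))
    # the matrix agrees with the pairwise entry point
    g <- genes(ann)[1:2]
    expect_equal(R[g[1], g[2]],
                 geneSimilarityBMA(g[1], g[2], ann, ic, dag))
  }
})

test_that("OBO and GAF readers round-trip the synthetic writers", {
  bench <- generateBenchmark(nGenes = 25, nTerms = 8, nSources = 2,
                             seed = 5)
  dir <- withr::local_tempdir()
  writeBenchmark(bench, dir)

  dag2 <- readOBO(file.path(dir, "ontology.obo"))
  expect_setequal(ontologyTerms(dag2), ontologyTerms(bench@dag))
  expect_identical(ontologyRoot(dag2), ontologyRoot(bench@dag))

  dag3 <- readOntologyTSV(file.path(dir, "ontology.tsv"))
  for (tm in ontologyTerms(bench@dag))
    expect_setequal(termAncestors(dag3, tm),
                    termAncestors(bench@dag, tm))

  ann2 <- readGAF(file.path(dir, "annotations.gaf"), closed = TRUE)
  expect_identical(annotations(ann2)[genes(bench@annotations)],
                   annotations(bench@annotations))
  ann3 <- readAnnotationsTSV(file.path(dir, "annotations.tsv"),
                             closed = TRUE)
  expect_identical(annotations(ann3)[genes(bench@annotations)],
                   annotations(bench@annotations))
})

test_that("GAF reader drops NOT-qualified rows", {
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "geneA", "geneA", "", "T1", "REF", "IEA",
                     "", "P", "", "", "gene", "taxon:0", "20260101",
                     "x", sep = "\t"),
               paste("DB", "geneB", "geneB", "NOT", "T1", "REF", "IEA",
                     "", "P", "", "", "gene", "taxon:0", "20260101",
                     "x", sep = "\t")), path)
  ann <- readGAF(path)
  expect_identical(genes(ann), "geneA")
})
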