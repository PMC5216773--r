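makeDag <- function(id, nodes) {
  new("DiseaseDAG", diseaseId = id, nodes = unique(c(id, nodes)),
      edges = matrix(character(0), ncol = 2,
                     dimnames = list(NULL, c("parent", "child"))))
}

test_that("information content counts DAG occurrences on a log scale", {
  dags <- c(
    lapply(1:8, function(i) makeDag(paste0("d", i),
                                    c("shared", paste0("own", i)))),
    list())
  dags <- dags[1:8]
  # make 'rare' occur in exactly 2 of 8 DAGs
  dags[[1]]@nodes <- c(dags[[1]]@nodes, "rare")
  dags[[2]]@nodes <- c(dags[[2]]@nodes, "rare")
  ict <- computeIC(dags)
  expect_equal(ict$tnDag, 8)
  expect_equal(unname(ict$ic[["shared"]]), 0)
  expect_equal(unname(ict$ic[["rare"]]), -log(0.25), tolerance = 1e-12)
  expect_equal(unname(ict$ic[["own3"]]), log(8), tolerance = 1e-12)

  # two DAGs sharing no terms: every term in exactly one DAG
  ict2 <- computeIC(list(makeDag("a", c("x", "y")),
                         makeDag("b", c("z"))))
  expect_true(all(abs(ict2$ic - log(2)) < 1e-12))
  expect_error(computeIC(list()), "empty")
})

test_that("fuzzy densities are capped normalized ICs with zeros pruned", {
  dags <- list(makeDag("a", c("u", "rare")),
               makeDag("b", c("u", "mid")),
               makeDag("c", c("u", "mid")),
               makeDag("d", c("u", "mid")))
  ict <- computeIC(dags)
  fda <- computeFuzzyDensity(ict, dags[[1]], cap = 0.999)
  # rarest term gets exactly the cap; universal term is pruned
  expect_equal(unname(densities(fda)[["rare"]]), 0.999)
  expect_false("u" %in% names(densities(fda)))

  # a term with half the maximum IC scales as cap * ratio
  dags3 <- list(makeDag("a", c("q1")), makeDag("b", c("q2")),
                makeDag("c", c("q3", "h")), makeDag("d", c("q4", "h")))
  ict3 <- computeIC(dags3)
  fdc <- computeFuzzyDensity(ict3, dags3[[3]], cap = 0.999)
  expect_equal(unname(densities(fdc)[["h"]]),
               0.999 * log(2) / log(4), tolerance = 1e-12)
  # a cap of exactly 1 would give the disease's own (rarest) term density
  # 1, which the density contract rejects
  expect_error(computeFuzzyDensity(ict3, dags3[[3]], cap = 1),
               "strictly in")

  # single-disease corpus: every term universal, normalization impossible
  ict1 <- computeIC(list(makeDag("solo", c("t1", "t2"))))
  expect_error(computeFuzzyDensity(ict1, makeDag("solo", c("t1", "t2"))),
               "universal")
})

test_that("the Sugeno lambda equation is solved with the analytic roots", {
  expect_equal(solveLambda(c(0.3, 0.4)), 2.5, tolerance = 1e-10)
  expect_equal(solveLambda(c(0.6, 0.8)), -5 / 6, tolerance = 1e-10)
  expect_identical(solveLambda(c(0.5, 0.5)), 0)
  expect_identical(solveLambda(0.7), 0)
  expect_error(solveLambda(c(0.5, 1.2)), "strictly in")
  expect_error(solveLambda(numeric(0)), "empty")
})

test_that("solved lambdas satisfy the normalization identity with the right sign", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      n <- sample(2:30, 1)
      g <- runif(n, 1e-6, 0.999)
      lam <- solveLambda(g)
      expect_lt(abs(prod(1 + lam * g) - (1 + lam)), 1e-10)
      if (abs(sum(g) - 1) > 1e-9)
        expect_identical(sign(lam), sign(1 - sum(g)))
    }
  })
})

test_that("the recursive Sugeno measure matches the product closed form", {
  expect_equal(sugenoMeasure(0.3, 2.5), 0.3)
  expect_equal(sugenoMeasure(c(0.3, 0.4), 2.5), 1.0, tolerance = 1e-12)
  expect_equal(sugenoMeasure(c(0.3, 0.4), 0), 0.7)
  expect_identical(sugenoMeasure(numeric(0), 1), 0)
  expect_error(sugenoMeasure(c(0.3), -1), "lambda")

  withr::with_seed(11, {
    for (rep in 1:100) {
      full <- runif(sample(2:12, 1), 0.01, 0.95)
      lam <- solveLambda(full)
      g <- full[sample(seq_along(full), sample(seq_along(full), 1))]
      m <- sugenoMeasure(g, lam)
      expect_lt(abs(m - sugenoClosedForm(g, lam)), 1e-10)
      expect_lt(abs(sugenoMeasure(sample(g), lam) - m), 1e-10)
    }
  })
})

test_that("the full density set has measure one under its own lambda", {
  withr::with_seed(3, {
    for (rep in 1:50) {
      g <- runif(sample(2:20, 1), 0.01, 0.999)
      lam <- solveLambda(g)
      expect_equal(sugenoMeasure(g, lam), 1, tolerance = 1e-8)
    }
  })
})

test_that("the Sugeno measure is monotone under subset growth", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      g <- runif(sample(3:15, 1), 0.01, 0.98)
      lam <- solveLambda(g)
      k <- sample(seq_along(g), 1)
      a <- g[sample(seq_along(g), k)]
      expect_lte(sugenoMeasure(a, lam),
                 sugenoMeasure(g, lam) + 1e-12)
    }
  })
})

densSet <- function(id, d) {
  solveDensitySet(new("FuzzyDensitySet", diseaseId = id,
                      densities = d, lambda = NA_real_))
}

test_that("disease semantic similarity averages the two Sugeno measures", {
  a <- densSet("a", c(t1 = 0.3, t2 = 0.4))
  b <- densSet("b", c(t1 = 0.3, t3 = 0.6, t4 = 0.8))
  # shared set {t1}: singleton measure is its density under any lambda
  expect_equal(diseaseSemanticSimilarity(a, b), 0.3, tolerance = 1e-12)
  # identical sets: full-set measure 1 under both lambdas
  expect_equal(diseaseSemanticSimilarity(a, a), 1, tolerance = 1e-8)
  # disjoint term sets
  c_ <- densSet("c", c(t9 = 0.5))
  expect_equal(diseaseSemanticSimilarity(a, c_), 0)
  unsolved <- new("FuzzyDensitySet", diseaseId = "u",
                  densities = c(t1 = 0.3), lambda = NA_real_)
  expect_error(diseaseSemanticSimilarity(a, unsolved), "solve lambda")
})

test_that("the disease similarity matrix matches pairwise calls", {
  one <- buildDiseaseSimilarityMatrix(list(densSet("only",
                                                   c(x = 0.4, y = 0.2))))
  expect_equal(unname(as.matrix(one)), matrix(1))

  sets <- list(densSet("a", c(t1 = 0.3, t2 = 0.4)),
               densSet("b", c(t1 = 0.3, t3 = 0.6)),
               densSet("c", c(t9 = 0.7)))
  m <- as.matrix(buildDiseaseSimilarityMatrix(sets))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(unname(m[i, j]),
                 min(1, diseaseSemanticSimilarity(sets[[i]], sets[[j]])),
                 tolerance = 1e-12)
  }
  expect_equal(unname(m[1, 3]), 0)  # disjoint DAGs
})

test_that("disease similarity is invariant to the IC log base", {
  cfg <- smallCorpusConfig(21)
  corpus <- generateCorpus(cfg)
  ids <- diseaseNames(corpus@association)
  fsE <- diseaseSimilarityFromMesh(corpus@descriptors, ids,
                                   logBase = exp(1))
  fs2 <- diseaseSimilarityFromMesh(corpus@descriptors, ids, logBase = 2)
  expect_equal(as.matrix(fsE), as.matrix(fs2), tolerance = 1e-8)
})
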