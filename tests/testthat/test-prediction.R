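test_that("Laplacian RLS reduces to the labels without edges or regularization", {
  y <- makeAssoc(matrix(c(1, 0, 0, 0, 1, 1), 2, byrow = TRUE))
  idSim <- diag(2)
  f <- laplacianRLSScore(idSim, y, eta = 5, axis = "lncrna")
  expect_equal(unname(f), unname(as.matrix(y)), tolerance = 1e-12)

  sim <- matrix(c(1, 0.5, 0.5, 1), 2)
  fSmall <- laplacianRLSScore(sim, y, eta = 1e-10, axis = "lncrna")
  expect_equal(unname(fSmall), unname(as.matrix(y)), tolerance = 1e-6)
  expect_error(laplacianRLSScore(sim, y, eta = 0), "positive")
})

test_that("Laplacian RLS matches an explicit matrix-inversion oracle", {
  sim <- matrix(c(1, 0.7, 0.2,
                  0.7, 1, 0.4,
                  0.2, 0.4, 1), 3, byrow = TRUE)
  y <- makeAssoc(matrix(c(1, 0, 0, 1, 1, 0), 3, byrow = TRUE))
  eta <- 1.3
  # oracle: build the normalized Laplacian by explicit loops and invert
  d <- rowSums(sim)
  l <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    l[i, j] <- (i == j) - sim[i, j] / sqrt(d[i] * d[j])
  }
  ref <- solve(diag(3) + eta * l) %*% as.matrix(y)
  f <- laplacianRLSScore(sim, y, eta = eta, axis = "lncrna")
  expect_equal(unname(f), unname(ref), tolerance = 1e-10)

  # disease space: same algebra on the transpose
  simD <- matrix(c(1, 0.3, 0.3, 1), 2)
  dD <- rowSums(simD)
  lD <- diag(2) - simD / sqrt(outer(dD, dD))
  refD <- t(solve(diag(2) + eta * lD) %*% t(as.matrix(y)))
  fD <- laplacianRLSScore(simD, y, eta = eta, axis = "disease")
  expect_equal(unname(fD), unname(refD), tolerance = 1e-10)
})

test_that("two-space score combination is the expected weighted mean", {
  a <- matrix(0.2, 2, 3); b <- matrix(0.6, 2, 3)
  expect_equal(combineSpaceScores(a, b, w = 1), a)
  expect_equal(combineSpaceScores(a, b, w = 0), b)
  expect_equal(combineSpaceScores(a, b, w = 0.5), matrix(0.4, 2, 3))
  expect_error(combineSpaceScores(a, matrix(0, 3, 2)), "shape")
})

test_that("candidate ranking excludes known pairs and sorts reproducibly", {
  v <- matrix(c(1, 0, 0, 0, 0,
                0, 1, 0, 0, 0), 5, 2)
  assoc <- makeAssoc(v)
  scores <- as.matrix(assoc) * 0
  scores[, 1] <- c(0, 0.9, 0.5, 0.9, 0.1)
  dimnames(scores) <- list(lncNames(assoc), diseaseNames(assoc))
  r <- rankCandidates("D01", scores, assoc, topN = 10)
  expect_equal(r$lncrna, c("L02", "L04", "L03", "L05"))  # tie L02/L04 by id
  expect_equal(r$rank, 1:4)
  r2 <- rankCandidates("D01", scores, assoc, topN = 2)
  expect_equal(nrow(r2), 2L)
  # all lncRNAs associated -> empty candidate list
  full <- makeAssoc(matrix(1, 2, 1))
  sc <- matrix(0, 2, 1, dimnames = list(lncNames(full), "D01"))
  expect_equal(nrow(rankCandidates("D01", sc, full)), 0L)
  expect_error(rankCandidates("nope", scores, assoc), "unknown disease")
})

test_that("trapezoidal ROC area equals the rank statistic and pROC agrees", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      pos <- sample(round(runif(30), 2))  # coarse grid forces ties
      neg <- round(runif(100), 2)
      pts <- rocCurve(pos, neg)
      expect_equal(trapezoidAUC(pts), rankAUC(pos, neg),
                   tolerance = 1e-10)
      # strictly increasing transforms leave the AUC unchanged
      expect_equal(rankAUC(exp(3 * pos), exp(3 * neg)),
                   rankAUC(pos, neg), tolerance = 1e-12)
    }
  })
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    pos <- runif(40); neg <- runif(120)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 120)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(rankAUC(pos, neg), ref, tolerance = 1e-10)
})

test_that("global LOOCV ranks held-out pairs against the candidate set", {
  withr::with_seed(41, {
    v <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8)
  })
  v[rowSums(v) == 0, 1] <- 1
  assoc <- makeAssoc(v)
  truth <- as.matrix(assoc)

  # a scorer that always puts held-out pairs above every candidate
  perfect <- function(train) truth
  resP <- globalLOOCV(assoc, scorer = perfect)
  expect_equal(aucValue(resP), 1)

  # a seeded random scorer hovers at chance over >= 50 positives
  expect_gte(sum(truth), 50)
  rng <- new.env(); rng$i <- 0
  random <- function(train) {
    rng$i <- rng$i + 1
    withr::with_seed(1000 + rng$i,
      matrix(runif(length(truth)), nrow(truth)))
  }
  resR <- globalLOOCV(assoc, scorer = random)
  expect_gt(aucValue(resR), 0.45)
  expect_lt(aucValue(resR), 0.55)

  # ROC polyline reproduces the AUC and has valid endpoints
  pts <- rocPoints(resR)
  expect_equal(trapezoidAUC(pts), aucValue(resR), tolerance = 1e-10)
  expect_equal(pts[1, ], c(fpr = 0, tpr = 0))
  expect_equal(pts[nrow(pts), ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts[, 1]) >= 0) && all(diff(pts[, 2]) >= 0))
})

test_that("LOOCV AUC equals exhaustive pair counting on a small fixture", {
  v <- matrix(c(1, 0, 0, 1,
                0, 1, 0, 0,
                0, 0, 1, 0,
                1, 0, 0, 0), 4, byrow = TRUE)
  assoc <- makeAssoc(v)
  scores <- matrix(c(0.9, 0.1, 0.2, 0.8,
                     0.3, 0.7, 0.1, 0.2,
                     0.2, 0.2, 0.6, 0.1,
                     0.5, 0.4, 0.3, 0.2), 4, byrow = TRUE)
  res <- globalLOOCV(assoc, scorer = function(train) scores)
  # oracle: concordant + half-tied candidate comparisons per positive
  pos <- which(v == 1); cand <- which(v == 0)
  tot <- 0
  for (p in pos) {
    for (cd in cand) {
      tot <- tot + (scores[p] > scores[cd]) +
        0.5 * (scores[p] == scores[cd])
    }
  }
  expect_equal(aucValue(res), tot / (length(pos) * length(cand)),
               tolerance = 1e-10)
})

test_that("every LOOCV iteration trains on a masked association matrix", {
  withr::with_seed(43, v <- matrix(rbinom(30, 1, 0.4), 6, 5))
  v[rowSums(v) == 0, 1] <- 1
  assoc <- makeAssoc(v)
  seen <- new.env(); seen$masked <- TRUE; seen$count <- 0
  spy <- function(train) {
    tm <- as.matrix(train)
    seen$count <- seen$count + 1
    # exactly one known association must be removed, none added
    diffs <- as.matrix(assoc) - tm
    if (!(sum(diffs == 1) == 1 && sum(diffs == -1) == 0))
      seen$masked <- FALSE
    tm * 0 + 0.5
  }
  globalLOOCV(assoc, scorer = spy)
  expect_equal(seen$count, sum(v))
  expect_true(seen$masked)
})

test_that("the incremental LOOCV path matches full rescoring per iteration", {
  cfg <- smallCorpusConfig(77)
  corpus <- generateCorpus(cfg)
  assoc <- corpus@association
  fs <- diseaseSimilarityFromMesh(corpus@descriptors,
                                  diseaseNames(assoc))
  config <- fmlncsimConfig()
  fast <- globalLOOCV(assoc, fs, config = config)
  naive <- globalLOOCV(assoc,
                       scorer = function(train)
                         scoreAssociations(train, fs, config = config))
  expect_equal(aucValue(fast), aucValue(naive), tolerance = 1e-10)
})

test_that("repeated k-fold CV is reproducible and correct at the extremes", {
  withr::with_seed(51, v <- matrix(rbinom(60, 1, 0.4), 10, 6))
  v[rowSums(v) == 0, 1] <- 1
  assoc <- makeAssoc(v)
  truth <- as.matrix(assoc)
  perfect <- function(train) truth
  r1 <- kfoldCV(assoc, k = 5, repeats = 3, seed = 9, scorer = perfect)
  r2 <- kfoldCV(assoc, k = 5, repeats = 3, seed = 9, scorer = perfect)
  expect_identical(repeatAUCs(r1), repeatAUCs(r2))
  expect_equal(r1@aucMean, 1)
  expect_equal(r1@aucSD, 0)
  expect_length(repeatAUCs(r1), 3L)

  rng <- new.env(); rng$i <- 0
  random <- function(train) {
    rng$i <- rng$i + 1
    withr::with_seed(2000 + rng$i,
      matrix(runif(length(truth)), nrow(truth)))
  }
  rr <- kfoldCV(assoc, k = 5, repeats = 4, seed = 9, scorer = random)
  expect_true(all(repeatAUCs(rr) > 0.3 & repeatAUCs(rr) < 0.7))
  expect_error(kfoldCV(assoc, k = sum(v) + 1, scorer = perfect),
               "exceeds")
})
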