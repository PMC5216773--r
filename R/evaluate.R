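#' @include AllClasses.R
NULL

#' ROC curve from two score samples
#'
#' Pooled ROC over all distinct thresholds: positives and negatives with a
#' score at or above the threshold count as called. Ties produce diagonal
#' segments, so the trapezoidal area equals the Mann-Whitney statistic with
#' half-credit for ties (\code{\link{rankAUC}}).
#'
#' @param pos,neg numeric score vectors for positive and negative samples.
#' @return Two-column matrix (FPR, TPR) from (0,0) to (1,1).
#' @export
rocCurve <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), 0)
  fpr <- vapply(th, function(t) mean(neg >= t), 0)
  pts <- rbind(c(0, 0), cbind(fpr, tpr))
  if (pts[nrow(pts), 1] != 1 || pts[nrow(pts), 2] != 1)
    pts <- rbind(pts, c(1, 1))
  dimnames(pts) <- list(NULL, c("fpr", "tpr"))
  pts
}

#' Trapezoidal area under a ROC polyline
#'
#' @param points two-column (FPR, TPR) matrix with non-decreasing
#'   coordinates.
#' @return The area, a real in [0,1].
#' @export
trapezoidAUC <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Rank-statistic (Mann-Whitney) AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted half: (concordant + ties/2) / (n_pos * n_neg).
#'
#' @inheritParams rocCurve
#' @return The AUC.
#' @export
rankAUC <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Fraction of candidate scores strictly below s, ties counted half.
.percentile <- function(s, cand) {
  (sum(cand < s) + 0.5 * sum(cand == s)) / length(cand)
}

# ROC staircase for per-positive candidate percentiles p_i: the positive's
# own iteration defines its FPR coordinate q_i = 1 - p_i; TPR steps up at
# each q. Corner points are explicit so the trapezoidal area equals
# mean(p) exactly.
.rankROC <- function(p) {
  n <- length(p)
  q <- sort(1 - p)
  uq <- unique(q)
  tprAt <- cumsum(tabulate(match(q, uq), length(uq))) / n
  pts <- matrix(c(0, 0), ncol = 2)
  prev <- 0
  for (i in seq_along(uq)) {
    pts <- rbind(pts, c(uq[i], prev), c(uq[i], tprAt[i]))
    prev <- tprAt[i]
  }
  pts <- rbind(pts, c(1, prev), c(1, 1))
  dimnames(pts) <- list(NULL, c("fpr", "tpr"))
  pts
}

.cvResult <- function(percentiles, perRepeat, config) {
  pts <- .rankROC(percentiles)
  auc <- trapezoidAUC(pts)
  new("CVResult", auc = auc, rocPoints = pts,
      perRepeatAUCs = perRepeat, aucMean = mean(perRepeat),
      aucSD = if (length(perRepeat) > 1) stats::sd(perRepeat) else 0,
      config = config)
}

# Update row/column `l` of the functional-similarity matrix after lncRNA
# l's disease group changed; groups are already restricted to scored
# diseases.
.updateFuncRow <- function(sFunc, l, groups, fsm) {
  v <- sFunc@values
  ids <- sFunc@ids
  okL <- length(groups[[l]]) > 0
  un <- setdiff(sFunc@unscored, ids[l])
  if (!okL) un <- union(un, ids[l])
  for (j in seq_along(ids)) {
    if (j == l) next
    if (okL && length(groups[[j]]) > 0) {
      s <- min(1, lncFunctionalSimilarity(groups[[l]], groups[[j]], fsm))
    } else s <- NA_real_
    v[l, j] <- v[j, l] <- s
  }
  new("SimilarityMatrix", ids = ids, values = v, unscored = un)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is withheld in turn: its entry is zeroed in the
#' training matrix, every similarity component that depends on the
#' association matrix (both Gaussian kernels and the group-based functional
#' similarity) is recomputed from the masked matrix, the model is rescored,
#' and the held-out pair is ranked against all pairs without recorded
#' association evidence (the global candidate set, fixed by the original
#' matrix). The AUC is the mean candidate percentile of the held-out pairs,
#' identical to the trapezoidal area of the returned ROC staircase.
#'
#' @param assoc \linkS4class{AssociationMatrix} of known associations
#'   (>= 2 positives).
#' @param fs disease semantic \linkS4class{SimilarityMatrix} aligned to the
#'   association columns.
#' @param sExpr optional lncRNA expression \linkS4class{SimilarityMatrix}.
#' @param config an \code{\link{fmlncsimConfig}}.
#' @param scorer optional replacement scoring function
#'   \code{function(trainAssoc) -> score matrix}; when supplied it is
#'   called on the masked training matrix instead of the built-in model
#'   (used for harness validation with reference scorers).
#' @return A \linkS4class{CVResult}.
#' @export
globalLOOCV <- function(assoc, fs = NULL, sExpr = NULL,
                        config = fmlncsimConfig(), scorer = NULL) {
  stopifnot(is(assoc, "AssociationMatrix"))
  a <- as.matrix(assoc)
  pos <- which(a == 1)
  if (length(pos) < 2) stop("need at least two known associations")
  cand <- which(a == 0)
  useModel <- is.null(scorer)
  if (useModel) {
    if (is.null(fs)) stop("fs is required for the built-in model")
    fsm <- as.matrix(fs)
    scored <- entityIds(fs)[!entityIds(fs) %in% unscoredIds(fs)]
    baseGroups <- lapply(diseaseGroups(assoc), intersect, scored)
    sFuncBase <- buildLncSimilarityMatrix(diseaseGroups(assoc), fs)
  }
  p <- numeric(length(pos))
  for (k in seq_along(pos)) {
    idx <- pos[k]
    l <- (idx - 1L) %% nrow(a) + 1L
    d <- (idx - 1L) %/% nrow(a) + 1L
    train <- assoc
    train@values[l, d] <- 0
    if (useModel) {
      groups <- baseGroups
      groups[[l]] <- setdiff(groups[[l]], assoc@diseaseIds[d])
      sFunc <- .updateFuncRow(sFuncBase, l, groups, fsm)
      f <- scoreAssociations(train, fs, sExpr, config, sFunc = sFunc)
    } else {
      f <- scorer(train)
    }
    p[k] <- .percentile(f[idx], f[cand])
  }
  .cvResult(p, mean(p), c(unclass(config), mode = "loocv",
                          nPositives = length(pos)))
}

#' Repeated k-fold cross-validation
#'
#' Known associations are randomly divided into k disjoint folds; each fold
#' is removed from training in turn, the association-dependent similarities
#' are recomputed from the masked matrix, and the fold's pairs are ranked
#' against the never-associated candidate set. The per-repeat AUC is the
#' mean candidate percentile over all positives of that repeat; mean and
#' standard deviation are reported over repeats. The fold partition is
#' fully reproducible from \code{seed}.
#'
#' @inheritParams globalLOOCV
#' @param k number of folds (>= 2, at most the number of positives).
#' @param repeats number of random re-partitions.
#' @param seed integer seed driving all fold assignments.
#' @return A \linkS4class{CVResult} with one AUC per repeat.
#' @export
kfoldCV <- function(assoc, k = 5L, repeats = 100L, seed = 1L, fs = NULL,
                    sExpr = NULL, config = fmlncsimConfig(),
                    scorer = NULL) {
  stopifnot(is(assoc, "AssociationMatrix"), k >= 2)
  a <- as.matrix(assoc)
  pos <- which(a == 1)
  if (length(pos) < k) stop("k exceeds the number of known associations")
  cand <- which(a == 0)
  useModel <- is.null(scorer)
  if (useModel && is.null(fs))
    stop("fs is required for the built-in model")
  folds <- withr::with_seed(seed, lapply(seq_len(repeats), function(r)
    sample(rep(seq_len(k), length.out = length(pos)))))
  perRepeat <- numeric(repeats)
  allP <- numeric(0)
  for (r in seq_len(repeats)) {
    p <- numeric(length(pos))
    for (fold in seq_len(k)) {
      inFold <- which(folds[[r]] == fold)
      train <- assoc
      train@values[pos[inFold]] <- 0
      f <- if (useModel) scoreAssociations(train, fs, sExpr, config)
           else scorer(train)
      fc <- f[cand]
      for (i in inFold) p[i] <- .percentile(f[pos[i]], fc)
    }
    perRepeat[r] <- mean(p)
    allP <- c(allP, p)
  }
  .cvResult(allP, perRepeat, c(unclass(config), mode = "kfold", k = k,
                               repeats = repeats, seed = seed,
                               nPositives = length(pos)))
}
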