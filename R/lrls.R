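#' @include AllClasses.R
NULL

#' Model configuration
#'
#' Bundles every tunable parameter of the scoring pipeline so that results
#' carry a complete provenance snapshot.
#'
#' @param cap fuzzy density cap in (0,1], see
#'   \code{\link{computeFuzzyDensity}}.
#' @param gammaPrime Gaussian kernel bandwidth multiplier.
#' @param etaLnc,etaDis Laplacian regularization strengths in the lncRNA
#'   and disease spaces (positive).
#' @param w combination weight on the lncRNA-space scores in [0,1].
#' @param exprRescale Spearman rescaling mode, see
#'   \code{\link{spearmanExpressionSimilarity}}.
#' @return A named list of class \code{fmlncsimConfig}.
#' @export
fmlncsimConfig <- function(cap = 0.999, gammaPrime = 1, etaLnc = 1,
                           etaDis = 1, w = 0.5,
                           exprRescale = c("shift", "clamp")) {
  stopifnot(cap > 0, cap <= 1, gammaPrime > 0, etaLnc > 0, etaDis > 0,
            w >= 0, w <= 1)
  structure(list(cap = cap, gammaPrime = gammaPrime, etaLnc = etaLnc,
                 etaDis = etaDis, w = w,
                 exprRescale = match.arg(exprRescale)),
            class = "fmlncsimConfig")
}

# Normalized graph Laplacian I - D^{-1/2} S D^{-1/2}. Entities whose
# similarity row sums to zero have no edges; their Laplacian row is zeroed
# so regularization leaves their scores at the label values.
.normalizedLaplacian <- function(sim) {
  d <- rowSums(sim)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  l <- -sim * tcrossprod(inv)
  diag(l) <- diag(l) + 1
  iso <- d == 0
  if (any(iso)) {
    l[iso, ] <- 0
    l[, iso] <- 0
  }
  l
}

#' Laplacian-regularized least-squares scores in one similarity space
#'
#' Solves F = (I + eta L)^{-1} Y with L the normalized graph Laplacian of
#' the similarity matrix: scores reproduce the known labels while being
#' smoothed along strong similarity edges. \code{axis = "lncrna"} smooths
#' over lncRNAs (rows of Y); \code{axis = "disease"} over diseases (Y is
#' transposed in and the result transposed back). As eta -> 0 the scores
#' approach Y; a similarity with no edges leaves Y unchanged for any eta.
#'
#' @param sim square symmetric similarity matrix (plain matrix or
#'   \linkS4class{SimilarityMatrix}) over the chosen axis.
#' @param y \linkS4class{AssociationMatrix} or plain binary matrix
#'   (lncRNA x disease).
#' @param eta positive regularization strength.
#' @param axis \code{"lncrna"} or \code{"disease"}.
#' @return Score matrix with the shape and dimnames of \code{y}.
#' @export
laplacianRLSScore <- function(sim, y, eta = 1,
                              axis = c("lncrna", "disease")) {
  axis <- match.arg(axis)
  if (eta <= 0) stop("eta must be positive")
  s <- if (is(sim, "SimilarityMatrix")) as.matrix(sim) else sim
  ym <- if (is(y, "AssociationMatrix")) as.matrix(y) else y
  lab <- if (axis == "lncrna") ym else t(ym)
  if (nrow(s) != nrow(lab))
    stop("similarity matrix does not match the association matrix on the ",
         axis, " axis")
  l <- .normalizedLaplacian(s)
  a <- diag(nrow(l)) + eta * l
  f <- tryCatch(solve(a, lab),
                error = function(e) stop("Laplacian RLS system could not ",
                                         "be solved: ", conditionMessage(e)))
  if (axis == "disease") f <- t(f)
  dimnames(f) <- dimnames(ym)
  f
}

#' Combine lncRNA-space and disease-space scores
#'
#' Weighted average w * F_lnc + (1-w) * F_dis of the two per-space score
#' matrices (default w = 0.5).
#'
#' @param fLnc,fDis score matrices of identical shape.
#' @param w weight on the lncRNA-space scores in [0,1].
#' @return Combined score matrix.
#' @export
combineSpaceScores <- function(fLnc, fDis, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  if (!identical(dim(fLnc), dim(fDis)))
    stop("score matrices must have the same shape")
  w * fLnc + (1 - w) * fDis
}

#' Score all lncRNA-disease pairs with the two-space model
#'
#' Full scoring pass: Gaussian interaction-profile kernels are computed
#' from the (training) association matrix, integrated with the disease
#' semantic similarity, the group-based lncRNA functional similarity and
#' the optional expression similarity, and Laplacian RLS is solved in both
#' spaces and averaged.
#'
#' @param assoc training \linkS4class{AssociationMatrix}.
#' @param fs disease semantic \linkS4class{SimilarityMatrix} indexed like
#'   the association columns (NA rows allowed for unscored diseases).
#' @param sExpr optional lncRNA expression \linkS4class{SimilarityMatrix}
#'   indexed like the association rows.
#' @param config an \code{\link{fmlncsimConfig}}.
#' @param sFunc optional precomputed lncRNA functional similarity; when
#'   omitted it is derived from \code{assoc} and \code{fs}.
#' @return Score matrix (lncRNA x disease) with dimnames.
#' @export
scoreAssociations <- function(assoc, fs, sExpr = NULL,
                              config = fmlncsimConfig(), sFunc = NULL) {
  stopifnot(is(assoc, "AssociationMatrix"))
  kl <- gaussianProfileKernel(assoc, "lncrna", config$gammaPrime)
  kd <- gaussianProfileKernel(assoc, "disease", config$gammaPrime)
  if (is.null(sFunc))
    sFunc <- buildLncSimilarityMatrix(diseaseGroups(assoc), fs)
  simL <- integrateLncSimilarity(sFunc, kl, sExpr)
  simD <- integrateDiseaseSimilarity(fs, kd)
  fLnc <- laplacianRLSScore(simL, assoc, config$etaLnc, "lncrna")
  fDis <- laplacianRLSScore(simD, assoc, config$etaDis, "disease")
  combineSpaceScores(fLnc, fDis, config$w)
}

#' Rank candidate lncRNAs for one disease
#'
#' Candidates are the lncRNAs with no recorded association to the disease,
#' ordered by decreasing score; ties are broken lexicographically on the
#' lncRNA id so ranked lists are byte-reproducible.
#'
#' @param diseaseId a disease present in the association matrix.
#' @param scores score matrix from \code{\link{scoreAssociations}}.
#' @param assoc the \linkS4class{AssociationMatrix} defining known pairs.
#' @param topN number of candidates to return (default 10).
#' @return data.frame with columns \code{lncrna}, \code{score},
#'   \code{rank}.
#' @export
rankCandidates <- function(diseaseId, scores, assoc, topN = 10L) {
  stopifnot(is(assoc, "AssociationMatrix"))
  j <- match(diseaseId, assoc@diseaseIds)
  if (is.na(j)) stop("unknown disease: ", diseaseId)
  cand <- assoc@lncIds[assoc@values[, j] == 0]
  if (length(cand) == 0)
    return(data.frame(lncrna = character(0), score = numeric(0),
                      rank = integer(0)))
  sc <- scores[cand, diseaseId]
  ord <- order(-sc, cand)
  out <- data.frame(lncrna = cand[ord], score = unname(sc[ord]),
                    rank = seq_along(ord))
  utils::head(out, topN)
}
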