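#' @include AllClasses.R
NULL

#' Gaussian interaction-profile kernel similarity
#'
#' The interaction profile of an entity is its binary association vector
#' (row for a lncRNA, column for a disease). Similarity between entities i
#' and j is \eqn{\exp(-\gamma \|IP(i)-IP(j)\|^2)} with the bandwidth
#' normalized by the mean squared profile norm,
#' \eqn{\gamma = \gamma' / \mathrm{mean}_k \|IP(k)\|^2}; entities with
#' all-zero profiles contribute 0 to that mean but still count in it.
#'
#' @param assoc an \linkS4class{AssociationMatrix} (or plain binary matrix
#'   with dimnames).
#' @param axis \code{"lncrna"} (profiles = rows) or \code{"disease"}
#'   (profiles = columns).
#' @param gammaPrime positive bandwidth multiplier (default 1).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
gaussianProfileKernel <- function(assoc, axis = c("lncrna", "disease"),
                                  gammaPrime = 1) {
  axis <- match.arg(axis)
  stopifnot(gammaPrime > 0)
  a <- if (is(assoc, "AssociationMatrix")) as.matrix(assoc) else assoc
  p <- if (axis == "lncrna") a else t(a)
  norms <- rowSums(p^2)
  if (all(norms == 0))
    stop("every interaction profile is all-zero; ",
         "the kernel bandwidth is undefined")
  gamma <- gammaPrime / mean(norms)
  cross <- tcrossprod(p)
  d2 <- outer(norms, norms, "+") - 2 * cross
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-gamma * d2)
  diag(k) <- 1
  new("SimilarityMatrix", ids = rownames(p), values = unname(k),
      unscored = character(0))
}

#' Spearman rank-correlation expression similarity
#'
#' Pairwise Spearman correlation between lncRNA expression profiles,
#' rescaled from [-1, 1] to [0, 1] by (r+1)/2 so all similarity components
#' share a range (\code{rescale = "clamp"} instead truncates negative
#' correlations at 0). Constant profiles have undefined rank correlation:
#' their off-diagonal entries are set to 0 and a warning names them.
#'
#' @param expr numeric matrix, one row per lncRNA, one column per sample
#'   (>= 2 samples).
#' @param rescale \code{"shift"} for (r+1)/2 (default) or \code{"clamp"}
#'   for max(r, 0).
#' @return A \linkS4class{SimilarityMatrix} over the rows of \code{expr}.
#' @export
spearmanExpressionSimilarity <- function(expr,
                                         rescale = c("shift", "clamp")) {
  rescale <- match.arg(rescale)
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  r <- suppressWarnings(stats::cor(t(expr), method = "spearman"))
  flat <- which(apply(expr, 1L, function(x) stats::sd(x) == 0))
  v <- if (rescale == "shift") (r + 1) / 2 else pmax(r, 0)
  if (length(flat) > 0) {
    v[flat, ] <- 0
    v[, flat] <- 0
    warning("constant expression profile(s): ",
            paste(rownames(expr)[flat], collapse = ", "), call. = FALSE)
  }
  diag(v) <- 1
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("lnc", seq_len(nrow(expr)))
  new("SimilarityMatrix", ids = ids, values = unname(v),
      unscored = character(0))
}

# Entry-wise mean of similarity components sharing an id order; rows of
# entities unscored in a component take the mean of the remaining
# components (kernel fallback).
.integrateComponents <- function(components, ids) {
  mats <- lapply(components, function(s) {
    m <- if (is(s, "SimilarityMatrix")) as.matrix(s) else s
    if (!identical(rownames(m), ids))
      stop("similarity components must share the same id order")
    m
  })
  n <- length(ids)
  num <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (m in mats) {
    miss <- is.na(m)
    m[miss] <- 0
    num <- num + m
    cnt <- cnt + !miss
  }
  out <- num / cnt  # kernel component is always complete, so cnt >= 1
  dimnames(out) <- list(ids, ids)
  out
}

#' Integrated disease similarity
#'
#' Entry-wise mean ("simple average") of the semantic similarity matrix and
#' the disease Gaussian kernel; diseases without a semantic score (absent
#' from MeSH or with an all-universal DAG) take the kernel value alone.
#'
#' @param fs disease semantic \linkS4class{SimilarityMatrix} (NA rows for
#'   unscored diseases).
#' @param kd disease Gaussian kernel \linkS4class{SimilarityMatrix}, same
#'   id order.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
integrateDiseaseSimilarity <- function(fs, kd) {
  ids <- entityIds(kd)
  fsm <- as.matrix(fs)
  un <- unscoredIds(fs)
  fsm[un, ] <- NA_real_
  fsm[, un] <- NA_real_
  out <- .integrateComponents(list(fsm, kd), ids)
  new("SimilarityMatrix", ids = ids, values = unname(out),
      unscored = character(0))
}

#' Integrated lncRNA similarity
#'
#' Entry-wise mean of the functional-similarity matrix, the lncRNA Gaussian
#' kernel and (when provided) the expression similarity; lncRNAs without a
#' functional score fall back to the mean of the remaining components.
#'
#' @param sFunc lncRNA functional \linkS4class{SimilarityMatrix}.
#' @param kl lncRNA Gaussian kernel \linkS4class{SimilarityMatrix}, same id
#'   order.
#' @param sExpr optional expression \linkS4class{SimilarityMatrix}.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
integrateLncSimilarity <- function(sFunc, kl, sExpr = NULL) {
  ids <- entityIds(kl)
  fm <- as.matrix(sFunc)
  un <- unscoredIds(sFunc)
  fm[un, ] <- NA_real_
  fm[, un] <- NA_real_
  comp <- list(fm, kl)
  if (!is.null(sExpr)) comp <- c(comp, list(sExpr))
  out <- .integrateComponents(comp, ids)
  new("SimilarityMatrix", ids = ids, values = unname(out),
      unscored = character(0))
}
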