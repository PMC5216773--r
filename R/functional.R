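#' @include AllClasses.R
NULL

#' Disease groups of each lncRNA
#'
#' The disease group G(i) of lncRNA i is the set of diseases it is known to
#' be associated with; group-to-group similarity of these sets defines
#' lncRNA functional similarity.
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @return Named list (one entry per lncRNA) of disease-id character
#'   vectors; lncRNAs with no associations get an empty vector.
#' @export
diseaseGroups <- function(assoc) {
  stopifnot(is(assoc, "AssociationMatrix"))
  apply(assoc@values, 1L, function(r) assoc@diseaseIds[r > 0],
        simplify = FALSE) |>
    stats::setNames(assoc@lncIds)
}

#' Best-match similarity of one disease against a disease group
#'
#' Sd(d, G) = max over members dj of G of FS(d, dj): the group is credited
#' with its most similar member.
#'
#' @param d a disease id present in \code{fs}.
#' @param group character vector of disease ids (nonempty).
#' @param fs a disease \linkS4class{SimilarityMatrix} (or plain named
#'   matrix).
#' @return The maximum similarity, a real in [0,1].
#' @export
termGroupSimilarity <- function(d, group, fs) {
  if (length(group) == 0) stop("empty disease group")
  m <- if (is(fs, "SimilarityMatrix")) as.matrix(fs) else fs
  if (!d %in% rownames(m) || !all(group %in% colnames(m)))
    stop("disease id missing from the similarity matrix")
  max(m[d, group])
}

#' Functional similarity of two lncRNAs from their disease groups
#'
#' The group-wise best-match average: every disease of G(i) is matched to
#' its most similar disease in G(j) and vice versa, and the matches are
#' averaged over both groups,
#' S(i,j) = (sum_di Sd(di, G(j)) + sum_dj Sd(dj, G(i))) / (|G(i)|+|G(j)|).
#' Identical groups give 1; groups with no cross-similarity give 0.
#'
#' @param gi,gj character vectors of disease ids (both nonempty).
#' @param fs a disease \linkS4class{SimilarityMatrix} or plain named matrix.
#' @return S(i, j), a real in [0,1].
#' @export
lncFunctionalSimilarity <- function(gi, gj, fs) {
  if (length(gi) == 0 || length(gj) == 0) stop("empty disease group")
  m <- if (is(fs, "SimilarityMatrix")) as.matrix(fs) else fs
  sub <- m[gi, gj, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
    (length(gi) + length(gj))
}

#' LncRNA functional similarity matrix
#'
#' Fills all unordered lncRNA pairs with the group-wise best-match average
#' and sets the diagonal to 1 by definition. LncRNAs whose group is empty
#' (or whose diseases all lack a semantic score) cannot be scored: their
#' rows are NA and they are listed as unscored, so integration can fall
#' back to kernel similarity for them.
#'
#' @param groups named list of disease-id vectors
#'   (\code{\link{diseaseGroups}}).
#' @param fs disease \linkS4class{SimilarityMatrix}.
#' @return A \linkS4class{SimilarityMatrix} over the lncRNAs.
#' @export
buildLncSimilarityMatrix <- function(groups, fs) {
  stopifnot(length(groups) >= 1)
  ids <- names(groups)
  fsm <- as.matrix(fs)
  scored <- colnames(fsm)[!colnames(fsm) %in% unscoredIds(fs)]
  groups <- lapply(groups, intersect, scored)
  ok <- lengths(groups) > 0
  n <- length(ids)
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    v[i, i] <- 1
    if (i < n) for (j in seq(i + 1L, n)) {
      if (ok[i] && ok[j]) {
        s <- lncFunctionalSimilarity(groups[[i]], groups[[j]], fsm)
        v[i, j] <- v[j, i] <- min(1, s)
      }
    }
  }
  new("SimilarityMatrix", ids = ids, values = v,
      unscored = ids[!ok])
}
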