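#' @import methods
NULL

.TREE_NUMBER_RE <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

#' MeshDescriptorSet: a parsed set of MeSH descriptors
#'
#' Holds the heading (MH), unique identifier (UI) and tree numbers (MN) of
#' each descriptor retained from a MeSH ASCII file, typically restricted to
#' Category C (diseases). Tree numbers are dotted codes such as
#' \code{"C04.557.337"}; their shared prefixes encode the disease hierarchy.
#'
#' @slot heading character vector of descriptor headings.
#' @slot uniqueId character vector of descriptor unique identifiers.
#' @slot treeNumbers list of character vectors, one per descriptor.
#'
#' @exportClass MeshDescriptorSet
setClass("MeshDescriptorSet",
  slots = c(heading = "character", uniqueId = "character",
            treeNumbers = "list"))

setValidity("MeshDescriptorSet", function(object) {
  n <- length(object@heading)
  if (length(object@uniqueId) != n || length(object@treeNumbers) != n)
    return("heading, uniqueId and treeNumbers must have equal length")
  if (anyDuplicated(object@uniqueId))
    return("unique identifiers must be unique")
  if (n > 0) {
    tn <- unlist(object@treeNumbers, use.names = FALSE)
    if (any(lengths(object@treeNumbers) < 1))
      return("every descriptor must carry at least one tree number")
    if (!all(grepl(.TREE_NUMBER_RE, tn)))
      return("malformed tree number present")
  }
  TRUE
})

#' DiseaseDAG: a disease term plus its hierarchical ancestors
#'
#' The directed acyclic graph of one disease: its own MeSH heading together
#' with every ancestor reachable through tree-number prefixes. Edges point
#' from the more general term (parent) to the more specific term (child).
#'
#' @slot diseaseId heading of the disease the DAG belongs to.
#' @slot nodes character vector of headings (the disease and its ancestors).
#' @slot edges two-column character matrix, columns \code{parent}, \code{child}.
#'
#' @exportClass DiseaseDAG
setClass("DiseaseDAG",
  slots = c(diseaseId = "character", nodes = "character", edges = "matrix"))

setValidity("DiseaseDAG", function(object) {
  if (length(object@diseaseId) != 1L) return("diseaseId must be length 1")
  if (!object@diseaseId %in% object@nodes)
    return("the disease's own heading must be a node")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns (parent, child)")
  if (nrow(e) > 0) {
    if (!all(e %in% object@nodes))
      return("every edge endpoint must be a node")
    if (!.isAcyclic(object@nodes, e))
      return("edge set must be acyclic")
  }
  TRUE
})

# Kahn topological check; edges[,1] = parent, edges[,2] = child.
.isAcyclic <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  active <- rep(TRUE, nrow(edges))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    out <- which(active & edges[, 1L] == v)
    for (k in out) {
      active[k] <- FALSE
      ch <- edges[k, 2L]
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(nodes)
}

#' FuzzyDensitySet: per-disease term densities with a solved Sugeno lambda
#'
#' Each retained term of a disease DAG carries a fuzzy density in (0,1)
#' (its information content normalized by the corpus maximum, then scaled by
#' the density cap). \code{lambda} is the Sugeno parameter solving
#' \eqn{1+\lambda=\prod_i (1+\lambda g_i)}; it is \code{NA} until solved.
#'
#' @slot diseaseId disease heading.
#' @slot densities named numeric vector of term densities in (0,1).
#' @slot lambda solved Sugeno parameter (> -1), or \code{NA_real_}.
#'
#' @exportClass FuzzyDensitySet
setClass("FuzzyDensitySet",
  slots = c(diseaseId = "character", densities = "numeric",
            lambda = "numeric"))

setValidity("FuzzyDensitySet", function(object) {
  d <- object@densities
  if (length(d) > 0 && (is.null(names(d)) || any(!nzchar(names(d)))))
    return("densities must be named by term heading")
  if (any(d <= 0 | d >= 1)) return("densities must lie strictly in (0,1)")
  if (length(object@lambda) != 1L) return("lambda must be length 1")
  if (!is.na(object@lambda) && object@lambda <= -1)
    return("lambda must exceed -1")
  TRUE
})

#' SimilarityMatrix: a symmetric similarity matrix with entity names
#'
#' Shared container for disease semantic similarity, lncRNA functional
#' similarity, Gaussian interaction-profile kernels and integrated
#' similarities. Rows of entities that could not be scored (e.g. diseases
#' absent from MeSH) are \code{NA} and their ids listed in \code{unscored};
#' downstream integration substitutes kernel similarity for them.
#'
#' @slot ids ordered entity names (row/column order of \code{values}).
#' @slot values square numeric matrix, symmetric, non-NA entries in [0,1].
#' @slot unscored ids whose rows/columns are NA placeholders.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(ids = "character", values = "matrix", unscored = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  if (nrow(v) != n || ncol(v) != n) return("values must be n x n")
  if (!all(object@unscored %in% object@ids))
    return("unscored ids must be a subset of ids")
  fin <- v[!is.na(v)]
  if (any(fin < -1e-9 | fin > 1 + 1e-9))
    return("similarity entries must lie in [0,1]")
  if (any(abs(v - t(v)) > 1e-8, na.rm = TRUE))
    return("similarity matrix must be symmetric")
  TRUE
})

#' AssociationMatrix: binary lncRNA x disease adjacency
#'
#' One entry per (lncRNA, disease) pair; 1 marks an experimentally supported
#' association. Rows are lncRNAs, columns diseases.
#'
#' @slot lncIds ordered lncRNA names (rows).
#' @slot diseaseIds ordered disease names (columns).
#' @slot values binary matrix.
#'
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  slots = c(lncIds = "character", diseaseIds = "character",
            values = "matrix"))

setValidity("AssociationMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@lncIds) ||
      ncol(v) != length(object@diseaseIds))
    return("matrix shape must match id vectors")
  if (anyDuplicated(object@lncIds) || anyDuplicated(object@diseaseIds))
    return("duplicate entity ids")
  if (!all(v %in% c(0, 1))) return("entries must be 0 or 1")
  TRUE
})

#' CVResult: cross-validation outcome with ROC points and AUC
#'
#' @slot auc overall area under the ROC curve.
#' @slot rocPoints two-column matrix (FPR, TPR), both coordinates
#'   non-decreasing from (0,0) to (1,1).
#' @slot perRepeatAUCs AUC per repeat (repeated k-fold; length 1 for LOOCV).
#' @slot aucMean,aucSD mean and standard deviation over repeats.
#' @slot config parameter snapshot used for the run.
#'
#' @exportClass CVResult
setClass("CVResult",
  slots = c(auc = "numeric", rocPoints = "matrix",
            perRepeatAUCs = "numeric", aucMean = "numeric",
            aucSD = "numeric", config = "list"))

setValidity("CVResult", function(object) {
  p <- object@rocPoints
  if (ncol(p) != 2L) return("rocPoints must have two columns (FPR, TPR)")
  if (nrow(p) > 0) {
    if (any(diff(p[, 1L]) < -1e-12) || any(diff(p[, 2L]) < -1e-12))
      return("ROC coordinates must be non-decreasing")
    if (any(abs(p[1L, ] - c(0, 0)) > 1e-12) ||
        any(abs(p[nrow(p), ] - c(1, 1)) > 1e-12))
      return("ROC must start at (0,0) and end at (1,1)")
  }
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    return("auc must lie in [0,1]")
  TRUE
})
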