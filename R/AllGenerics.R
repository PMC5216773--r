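#' @include AllClasses.R
NULL

#' Accessors for fmlncsim objects
#'
#' Small accessor family: headings, identifiers and tree numbers of a
#' \linkS4class{MeshDescriptorSet}; nodes and edges of a
#' \linkS4class{DiseaseDAG}; densities and lambda of a
#' \linkS4class{FuzzyDensitySet}; names of a \linkS4class{SimilarityMatrix}
#' or \linkS4class{AssociationMatrix}; AUC and ROC points of a
#' \linkS4class{CVResult}.
#'
#' @param x,object an fmlncsim S4 object.
#' @param ... unused.
#' @return The respective slot contents; \code{as.matrix} returns a base
#'   matrix with dimnames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshHeadings", function(x) standardGeneric("meshHeadings"))
#' @rdname accessors
#' @export
setGeneric("meshIds", function(x) standardGeneric("meshIds"))
#' @rdname accessors
#' @export
setGeneric("treeNumbers", function(x) standardGeneric("treeNumbers"))
#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))
#' @rdname accessors
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))
#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
#' @rdname accessors
#' @export
setGeneric("lambdaValue", function(x) standardGeneric("lambdaValue"))
#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("unscoredIds", function(x) standardGeneric("unscoredIds"))
#' @rdname accessors
#' @export
setGeneric("lncNames", function(x) standardGeneric("lncNames"))
#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("repeatAUCs", function(x) standardGeneric("repeatAUCs"))

#' @rdname accessors
#' @export
setMethod("meshHeadings", "MeshDescriptorSet", function(x) x@heading)
#' @rdname accessors
#' @export
setMethod("meshIds", "MeshDescriptorSet", function(x) x@uniqueId)
#' @rdname accessors
#' @export
setMethod("treeNumbers", "MeshDescriptorSet",
  function(x) stats::setNames(x@treeNumbers, x@heading))
#' @rdname accessors
#' @export
setMethod("length", "MeshDescriptorSet", function(x) length(x@heading))
#' @rdname accessors
#' @export
setMethod("dagNodes", "DiseaseDAG", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("dagEdges", "DiseaseDAG", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("densities", "FuzzyDensitySet", function(x) x@densities)
#' @rdname accessors
#' @export
setMethod("lambdaValue", "FuzzyDensitySet", function(x) x@lambda)
#' @rdname accessors
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("unscoredIds", "SimilarityMatrix", function(x) x@unscored)
#' @rdname accessors
#' @export
setMethod("lncNames", "AssociationMatrix", function(x) x@lncIds)
#' @rdname accessors
#' @export
setMethod("diseaseNames", "AssociationMatrix", function(x) x@diseaseIds)
#' @rdname accessors
#' @export
setMethod("aucValue", "CVResult", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("rocPoints", "CVResult", function(x) x@rocPoints)
#' @rdname accessors
#' @export
setMethod("repeatAUCs", "CVResult", function(x) x@perRepeatAUCs)

#' @rdname accessors
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
})

#' @rdname accessors
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@lncIds, x@diseaseIds)
  v
})

#' @rdname accessors
#' @export
setMethod("show", "MeshDescriptorSet", function(object) {
  cat("MeshDescriptorSet with", length(object@heading), "descriptors\n")
  if (length(object@heading) > 0) {
    k <- min(5L, length(object@heading))
    for (i in seq_len(k))
      cat("  ", object@heading[i], " [", object@uniqueId[i], "] ",
          paste(object@treeNumbers[[i]], collapse = " "), "\n", sep = "")
    if (length(object@heading) > k) cat("  ...\n")
  }
})

#' @rdname accessors
#' @export
setMethod("show", "DiseaseDAG", function(object) {
  cat("DiseaseDAG for '", object@diseaseId, "': ",
      length(object@nodes), " nodes, ", nrow(object@edges), " edges\n",
      sep = "")
})

#' @rdname accessors
#' @export
setMethod("show", "FuzzyDensitySet", function(object) {
  cat("FuzzyDensitySet for '", object@diseaseId, "': ",
      length(object@densities), " terms, lambda = ",
      format(object@lambda, digits = 6), "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix: ", length(object@ids), " x ", length(object@ids),
      sep = "")
  if (length(object@unscored) > 0)
    cat(" (", length(object@unscored), " unscored)", sep = "")
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix: ", length(object@lncIds), " lncRNAs x ",
      length(object@diseaseIds), " diseases, ",
      sum(object@values), " known associations\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("show", "CVResult", function(object) {
  cat("CVResult: AUC = ", format(object@auc, digits = 4), sep = "")
  if (length(object@perRepeatAUCs) > 1)
    cat(" (mean ", format(object@aucMean, digits = 4), " +/- ",
        format(object@aucSD, digits = 4), " over ",
        length(object@perRepeatAUCs), " repeats)", sep = "")
  cat("\n")
})

#' Subset a MeshDescriptorSet
#'
#' @param x a \linkS4class{MeshDescriptorSet}.
#' @param i index vector (numeric, logical, or heading names).
#' @param j,...,drop unused.
#' @return A \linkS4class{MeshDescriptorSet} with the selected descriptors.
#' @export
setMethod("[", "MeshDescriptorSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@heading)
  new("MeshDescriptorSet", heading = x@heading[i],
      uniqueId = x@uniqueId[i], treeNumbers = x@treeNumbers[i])
})
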