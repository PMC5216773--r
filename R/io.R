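#' @include AllClasses.R
NULL

#' Read a lncRNA-disease association table
#'
#' Expects a TSV with a lncRNA column and a disease column (header or not;
#' further columns such as evidence annotations are ignored). Duplicate
#' pairs — the same association supported by several evidence lines — are
#' collapsed to a single entry.
#'
#' @param path TSV path.
#' @param header whether the file has a header line (default TRUE).
#' @return An \linkS4class{AssociationMatrix}.
#' @export
readAssociationTable <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("association table needs >= 2 columns")
  lnc <- trimws(as.character(df[[1]]))
  dis <- trimws(as.character(df[[2]]))
  keep <- !duplicated(paste0(lnc, "\r", dis))
  lnc <- lnc[keep]; dis <- dis[keep]
  lncIds <- sort(unique(lnc))
  disIds <- sort(unique(dis))
  v <- matrix(0, length(lncIds), length(disIds))
  v[cbind(match(lnc, lncIds), match(dis, disIds))] <- 1
  new("AssociationMatrix", lncIds = lncIds, diseaseIds = disIds,
      values = v)
}

#' Write an association matrix as a two-column pair table
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAssociationTable <- function(assoc, path) {
  stopifnot(is(assoc, "AssociationMatrix"))
  idx <- which(assoc@values == 1, arr.ind = TRUE)
  df <- data.frame(lncrna = assoc@lncIds[idx[, 1]],
                   disease = assoc@diseaseIds[idx[, 2]])
  df <- df[order(df$lncrna, df$disease), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a similarity (or score) matrix as header-indexed TSV
#'
#' @param m a \linkS4class{SimilarityMatrix} or plain named matrix.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  mm <- if (is(m, "SimilarityMatrix")) as.matrix(m) else m
  df <- data.frame(id = rownames(mm), mm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a header-indexed square matrix TSV
#'
#' @param path TSV path as written by \code{\link{writeMatrixTSV}}.
#' @param asSimilarity wrap the result in a
#'   \linkS4class{SimilarityMatrix} (default) or return a plain matrix.
#' @return A \linkS4class{SimilarityMatrix} or matrix.
#' @export
readMatrixTSV <- function(path, asSimilarity = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!asSimilarity) return(m)
  offDiag <- m
  diag(offDiag) <- NA
  un <- if (nrow(m) > 1)
    rownames(m)[rowSums(!is.na(offDiag)) == 0] else character(0)
  new("SimilarityMatrix", ids = rownames(m), values = unname(m),
      unscored = un)
}

#' Write an expression matrix (lncRNA x sample) as TSV
#'
#' @param expr numeric matrix with row names.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTSV <- function(expr, path) {
  df <- data.frame(lncrna = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' @param path TSV path as written by \code{\link{writeExpressionTSV}}.
#' @return Numeric matrix with lncRNA row names.
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
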