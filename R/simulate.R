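#' @include AllClasses.R
NULL

#' SyntheticCorpus: a generated benchmark instance
#'
#' @slot descriptors synthetic MeSH-like \linkS4class{MeshDescriptorSet}.
#' @slot association \linkS4class{AssociationMatrix} with planted block
#'   structure.
#' @slot expression lncRNA x sample expression matrix.
#' @slot lncBlocks,diseaseBlocks integer block assignment per entity.
#'
#' @exportClass SyntheticCorpus
setClass("SyntheticCorpus",
  slots = c(descriptors = "MeshDescriptorSet",
            association = "AssociationMatrix",
            expression = "matrix",
            lncBlocks = "integer", diseaseBlocks = "integer"))

#' @rdname accessors
#' @export
setMethod("show", "SyntheticCorpus", function(object) {
  cat("SyntheticCorpus: ", length(object@descriptors), " terms, ",
      length(object@association@lncIds), " lncRNAs x ",
      length(object@association@diseaseIds), " diseases, ",
      max(object@lncBlocks), " blocks\n", sep = "")
})

#' Fixture generator configuration
#'
#' Defaults describe the standard signal fixture used throughout testing:
#' 40 lncRNAs and 25 diseases organized in 5 blocks, within-block
#' association probability 0.6 against a 0.02 background, over a 60-term
#' hierarchy of depth 4.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param nTerms number of hierarchy terms (>= nBlocks).
#' @param maxDepth maximum number of dotted segments in a tree number.
#' @param branching maximum children per term.
#' @param nDiseases,nLncrnas entity counts.
#' @param nBlocks number of planted blocks (each rooted in its own
#'   subtree).
#' @param withinProb,backgroundProb association probabilities inside and
#'   outside a matched block.
#' @param nExprSamples expression samples per lncRNA.
#' @param exprNoiseSd standard deviation of expression noise around the
#'   block mean profile.
#' @return Named list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(seed = 1L, nTerms = 60L, maxDepth = 4L,
                          branching = 3L, nDiseases = 25L,
                          nLncrnas = 40L, nBlocks = 5L,
                          withinProb = 0.6, backgroundProb = 0.02,
                          nExprSamples = 20L, exprNoiseSd = 0.5) {
  stopifnot(nTerms >= nBlocks, nDiseases >= nBlocks,
            nLncrnas >= nBlocks, withinProb >= 0, withinProb <= 1,
            backgroundProb >= 0, backgroundProb <= 1,
            maxDepth >= 1, branching >= 1, nExprSamples >= 2)
  structure(list(seed = as.integer(seed), nTerms = as.integer(nTerms),
                 maxDepth = as.integer(maxDepth),
                 branching = as.integer(branching),
                 nDiseases = as.integer(nDiseases),
                 nLncrnas = as.integer(nLncrnas),
                 nBlocks = as.integer(nBlocks),
                 withinProb = withinProb,
                 backgroundProb = backgroundProb,
                 nExprSamples = as.integer(nExprSamples),
                 exprNoiseSd = exprNoiseSd),
            class = "fixtureConfig")
}

#' Generate a MeSH-like term forest
#'
#' Grows \code{nBlocks} rooted subtrees ("C01", "C02", ...) to a total of
#' \code{nTerms} terms by repeatedly attaching a child to a uniformly
#' chosen eligible node (depth below maxDepth, fewer than branching
#' children). Tree numbers follow the dotted MeSH grammar, so the emitted
#' descriptors round-trip byte-exactly through
#' \code{\link{writeMeshAscii}} / \code{\link{parseMeshAscii}}.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @return A \linkS4class{MeshDescriptorSet}; the attribute
#'   \code{"block"} carries each term's subtree index.
#' @export
generateTermForest <- function(cfg) {
  withr::with_seed(cfg$seed, {
    tn <- sprintf("C%02d", seq_len(cfg$nBlocks))
    depth <- rep(1L, cfg$nBlocks)
    block <- seq_len(cfg$nBlocks)
    nChildren <- rep(0L, cfg$nBlocks)
    while (length(tn) < cfg$nTerms) {
      eligible <- which(depth < cfg$maxDepth & nChildren < cfg$branching)
      if (length(eligible) == 0) break
      par <- eligible[sample.int(length(eligible), 1L)]
      nChildren[par] <- nChildren[par] + 1L
      tn <- c(tn, paste0(tn[par], ".",
                         sprintf("%03d", nChildren[par])))
      depth <- c(depth, depth[par] + 1L)
      block <- c(block, block[par])
      nChildren <- c(nChildren, 0L)
    }
  })
  n <- length(tn)
  ds <- new("MeshDescriptorSet",
            heading = sprintf("Synthetic Disease %03d", seq_len(n)),
            uniqueId = sprintf("SYN%06d", seq_len(n)),
            treeNumbers = as.list(tn))
  attr(ds, "block") <- block
  ds
}

#' Generate a block-structured association matrix
#'
#' Diseases are drawn from the term forest so that diseases of a block
#' share a subtree ancestor (DAG-coherent blocks); lncRNAs are assigned to
#' blocks round-robin. A pair associates with probability
#' \code{withinProb} when lncRNA and disease share a block and
#' \code{backgroundProb} otherwise — the planted version of the modelling
#' assumption that functionally similar lncRNAs attach to similar
#' diseases. All-zero rows/columns are resampled once and reported if they
#' persist.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @param forest optional pre-generated term forest (from
#'   \code{\link{generateTermForest}} with the same config).
#' @return A \linkS4class{SyntheticCorpus} (expression filled by
#'   \code{\link{generateCorpus}}; empty matrix here).
#' @export
generateBlockAssociations <- function(cfg, forest = NULL) {
  if (cfg$nBlocks > cfg$nDiseases || cfg$nBlocks > cfg$nLncrnas)
    stop("more blocks than entities")
  if (cfg$nDiseases > cfg$nTerms)
    stop("cannot draw ", cfg$nDiseases, " diseases from ",
         cfg$nTerms, " terms")
  if (is.null(forest)) forest <- generateTermForest(cfg)
  termBlock <- attr(forest, "block")
  withr::with_seed(cfg$seed + 1L, {
    # balanced draw of diseases across block subtrees
    perBlock <- tabulate(rep(seq_len(cfg$nBlocks),
                             length.out = cfg$nDiseases), cfg$nBlocks)
    dIdx <- integer(0); dBlock <- integer(0)
    for (b in seq_len(cfg$nBlocks)) {
      pool <- which(termBlock == b)
      take <- min(perBlock[b], length(pool))
      pick <- pool[sample.int(length(pool), take)]
      dIdx <- c(dIdx, pick); dBlock <- c(dBlock, rep(b, take))
    }
    while (length(dIdx) < cfg$nDiseases) {  # subtree smaller than quota
      extra <- setdiff(seq_along(termBlock), dIdx)
      pick <- extra[sample.int(length(extra), 1L)]
      dIdx <- c(dIdx, pick); dBlock <- c(dBlock, termBlock[pick])
    }
    lBlock <- rep(seq_len(cfg$nBlocks), length.out = cfg$nLncrnas)
    prob <- ifelse(outer(lBlock, dBlock, "=="),
                   cfg$withinProb, cfg$backgroundProb)
    v <- matrix(stats::rbinom(length(prob), 1L, prob),
                nrow = cfg$nLncrnas)
    # one resampling pass for isolated entities
    for (pass in 1:1) {
      zr <- which(rowSums(v) == 0)
      for (i in zr) v[i, ] <- stats::rbinom(ncol(v), 1L, prob[i, ])
      zc <- which(colSums(v) == 0)
      for (j in zc) v[, j] <- stats::rbinom(nrow(v), 1L, prob[, j])
    }
  })
  if (any(rowSums(v) == 0) || any(colSums(v) == 0))
    message("isolated entities remain after resampling: ",
            sum(rowSums(v) == 0), " lncRNA(s), ",
            sum(colSums(v) == 0), " disease(s)")
  assoc <- new("AssociationMatrix",
               lncIds = sprintf("LNC%03d", seq_len(cfg$nLncrnas)),
               diseaseIds = meshHeadings(forest)[dIdx],
               values = v)
  new("SyntheticCorpus", descriptors = forest, association = assoc,
      expression = matrix(numeric(0), 0, 0),
      lncBlocks = as.integer(lBlock), diseaseBlocks = as.integer(dBlock))
}

#' Generate block-coherent expression profiles
#'
#' Each block has a latent mean profile; a lncRNA's profile is its block
#' mean plus Gaussian noise, so same-block lncRNAs have higher expected
#' Spearman similarity. With zero noise same-block profiles are identical.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @param lncBlocks integer block assignment per lncRNA.
#' @return Numeric matrix, one row per lncRNA.
#' @export
generateExpression <- function(cfg, lncBlocks) {
  withr::with_seed(cfg$seed + 2L, {
    means <- matrix(stats::rnorm(cfg$nBlocks * cfg$nExprSamples),
                    nrow = cfg$nBlocks)
    noise <- matrix(stats::rnorm(length(lncBlocks) * cfg$nExprSamples,
                                 sd = cfg$exprNoiseSd),
                    nrow = length(lncBlocks))
    expr <- means[lncBlocks, , drop = FALSE] + noise
  })
  rownames(expr) <- sprintf("LNC%03d", seq_along(lncBlocks))
  colnames(expr) <- sprintf("S%02d", seq_len(cfg$nExprSamples))
  expr
}

#' Generate a complete synthetic corpus
#'
#' Term forest, block-structured association matrix and expression
#' profiles, all deterministic functions of \code{cfg$seed}.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @return A \linkS4class{SyntheticCorpus}.
#' @export
generateCorpus <- function(cfg) {
  corpus <- generateBlockAssociations(cfg)
  corpus@expression <- generateExpression(cfg, corpus@lncBlocks)
  corpus
}

#' Permuted-label null of an association matrix
#'
#' Independently permutes the entries within each disease column: disease
#' degrees are preserved but the alignment between lncRNA blocks and
#' disease blocks is destroyed, giving a null instance for
#' signal-recovery comparisons. (Permuting whole rows would merely relabel
#' lncRNAs, to which the model is invariant.)
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param seed integer seed.
#' @return A permuted \linkS4class{AssociationMatrix}.
#' @export
permuteAssociations <- function(assoc, seed = 1L) {
  stopifnot(is(assoc, "AssociationMatrix"))
  v <- assoc@values
  withr::with_seed(seed, {
    for (j in seq_len(ncol(v))) v[, j] <- v[sample.int(nrow(v)), j]
  })
  new("AssociationMatrix", lncIds = assoc@lncIds,
      diseaseIds = assoc@diseaseIds, values = v)
}
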