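#' @include AllClasses.R
NULL

#' Information content of terms across a collection of disease DAGs
#'
#' A term occurring in few DAGs is specific and informative; one present in
#' every DAG carries no information. IC(t) = -log(N_DAG(t) / TN_DAG) with
#' N_DAG(t) the number of distinct disease DAGs whose node set contains t
#' and TN_DAG the number of DAGs in the collection. The natural log is used;
#' downstream fuzzy densities are ratios of ICs, so the similarity model is
#' invariant to this choice of base.
#'
#' @param dags list of \linkS4class{DiseaseDAG} objects (the disease
#'   universe; typically the diseases of the association table).
#' @param logBase base of the logarithm (default \code{exp(1)}).
#' @return A list with \code{ic} (named numeric, term -> IC), \code{nDag}
#'   (named integer counts) and \code{tnDag} (number of DAGs).
#' @export
computeIC <- function(dags, logBase = exp(1)) {
  if (length(dags) == 0) stop("empty DAG collection")
  stopifnot(all(vapply(dags, is, TRUE, "DiseaseDAG")))
  counts <- table(unlist(lapply(dags, function(d) unique(d@nodes)),
                         use.names = FALSE))
  nDag <- stats::setNames(as.integer(counts), names(counts))
  tn <- length(dags)
  ic <- -log(nDag / tn, base = logBase)
  ic[nDag == tn] <- 0  # exact zero for universal terms
  list(ic = ic, nDag = nDag, tnDag = tn)
}

#' Fuzzy densities of one disease's terms
#'
#' Each term's IC is normalized by the maximum IC over all terms appearing
#' in the dataset's DAGs and scaled by \code{cap}, giving densities in
#' (0, cap]. Universal terms (IC = 0) are pruned: they occur in every DAG
#' and cannot discriminate between diseases. The cap (default 0.999) keeps
#' the globally rarest term's density strictly below 1, which guarantees
#' the Sugeno lambda equation has a bracketed root for every density set.
#'
#' @param icTable result of \code{\link{computeIC}}.
#' @param dag the disease's \linkS4class{DiseaseDAG}.
#' @param cap density cap in (0, 1].
#' @return A \linkS4class{FuzzyDensitySet} with lambda unset
#'   (\code{NA_real_}).
#' @export
computeFuzzyDensity <- function(icTable, dag, cap = 0.999) {
  stopifnot(is(dag, "DiseaseDAG"), cap > 0, cap <= 1)
  ic <- icTable$ic
  if (!all(dag@nodes %in% names(ic)))
    stop("DAG contains terms absent from the IC table")
  maxIC <- max(ic)
  if (maxIC <= 0)
    stop("all terms are universal (max IC = 0); ",
         "a single-disease corpus cannot be normalized -- supply at ",
         "least two diseases with distinct DAGs")
  raw <- ic[dag@nodes] / maxIC
  dens <- cap * raw[raw > 0]
  new("FuzzyDensitySet", diseaseId = dag@diseaseId,
      densities = dens, lambda = NA_real_)
}

# f(lambda) = prod(1 + lambda g_i) - (1 + lambda); root of the Sugeno
# normalization identity.
.lambdaResidual <- function(lam, g) prod(1 + lam * g) - (1 + lam)

#' Solve the Sugeno lambda equation for a density set
#'
#' Finds the unique root lambda > -1 of
#' \eqn{1+\lambda = \prod_i (1+\lambda g_i)} for densities
#' \eqn{g_i \in (0,1)}. When the densities sum to 1 the measure is additive
#' and lambda = 0 exactly; a singleton set likewise gets lambda = 0 (the
#' additive limit, the unique continuous choice for the degenerate
#' one-element equation). Otherwise the root is bracketed — in (-1, 0) when
#' the densities sum above 1, in (0, Inf) when below — and solved by
#' bracketed root-finding with Newton polishing.
#'
#' @param g numeric vector of densities, each strictly in (0,1).
#' @param tol additive-case detection tolerance on |sum(g) - 1|.
#' @return The solved lambda (> -1).
#' @export
solveLambda <- function(g, tol = 1e-12) {
  if (length(g) == 0) stop("empty density set")
  if (any(g <= 0 | g >= 1))
    stop("densities must lie strictly in (0,1)")
  if (length(g) == 1L) return(0)
  s <- sum(g)
  if (abs(s - 1) <= tol) return(0)
  if (s > 1) {
    lo <- -1 + .Machine$double.eps
    hi <- -1e-12
    # With many large densities the root can be squeezed against -1 beyond
    # double resolution; the residual at the closest representable point is
    # then already at machine-precision scale.
    if (.lambdaResidual(lo, g) <= 0) return(lo)
  } else {
    lo <- 1e-12
    hi <- 2
    while (.lambdaResidual(hi, g) < 0) hi <- hi * 2
  }
  lam <- stats::uniroot(.lambdaResidual, c(lo, hi), g = g,
                        tol = .Machine$double.eps^0.75)$root
  # Newton polish to drive the residual to machine precision
  for (k in 1:5) {
    f <- .lambdaResidual(lam, g)
    if (f == 0) break
    fp <- sum(g / (1 + lam * g)) * prod(1 + lam * g) - 1
    if (!is.finite(fp) || fp == 0) break
    step <- f / fp
    cand <- lam - step
    if (cand <= -1) break
    if (abs(.lambdaResidual(cand, g)) < abs(f)) lam <- cand else break
  }
  lam
}

#' Sugeno measure of a subset of densities
#'
#' Evaluates the lambda-measure of a term subset by the recursive
#' combination g(T) = FD(t) + g(T') + lambda FD(t) g(T'): the empty set has
#' measure 0, a singleton the value of its only element. The recursion is
#' order-independent; \code{\link{sugenoClosedForm}} gives the equivalent
#' product form used as a cross-check.
#'
#' @param g numeric vector of densities in (0,1) (possibly empty).
#' @param lambda a Sugeno parameter > -1.
#' @return The measure, a non-negative real.
#' @export
sugenoMeasure <- function(g, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda <= -1)
    stop("lambda must be a single value > -1")
  if (length(g) == 0) return(0)
  if (any(g <= 0 | g >= 1))
    stop("densities must lie strictly in (0,1)")
  acc <- g[[1L]]
  for (x in g[-1L]) acc <- x + acc + lambda * x * acc
  acc
}

#' Product closed form of the Sugeno measure
#'
#' \eqn{(\prod_i (1+\lambda g_i) - 1)/\lambda} for lambda != 0 and
#' \eqn{\sum_i g_i} in the additive limit lambda = 0.
#'
#' @inheritParams sugenoMeasure
#' @return The measure.
#' @export
sugenoClosedForm <- function(g, lambda) {
  if (length(g) == 0) return(0)
  if (lambda == 0) return(sum(g))
  (prod(1 + lambda * g) - 1) / lambda
}

#' Solve lambda for a FuzzyDensitySet
#'
#' @param fds a \linkS4class{FuzzyDensitySet} (lambda may be unset).
#' @return The set with its lambda slot filled.
#' @export
solveDensitySet <- function(fds) {
  stopifnot(is(fds, "FuzzyDensitySet"))
  if (length(fds@densities) == 0) {
    fds@lambda <- 0
    return(fds)
  }
  fds@lambda <- solveLambda(fds@densities)
  fds
}

#' Fuzzy-measure semantic similarity of two diseases
#'
#' The shared terms of the two density sets form the intersection set T_i
#' (densities are globally normalized, so a shared term carries the same
#' density in both). Its Sugeno measure is evaluated once under each
#' disease's own lambda and the two measures are averaged. Disjoint term
#' sets give 0; identical sets give 1 (up to solver tolerance) because the
#' full set has measure 1 under its own lambda by construction.
#'
#' @param a,b \linkS4class{FuzzyDensitySet} objects with solved lambda.
#' @return FS(a, b), a real in [0, 1].
#' @export
diseaseSemanticSimilarity <- function(a, b) {
  stopifnot(is(a, "FuzzyDensitySet"), is(b, "FuzzyDensitySet"))
  if (is.na(a@lambda) || is.na(b@lambda))
    stop("solve lambda before computing similarity")
  shared <- intersect(names(a@densities), names(b@densities))
  if (length(shared) == 0) return(0)
  gi <- a@densities[shared]
  (sugenoMeasure(gi, a@lambda) + sugenoMeasure(gi, b@lambda)) / 2
}

#' Disease semantic similarity matrix
#'
#' Builds the symmetric matrix FS over a list of solved density sets, one
#' row/column per disease, computing each unordered pair once. The diagonal
#' is 1 for every disease with a nonempty density set (and 0 for a disease
#' whose every term was pruned as universal, which is flagged as unscored).
#'
#' @param densitySets named list of solved \linkS4class{FuzzyDensitySet}
#'   objects.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
buildDiseaseSimilarityMatrix <- function(densitySets) {
  stopifnot(length(densitySets) >= 1)
  ids <- vapply(densitySets, function(x) x@diseaseId, "")
  n <- length(ids)
  v <- matrix(0, n, n)
  empty <- vapply(densitySets, function(x) length(x@densities) == 0, TRUE)
  for (i in seq_len(n)) {
    v[i, i] <- if (empty[i]) 0 else 1
    if (i < n) for (j in seq(i + 1L, n)) {
      fs <- diseaseSemanticSimilarity(densitySets[[i]], densitySets[[j]])
      v[i, j] <- v[j, i] <- min(1, fs)
    }
  }
  new("SimilarityMatrix", ids = unname(ids), values = v,
      unscored = unname(ids[empty]))
}

#' End-to-end disease semantic similarity from descriptors
#'
#' Convenience pipeline: build DAGs for the given disease headings, compute
#' IC over that disease universe, derive capped fuzzy densities, solve each
#' disease's lambda and assemble the similarity matrix.
#'
#' @param descriptors a \linkS4class{MeshDescriptorSet}.
#' @param diseases disease headings (default: all descriptors).
#' @param cap density cap, see \code{\link{computeFuzzyDensity}}.
#' @param logBase IC log base, see \code{\link{computeIC}}.
#' @return A \linkS4class{SimilarityMatrix} over \code{diseases}.
#' @export
diseaseSimilarityFromMesh <- function(descriptors,
                                      diseases = meshHeadings(descriptors),
                                      cap = 0.999, logBase = exp(1)) {
  dags <- buildDiseaseDAGs(descriptors, diseases)
  icTable <- computeIC(dags, logBase = logBase)
  sets <- lapply(dags, function(d)
    solveDensitySet(computeFuzzyDensity(icTable, d, cap = cap)))
  buildDiseaseSimilarityMatrix(sets)
}
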