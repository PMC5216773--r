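# Hand-authored five-record MeSH ASCII fixture: four Category C
# descriptors forming a small hierarchy plus one Category D record.
meshFixtureLines <- function() {
  c("*NEWRECORD",
    "MH = Neoplasms",
    "UI = D009369",
    "MN = C04",
    "",
    "*NEWRECORD",
    "MH = Neoplasms by Site",
    "UI = D009371",
    "MN = C04.588",
    "",
    "*NEWRECORD",
    "MH = Lung Neoplasms",
    "UI = D008175",
    "MN = C04.588.894",
    "",
    "*NEWRECORD",
    "MH = Leukemia",
    "UI = D007938",
    "MN = C04.557",
    "",
    "*NEWRECORD",
    "MH = Aspirin",
    "UI = D001241",
    "MN = D02.455",
    "")
}

writeMeshFixture <- function(lines = meshFixtureLines()) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# Descriptor set built directly (no file), for DAG unit tests.
handDescriptors <- function() {
  new("MeshDescriptorSet",
      heading = c("Neoplasms", "Neoplasms by Site", "Lung Neoplasms",
                  "Leukemia"),
      uniqueId = c("D009369", "D009371", "D008175", "D007938"),
      treeNumbers = list("C04", "C04.588", "C04.588.894", "C04.557"))
}

# Random symmetric similarity matrix with unit diagonal and disease names.
randomFS <- function(nDiseases, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(nDiseases^2), nDiseases)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  })
  ids <- sprintf("D%02d", seq_len(nDiseases))
  dimnames(m) <- list(ids, ids)
  m
}

# Random nonempty disease groups over the ids of a similarity matrix.
randomGroups <- function(nLnc, diseaseIds, seed) {
  withr::with_seed(seed, {
    g <- lapply(seq_len(nLnc), function(i)
      sample(diseaseIds, sample.int(min(6, length(diseaseIds)), 1)))
  })
  stats::setNames(g, sprintf("L%02d", seq_len(nLnc)))
}

# Brute-force evaluation of the best-match group average by explicit
# loops; the independent oracle for the functional-similarity code path.
bruteForceGroupSim <- function(gi, gj, fsm) {
  best <- function(d, grp) {
    m <- -Inf
    for (x in grp) m <- max(m, fsm[d, x])
    m
  }
  tot <- 0
  for (d in gi) tot <- tot + best(d, gj)
  for (d in gj) tot <- tot + best(d, gi)
  tot / (length(gi) + length(gj))
}

# Small association matrix built from an explicit binary matrix.
makeAssoc <- function(v, lncIds = sprintf("L%02d", seq_len(nrow(v))),
                      diseaseIds = sprintf("D%02d", seq_len(ncol(v)))) {
  new("AssociationMatrix", lncIds = lncIds, diseaseIds = diseaseIds,
      values = v)
}

# A reduced synthetic corpus for fast pipeline tests.
smallCorpusConfig <- function(seed) {
  fixtureConfig(seed = seed, nTerms = 30L, maxDepth = 3L,
                branching = 3L, nDiseases = 12L, nLncrnas = 16L,
                nBlocks = 3L, withinProb = 0.6, backgroundProb = 0.03,
                nExprSamples = 10L)
}
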