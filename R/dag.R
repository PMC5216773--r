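#' @include AllClasses.R
NULL

# All dotted prefixes of a tree number, shortest first, including itself.
.treePrefixes <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
  vapply(seq_along(parts),
         function(k) paste(parts[seq_len(k)], collapse = "."), "")
}

# Lookup table tree number -> owning heading over a descriptor set.
.treeOwners <- function(descriptors) {
  tn <- unlist(descriptors@treeNumbers, use.names = FALSE)
  owner <- rep(descriptors@heading, lengths(descriptors@treeNumbers))
  stats::setNames(owner, tn)
}

#' Build the disease DAG of one MeSH descriptor
#'
#' Collects the descriptor itself plus every descriptor owning a proper
#' dotted prefix of any of its tree numbers; edges run from the more general
#' term to its one-segment extension. When an intermediate prefix has no
#' descriptor record the level is skipped and the child connects to the
#' nearest resolvable ancestor (a warning reports the gap). A heading
#' reachable through several tree numbers appears once.
#'
#' @param descriptor a single-descriptor \linkS4class{MeshDescriptorSet}
#'   (e.g. \code{all[i]}) or a heading present in \code{allDescriptors}.
#' @param allDescriptors the full \linkS4class{MeshDescriptorSet} used to
#'   resolve ancestors.
#' @return A \linkS4class{DiseaseDAG}.
#' @export
buildDiseaseDAG <- function(descriptor, allDescriptors) {
  stopifnot(is(allDescriptors, "MeshDescriptorSet"))
  if (is.character(descriptor)) {
    i <- match(descriptor, allDescriptors@heading)
    if (is.na(i)) stop("descriptor '", descriptor,
                       "' not found in the descriptor set")
    descriptor <- allDescriptors[i]
  }
  stopifnot(is(descriptor, "MeshDescriptorSet"),
            length(descriptor) == 1L)
  if (!descriptor@heading %in% allDescriptors@heading)
    stop("descriptor '", descriptor@heading,
         "' not present in allDescriptors")
  owners <- .treeOwners(allDescriptors)
  nodes <- descriptor@heading
  edges <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  for (tn in descriptor@treeNumbers[[1L]]) {
    prefixes <- .treePrefixes(tn)
    lastOwner <- NA_character_
    for (p in prefixes) {
      own <- owners[p]
      if (is.na(own)) {
        if (p != tn)
          warning("no descriptor owns tree position ", p,
                  "; level skipped", call. = FALSE)
        next
      }
      own <- unname(own)
      nodes <- union(nodes, own)
      if (!is.na(lastOwner) && lastOwner != own)
        edges <- rbind(edges, c(lastOwner, own))
      lastOwner <- own
    }
  }
  edges <- unique(edges)
  new("DiseaseDAG", diseaseId = descriptor@heading, nodes = nodes,
      edges = edges)
}

#' Build disease DAGs for a set of headings
#'
#' @param headings disease headings to build DAGs for; defaults to every
#'   descriptor in the set.
#' @param allDescriptors the full \linkS4class{MeshDescriptorSet}.
#' @return Named list of \linkS4class{DiseaseDAG} objects.
#' @export
buildDiseaseDAGs <- function(allDescriptors,
                             headings = meshHeadings(allDescriptors)) {
  dags <- lapply(headings, buildDiseaseDAG,
                 allDescriptors = allDescriptors)
  stats::setNames(dags, headings)
}

#' Write a disease DAG as edge-list and node-membership TSVs
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param edgePath path for the `child<TAB>parent` edge list.
#' @param nodePath optional path for the one-column node membership file.
#' @return \code{edgePath}, invisibly.
#' @export
writeDagEdges <- function(dag, edgePath, nodePath = NULL) {
  stopifnot(is(dag, "DiseaseDAG"))
  df <- data.frame(child = dag@edges[, "child"],
                   parent = dag@edges[, "parent"])
  utils::write.table(df, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nodePath))
    writeLines(c("node", dag@nodes), nodePath)
  invisible(edgePath)
}
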