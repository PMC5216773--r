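#' @include AllClasses.R
NULL

#' Parse a MeSH ASCII descriptor file
#'
#' Reads the `*NEWRECORD` / `KEY = value` ASCII layout of a MeSH descriptor
#' export (the d####.bin format) and keeps descriptors that carry at least
#' one tree number in the requested category. Tree numbers outside the
#' category are dropped from retained descriptors, so a descriptor filed
#' both under diseases (C...) and elsewhere keeps only its disease
#' positions. Records with an MH heading but no well-formed MN line are
#' skipped with a warning rather than aborting the parse.
#'
#' @param path path to the MeSH ASCII file.
#' @param categoryPrefix single-letter category to retain; \code{"C"}
#'   (diseases) by default.
#' @return A \linkS4class{MeshDescriptorSet}.
#' @examples
#' tmp <- tempfile()
#' writeLines(c("*NEWRECORD", "MH = Neoplasms", "UI = D009369",
#'              "MN = C04"), tmp)
#' parseMeshAscii(tmp)
#' @export
parseMeshAscii <- function(path, categoryPrefix = "C") {
  if (!file.exists(path)) stop("cannot read MeSH file: ", path)
  stopifnot(is.character(categoryPrefix), nchar(categoryPrefix) >= 1)
  lines <- readLines(path, warn = FALSE)
  starts <- c(which(lines == "*NEWRECORD"), length(lines) + 1L)
  heading <- character(0); uid <- character(0); tns <- list()
  skipped <- 0L
  for (r in seq_len(length(starts) - 1L)) {
    block <- lines[seq(starts[r] + 1L, starts[r + 1L] - 1L)]
    kv <- regmatches(block, regexec("^([A-Z ]+?) = (.*)$", block))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else "", "")
    mh <- vals[keys == "MH"]
    ui <- vals[keys == "UI"]
    mn <- vals[keys == "MN"]
    if (length(mh) == 0) next
    bad <- !grepl(.TREE_NUMBER_RE, mn)
    if (length(mn) > 0 && any(bad)) {
      skipped <- skipped + 1L
      warning("record '", mh[1], "' has malformed MN line(s); skipped",
              call. = FALSE)
      next
    }
    keep <- mn[startsWith(mn, categoryPrefix)]
    if (length(keep) == 0) next
    heading <- c(heading, mh[1])
    uid <- c(uid, if (length(ui) > 0) ui[1] else paste0("UI:", mh[1]))
    tns <- c(tns, list(unname(keep)))
  }
  new("MeshDescriptorSet", heading = heading, uniqueId = uid,
      treeNumbers = tns)
}

#' Write a MeshDescriptorSet in MeSH ASCII layout
#'
#' Emits `*NEWRECORD` blocks with MH/UI/MN lines that
#' \code{\link{parseMeshAscii}} reads back byte-exactly; used both for
#' exporting and for round-trip testing of synthetic fixtures.
#'
#' @param descriptors a \linkS4class{MeshDescriptorSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMeshAscii <- function(descriptors, path) {
  stopifnot(is(descriptors, "MeshDescriptorSet"))
  out <- character(0)
  for (i in seq_along(descriptors@heading)) {
    out <- c(out, "*NEWRECORD",
             paste0("MH = ", descriptors@heading[i]),
             paste0("UI = ", descriptors@uniqueId[i]),
             paste0("MN = ", descriptors@treeNumbers[[i]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

.normalizeName <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Map raw disease names onto MeSH headings
#'
#' Matching is exact after trimming, collapsing internal whitespace and
#' case-folding; no fuzzy matching is attempted, so a miss is always
#' surfaced in \code{unmapped} rather than silently resolved to a wrong
#' heading.
#'
#' @param rawNames character vector of disease names as they appear in an
#'   association table.
#' @param descriptors a \linkS4class{MeshDescriptorSet}.
#' @return A list with \code{mapped} (named character vector, raw name ->
#'   heading) and \code{unmapped} (character vector of unmatched names).
#' @export
mapDiseaseNames <- function(rawNames, descriptors) {
  stopifnot(is(descriptors, "MeshDescriptorSet"))
  if (any(!nzchar(trimws(rawNames))))
    stop("empty disease name in input")
  key <- .normalizeName(descriptors@heading)
  idx <- match(.normalizeName(rawNames), key)
  hit <- !is.na(idx)
  list(mapped = stats::setNames(descriptors@heading[idx[hit]],
                                rawNames[hit]),
       unmapped = rawNames[!hit])
}
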