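# Ordered-SMARTS structure tagging.
#
# Tag tables are TSV files with header columns SMARTS, TagName and
# TagSetName. One execution uses exactly one tag set; patterns are
# applied to each molecule in file order. Substructure matching is
# delegated to the OpenBabel engine (ChemmineR/ChemmineOB) with its
# default aromaticity perception.

#' @rdname TagSet-accessors
setMethod("tagSetName", "TagSet", function(x) x@name)
#' @rdname TagSet-accessors
setMethod("tagDefinitions", "TagSet", function(x) x@definitions)

#' Accessors for TagSet objects
#'
#' @param x a [TagSet-class].
#' @name TagSet-accessors
NULL

setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet '%s' (%d definitions)\n", object@name,
              nrow(object@definitions)))
  for (i in seq_len(nrow(object@definitions)))
    cat(sprintf("  %2d. %-24s %s\n", i, object@definitions$tagName[i],
                object@definitions$smarts[i]))
})

# cached single-molecule SDFset used to validate SMARTS patterns
probeSDFset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- sdRecord(title = "probe",
                      atoms = data.frame(elem = c("C", "H"),
                                         x = c(0, 1.09), y = 0, z = 0,
                                         charge = 0L),
                      bonds = data.frame(a1 = 1L, a2 = 2L, order = 1L))
      cache <<- recordToSDFset(rec)
    }
    cache
  }
})

validSmarts <- function(pattern) {
  !inherits(try(suppressWarnings(
    ChemmineR::smartsSearchOB(probeSDFset(), pattern,
                              uniqueMatches = FALSE)), silent = TRUE),
    "try-error")
}

#' Load one tag set from a tag table
#'
#' @param table a tag table: a data.frame (or TSV file path readable
#'   by [readTab()]) with columns `SMARTS`, `TagName`, `TagSetName`.
#' @param setName which tag set to load; rows are kept in file order.
#' @return A [TagSet-class] with all SMARTS validated.
#' @examples
#' tab <- data.frame(SMARTS = "c1ccccc1", TagName = "Aryl",
#'                   TagSetName = "main")
#' loadTags(tab, "main")
#' @export
loadTags <- function(table, setName) {
  if (is.character(table)) table <- readTab(table)
  need <- c("SMARTS", "TagName", "TagSetName")
  if (!all(need %in% names(table)))
    stop("tag table must have columns ", paste(need, collapse = ", "))
  sets <- unique(table$TagSetName)
  rows <- which(table$TagSetName == setName)
  if (length(rows) == 0L)
    stop(sprintf("unknown tag set '%s'; available sets: %s", setName,
                 paste(sets, collapse = ", ")))
  for (r in rows)
    if (!validSmarts(table$SMARTS[r]))
      stop(sprintf("invalid SMARTS in row %d: %s", r, table$SMARTS[r]))
  new("TagSet", name = setName,
      definitions = data.frame(smarts = table$SMARTS[rows],
                               tagName = table$TagName[rows],
                               stringsAsFactors = FALSE))
}

#' Tag records with an ordered SMARTS set
#'
#' Applies the tag set's SMARTS to each molecule in definition order.
#' In `first` mode the tag of the first matching pattern is written to
#' `firstField`; in `all` mode the tags of every matching pattern,
#' joined by `"; "` in definition order (duplicate tag names reported
#' once), are written to `allField`; `both` writes both fields. A
#' molecule matching no pattern passes through with no field added.
#' Records whose molecule cannot be handed to the matcher (including
#' data-only records) pass through untagged with a warning.
#'
#' @param records a `RecordStream` or list of records.
#' @param tagSet a [TagSet-class] from [loadTags()].
#' @param mode `"first"`, `"all"`, or `"both"`.
#' @param firstField field name for the first match.
#' @param allField field name for all matches.
#' @return A lazy `RecordStream`; output count equals input count.
#' @export
tagRecords <- function(records, tagSet, mode = c("first", "all", "both"),
                       firstField = "StructureTag",
                       allField = "AllStructureTags") {
  mode <- match.arg(mode)
  defs <- tagDefinitions(tagSet)
  streamMap(records, function(rec, i) {
    sdf <- if (atomCount(rec) > 0L) recordToSDFset(rec) else NULL
    if (is.null(sdf)) {
      warning(sprintf("record %d: no usable molecule; passed untagged", i))
      return(rec)
    }
    hits <- logical(nrow(defs))
    for (d in seq_len(nrow(defs))) {
      cnt <- tryCatch(suppressWarnings(
        ChemmineR::smartsSearchOB(sdf, defs$smarts[d],
                                  uniqueMatches = FALSE)),
        error = function(e) NA)
      if (is.na(cnt)) {
        warning(sprintf("record %d: matcher failed; passed untagged", i))
        return(rec)
      }
      hits[d] <- cnt > 0
      if (hits[d] && mode == "first") break
    }
    if (!any(hits)) return(rec)
    if (mode %in% c("first", "both"))
      sdField(rec, firstField) <- defs$tagName[which(hits)[1L]]
    if (mode %in% c("all", "both"))
      sdField(rec, allField) <-
        paste(unique(defs$tagName[hits]), collapse = "; ")
    rec
  })
}
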