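# Tab-delimited tables and SD/tab merging.
#
# Tables are plain character data.frames with a mandatory header row.
# Parsing is strict: every row must have exactly as many cells as the
# header, and cells may not contain the delimiter.

#' Read a tab-delimited table
#'
#' @param input file path, character vector of lines, or connection.
#' @return A character `data.frame`; zero rows for a header-only file.
#' @export
readTab <- function(input) {
  src <- lineSource(input)
  lines <- character()
  repeat {
    ln <- src$nextLine()
    if (is.null(ln)) break
    lines[[length(lines) + 1L]] <- ln
  }
  if (length(lines) == 0L) stop("empty input: missing header row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops an empty trailing cell; restore from delimiter count
  want <- vapply(lines, function(l)
    lengths(gregexpr("\t", l, fixed = TRUE))[
      nchar(gsub("[^\t]", "", l)) >= 0] , 1L)
  want <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  cells <- lapply(seq_along(cells), function(i) {
    v <- cells[[i]]
    if (length(v) < want[i]) c(v, rep("", want[i] - length(v))) else v
  })
  header <- cells[[1L]]
  ncol <- length(header)
  for (i in seq_along(cells)[-1L]) {
    if (length(cells[[i]]) != ncol)
      stop(sprintf("ragged row at line %d: %d cells, header has %d",
                   i, length(cells[[i]]), ncol))
  }
  if (length(cells) == 1L) {
    tab <- as.data.frame(matrix(character(), nrow = 0L, ncol = ncol),
                         stringsAsFactors = FALSE)
    names(tab) <- header
    return(tab)
  }
  body <- do.call(rbind, cells[-1L])
  tab <- as.data.frame(body, stringsAsFactors = FALSE)
  names(tab) <- header
  rownames(tab) <- NULL
  tab
}

#' Write a tab-delimited table
#'
#' @param table a `data.frame`; all columns are written as character.
#' @param output file path or writable connection.
#' @return The number of data rows written, invisibly.
#' @export
writeTab <- function(table, output = stdout()) {
  mat <- as.matrix(format(table, trim = TRUE, justify = "none"))
  mode(mat) <- "character"
  if (nrow(table) == 0L) mat <- matrix(character(), 0L, ncol(table))
  cells <- c(names(table), t(mat))
  if (any(grepl("[\t\n]", cells)))
    stop("cells may not contain tab or newline characters")
  lines <- c(paste(names(table), collapse = "\t"),
             apply(mat, 1L, paste, collapse = "\t"))
  if (is.character(output)) {
    con <- file(output, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
  } else con <- output
  writeLines(lines, con)
  invisible(nrow(table))
}

#' Merge a tab-delimited table into an SD record stream
#'
#' For each record whose `sdKey` field equals some row's `tabKey`
#' cell, all other columns of that row are added as data fields
#' (column name becomes field name). With `mode = "keep_all"`,
#' unmatched records pass through unchanged; with
#' `mode = "matched_only"` they are dropped. Records lacking the
#' `sdKey` field are treated as unmatched.
#'
#' Duplicate keys in the table are resolved by first occurrence (with
#' a warning); a tab column colliding with an existing SD field
#' overwrites the field value in place (with a warning).
#'
#' @param records a `RecordStream` or list of records.
#' @param table a character `data.frame` as from [readTab()].
#' @param sdKey name of the SD field holding the join key.
#' @param tabKey name of the table column holding the join key.
#' @param mode `"keep_all"` or `"matched_only"`.
#' @return A lazy `RecordStream`.
#' @export
mergeTab <- function(records, table, sdKey, tabKey,
                     mode = c("keep_all", "matched_only")) {
  mode <- match.arg(mode)
  if (!tabKey %in% names(table))
    stop(sprintf("table has no column '%s' (columns: %s)", tabKey,
                 paste(names(table), collapse = ", ")))
  keys <- as.character(table[[tabKey]])
  if (anyDuplicated(keys)) {
    warning("duplicate keys in table; first occurrence wins")
    first <- !duplicated(keys)
    table <- table[first, , drop = FALSE]
    keys <- keys[first]
  }
  valueCols <- setdiff(names(table), tabKey)
  streamMap(records, function(rec, i) {
    k <- sdField(rec, sdKey)
    row <- if (!is.na(k)) match(k, keys) else NA_integer_
    if (is.na(row)) {
      if (mode == "keep_all") rec else NULL
    } else {
      existing <- names(sdFields(rec))
      for (col in valueCols) {
        if (col %in% existing)
          warning(sprintf(
            "record %d: field '%s' overwritten by table column", i, col))
        sdField(rec, col) <- table[[col]][row]
      }
      rec
    }
  })
}
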