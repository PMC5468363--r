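# Streaming SD-file input/output.
#
# The reader consumes input incrementally (constant memory per record)
# and preserves data-field order and multi-line values verbatim. The
# writer emits a canonical V2000 serialization, so write -> read ->
# write is byte-stable. Only the V2000 dialect is supported; V3000
# input raises an error. Line endings are normalized to "\n" on read
# and written as "\n".

# Buffered line source over a connection or a character vector.
lineSource <- function(input) {
  if (is.character(input) && length(input) == 1L && !grepl("\n", input) &&
      file.exists(input)) {
    con <- file(input, open = "r", encoding = "UTF-8")
    owned <- TRUE
  } else if (is.character(input)) {
    lines <- unlist(strsplit(paste(input, collapse = "\n"), "\n",
                             fixed = TRUE), use.names = FALSE)
    i <- 0L
    return(list(nextLine = function() {
      if (i >= length(lines)) return(NULL)
      i <<- i + 1L
      lines[[i]]
    }, close = function() invisible()))
  } else if (inherits(input, "connection")) {
    con <- input
    if (!isOpen(con)) { open(con, "r"); owned <- TRUE } else owned <- FALSE
  } else stop("input must be a file path, character vector, or connection")
  buf <- character()
  pos <- 0L
  done <- FALSE
  list(
    nextLine = function() {
      if (pos >= length(buf)) {
        if (done) return(NULL)
        buf <<- readLines(con, n = 512L, warn = FALSE)
        pos <<- 0L
        if (length(buf) == 0L) {
          done <<- TRUE
          if (owned) try(close(con), silent = TRUE)
          return(NULL)
        }
      }
      pos <<- pos + 1L
      sub("\r$", "", buf[[pos]])
    },
    close = function() if (owned) try(close(con), silent = TRUE)
  )
}

parseDataItems <- function(lines, rec) {
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      m <- regmatches(ln, regexpr("<[^>]*>", ln))
      if (length(m) == 0L) stop("malformed data header: ", ln)
      name <- substr(m, 2L, nchar(m) - 1L)
      vals <- character()
      i <- i + 1L
      while (i <= n && nzchar(lines[[i]])) {
        vals <- c(vals, lines[[i]])
        i <- i + 1L
      }
      rec@fields[[name]] <- paste(vals, collapse = "\n")
    }
    i <- i + 1L
  }
  rec
}

parseMolblock <- function(lines, index) {
  if (length(lines) < 4L)
    stop(sprintf("truncated molblock in record %d", index))
  counts <- lines[[4L]]
  if (grepl("V3000", counts, fixed = TRUE))
    stop(sprintf("record %d is a V3000 molblock; only V2000 is supported",
                 index))
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("unparsable counts line in record %d", index))
  if (length(lines) < 4L + natoms + nbonds)
    stop(sprintf("truncated molblock in record %d", index))
  atoms <- emptyAtomTable()
  if (natoms > 0L) {
    al <- lines[5:(4L + natoms)]
    atoms <- data.frame(
      elem = trimws(substr(al, 32L, 34L)),
      x = as.numeric(substr(al, 1L, 10L)),
      y = as.numeric(substr(al, 11L, 20L)),
      z = as.numeric(substr(al, 21L, 30L)),
      charge = 0L, stringsAsFactors = FALSE)
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
        any(atoms$elem == ""))
      stop(sprintf("unparsable atom block in record %d", index))
  }
  bonds <- emptyBondTable()
  if (nbonds > 0L) {
    bl <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1L, 3L)),
      a2 = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L)),
      stringsAsFactors = FALSE)
    if (anyNA(bonds$a1) || anyNA(bonds$a2))
      stop(sprintf("unparsable bond block in record %d", index))
  }
  # properties block: only M CHG is interpreted
  rest <- if (length(lines) > 4L + natoms + nbonds)
    lines[(5L + natoms + nbonds):length(lines)] else character()
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    nn <- as.integer(substr(ln, 7L, 9L))
    for (g in seq_len(nn)) {
      off <- 10L + (g - 1L) * 8L
      ai <- as.integer(substr(ln, off, off + 3L))
      ch <- as.integer(substr(ln, off + 4L, off + 7L))
      if (!is.na(ai) && ai >= 1L && ai <= nrow(atoms)) atoms$charge[ai] <- ch
    }
  }
  sdRecord(title = lines[[1L]], atoms = atoms, bonds = bonds)
}

#' Read an SD file as a lazy record stream
#'
#' Records are parsed one at a time as the stream is pulled; the input
#' is never materialized whole. Data items introduced by `> <name>`
#' headers (the indexed `>  <name>  (1)` form is also accepted) are
#' attached in file order; multi-line values are preserved up to the
#' blank-line terminator. A chunk carrying data items but no molblock
#' is returned as a data-only record (zero atoms) with a warning.
#'
#' @param input file path, character vector of lines, or connection.
#' @return A `RecordStream` of [SDRecord-class] objects.
#' @seealso [writeSD()], [streamCollect()]
#' @examples
#' f <- tempfile(fileext = ".sdf")
#' writeSD(sdRecord(title = "m", fields = list(MW = "16.04")), f)
#' recs <- streamCollect(readSD(f))
#' sdField(recs[[1]], "MW")
#' @export
readSD <- function(input) {
  src <- lineSource(input)
  index <- 0L
  exhausted <- FALSE
  newStream(function() {
    if (exhausted) return(NULL)
    chunk <- character()
    repeat {
      ln <- src$nextLine()
      if (is.null(ln)) {
        exhausted <<- TRUE
        break
      }
      if (ln == "$$$$") break
      chunk[[length(chunk) + 1L]] <- ln
    }
    nonblank <- which(nzchar(trimws(chunk)))
    if (length(nonblank) == 0L) {
      if (exhausted) return(NULL)
      # empty record chunk between delimiters: empty record
      index <<- index + 1L
      return(sdRecord())
    }
    index <<- index + 1L
    first <- chunk[[nonblank[1L]]]
    if (startsWith(first, ">")) {
      warning(sprintf(
        "record %d has data items but no molblock; data-only record",
        index))
      return(parseDataItems(chunk, sdRecord()))
    }
    mend <- which(chunk == "M  END")
    molLines <- if (length(mend)) chunk[seq_len(mend[1L])] else chunk
    rec <- parseMolblock(molLines, index)
    rest <- if (length(mend) && mend[1L] < length(chunk))
      chunk[(mend[1L] + 1L):length(chunk)] else character()
    parseDataItems(rest, rec)
  })
}

formatMolblock <- function(rec, index) {
  na <- nrow(rec@atoms)
  nb <- nrow(rec@bonds)
  if (na > 999L || nb > 999L)
    stop(sprintf("record %d ('%s') is not representable in V2000 (>999 atoms or bonds)",
                 index, rec@title))
  out <- c(rec@title, "  sdpipe          3D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  if (na > 0L)
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      rec@atoms$x, rec@atoms$y, rec@atoms$z, rec@atoms$elem))
  if (nb > 0L)
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          rec@bonds$a1, rec@bonds$a2, rec@bonds$order))
  charged <- which(rec@atoms$charge != 0L)
  while (length(charged) > 0L) {
    grp <- charged[seq_len(min(8L, length(charged)))]
    charged <- charged[-seq_len(min(8L, length(charged)))]
    out <- c(out, paste0(sprintf("M  CHG%3d", length(grp)),
                         paste0(sprintf("%4d%4d", grp,
                                        rec@atoms$charge[grp]),
                                collapse = "")))
  }
  c(out, "M  END")
}

#' Write records to an SD file
#'
#' Emits, per record: the molblock, then for each field a `> <name>`
#' header, the value lines, a blank line, and finally `$$$$`. Field
#' order is preserved exactly as stored; long value lines are written
#' unwrapped to keep the round trip faithful.
#'
#' @param records a `RecordStream`, list of records, or single
#'   [SDRecord-class].
#' @param output file path or writable connection (default stdout).
#' @return The number of records written, invisibly.
#' @export
writeSD <- function(records, output = stdout()) {
  stream <- asRecordStream(records)
  if (is.character(output)) {
    con <- file(output, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
  } else con <- output
  count <- 0L
  repeat {
    rec <- streamNext(stream)
    if (is.null(rec)) break
    count <- count + 1L
    lines <- formatMolblock(rec, count)
    for (nm in names(rec@fields)) {
      lines <- c(lines, paste0("> <", nm, ">"),
                 unlist(strsplit(rec@fields[[nm]], "\n", fixed = TRUE)),
                 "")
    }
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(count)
}

#' Serialize records to a character vector of SD lines
#'
#' @param records records as for [writeSD()].
#' @return Character vector of lines.
#' @export
sdLines <- function(records) {
  tc <- textConnection("sdtxt", open = "w", local = TRUE)
  writeSD(records, tc)
  close(tc)
  sdtxt
}
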