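# Lazy record streams.
#
# A RecordStream is a closure-based iterator: calling streamNext()
# returns the next SDRecord or NULL when exhausted. Streams are the
# unit of composition for pipeline stages; they guarantee that reading
# N records from a source of M > N records never materializes more
# than N + 1 records.

#' Create a record stream from a generator function
#'
#' @param nextFn a function of no arguments returning the next
#'   [SDRecord-class] or `NULL` when the stream is exhausted.
#' @return A `RecordStream` object.
#' @export
newStream <- function(nextFn) {
  stopifnot(is.function(nextFn))
  structure(list(nextRec = nextFn), class = "RecordStream")
}

#' @export
print.RecordStream <- function(x, ...) {
  cat("RecordStream (lazy)\n")
  invisible(x)
}

#' Advance a stream
#'
#' @param stream a `RecordStream`.
#' @return The next [SDRecord-class], or `NULL` at end of stream.
#' @export
streamNext <- function(stream) stream$nextRec()

#' Coerce a list of records (or a stream) to a stream
#'
#' @param x a `RecordStream`, a list of [SDRecord-class] objects, or a
#'   single [SDRecord-class].
#' @return A `RecordStream`.
#' @export
asRecordStream <- function(x) {
  if (inherits(x, "RecordStream")) return(x)
  if (is(x, "SDRecord")) x <- list(x)
  stopifnot(is.list(x))
  i <- 0L
  newStream(function() {
    if (i >= length(x)) return(NULL)
    i <<- i + 1L
    x[[i]]
  })
}

#' Materialize a stream
#'
#' @param stream a `RecordStream` (or a list, returned unchanged).
#' @param n maximum number of records to pull (default all).
#' @return A list of [SDRecord-class] objects.
#' @export
streamCollect <- function(stream, n = Inf) {
  if (is.list(stream) && !inherits(stream, "RecordStream")) return(stream)
  out <- list()
  while (length(out) < n) {
    r <- streamNext(stream)
    if (is.null(r)) break
    out[[length(out) + 1L]] <- r
  }
  out
}

#' Lazily map a function over a stream
#'
#' `f` is called as `f(record, ordinal)` and may return a single
#' record, a list of records (fan-out), or `NULL` (drop).
#'
#' @param stream a `RecordStream` or list.
#' @param f the per-record function.
#' @return A `RecordStream`.
#' @export
streamMap <- function(stream, f) {
  stream <- asRecordStream(stream)
  pending <- list()
  ordinal <- 0L
  newStream(function() {
    repeat {
      if (length(pending) > 0L) {
        r <- pending[[1L]]
        pending <<- pending[-1L]
        return(r)
      }
      rec <- streamNext(stream)
      if (is.null(rec)) return(NULL)
      ordinal <<- ordinal + 1L
      res <- f(rec, ordinal)
      if (is.null(res)) next
      if (is(res, "SDRecord")) return(res)
      pending <<- res
    }
  })
}
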