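#' Accessors for SDRecord objects
#'
#' @param x an [SDRecord-class].
#' @param name field name.
#' @param names character vector of field names to remove.
#' @param value replacement value.
#' @return `sdField` returns the field value as a character scalar, or
#'   `NA_character_` if absent. `sdFields` returns the named list of
#'   fields in file order. `coords` returns an n x 3 numeric matrix.
#' @details Setting a field that already exists replaces its value in
#'   place: the field keeps its position in the record. Setting a new
#'   field appends it.
#' @examples
#' r <- sdRecord(title = "m", fields = list(a = "1", b = "2"))
#' sdField(r, "a") <- "9"   # replaced in place, order kept
#' names(sdFields(r))
#' @name SDRecord-accessors
NULL

#' @rdname SDRecord-accessors
setMethod("sdTitle", "SDRecord", function(x) x@title)

#' @rdname SDRecord-accessors
setMethod("sdTitle<-", "SDRecord", function(x, value) {
  x@title <- as.character(value)[1L]
  x
})

#' @rdname SDRecord-accessors
setMethod("sdFields", "SDRecord", function(x) x@fields)

#' @rdname SDRecord-accessors
setMethod("sdField", "SDRecord", function(x, name) {
  v <- x@fields[[name]]
  if (is.null(v)) NA_character_ else v
})

#' @rdname SDRecord-accessors
setMethod("sdField<-", "SDRecord", function(x, name, value) {
  x@fields[[name]] <- as.character(value)[1L]
  x
})

#' @rdname SDRecord-accessors
setMethod("dropFields", "SDRecord", function(x, names) {
  x@fields <- x@fields[setdiff(base::names(x@fields), names)]
  x
})

#' @rdname SDRecord-accessors
setMethod("atomCount", "SDRecord", function(x) nrow(x@atoms))

#' @rdname SDRecord-accessors
setMethod("bondCount", "SDRecord", function(x) nrow(x@bonds))

#' @rdname SDRecord-accessors
setMethod("atomTable", "SDRecord", function(x) x@atoms)

#' @rdname SDRecord-accessors
setMethod("bondTable", "SDRecord", function(x) x@bonds)

#' @rdname SDRecord-accessors
setMethod("coords", "SDRecord", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname SDRecord-accessors
setMethod("coords<-", "SDRecord", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms),
            ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  x
})

setMethod("show", "SDRecord", function(object) {
  cat(sprintf("SDRecord '%s': %d atoms, %d bonds, %d fields\n",
              object@title, nrow(object@atoms), nrow(object@bonds),
              length(object@fields)))
  if (length(object@fields)) {
    nm <- names(object@fields)
    preview <- vapply(object@fields, function(v)
      substr(gsub("\n", " | ", v), 1L, 40L), "")
    for (i in seq_along(nm))
      cat(sprintf("  %s: %s\n", nm[i], preview[i]))
  }
})

#' Compare two records on the round-trip contract
#'
#' Equality on title, atom and bond counts, elements, bond orders and
#' the ordered field list; coordinates compared to a tolerance.
#'
#' @param a,b [SDRecord-class] objects.
#' @param tol coordinate tolerance in Angstrom (V2000 stores 4
#'   decimals).
#' @return `TRUE` or `FALSE`.
#' @export
sameRecord <- function(a, b, tol = 5e-5) {
  isTRUE(a@title == b@title) &&
    nrow(a@atoms) == nrow(b@atoms) &&
    nrow(a@bonds) == nrow(b@bonds) &&
    identical(a@atoms$elem, b@atoms$elem) &&
    identical(a@bonds$a1, b@bonds$a1) &&
    identical(a@bonds$a2, b@bonds$a2) &&
    identical(a@bonds$order, b@bonds$order) &&
    identical(names(a@fields), names(b@fields)) &&
    identical(unname(unlist(a@fields)), unname(unlist(b@fields))) &&
    (nrow(a@atoms) == 0L || max(abs(coords(a) - coords(b))) <= tol)
}
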