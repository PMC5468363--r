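# Record-stream pipelines.
#
# A Pipeline composes stages left to right. Running in-process is the
# left-fold of the stage transforms over a lazy stream; compiling
# yields the equivalent shell pipe, which produces byte-identical SD
# output when executed with the package CLI on the same input.

#' @rdname Pipeline-accessors
setMethod("stageName", "PipelineStage", function(x) x@name)
#' @rdname Pipeline-accessors
setMethod("pipelineStages", "Pipeline", function(x) x@stages)

#' Accessors for pipelines and stages
#'
#' @param x a [Pipeline-class] or [PipelineStage-class].
#' @name Pipeline-accessors
NULL

setMethod("show", "PipelineStage", function(object) {
  cat(sprintf("PipelineStage '%s'%s\n  cmd: %s\n", object@name,
              if (object@recordIndependent) " [record-independent]" else "",
              if (nzchar(object@commandText)) object@commandText else
                "<in-process only>"))
})

setMethod("show", "Pipeline", function(object) {
  cat(sprintf("Pipeline (%d stages)\n", length(object@stages)))
  for (s in object@stages) cat("  -", s@name, "\n")
})

#' Construct a pipeline stage
#'
#' @param name stage name.
#' @param transform `function(stream) -> stream`.
#' @param commandText equivalent shell invocation (empty string for
#'   stages that cannot be compiled).
#' @param recordIndependent does each output record depend on exactly
#'   one input record?
#' @return A [PipelineStage-class].
#' @export
pipelineStage <- function(name, transform, commandText = "",
                          recordIndependent = FALSE) {
  new("PipelineStage", name = name, transform = transform,
      commandText = commandText,
      recordIndependent = isTRUE(recordIndependent))
}

#' Construct a record-wise stage
#'
#' Wraps a per-record function `f(record, ordinal)` (returning a
#' record, a list of records, or `NULL`) into a stage; errors raised
#' by `f` abort the run naming the stage and the record ordinal.
#'
#' @inheritParams pipelineStage
#' @param f the per-record function.
#' @return A [PipelineStage-class] with `recordIndependent = TRUE`.
#' @export
recordStage <- function(name, f, commandText = "") {
  pipelineStage(name, transform = function(stream)
    streamMap(stream, function(rec, i)
      tryCatch(f(rec, i), error = function(e)
        stop(sprintf("stage '%s' failed at record %d: %s", name, i,
                     conditionMessage(e)), call. = FALSE))),
    commandText = commandText, recordIndependent = TRUE)
}

#' Assemble a pipeline
#'
#' @param ... [PipelineStage-class] objects (or a single list of
#'   them).
#' @return A [Pipeline-class].
#' @export
sdPipeline <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.list(stages[[1L]]) &&
      !is(stages[[1L]], "PipelineStage"))
    stages <- stages[[1L]]
  new("Pipeline", stages = stages)
}

#' Run a pipeline in-process
#'
#' The left-fold of the stage transforms over the input; evaluation
#' is lazy end-to-end, so the first output record is available
#' without exhausting the input.
#'
#' @param pipeline a [Pipeline-class].
#' @param records a `RecordStream` or list of records.
#' @return A lazy `RecordStream`.
#' @export
runPipeline <- function(pipeline, records) {
  stream <- asRecordStream(records)
  for (stage in pipeline@stages) stream <- stage@transform(stream)
  stream
}

#' Compile a pipeline to shell text
#'
#' Stage commands joined by `" \\\n | "`. Executed in a POSIX shell
#' with the package command-line interface available, the text reads
#' the same SD input on stdin and writes byte-identical SD output to
#' stdout as [runPipeline()].
#'
#' @param pipeline a [Pipeline-class].
#' @return A single string of shell text.
#' @export
compilePipeline <- function(pipeline) {
  txt <- vapply(pipeline@stages, function(s) s@commandText, "")
  missing <- !nzchar(txt)
  if (any(missing))
    stop("stage(s) without command text: ",
         paste(vapply(pipeline@stages[missing], stageName, ""),
               collapse = ", "))
  paste(txt, collapse = " \\\n | ")
}

#' Parallelize a record-independent stage over workers
#'
#' Records are numbered and dispatched round-robin to forked workers,
#' each of which applies the stage sequentially to its share; worker
#' outputs are then recombined. With `preserveOrder = TRUE` outputs
#' are reassembled into input order (the result equals sequential
#' execution exactly); otherwise outputs are concatenated worker by
#' worker and only the multiset of records is guaranteed. A failing
#' record aborts the run with its ordinal.
#'
#' @param stage a [PipelineStage-class] with
#'   `recordIndependent = TRUE`.
#' @param records a `RecordStream` or list of records.
#' @param workers number of parallel workers (>= 1).
#' @param preserveOrder reassemble outputs into input order?
#' @return A list of output records.
#' @export
multiplex <- function(stage, records, workers = 2L, preserveOrder = TRUE) {
  if (workers < 1L) stop("workers must be >= 1")
  if (!stage@recordIndependent)
    stop(sprintf("stage '%s' is not record-independent", stage@name))
  recs <- streamCollect(records)
  n <- length(recs)
  if (n == 0L) return(list())
  runOne <- function(i) {
    out <- tryCatch(
      streamCollect(stage@transform(asRecordStream(recs[[i]]))),
      error = function(e)
        structure(list(ordinal = i, msg = conditionMessage(e)),
                  class = "sdpipe_worker_error"))
    out
  }
  if (workers == 1L) {
    shares <- list(seq_len(n))
  } else {
    shares <- split(seq_len(n), (seq_len(n) - 1L) %% workers)
  }
  runShare <- function(idx) lapply(idx, runOne)
  results <- if (workers == 1L) lapply(shares, runShare)
  else parallel::mclapply(shares, runShare, mc.cores = workers)
  for (share in results) {
    if (inherits(share, "try-error"))
      stop("worker failed: ", attr(share, "condition")$message)
    for (out in share)
      if (inherits(out, "sdpipe_worker_error"))
        stop(sprintf("multiplex worker failed at record %d: %s",
                     out$ordinal, out$msg))
  }
  if (preserveOrder) {
    byInput <- vector("list", n)
    for (s in seq_along(shares))
      for (k in seq_along(shares[[s]]))
        byInput[[shares[[s]][k]]] <- results[[s]][[k]]
    unname(unlist(byInput, recursive = FALSE))
  } else {
    unname(unlist(lapply(results, function(s)
      unlist(s, recursive = FALSE)), recursive = FALSE))
  }
}

#' Shell text for a package CLI invocation
#'
#' Builds the command line equivalent of a package operation:
#' `Rscript <installed sdpipe.R> <subcommand> <args...>`, reading SD
#' records on stdin and writing SD records on stdout.
#'
#' @param subcommand CLI subcommand name.
#' @param args character vector of arguments.
#' @return A single string of shell text.
#' @export
cliCommand <- function(subcommand, args = character()) {
  script <- system.file("cli", "sdpipe.R", package = "sdpipe",
                        mustWork = TRUE)
  rscript <- file.path(R.home("bin"), "Rscript")
  paste(c(shQuote(rscript), shQuote(script), subcommand,
          vapply(args, function(a)
            if (grepl("^[-A-Za-z0-9_.,=/]+$", a)) a else shQuote(a), "")),
        collapse = " ")
}

# ---- stage constructors -------------------------------------------------

#' Built-in pipeline stages
#'
#' Constructors wrapping the package operations as pipeline stages
#' with their equivalent CLI text.
#'
#' @param tagFile path of the tag TSV (columns `SMARTS`, `TagName`,
#'   `TagSetName`).
#' @param setName tag set to apply.
#' @param mode tagging output mode (`first`, `all`, `both`).
#' @param firstField,allField output field names for the tagger.
#' @param props character vector of property names.
#' @param registryFile path of a registry XML, `NULL` for the default
#'   registry.
#' @param tabFile path of the tab-delimited file to merge.
#' @param sdKey,tabKey join keys (SD field / table column).
#' @param mergeMode `"keep_all"` or `"matched_only"`.
#' @return A [PipelineStage-class].
#' @name builtin-stages
NULL

#' @rdname builtin-stages
#' @export
taggerStage <- function(tagFile, setName, mode = "first",
                        firstField = "StructureTag",
                        allField = "AllStructureTags") {
  tagSet <- loadTags(tagFile, setName)
  pipelineStage(
    name = "sdf_tagger",
    transform = function(stream)
      tagRecords(stream, tagSet, mode = mode, firstField = firstField,
                 allField = allField),
    commandText = cliCommand("tagger",
                             c("-in", "-", "-out", "-", "-smarts", tagFile,
                               "-set", setName, "-output", mode,
                               "-firstTag", firstField,
                               "-allTag", allField)),
    recordIndependent = TRUE)
}

#' @rdname builtin-stages
#' @export
calcPropsStage <- function(props, registryFile = NULL) {
  registry <- if (is.null(registryFile)) defaultRegistry() else
    loadRegistry(registryFile)
  plan <- resolvePlan(props, registry)
  args <- c("-in", "-", "-out", "-", "-props", paste(props, collapse = ","))
  if (!is.null(registryFile)) args <- c(args, "-registry", registryFile)
  pipelineStage(
    name = "sdf_calc_props",
    transform = function(stream) applyPlan(plan, stream),
    commandText = cliCommand("calcprops", args),
    recordIndependent = TRUE)
}

#' @rdname builtin-stages
#' @export
tabMergeStage <- function(tabFile, sdKey, tabKey, mergeMode = "keep_all") {
  table <- readTab(tabFile)
  pipelineStage(
    name = "sdf_tab_merge",
    transform = function(stream)
      suppressWarnings(mergeTab(stream, table, sdKey, tabKey,
                                mode = mergeMode)),
    commandText = cliCommand("tabmerge",
                             c("-in", "-", "-out", "-", "-tab", tabFile,
                               "-sdTag", sdKey, "-tabTag", tabKey,
                               "-mode", mergeMode)),
    recordIndependent = TRUE)
}
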