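# Dependency-resolved property calculation.
#
# Calculators are declared in an XML registry; each <property> element
# names its required calculators, whether their outputs are kept, and
# an optional progAggregateID grouping properties computed by one
# program invocation. Resolution expands the transitive dependency
# closure, merges shared-aggregate calculators into single steps,
# topologically orders the steps (registry declaration order breaks
# ties, so plans are deterministic), and marks dependency-only outputs
# for stripping.

#' Construct a calculator spec
#'
#' @param name property name.
#' @param requiredCalculators dependency property names.
#' @param keepRequired keep dependency outputs in the final output?
#' @param aggregateId aggregation id (`NA` for none).
#' @param commandTemplate shell text or `"builtin:<name>"`.
#' @param outputFields fields written (defaults to `name`).
#' @return A [CalculatorSpec-class].
#' @export
calculatorSpec <- function(name, requiredCalculators = character(),
                           keepRequired = FALSE, aggregateId = NA_character_,
                           commandTemplate = paste0("builtin:", name),
                           outputFields = name) {
  new("CalculatorSpec", name = name,
      requiredCalculators = as.character(requiredCalculators),
      keepRequired = isTRUE(keepRequired),
      aggregateId = as.character(aggregateId),
      commandTemplate = commandTemplate,
      outputFields = as.character(outputFields))
}

#' Build a registry from calculator specs
#'
#' @param specs list of [CalculatorSpec-class] objects, in declaration
#'   order.
#' @return A validated [CalcRegistry-class].
#' @export
calcRegistry <- function(specs) {
  names(specs) <- vapply(specs, function(s) s@name, "")
  new("CalcRegistry", specs = specs)
}

setMethod("show", "CalcRegistry", function(object) {
  cat(sprintf("CalcRegistry (%d calculators)\n", length(object@specs)))
  for (s in object@specs)
    cat(sprintf("  %-10s%s%s\n", s@name,
                if (length(s@requiredCalculators))
                  paste0(" <- {", paste(s@requiredCalculators,
                                        collapse = ", "), "}") else "",
                if (!is.na(s@aggregateId))
                  paste0("  [", s@aggregateId, "]") else ""))
})

#' Load a calculator registry from XML
#'
#' Expected shape (element names follow the registry vocabulary):
#' ```
#' <properties>
#'   <property name="RO5">
#'     <requiredCalculators>MW,cLogP,N_O,NH_OH</requiredCalculators>
#'     <keepRequiredCalculators>false</keepRequiredCalculators>
#'     <command>builtin:RO5</command>
#'     <outputFields>RO5</outputFields>
#'   </property>
#'   <property name="MW" progAggregateID="PhysChem">...</property>
#' </properties>
#' ```
#' Duplicate property names and dangling dependency references are
#' rejected eagerly.
#'
#' @param input XML file path or literal XML string.
#' @return A [CalcRegistry-class].
#' @export
loadRegistry <- function(input) {
  doc <- xml2::read_xml(input)
  props <- xml2::xml_find_all(doc, ".//property")
  if (length(props) == 0L) stop("registry contains no property elements")
  splitList <- function(x) {
    if (length(x) == 0L || is.na(x) || !nzchar(trimws(x)))
      return(character())
    trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  specs <- lapply(props, function(p) {
    name <- xml2::xml_attr(p, "name")
    if (is.na(name) || !nzchar(name))
      stop("property element without a name attribute")
    agg <- xml2::xml_attr(p, "progAggregateID")
    getChild <- function(tag) {
      node <- xml2::xml_find_first(p, tag)
      if (inherits(node, "xml_missing")) NA_character_
      else xml2::xml_text(node)
    }
    cmd <- getChild("command")
    fields <- splitList(getChild("outputFields"))
    calculatorSpec(
      name = name,
      requiredCalculators = splitList(getChild("requiredCalculators")),
      keepRequired = isTRUE(tolower(getChild("keepRequiredCalculators"))
                            %in% "true"),
      aggregateId = agg,
      commandTemplate = if (is.na(cmd)) paste0("builtin:", name) else
        trimws(cmd),
      outputFields = if (length(fields)) fields else name)
  })
  nms <- vapply(specs, function(s) s@name, "")
  if (anyDuplicated(nms))
    stop("duplicate property name in registry: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  reg <- calcRegistry(specs)
  methods::validObject(reg)
  reg
}

#' The calculator registry shipped with the package
#'
#' Builtin calculators: `MW` (molecular weight), `N_O` (H-bond
#' acceptors), `NH_OH` (H-bond donors), `RotBonds`, `cLogP`
#' (OpenBabel lipophilicity estimate), and `RO5` (Lipinski
#' rule-of-five violation count over MW > 500, cLogP > 5,
#' NH+OH > 5, N+O > 10). `MW`, `N_O` and `NH_OH` share one
#' aggregation id and are computed by a single invocation.
#'
#' @return A [CalcRegistry-class].
#' @export
defaultRegistry <- function() {
  loadRegistry(system.file("extdata", "calculators.xml",
                           package = "sdpipe", mustWork = TRUE))
}

#' @rdname CalcPlan-accessors
setMethod("planSteps", "CalcPlan", function(x) x@steps)
#' @rdname CalcPlan-accessors
setMethod("transientFields", "CalcPlan", function(x) x@transientFields)

#' Accessors for CalcPlan objects
#'
#' @param x a [CalcPlan-class].
#' @name CalcPlan-accessors
NULL

setMethod("show", "CalcPlan", function(object) {
  cat(sprintf("CalcPlan for {%s}: %d step(s)\n",
              paste(object@requested, collapse = ", "),
              length(object@steps)))
  for (i in seq_along(object@steps))
    cat(sprintf("  %d. %s\n", i,
                paste(object@steps[[i]]$calculators, collapse = " + ")))
  if (length(object@transientFields))
    cat("  strip:", paste(object@transientFields, collapse = ", "), "\n")
})

#' Resolve requested properties into an execution plan
#'
#' Expands the transitive closure of `requiredCalculators`, merges
#' calculators sharing a `progAggregateID` (and the same program)
#' into single steps, orders steps topologically with registry
#' declaration order breaking ties, and collects the transient fields
#' to strip: outputs of calculators that were not requested and whose
#' dependents all set `keepRequired = FALSE` (one dependent asking to
#' keep wins).
#'
#' @param requested character vector of property names.
#' @param registry a [CalcRegistry-class].
#' @return A [CalcPlan-class]; each needed calculator appears in
#'   exactly one step.
#' @examples
#' reg <- defaultRegistry()
#' resolvePlan("RO5", reg)
#' @export
resolvePlan <- function(requested, registry) {
  specs <- registry@specs
  nms <- names(specs)
  unknown <- setdiff(requested, nms)
  if (length(unknown))
    stop("unknown propert(ies): ", paste(unknown, collapse = ", "))

  # transitive closure + cycle detection (DFS with in-progress marks)
  state <- new.env(parent = emptyenv())
  needed <- character()
  visit <- function(name, path) {
    st <- state[[name]]
    if (identical(st, "doing"))
      stop("dependency cycle: ",
           paste(c(path[which(path == name):length(path)], name),
                 collapse = " -> "))
    if (identical(st, "done")) return(invisible())
    state[[name]] <- "doing"
    for (d in specs[[name]]@requiredCalculators) visit(d, c(path, name))
    state[[name]] <- "done"
    needed <<- c(needed, name)
    invisible()
  }
  for (r in unique(requested)) visit(r, character())

  # group into merged invocations
  groupOf <- vapply(needed, function(n) {
    agg <- specs[[n]]@aggregateId
    if (is.na(agg)) paste0("solo:", n) else paste0("agg:", agg)
  }, "")
  groups <- split(needed, groupOf)
  # merging requires one program per aggregate id (builtins count as
  # one program; the merged step invokes each member calculator)
  progOf <- function(n) {
    ct <- specs[[n]]@commandTemplate
    if (startsWith(ct, "builtin:")) "builtin" else sub("\\s.*$", "", ct)
  }
  for (g in groups)
    if (length(unique(vapply(g, progOf, ""))) > 1L)
      stop("calculators sharing an aggregate id use different programs: ",
           paste(g, collapse = ", "))

  gIndex <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                            unlist(groups))
  # a dependency between members of one aggregate group would collapse
  # onto the merged step itself: a self-cycle
  for (g in groups)
    for (m in g) {
      inner <- intersect(specs[[m]]@requiredCalculators, setdiff(g, m))
      if (length(inner))
        stop(sprintf(
          "aggregate merging creates a self-cycle: '%s' requires '%s' %s",
          m, inner[1L], "within the same aggregate group"))
    }
  declOrder <- stats::setNames(seq_along(nms), nms)
  gDecl <- vapply(groups, function(g) min(declOrder[g]), 0)
  # merged-graph edges
  gDeps <- lapply(groups, function(g) {
    d <- unique(unlist(lapply(g, function(n)
      specs[[n]]@requiredCalculators)))
    d <- intersect(d, needed)
    setdiff(unique(unname(gIndex[d])), unname(gIndex[g[1L]]))
  })
  # Kahn with declaration-order priority (also catches cycles that
  # aggregate merging introduced)
  remaining <- seq_along(groups)
  satisfied <- integer()
  order <- integer()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      all(gDeps[[i]] %in% satisfied), TRUE)]
    if (length(ready) == 0L)
      stop("dependency cycle introduced by aggregate merging: ",
           paste(unlist(groups[remaining]), collapse = ", "))
    pick <- ready[which.min(gDecl[ready])]
    order <- c(order, pick)
    satisfied <- c(satisfied, pick)
    remaining <- setdiff(remaining, pick)
  }

  steps <- lapply(order, function(i) {
    members <- groups[[i]][order(declOrder[groups[[i]]])]
    list(calculators = unname(members),
         command = specs[[members[1L]]]@commandTemplate,
         outputFields = unname(unlist(lapply(members, function(n)
           specs[[n]]@outputFields))))
  })

  # transient fields: not requested, and no needed dependent keeps them
  transient <- character()
  for (n in needed) {
    if (n %in% requested) next
    dependents <- needed[vapply(needed, function(m)
      n %in% specs[[m]]@requiredCalculators, TRUE)]
    if (length(dependents) && !any(vapply(dependents, function(m)
      specs[[m]]@keepRequired, TRUE)))
      transient <- c(transient, specs[[n]]@outputFields)
  }
  new("CalcPlan", steps = steps, transientFields = unique(transient),
      requested = unique(requested))
}

#' Render a plan as shell pipe text
#'
#' Steps are joined in plan order with `" \\\n | "`; a final
#' field-stripping stage is appended when the plan has transient
#' fields. Builtin command references are rendered as invocations of
#' the package command-line interface.
#'
#' @param plan a [CalcPlan-class].
#' @return A single string of shell text.
#' @export
renderScript <- function(plan) {
  cmds <- vapply(plan@steps, function(st) {
    if (startsWith(st$command, "builtin:"))
      cliCommand("calcstep",
                 c("-calcs", paste(st$calculators, collapse = ",")))
    else st$command
  }, "")
  if (length(plan@transientFields))
    cmds <- c(cmds, cliCommand("rmfields",
                               c("-fields",
                                 paste(plan@transientFields,
                                       collapse = ","))))
  paste(cmds, collapse = " \\\n | ")
}

# builtin calculator implementations: name -> function(record) value
builtinCalculators <- function() {
  list(
    MW = function(rec) sprintf("%.2f", molWeight(rec)),
    N_O = function(rec) sprintf("%d", countHBA(rec)),
    NH_OH = function(rec) sprintf("%d", countHBD(rec)),
    RotBonds = function(rec) sprintf("%d", countRotatableBonds(rec)),
    cLogP = function(rec) sprintf("%.2f", calcLogP(rec)),
    RO5 = function(rec) {
      mw <- as.numeric(sdField(rec, "MW"))
      lp <- as.numeric(sdField(rec, "cLogP"))
      don <- as.numeric(sdField(rec, "NH_OH"))
      acc <- as.numeric(sdField(rec, "N_O"))
      if (anyNA(c(mw, lp, don, acc)))
        stop("RO5 requires MW, cLogP, NH_OH and N_O fields")
      sprintf("%d", sum(mw > 500, lp > 5, don > 5, acc > 10))
    })
}

#' Execute a calculator plan in-process
#'
#' Applies every step's builtin calculators to each record in plan
#' order, then strips the plan's transient fields. A calculator
#' failing on a record writes an empty string for its field(s) and
#' emits a warning.
#'
#' @param plan a [CalcPlan-class] whose steps all resolve to builtin
#'   calculators.
#' @param records a `RecordStream` or list of records.
#' @return A lazy `RecordStream`.
#' @export
applyPlan <- function(plan, records) {
  builtins <- builtinCalculators()
  for (st in plan@steps)
    for (calc in st$calculators)
      if (!calc %in% names(builtins))
        stop(sprintf("calculator '%s' is not a builtin; use renderScript()",
                     calc))
  stream <- streamMap(records, function(rec, i) {
    for (st in plan@steps) {
      for (calc in st$calculators) {
        val <- tryCatch(builtins[[calc]](rec), error = function(e) {
          warning(sprintf("record %d: calculator %s failed (%s)", i, calc,
                          conditionMessage(e)))
          ""
        })
        sdField(rec, calc) <- val
      }
    }
    if (length(plan@transientFields))
      rec <- dropFields(rec, plan@transientFields)
    rec
  })
  stream
}
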