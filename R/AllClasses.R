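#' @import methods
NULL

emptyAtomTable <- function() {
  data.frame(elem = character(), x = numeric(), y = numeric(),
             z = numeric(), charge = integer(), stringsAsFactors = FALSE)
}

emptyBondTable <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             stringsAsFactors = FALSE)
}

#' SDRecord: one SD-file record
#'
#' A single record of a structure-data (SD) file: a molecule (possibly
#' empty, for data-only records) plus an ordered list of named data
#' fields. Field names are unique within a record; assigning to an
#' existing name replaces the value in place, preserving its position.
#'
#' @slot title character, the first molblock line.
#' @slot atoms data.frame with columns `elem`, `x`, `y`, `z`, `charge`.
#' @slot bonds data.frame with columns `a1`, `a2`, `order` (1, 2, 3, or
#'   4 for aromatic), indices into `atoms`.
#' @slot fields named list of character scalars, in file order.
#'   Multi-line values contain embedded `"\n"`.
#'
#' @exportClass SDRecord
setClass("SDRecord",
  representation(title = "character", atoms = "data.frame",
                 bonds = "data.frame", fields = "list"),
  prototype(title = "", atoms = emptyAtomTable(), bonds = emptyBondTable(),
            fields = list()))

setValidity("SDRecord", function(object) {
  msg <- character()
  if (length(object@title) != 1L) msg <- c(msg, "title must be a single string")
  nm <- names(object@fields)
  if (length(object@fields) > 0L &&
      (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)))
    msg <- c(msg, "field names must be unique and non-empty")
  if (!all(c("elem", "x", "y", "z", "charge") %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns elem, x, y, z, charge")
  if (!all(c("a1", "a2", "order") %in% names(object@bonds)))
    msg <- c(msg, "bonds must have columns a1, a2, order")
  if (nrow(object@bonds) > 0L) {
    idx <- c(object@bonds$a1, object@bonds$a2)
    if (any(idx < 1L | idx > nrow(object@atoms)))
      msg <- c(msg, "bond atom indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SDRecord
#'
#' @param title record title (molblock line 1).
#' @param atoms atom table (`elem`, `x`, `y`, `z`, `charge`).
#' @param bonds bond table (`a1`, `a2`, `order`).
#' @param fields named list (or named character vector) of data fields.
#' @return An [SDRecord-class] object.
#' @examples
#' r <- sdRecord(title = "empty", fields = list(ID = "1"))
#' @export
sdRecord <- function(title = "", atoms = emptyAtomTable(),
                     bonds = emptyBondTable(), fields = list()) {
  if (is.character(fields)) fields <- as.list(fields)
  if (nrow(atoms) > 0L) {
    atoms$elem <- as.character(atoms$elem)
    for (cl in c("x", "y", "z")) atoms[[cl]] <- as.numeric(atoms[[cl]])
    if (is.null(atoms$charge)) atoms$charge <- 0L
    atoms$charge <- as.integer(atoms$charge)
  } else atoms <- emptyAtomTable()
  if (nrow(bonds) > 0L) {
    for (cl in c("a1", "a2", "order")) bonds[[cl]] <- as.integer(bonds[[cl]])
  } else bonds <- emptyBondTable()
  new("SDRecord", title = as.character(title), atoms = atoms, bonds = bonds,
      fields = lapply(fields, as.character))
}

#' TagSet: an ordered set of SMARTS tag definitions
#'
#' Scaffold/series definitions loaded from a tag table. Order is
#' significant: in `first` mode the first matching SMARTS wins.
#'
#' @slot name the tag-set name.
#' @slot definitions data.frame with columns `smarts` and `tagName`,
#'   one row per definition, in input-file order.
#' @exportClass TagSet
setClass("TagSet",
  representation(name = "character", definitions = "data.frame"))

setValidity("TagSet", function(object) {
  if (nrow(object@definitions) < 1L) return("tag set must be non-empty")
  if (!all(c("smarts", "tagName") %in% names(object@definitions)))
    return("definitions must have columns smarts, tagName")
  TRUE
})

#' CalculatorSpec: one entry of the property-calculator registry
#'
#' @slot name property name (unique within the registry).
#' @slot requiredCalculators names of properties that must be computed
#'   first.
#' @slot keepRequired if `TRUE`, the outputs of required calculators
#'   are retained in the final output.
#' @slot aggregateId optional aggregation id; calculators sharing one
#'   id are merged into a single invocation.
#' @slot commandTemplate shell text, or `"builtin:<name>"` for a
#'   calculator shipped with the package.
#' @slot outputFields data-field names the calculator writes.
#' @exportClass CalculatorSpec
setClass("CalculatorSpec",
  representation(name = "character", requiredCalculators = "character",
                 keepRequired = "logical", aggregateId = "character",
                 commandTemplate = "character", outputFields = "character"))

#' CalcRegistry: ordered collection of calculator specs
#'
#' @slot specs named list of [CalculatorSpec-class] in declaration
#'   order.
#' @exportClass CalcRegistry
setClass("CalcRegistry", representation(specs = "list"))

setValidity("CalcRegistry", function(object) {
  nms <- vapply(object@specs, function(s) s@name, "")
  if (anyDuplicated(nms)) return("duplicate property names in registry")
  for (s in object@specs)
    for (d in s@requiredCalculators)
      if (!d %in% nms)
        return(sprintf("property '%s' requires unknown calculator '%s'",
                       s@name, d))
  TRUE
})

#' CalcPlan: a resolved, dependency-ordered calculator execution plan
#'
#' @slot steps list of plan steps; each step is a list with elements
#'   `calculators` (member property names, merged invocations have
#'   several), `command` (shell text or builtin reference) and
#'   `outputFields`.
#' @slot transientFields fields written only to satisfy dependencies;
#'   stripped after the last step.
#' @slot requested the property names the plan was resolved for.
#' @exportClass CalcPlan
setClass("CalcPlan",
  representation(steps = "list", transientFields = "character",
                 requested = "character"))

#' PipelineStage: a record-stream transformer
#'
#' A stage maps a lazy record stream to a lazy record stream and knows
#' the equivalent shell command. Stages whose output records each
#' depend on exactly one input record may be parallelized with
#' [multiplex()].
#'
#' @slot name stage name (used in error messages).
#' @slot transform `function(stream) -> stream`.
#' @slot commandText equivalent shell invocation (may be `""` for
#'   in-process-only stages; such stages cannot be compiled).
#' @slot recordIndependent `TRUE` if each output record depends on
#'   exactly one input record.
#' @exportClass PipelineStage
setClass("PipelineStage",
  representation(name = "character", transform = "function",
                 commandText = "character", recordIndependent = "logical"))

#' Pipeline: an ordered list of stages
#'
#' @slot stages list of [PipelineStage-class].
#' @exportClass Pipeline
setClass("Pipeline", representation(stages = "list"))

setValidity("Pipeline", function(object) {
  if (!all(vapply(object@stages, is, TRUE, "PipelineStage")))
    return("all stages must be PipelineStage objects")
  TRUE
})

#' Conformer: a 3D geometry with energy and provenance
#'
#' @slot coords numeric matrix (n x 3), Angstrom.
#' @slot energy force-field energy, kcal/mol (restraint terms always
#'   excluded).
#' @slot rmsdToInput heavy-atom RMSD to the input conformation,
#'   Angstrom.
#' @slot role one of `"input"`, `"constrained"`, `"local_min"`,
#'   `"global_min"`, `"pareto"`, `"ensemble"`.
#' @slot radius flat-bottom radius for `role == "constrained"`,
#'   `NA` otherwise.
#' @exportClass Conformer
setClass("Conformer",
  representation(coords = "matrix", energy = "numeric",
                 rmsdToInput = "numeric", role = "character",
                 radius = "numeric"),
  prototype(rmsdToInput = NA_real_, role = "ensemble", radius = NA_real_))

setValidity("Conformer", function(object) {
  if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
  if (!is.finite(object@energy)) return("energy must be finite")
  if (!is.na(object@rmsdToInput) && object@rmsdToInput < -1e-9)
    return("rmsdToInput must be >= 0")
  TRUE
})

#' StrainParams: parameters of the strain-analysis protocol
#'
#' @slot radii flat-bottom radii (Angstrom), strictly increasing.
#' @slot maxEnsemble cap on enumerated conformers.
#' @slot polarHIncrement torsion step for OH/NH sampling (degrees).
#' @slot flagRMSD relaxation allowance used by [flagStrained()]
#'   (Angstrom).
#' @slot flagEnergy strain threshold used by [flagStrained()]
#'   (kcal/mol).
#' @slot seed integer seed controlling ensemble sub-sampling.
#' @exportClass StrainParams
setClass("StrainParams",
  representation(radii = "numeric", maxEnsemble = "numeric",
                 polarHIncrement = "numeric", flagRMSD = "numeric",
                 flagEnergy = "numeric", seed = "numeric"))

setValidity("StrainParams", function(object) {
  if (length(object@radii) < 1L || any(object@radii <= 0) ||
      is.unsorted(object@radii, strictly = TRUE))
    return("radii must be positive and strictly increasing")
  if (object@maxEnsemble < 1) return("maxEnsemble must be >= 1")
  if (object@polarHIncrement <= 0 || object@polarHIncrement > 360)
    return("polarHIncrement must be in (0, 360]")
  TRUE
})

#' Construct strain-analysis parameters
#'
#' Defaults follow the analysis protocol: four flat-bottom radii 0.2,
#' 0.6, 1.0 and 1.4 Angstrom, an ensemble cap of 500 minimizations, a
#' 120 degree polar-hydrogen torsion increment, and flagging of poses
#' whose strain exceeds 4 kcal/mol at 0.4 Angstrom maximum relaxation.
#'
#' @param radii flat-bottom radii in Angstrom.
#' @param maxEnsemble maximum number of enumerated conformers.
#' @param polarHIncrement OH/NH torsion step in degrees.
#' @param flagRMSD maximum relaxation (Angstrom) for [flagStrained()].
#' @param flagEnergy strain threshold (kcal/mol) for [flagStrained()].
#' @param seed seed for ensemble sub-sampling when the torsion grid
#'   exceeds `maxEnsemble`.
#' @return A [StrainParams-class] object.
#' @examples
#' strainParams(radii = c(0.3, 0.9))
#' @export
strainParams <- function(radii = c(0.2, 0.6, 1.0, 1.4), maxEnsemble = 500,
                         polarHIncrement = 120, flagRMSD = 0.4,
                         flagEnergy = 4.0, seed = 42) {
  new("StrainParams", radii = as.numeric(radii),
      maxEnsemble = as.numeric(maxEnsemble),
      polarHIncrement = as.numeric(polarHIncrement),
      flagRMSD = as.numeric(flagRMSD), flagEnergy = as.numeric(flagEnergy),
      seed = as.numeric(seed))
}

#' StrainProfile: the retained conformer set of one analysis
#'
#' @slot mol the analyzed molecule (an [SDRecord-class]; coordinates
#'   are those of the input pose).
#' @slot conformers list of retained [Conformer-class] objects: the
#'   input (single-point energy, RMSD 0), one constrained minimum per
#'   radius, the local minimum, the global minimum, and any additional
#'   Pareto-optimal minima.
#' @slot globalMinEnergy kcal/mol; the minimum retained energy.
#' @exportClass StrainProfile
setClass("StrainProfile",
  representation(mol = "SDRecord", conformers = "list",
                 globalMinEnergy = "numeric"))

setValidity("StrainProfile", function(object) {
  if (!all(vapply(object@conformers, is, TRUE, "Conformer")))
    return("conformers must be Conformer objects")
  roles <- vapply(object@conformers, function(cf) cf@role, "")
  if (sum(roles == "input") != 1L)
    return("profile must contain exactly one input conformer")
  en <- vapply(object@conformers, function(cf) cf@energy, 0)
  if (abs(min(en) - object@globalMinEnergy) > 1e-6)
    return("globalMinEnergy must equal the minimum retained energy")
  TRUE
})
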