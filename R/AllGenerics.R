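# Accessor generics. Slot access from user code is discouraged; these
# are the supported surface.

#' @rdname SDRecord-accessors
#' @export
setGeneric("sdTitle", function(x) standardGeneric("sdTitle"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("sdTitle<-", function(x, value) standardGeneric("sdTitle<-"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("sdFields", function(x) standardGeneric("sdFields"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("sdField", function(x, name) standardGeneric("sdField"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("sdField<-", function(x, name, value) standardGeneric("sdField<-"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("dropFields", function(x, names) standardGeneric("dropFields"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname SDRecord-accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname Conformer-accessors
#' @export
setGeneric("confEnergy", function(x) standardGeneric("confEnergy"))
#' @rdname Conformer-accessors
#' @export
setGeneric("confRMSD", function(x) standardGeneric("confRMSD"))
#' @rdname Conformer-accessors
#' @export
setGeneric("confRole", function(x) standardGeneric("confRole"))
#' @rdname Conformer-accessors
#' @export
setGeneric("confRadius", function(x) standardGeneric("confRadius"))

#' @rdname StrainProfile-accessors
#' @export
setGeneric("profileConformers", function(x) standardGeneric("profileConformers"))
#' @rdname StrainProfile-accessors
#' @export
setGeneric("globalMinEnergy", function(x) standardGeneric("globalMinEnergy"))

#' @rdname CalcPlan-accessors
#' @export
setGeneric("planSteps", function(x) standardGeneric("planSteps"))
#' @rdname CalcPlan-accessors
#' @export
setGeneric("transientFields", function(x) standardGeneric("transientFields"))

#' @rdname Pipeline-accessors
#' @export
setGeneric("stageName", function(x) standardGeneric("stageName"))
#' @rdname Pipeline-accessors
#' @export
setGeneric("pipelineStages", function(x) standardGeneric("pipelineStages"))

#' @rdname TagSet-accessors
#' @export
setGeneric("tagSetName", function(x) standardGeneric("tagSetName"))
#' @rdname TagSet-accessors
#' @export
setGeneric("tagDefinitions", function(x) standardGeneric("tagDefinitions"))
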