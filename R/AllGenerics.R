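#' @rdname ReferencePanel-class
#' @param x a ReferencePanel or Cohort.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname Cohort-class
#' @param x a Cohort.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname Cohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname Cohort-class
#' @export
setGeneric("fractureEvents", function(x) standardGeneric("fractureEvents"))

#' @rdname Cohort-class
#' @export
setGeneric("discoveryFlag", function(x) standardGeneric("discoveryFlag"))

#' @rdname ShapeAnnotation-class
#' @param x a ShapeAnnotation.
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname ShapeAnnotation-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname InstrumentSet-class
#' @param x an InstrumentSet or MRResult.
#' @export
setGeneric("instrumentData", function(x) standardGeneric("instrumentData"))
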