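#' Accessors for agreement objects
#'
#' Small generics giving read access to the slots of the core classes
#' without touching \code{@}.
#'
#' @param x a \code{RatingTable}, \code{CategoryCounts},
#'   \code{CoincidenceMatrix}, \code{AgreementEstimate},
#'   \code{ConfidenceInterval} or related object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("nRaters", function(x) standardGeneric("nRaters"))

#' @rdname accessors
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' @rdname accessors
#' @export
setGeneric("ratingValues", function(x) standardGeneric("ratingValues"))

#' @rdname accessors
#' @export
setGeneric("ratingScale", function(x) standardGeneric("ratingScale"))

#' @rdname accessors
#' @export
setGeneric("categoryLabels", function(x) standardGeneric("categoryLabels"))

#' @rdname accessors
#' @export
setGeneric("countValues", function(x) standardGeneric("countValues"))

#' @rdname accessors
#' @export
setGeneric("rowTotals", function(x) standardGeneric("rowTotals"))

#' @rdname accessors
#' @export
setGeneric("coincidenceValues", function(x) standardGeneric("coincidenceValues"))

#' @rdname accessors
#' @export
setGeneric("marginals", function(x) standardGeneric("marginals"))

#' @rdname accessors
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))

#' @rdname accessors
#' @export
setGeneric("excludedUnits", function(x) standardGeneric("excludedUnits"))

#' @rdname accessors
#' @export
setGeneric("estimateValue", function(x) standardGeneric("estimateValue"))

#' @rdname accessors
#' @export
setGeneric("estimateMethod", function(x) standardGeneric("estimateMethod"))

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("ciLower", function(x) standardGeneric("ciLower"))

#' @rdname accessors
#' @export
setGeneric("ciUpper", function(x) standardGeneric("ciUpper"))

#' @rdname accessors
#' @export
setGeneric("ciLevel", function(x) standardGeneric("ciLevel"))

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname accessors
#' @export
setGeneric("interval", function(x) standardGeneric("interval"))

#' @rdname accessors
#' @export
setGeneric("trueValues", function(x) standardGeneric("trueValues"))
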