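#' @include AllGenerics.R
NULL

#' Fragment a molecule into atom groups
#'
#' @param mol A \linkS4class{Molecule}.
#' @param ... Further arguments passed to methods.
#' @return A \linkS4class{FragmentProfile}.
#' @export
setGeneric("fragmentMolecule", function(mol, ...) standardGeneric("fragmentMolecule"))

#' @rdname Molecule-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Molecule-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname Molecule-accessors
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' @rdname Molecule-accessors
#' @export
setGeneric("properties", function(x) standardGeneric("properties"))

#' @rdname Molecule-accessors
#' @export
setGeneric("has3d", function(x) standardGeneric("has3d"))

#' @rdname FragmentProfile-accessors
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))

#' @rdname FragmentProfile-accessors
#' @export
setGeneric("specialCounts", function(x) standardGeneric("specialCounts"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("descriptorId", function(x) standardGeneric("descriptorId"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("tableEntries", function(x) standardGeneric("tableEntries"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("tableConstant", function(x) standardGeneric("tableConstant"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("tableUnits", function(x) standardGeneric("tableUnits"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' @rdname ParameterTable-accessors
#' @export
setGeneric("cvStats", function(x) standardGeneric("cvStats"))

#' @rdname Prediction-accessors
#' @export
setGeneric("predictedValue", function(x) standardGeneric("predictedValue"))

#' @rdname Prediction-accessors
#' @export
setGeneric("breakdown", function(x) standardGeneric("breakdown"))

#' @rdname Prediction-accessors
#' @export
setGeneric("isApplicable", function(x) standardGeneric("isApplicable"))
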