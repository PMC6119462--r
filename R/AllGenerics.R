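## Generics for the accessor layer.

#' @name accessors
#' @title Accessors for GeoForest objects
#' @description Slot access goes through these accessors rather than
#'   \code{@}.
#' @param x,object a GeoForest object.
#' @param name layer name or index.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("targetValues", function(x) standardGeneric("targetValues"))

#' @rdname accessors
#' @export
setGeneric("measurementSd", function(x) standardGeneric("measurementSd"))

#' @rdname accessors
#' @export
setGeneric("timeValues", function(x) standardGeneric("timeValues"))

#' @rdname accessors
#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @rdname accessors
#' @export
setGeneric("methodLabels", function(x) standardGeneric("methodLabels"))

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("layerRoles", function(x) standardGeneric("layerRoles"))

#' @rdname accessors
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname accessors
#' @export
setGeneric("nugget", function(x) standardGeneric("nugget"))

#' @rdname accessors
#' @export
setGeneric("psill", function(x) standardGeneric("psill"))

#' @rdname accessors
#' @export
setGeneric("rangeParam", function(x) standardGeneric("rangeParam"))

#' @rdname accessors
#' @export
setGeneric("vgmFamily", function(x) standardGeneric("vgmFamily"))

#' @rdname accessors
#' @export
setGeneric("totalSill", function(x) standardGeneric("totalSill"))

#' @rdname accessors
#' @export
setGeneric("practicalRange", function(x) standardGeneric("practicalRange"))

#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname accessors
#' @export
setGeneric("oobStats", function(x) standardGeneric("oobStats"))
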