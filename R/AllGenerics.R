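#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("axialSpacing", function(x) standardGeneric("axialSpacing"))

#' @export
setGeneric("lateralSpacing", function(x) standardGeneric("lateralSpacing"))

#' @export
setGeneric("foveaCol", function(x) standardGeneric("foveaCol"))

#' @export
setGeneric("meridian", function(x) standardGeneric("meridian"))

#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @export
setGeneric("upperPx", function(x) standardGeneric("upperPx"))

#' @export
setGeneric("lowerPx", function(x) standardGeneric("lowerPx"))

#' @export
setGeneric("validCols", function(x) standardGeneric("validCols"))

#' @export
setGeneric("choroidLabels", function(x) standardGeneric("choroidLabels"))

#' @export
setGeneric("lumenPixels", function(x) standardGeneric("lumenPixels"))

#' @export
setGeneric("stromaPixels", function(x) standardGeneric("stromaPixels"))

#' @export
setGeneric("bandThicknessPx", function(x) standardGeneric("bandThicknessPx"))
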