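#' @rdname NumberedChain-accessors
#' @export
setGeneric("chainRole", function(x) standardGeneric("chainRole"))

#' @rdname NumberedChain-accessors
#' @export
setGeneric("positionLabels", function(x) standardGeneric("positionLabels"))

#' @rdname NumberedChain-accessors
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname NumberedChain-accessors
#' @export
setGeneric("residueAt", function(x, label) standardGeneric("residueAt"))

#' @rdname RossMintonFit-accessors
#' @export
setGeneric("intrinsicViscosity", function(object)
  standardGeneric("intrinsicViscosity"))

#' @rdname RossMintonFit-accessors
#' @export
setGeneric("kOverV", function(object) standardGeneric("kOverV"))

#' @rdname RossMintonFit-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
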