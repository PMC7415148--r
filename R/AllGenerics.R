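#' @rdname Residue-class
#' @param x,object an object from this package.
#' @export
setGeneric("carbons", function(x) standardGeneric("carbons"))

#' @rdname Residue-class
#' @export
setGeneric("doubleBonds", function(x) standardGeneric("doubleBonds"))

#' @rdname Residue-class
#' @export
setGeneric("linkType", function(x) standardGeneric("linkType"))

#' @rdname Residue-class
#' @export
setGeneric("residueLabel", function(x) standardGeneric("residueLabel"))

#' Saturation test
#'
#' A residue is saturated when it carries no C=C double bond. On a
#' \linkS4class{ResidueTable} this returns one logical per residue row, the
#' predicate behind the saturated/unsaturated partition of
#' \code{\link{splitBySaturation}}.
#'
#' @param x a \linkS4class{Residue} or \linkS4class{ResidueTable}.
#' @return logical: TRUE where the double-bond count is zero.
#' @examples
#' isSaturated(Residue(16, 0))
#' isSaturated(Residue(18, 2))
#' @export
setGeneric("isSaturated", function(x) standardGeneric("isSaturated"))

#' @rdname Lipid-class
#' @export
setGeneric("ambiguityIndex", function(x) standardGeneric("ambiguityIndex"))

#' @rdname Lipid-class
#' @export
setGeneric("rawName", function(x) standardGeneric("rawName"))

#' @rdname Lipid-class
#' @export
setGeneric("alternatives", function(x) standardGeneric("alternatives"))

#' @rdname LipidTable-class
#' @export
setGeneric("identifiers", function(x) standardGeneric("identifiers"))

#' @rdname LipidTable-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname ResidueTable-class
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname ResidueTable-class
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname GroupDesign-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname GroupDesign-class
#' @export
setGeneric("baselinePairs", function(x) standardGeneric("baselinePairs"))
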