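#' @rdname GuideScreen-class
#' @param x,object a `GuideScreen`
#' @export
setGeneric("guideSeqs", function(x) standardGeneric("guideSeqs"))

#' @rdname GuideScreen-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GuideScreen-class
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname GuideScreen-class
#' @export
setGeneric("guideLabels", function(x) standardGeneric("guideLabels"))

#' @rdname GuideModel-class
#' @param x,object a `GuideModel`
#' @export
setGeneric("modelManifest", function(x) standardGeneric("modelManifest"))

#' @rdname GuideModel-class
#' @export
setGeneric("modelScaffold", function(x) standardGeneric("modelScaffold"))
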