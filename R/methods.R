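#' @rdname GuideScreen-class
#' @export
setMethod("guideSeqs", "GuideScreen", function(x) as.character(x@guides))

#' @rdname GuideScreen-class
#' @export
setMethod("geneIds", "GuideScreen", function(x) x@geneId)

#' @rdname GuideScreen-class
#' @export
setMethod("activities", "GuideScreen", function(x) x@activity)

#' @rdname GuideScreen-class
#' @export
setMethod("guideLabels", "GuideScreen", function(x) x@label)

#' @rdname GuideScreen-class
#' @export
setMethod("length", "GuideScreen", function(x) length(x@guides))

#' @rdname GuideScreen-class
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "GuideScreen", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
             guides = x@guides[i],
             geneId = x@geneId[i],
             activity = x@activity[i],
             label = x@label[i])
})

setMethod("show", "GuideScreen", function(object) {
  cat("GuideScreen with", length(object), "guides,",
      length(unique(object@geneId)), "genes\n")
  lab <- object@label
  if (all(is.na(lab))) {
    cat("  unlabeled (activity range ",
        sprintf("%.3g .. %.3g", min(object@activity), max(object@activity)),
        ")\n", sep = "")
  } else {
    tb <- table(lab)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' Records usable for training (extreme classes only)
#'
#' Subsets a labeled screen to its `functional` and `non-functional`
#' records, dropping the excluded middle of the activity distribution.
#'
#' @param x a labeled [GuideScreen-class]
#' @return a `GuideScreen` containing only the two extreme classes.
#' @export
trainingRecords <- function(x) {
  stopifnot(is(x, "GuideScreen"))
  keep <- !is.na(x@label) & x@label != "excluded-middle"
  if (!any(keep))
    stop("screen has no labeled records; run labelByPercentile() first")
  x[keep]
}

setMethod("show", "SgRNA", function(object) {
  cat("SgRNA (", nchar(object@fullSeq), " nt)\n", sep = "")
  cat("  guide:    ", object@guide, "\n", sep = "")
  cat("  scaffold: ", substr(object@scaffold, 1, 40),
      if (nchar(object@scaffold) > 40) "..." else "", "\n", sep = "")
})

setMethod("show", "ExonIndex", function(object) {
  cat("ExonIndex over", length(object@exons), "exon sequences (",
      sum(Biostrings::width(object@exons)), "nt );",
      length(ls(object@index)), "distinct seed+PAM keys\n")
})

setMethod("length", "ExonIndex", function(x) length(ls(x@index)))

#' @rdname GuideModel-class
#' @export
setMethod("modelManifest", "GuideModel", function(x) x@featureNames)

#' @rdname GuideModel-class
#' @export
setMethod("modelScaffold", "GuideModel", function(x) x@scaffold)

setMethod("show", "GuideModel", function(object) {
  cat("GuideModel: RBF-SVM over", length(object@featureNames), "features\n")
  cat(sprintf("  cost = %g, gamma = %g, trained on %s data\n",
              object@cost, object@gamma,
              if (object@prefiltered) "pre-filtered" else "unfiltered"))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): %d records in %d folds, AUC = %.3f\n",
              object@mode, length(object@scores),
              length(unique(object@fold)), object@auc))
})

#' @rdname CVResult-class
#' @param x a `CVResult`
#' @export
cvAUC <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@auc
}
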