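#' @import methods
#' @importFrom stats quantile rnorm runif sd setNames t.test chisq.test predict
#' @importFrom utils read.delim write.table head
NULL

setOldClass("svm")

#' GuideScreen: a guide-RNA activity screen
#'
#' Container for a functional CRISPR screen: one record
#' per 20-nt guide with the gene it targets and a continuous activity
#' measure (higher = more active).  After [labelByPercentile()] each record
#' additionally carries a potency class label.
#'
#' @slot guides [Biostrings::RNAStringSet] of 20-nt guide sequences
#'   (internal alphabet is RNA; DNA input is converted on construction).
#' @slot geneId character vector of target-gene identifiers.
#' @slot activity numeric vector of activity values (finite).
#' @slot label factor with levels `functional`, `non-functional`,
#'   `excluded-middle`; all `NA` until the screen is labeled.
#'
#' @seealso [readScreenTable()], [generateSyntheticScreen()],
#'   [labelByPercentile()]
#' @export
setClass("GuideScreen",
  slots = c(
    guides = "RNAStringSet",
    geneId = "character",
    activity = "numeric",
    label = "factor"
  )
)

.LABEL_LEVELS <- c("functional", "non-functional", "excluded-middle")

setValidity("GuideScreen", function(object) {
  n <- length(object@guides)
  msg <- character()
  if (length(object@geneId) != n || length(object@activity) != n ||
      length(object@label) != n)
    msg <- c(msg, "slot lengths differ")
  if (n > 0 && any(Biostrings::width(object@guides) != 20L))
    msg <- c(msg, "all guides must be exactly 20 nt")
  gc <- as.character(object@guides)
  if (n > 0 && any(grepl("[^ACGU]", gc)))
    msg <- c(msg, "guides must be over the {A,C,G,U} alphabet")
  if (n > 0 && any(!is.finite(object@activity)))
    msg <- c(msg, "activities must be finite")
  if (!identical(levels(object@label), .LABEL_LEVELS))
    msg <- c(msg, "label levels must be functional/non-functional/excluded-middle")
  if (length(msg)) msg else TRUE
})

#' Construct a GuideScreen
#'
#' @param guides character vector or `XStringSet` of 20-nt guide sequences;
#'   `T` is normalized to `U`.
#' @param geneId character vector of gene identifiers (recycled if scalar).
#' @param activity numeric activity values.
#' @param label optional class labels (character or factor).
#' @return a [GuideScreen-class] object.
#' @export
GuideScreen <- function(guides, geneId, activity, label = NULL) {
  g <- normalizeGuides(as.character(guides))
  n <- length(g)
  if (length(geneId) == 1L) geneId <- rep(geneId, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  new("GuideScreen",
      guides = Biostrings::RNAStringSet(g),
      geneId = as.character(geneId),
      activity = as.numeric(activity),
      label = factor(as.character(label), levels = .LABEL_LEVELS))
}

#' SgRNA: an assembled single guide RNA
#'
#' The 20-nt guide concatenated with the constant tracrRNA-derived scaffold.
#' Positions are numbered 1..length from the guide 5' end, so positions 1-20
#' are the guide and position 21 onward is the scaffold; with the default
#' S. pyogenes scaffold the assembly places `AAG` at positions 51-53, the
#' bases that can pair with a pyrimidine-rich guide 3' end and extend the
#' first scaffold stem-loop.
#'
#' @slot guide 20-nt RNA guide sequence.
#' @slot scaffold scaffold RNA sequence (>= 33 nt so positions 51-53 exist).
#' @slot fullSeq guide + scaffold concatenation.
#' @seealso [assembleSgRNA()], [defaultScaffold()]
#' @export
setClass("SgRNA",
  slots = c(guide = "character", scaffold = "character", fullSeq = "character"))

setValidity("SgRNA", function(object) {
  msg <- character()
  if (nchar(object@guide) != 20L || grepl("[^ACGU]", object@guide))
    msg <- c(msg, "guide must be a 20-nt RNA sequence")
  if (nchar(object@scaffold) < 33L)
    msg <- c(msg, "scaffold must be at least 33 nt (positions 51-53 undefined)")
  if (grepl("[^ACGU]", object@scaffold))
    msg <- c(msg, "scaffold must be an RNA sequence")
  if (!identical(object@fullSeq, paste0(object@guide, object@scaffold)))
    msg <- c(msg, "fullSeq must be guide followed by scaffold")
  if (length(msg)) msg else TRUE
})

#' ExonIndex: exact seed+PAM lookup over exon space
#'
#' Hash index mapping every 16-nt window of the exon set (both strands)
#' whose last three bases match `NGG` or `NAG` to its location, keyed by
#' the 13-nt PAM-proximal seed plus the 3-nt PAM.  Used for the exact
#' seed-match off-target exclusion rule.
#'
#' @slot index environment used as a hash map from 16-mer key to a
#'   data.frame of (exon_id, offset, strand) locations; offsets are 0-based
#'   starts of the 13-nt seed on the exon's plus strand.
#' @slot exons [Biostrings::DNAStringSet] the index was built from.
#' @seealso [buildExonIndex()], [seedPamHits()]
#' @export
setClass("ExonIndex",
  slots = c(index = "environment", exons = "DNAStringSet"))

#' GuideModel: trained RBF-SVM guide potency classifier
#'
#' Wraps an RBF-kernel support vector machine together with everything
#' needed to score new guides reproducibly: the feature manifest (name and
#' order of all predictors), per-feature min-max scaling constants learned
#' on the training data, the scaffold the structural features were computed
#' against, and the selected hyperparameters.
#'
#' @slot svm fitted [e1071::svm] object (probability model).
#' @slot featureNames character vector naming the predictor columns, in order.
#' @slot scaling 2 x p numeric matrix (rows `min`, `max`) of training-data
#'   feature ranges used for min-max scaling to \[0, 1\].
#' @slot scaffold scaffold sequence the accessibility features assume.
#' @slot cost,gamma selected RBF hyperparameters.
#' @slot prefiltered logical; whether training records were first passed
#'   through the hard pre-filters.
#' @seealso [trainGuideModel()], [predictScores()]
#' @export
setClass("GuideModel",
  slots = c(
    svm = "svm",
    featureNames = "character",
    scaling = "matrix",
    scaffold = "character",
    cost = "numeric",
    gamma = "numeric",
    prefiltered = "logical"
  )
)

setValidity("GuideModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@scaling), c("min", "max")))
    msg <- c(msg, "scaling must have rows 'min' and 'max'")
  if (ncol(object@scaling) != length(object@featureNames))
    msg <- c(msg, "scaling columns must match featureNames")
  if (object@cost <= 0 || object@gamma <= 0)
    msg <- c(msg, "cost and gamma must be positive")
  if (length(msg)) msg else TRUE
})

#' CVResult: pooled out-of-fold cross-validation scores
#'
#' @slot mode `"tenfold"` or `"gene"` (leave-one-gene-out).
#' @slot scores numeric out-of-fold scores, one per labeled record.
#' @slot labels factor of true classes (`functional` positive).
#' @slot fold integer fold assignment per record.
#' @slot auc area under the ROC curve of the pooled scores.
#' @slot cost,gamma hyperparameters used in every fold.
#' @seealso [crossValidate()]
#' @export
setClass("CVResult",
  slots = c(mode = "character", scores = "numeric", labels = "factor",
            fold = "integer", auc = "numeric",
            cost = "numeric", gamma = "numeric"))
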