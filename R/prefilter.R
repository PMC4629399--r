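#' Default pre-filter thresholds
#'
#' The hard exclusion rules applied before SVM scoring, with their default
#' cutoffs.  A guide fails:
#' \describe{
#'   \item{SELF_FOLD}{self-folding ΔG below `selfFoldDG` (-8 kcal/mol):
#'     strong intramolecular structure.}
#'   \item{DUPLEX}{guide:target duplex ΔG below `duplexDG` (-22 kcal/mol):
#'     over-stable hybrid.}
#'   \item{GC}{GC content above `gcMax` (0.80).}
#'   \item{UUU_SEED}{UUU within the last six bases (pol III termination
#'     signal next to the seed).}
#'   \item{REPETITIVE}{AAAAA, CCCCC, GGGG or UUUU run present.}
#'   \item{POS19_U}{U at guide position 19.}
#'   \item{POS20_CU}{C or U at guide position 20 (favors pairing with
#'     scaffold AAG at sgRNA positions 51-53, burying the seed).}
#' }
#' Boundary semantics are inclusive passes: a value exactly at a cutoff
#' passes (the rules exclude strictly beyond it).
#'
#' @return named list of thresholds.
#' @export
prefilterThresholds <- function() {
  list(selfFoldDG = -8, duplexDG = -22, gcMax = 0.80)
}

.PREFILTER_RULES <- c("SELF_FOLD", "DUPLEX", "GC", "UUU_SEED",
                      "REPETITIVE", "POS19_U", "POS20_CU")

#' Apply the hard pre-filters to guides
#'
#' Evaluates every rule for every guide (no short-circuiting), so the
#' report lists all failed rules per guide -- this is what makes class-wise
#' exclusion audits informative.
#'
#' @param guides character vector of 20-nt guides.
#' @param thresholds list as from [prefilterThresholds()]; numeric cutoffs
#'   are overridable.
#' @param selfFoldDG,duplexDG optional precomputed feature vectors (saves
#'   refolding when a feature matrix already exists).
#' @return data.frame with columns `guide`, `passed` (logical),
#'   `failed_rules` (comma-separated rule ids, `""` if none) and the
#'   numeric features `gc`, `selfFoldDG`, `duplexDG`.
#' @export
applyPrefilters <- function(guides, thresholds = prefilterThresholds(),
                            selfFoldDG = NULL, duplexDG = NULL) {
  guides <- normalizeGuides(guides)
  gc <- gcContent(guides)
  if (is.null(selfFoldDG)) selfFoldDG <- guideSelfFoldDG(guides)
  if (is.null(duplexDG)) duplexDG <- sgSelect::duplexDG(guides)
  flags <- motifFlags(guides)
  fail <- cbind(
    SELF_FOLD = selfFoldDG < thresholds$selfFoldDG,
    DUPLEX = duplexDG < thresholds$duplexDG,
    GC = gc > thresholds$gcMax,
    UUU_SEED = flags$uuuSeed,
    REPETITIVE = flags$repetitive,
    POS19_U = substr(guides, 19, 19) == "U",
    POS20_CU = substr(guides, 20, 20) %in% c("C", "U")
  )
  failed <- apply(fail, 1L, function(r)
    paste(.PREFILTER_RULES[r], collapse = ","))
  data.frame(guide = guides, passed = !apply(fail, 1L, any),
             failed_rules = failed,
             gc = gc, selfFoldDG = selfFoldDG, duplexDG = duplexDG,
             stringsAsFactors = FALSE)
}

#' Audit pre-filter exclusion by potency class
#'
#' On a labeled screen, reports what fraction of each class the pre-filters
#' exclude and retain.  A well-behaved filter set excludes most
#' non-functional guides while retaining the majority of functional ones.
#'
#' @param screen a labeled [GuideScreen-class].
#' @param thresholds see [applyPrefilters()].
#' @return data.frame with one row per class: `n`, `excluded`,
#'   `fraction_excluded`, `fraction_retained`.
#' @export
auditPrefilters <- function(screen, thresholds = prefilterThresholds()) {
  tr <- trainingRecords(screen)
  pf <- applyPrefilters(guideSeqs(tr), thresholds)
  lab <- droplevels(guideLabels(tr))
  do.call(rbind, lapply(levels(lab), function(cl) {
    sel <- lab == cl
    data.frame(class = cl, n = sum(sel),
               excluded = sum(!pf$passed[sel]),
               fraction_excluded = mean(!pf$passed[sel]),
               fraction_retained = mean(pf$passed[sel]),
               stringsAsFactors = FALSE)
  }))
}
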