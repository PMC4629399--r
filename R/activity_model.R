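#' Names and order of the potency-model predictors
#'
#' The fixed 176-entry feature manifest: GC content (1), mononucleotide
#' counts (4), dinucleotide counts (16), trinucleotide counts (64), the
#' three motif flags, guide self-folding ΔG, guide:target duplex ΔG,
#' MFE-structure accessibility at sgRNA positions 18-20 and 51-53 (6), and
#' the position-specific one-hot encoding (80).  A trained model stores
#' this manifest and refuses to score against a different one.
#'
#' @return character vector of length 176.
#' @export
featureManifest <- function() {
  rna <- c("A", "C", "G", "U")
  di <- paste0(rep(rna, each = 4), rep(rna, 4))
  tri <- paste0(rep(rna, each = 16), rep(rep(rna, each = 4), 4),
                rep(rna, 16))
  c("gc",
    paste0("mono", rna),
    paste0("di.", di),
    paste0("tri.", tri),
    "repetitive", "gggg", "uuuSeed",
    "selfFoldDG", "duplexDG",
    paste0("acc", c(18:20, 51:53)),
    paste0("pos", sprintf("%02d", rep(1:20, each = 4)), ".", rep(rna, 20)))
}

#' Assemble raw (unscaled) feature vectors for guides
#'
#' Computes every predictor in the manifest order.  Structural features
#' fold the full sgRNA (guide + scaffold) and the isolated guide with
#' RNAfold in one batch per call.
#'
#' @param guides character vector of 20-nt guides.
#' @param scaffold scaffold used for the accessibility features.
#' @return numeric matrix, one row per guide, 176 named columns.
#' @export
assembleFeatures <- function(guides, scaffold = defaultScaffold()) {
  guides <- normalizeGuides(guides)
  scaffold <- normalizeGuides(scaffold, length = NA)
  mono <- kmerCounts(guides, 1)
  di <- kmerCounts(guides, 2)
  tri <- kmerCounts(guides, 3)
  flags <- motifFlags(guides)
  self <- guideSelfFoldDG(guides)
  dup <- duplexDG(guides)
  full <- foldRNA(paste0(guides, scaffold))
  acc <- accessibilityFromStructure(full$structure)
  x <- cbind(gcContent(guides), mono, di, tri,
             as.numeric(flags$repetitive), as.numeric(flags$gggg),
             as.numeric(flags$uuuSeed), self, dup,
             acc * 1L, posOneHotMatrix(guides))
  colnames(x) <- featureManifest()
  rownames(x) <- NULL
  x
}

#' Hyperparameter grid for RBF-SVM tuning
#'
#' Log-spaced cost and gamma ranges following the libsvm practical guide
#' (C in 2^-5..2^15, gamma in 2^-15..2^3), at a coarse step of 2^4.
#'
#' @param costStep,gammaStep exponent step sizes.
#' @return list with numeric vectors `cost` and `gamma`.
#' @export
svmGrid <- function(costStep = 4, gammaStep = 4) {
  list(cost = 2^seq(-5, 15, by = costStep),
       gamma = 2^seq(-15, 3, by = gammaStep))
}

# min-max scaling constants; constant features get max = min + 1 so they
# scale to 0 instead of dividing by zero
.scalingConstants <- function(x) {
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  maxs[maxs == mins] <- mins[maxs == mins] + 1
  rbind(min = mins, max = maxs)
}

.applyScaling <- function(x, scaling) {
  sweep(sweep(x, 2, scaling["min", ]), 2,
        scaling["max", ] - scaling["min", ], "/")
}

# grid search by k-fold CV accuracy on (optionally subsampled) scaled data;
# ties resolved toward the first grid point (smallest gamma, then cost)
.tuneRBF <- function(x, y, grid, folds = 3, subsample = 600, seed = 1) {
  withPrivateSeed(seed, {
    if (nrow(x) > subsample) {
      idx <- unlist(lapply(split(seq_along(y), y), function(i)
        sample(i, round(length(i) * subsample / length(y)))))
      x <- x[idx, , drop = FALSE]
      y <- y[idx]
    }
    best <- NULL
    for (g in grid$gamma) for (co in grid$cost) {
      acc <- e1071::svm(x, y, kernel = "radial", cost = co, gamma = g,
                        scale = FALSE, cross = folds)$tot.accuracy
      if (is.null(best) || acc > best$acc)
        best <- list(cost = co, gamma = g, acc = acc)
    }
    best
  })
}

#' Train the RBF-SVM guide potency model
#'
#' Takes the extreme-class records of a labeled screen, optionally applies
#' the hard pre-filters to the training data first (the default, matching
#' the genome-wide design configuration; the unfiltered mode matches the
#' model the cross-validation analyses evaluate), min-max scales every
#' feature to \[0, 1\], selects (cost, gamma) by grid-search
#' cross-validation, and fits the final probability-output SVM.
#'
#' @param screen a labeled [GuideScreen-class].
#' @param grid hyperparameter grid, see [svmGrid()]; a single-point grid
#'   fixes the hyperparameters.
#' @param seed integer seed controlling tuning subsampling/fold RNG.
#' @param prefilter logical; drop training records failing
#'   [applyPrefilters()] before fitting (default `TRUE`).
#' @param scaffold scaffold for structural features.
#' @param tuneSubsample,tuneFolds grid-search economy knobs: records used
#'   and internal CV folds during tuning.
#' @return a [GuideModel-class].
#' @export
trainGuideModel <- function(screen, grid = svmGrid(), seed = 1,
                            prefilter = TRUE,
                            scaffold = defaultScaffold(),
                            tuneSubsample = 600, tuneFolds = 3) {
  tr <- trainingRecords(screen)
  if (prefilter) {
    pf <- applyPrefilters(guideSeqs(tr))
    tr <- tr[pf$passed]
  }
  y <- droplevels(guideLabels(tr))
  if (nlevels(y) < 2L)
    stop("training data contain a single class")
  if (any(table(y) < 10L))
    stop("need at least 10 records per class")
  x <- assembleFeatures(guideSeqs(tr), scaffold)
  scaling <- .scalingConstants(x)
  xs <- .applyScaling(x, scaling)
  tuned <- .tuneRBF(xs, y, grid, folds = tuneFolds,
                    subsample = tuneSubsample, seed = seed)
  fit <- withPrivateSeed(seed,
    e1071::svm(xs, y, kernel = "radial", cost = tuned$cost,
               gamma = tuned$gamma, scale = FALSE, probability = TRUE))
  new("GuideModel", svm = fit, featureNames = colnames(x),
      scaling = scaling, scaffold = scaffold,
      cost = tuned$cost, gamma = tuned$gamma, prefiltered = prefilter)
}

#' Score guides with a trained potency model
#'
#' @param model a [GuideModel-class].
#' @param guides character vector of 20-nt guides.
#' @return numeric scores in \[0, 1\]; higher = more likely functional.
#'   Scoring refuses to proceed if the model's feature manifest does not
#'   match this package's assembler.
#' @export
predictScores <- function(model, guides) {
  stopifnot(is(model, "GuideModel"))
  if (!identical(modelManifest(model), featureManifest()))
    stop("model feature manifest does not match the feature assembler; ",
         "refusing to score")
  x <- assembleFeatures(guides, modelScaffold(model))
  xs <- .applyScaling(x, model@scaling)
  p <- predict(model@svm, xs, probability = TRUE)
  unname(attr(p, "probabilities")[, "functional"])
}

#' Save / load a trained model
#'
#' The serialized file carries the SVM, scaling constants, manifest and
#' scaffold, so a reloaded model reproduces scores bit-identically.
#'
#' @param model a [GuideModel-class].
#' @param path file path.
#' @export
saveGuideModel <- function(model, path) {
  stopifnot(is(model, "GuideModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveGuideModel
#' @export
readGuideModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "GuideModel")) stop("file does not contain a GuideModel")
  validObject(model)
  model
}

# decision values oriented so that higher = functional
.decisionScores <- function(fit, xs) {
  p <- predict(fit, xs, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  score <- dv[, 1]
  cls <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (cls != "functional") score <- -score
  unname(score)
}

#' Cross-validated evaluation of the potency model
#'
#' Two schemes: `"tenfold"` random partition of the labeled records, and
#' `"gene"` (leave-one-gene-out), where each fold holds out every guide
#' targeting one gene so performance reflects generalization to unseen
#' genes.  Folds are trained without pre-filtering (the evaluation the ROC
#' analysis of the method is based on); feature scaling is learned inside
#' each training fold.  Pooled out-of-fold scores give the AUC.
#'
#' @param screen a labeled [GuideScreen-class].
#' @param mode `"tenfold"` or `"gene"`.
#' @param seed fold-assignment / tuning seed.
#' @param cost,gamma RBF hyperparameters; if `NULL` they are tuned once on
#'   the full labeled set with [svmGrid()] and reused in every fold.
#' @param scaffold scaffold for structural features.
#' @param nfold number of folds for `"tenfold"` mode.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(screen, mode = c("tenfold", "gene"), seed = 1,
                          cost = NULL, gamma = NULL,
                          scaffold = defaultScaffold(), nfold = 10) {
  mode <- match.arg(mode)
  tr <- trainingRecords(screen)
  y <- droplevels(guideLabels(tr))
  if (nlevels(y) < 2L) stop("both classes must be present")
  n <- length(tr)
  if (mode == "gene") {
    genes <- geneIds(tr)
    if (length(unique(genes)) < 2L)
      stop("leave-one-gene-out needs at least 2 genes")
    fold <- as.integer(factor(genes))
  } else {
    fold <- withPrivateSeed(seed, sample(rep_len(seq_len(nfold), n)))
  }
  x <- assembleFeatures(guideSeqs(tr), scaffold)
  if (is.null(cost) || is.null(gamma)) {
    scAll <- .scalingConstants(x)
    tuned <- .tuneRBF(.applyScaling(x, scAll), y, svmGrid(), seed = seed)
    cost <- tuned$cost
    gamma <- tuned$gamma
  }
  scores <- numeric(n)
  for (k in sort(unique(fold))) {
    test <- fold == k
    scaling <- .scalingConstants(x[!test, , drop = FALSE])
    fit <- e1071::svm(.applyScaling(x[!test, , drop = FALSE], scaling),
                      y[!test], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    scores[test] <- .decisionScores(
      fit, .applyScaling(x[test, , drop = FALSE], scaling))
  }
  new("CVResult", mode = mode, scores = scores, labels = y,
      fold = fold, auc = rocAUC(scores, y), cost = cost, gamma = gamma)
}

.positiveMask <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels) || is.character(labels)) {
    lv <- unique(as.character(labels))
    pos <- if ("functional" %in% lv) "functional" else sort(lv)[1]
    return(as.character(labels) == pos)
  }
  labels == 1
}

#' Area under the ROC curve
#'
#' Equals the probability that a randomly chosen positive outranks a
#' randomly chosen negative, with ties counted one half (the Mann-Whitney
#' statistic), so it is invariant to monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels: logical (`TRUE` positive), factor/character
#'   (`"functional"` positive), or 0/1.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  pos <- .positiveMask(labels)
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Precision-recall curve
#'
#' Precision (fraction of true positives among predicted positives) and
#' recall (fraction of positives recovered) at every distinct score
#' threshold, in descending threshold order.  The attribute `baseline`
#' carries the precision of random selection (the positive-class
#' fraction).
#'
#' @inheritParams rocAUC
#' @return data.frame with columns `threshold`, `precision`, `recall`,
#'   `n_selected`; attribute `baseline`.
#' @export
prCurve <- function(scores, labels) {
  pos <- .positiveMask(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  out <- do.call(rbind, lapply(thr, function(t) {
    sel <- scores >= t
    data.frame(threshold = t,
               precision = sum(pos & sel) / sum(sel),
               recall = sum(pos & sel) / sum(pos),
               n_selected = sum(sel))
  }))
  attr(out, "baseline") <- mean(pos)
  out
}
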