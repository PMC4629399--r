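#' Read a guide-activity screen table
#'
#' Reads a guide-activity screen: one row per guide with its 20-nt sequence,
#' target gene and a continuous activity measure.  Field separator is
#' sniffed from the header line (tab or comma).  `T` is normalized to `U`.
#'
#' @param path TSV/CSV file with a header row.
#' @param columnMap named character vector mapping the roles `guide`,
#'   `gene`, `activity` to column names in the file.  The activity column
#'   is user-selectable because screens may report raw or gene-normalized
#'   scores.
#' @return an unlabeled [GuideScreen-class].
#' @export
readScreenTable <- function(path,
                            columnMap = c(guide = "guide_seq",
                                          gene = "gene_id",
                                          activity = "activity")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- columnMap[c("guide", "gene", "activity")]
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("column(s) not found: ", paste(missing, collapse = ", "))
  guide <- as.character(tab[[need[["guide"]]]])
  act <- suppressWarnings(as.numeric(tab[[need[["activity"]]]]))
  # per-row validation so errors carry the offending file line (header = 1)
  for (i in seq_along(guide)) {
    ok <- tryCatch({normalizeGuides(guide[i]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("malformed row at line ", i + 1L, ": ", ok)
    if (!is.finite(act[i]))
      stop("malformed row at line ", i + 1L, ": non-finite activity")
  }
  GuideScreen(guide, as.character(tab[[need[["gene"]]]]), act)
}

#' Write a screen table
#'
#' @param screen a [GuideScreen-class].
#' @param path output TSV path.
#' @export
writeScreenTable <- function(screen, path) {
  df <- data.frame(guide_seq = guideSeqs(screen),
                   gene_id = geneIds(screen),
                   activity = activities(screen))
  lab <- guideLabels(screen)
  if (!all(is.na(lab))) df$label <- as.character(lab)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label a screen by activity percentile
#'
#' Assigns the most potent guides (top fraction of the activity ranking) to
#' the `functional` class and the least potent (bottom fraction) to
#' `non-functional`; everything in between is `excluded-middle` and omitted
#' from training.  Class size is `ceiling(fraction * n)` per class,
#' computed on order statistics so the labeling is invariant under any
#' order-preserving transform of activity; records tied with the boundary
#' value join the extreme class.
#'
#' @param screen a [GuideScreen-class].
#' @param top,bottom class fractions, defaults 0.2 / 0.2.
#' @return the screen with its `label` slot filled.
#' @export
labelByPercentile <- function(screen, top = 0.2, bottom = 0.2) {
  stopifnot(is(screen, "GuideScreen"))
  if (top <= 0 || bottom <= 0 || top + bottom > 1)
    stop("need 0 < bottom, 0 < top, top + bottom <= 1")
  act <- activities(screen)
  n <- length(act)
  if (n < 2L || diff(range(act)) == 0)
    stop("percentile labeling undefined: all activities identical")
  srt <- sort(act)
  thrTop <- srt[n - ceiling(top * n) + 1L]
  thrBottom <- srt[ceiling(bottom * n)]
  lab <- rep("excluded-middle", n)
  lab[act >= thrTop] <- "functional"
  lab[act <= thrBottom] <- "non-functional"
  if (any(act >= thrTop & act <= thrBottom))
    stop("top and bottom classes overlap; fractions too large for the ties")
  initialize(screen, label = factor(lab, levels = .LABEL_LEVELS))
}

#' Generate a synthetic guide-activity screen
#'
#' Emulates a flow-cytometry potency screen for testing and calibration
#' without any external download.  Guides are drawn uniformly over
#' `{A,C,G,U}^20`, rejecting any containing `UUUU` (such guides are
#' preselected out of real screens because UUUU terminates pol III
#' transcription).  Activity is a planted linear signal plus standard
#' normal noise:
#'
#'   `activity = effectSize * z(A-count - GGGG - |selfFoldDG| - pyr20) + N(0,1)`
#'
#' where `z()` standardizes the planted score, `GGGG` and `pyr20`
#' (position-20 C/U) are indicators and `|selfFoldDG|` is the magnitude of
#' the guide self-folding free energy -- a deliberate overlap with the
#' features the potency model uses, so parameter-recovery tests are
#' meaningful.  Genes are assigned round-robin over nine synthetic genes,
#' matching the gene count of the screen the method was developed on.
#'
#' @param n number of guides (>= 20); default 2000.
#' @param seed integer seed; generation is bit-reproducible and leaves the
#'   caller's RNG state untouched.
#' @param effectSize signal-to-noise scale; default 2.  0 yields activity
#'   independent of sequence.
#' @return an unlabeled [GuideScreen-class].
#' @export
generateSyntheticScreen <- function(n = 2000, seed = 1, effectSize = 2) {
  if (n < 20) stop("n must be at least 20")
  withPrivateSeed(seed, {
    guides <- character(0)
    while (length(guides) < n) {
      draw <- vapply(seq_len(n - length(guides) + 50L), function(i)
        paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE),
              collapse = ""), "")
      guides <- c(guides, draw[!grepl("UUUU", draw)])
    }
    guides <- guides[seq_len(n)]
    noise <- rnorm(n)
    aCount <- drop(kmerCounts(guides, 1)[, "A"])
    gggg <- as.numeric(motifFlags(guides)$gggg)
    selfDG <- guideSelfFoldDG(guides)
    pyr20 <- as.numeric(substr(guides, 20, 20) %in% c("C", "U"))
    planted <- aCount - gggg - abs(selfDG) - pyr20
    z <- if (sd(planted) > 0) (planted - mean(planted)) / sd(planted)
         else planted * 0
    activity <- effectSize * z + noise
    GuideScreen(guides,
                paste0("gene", rep_len(1:9, n)),
                activity)
  })
}
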