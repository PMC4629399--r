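#' GC content of guide sequences
#'
#' @param guides character vector of 20-nt guides.
#' @return numeric vector in \[0, 1\]: (#G + #C) / 20.
#' @export
gcContent <- function(guides) {
  guides <- normalizeGuides(guides)
  set <- Biostrings::RNAStringSet(guides)
  unname(drop(Biostrings::letterFrequency(set, "GC"))) / 20
}

#' Overlapping k-mer counts
#'
#' Counts every overlapping window of width `k` within the 20-mer; the
#' counts therefore sum to `21 - k`.  Windows never span guide boundaries.
#'
#' @param guides character vector of 20-nt guides.
#' @param k window width, 1, 2 or 3.
#' @return integer matrix, one row per guide, `4^k` named columns in
#'   lexicographic ACGU order.
#' @export
kmerCounts <- function(guides, k) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  guides <- normalizeGuides(guides)
  set <- Biostrings::RNAStringSet(guides)
  m <- Biostrings::oligonucleotideFrequency(set, width = k)
  rownames(m) <- NULL
  m
}

#' Synthesis/transcription liability motif flags
#'
#' Three boolean flags per guide: `repetitive` (any of AAAAA, CCCCC, GGGG
#' or UUUU -- runs that compromise oligo synthesis), `gggg` (the GGGG run
#' specifically, which additionally favors guanine-tetrad structure), and
#' `uuuSeed` (UUU anywhere within the last six bases, a potential RNA
#' polymerase III termination signal adjacent to the seed).
#'
#' @param guides character vector of 20-nt guides.
#' @return data.frame with logical columns `repetitive`, `gggg`, `uuuSeed`.
#' @export
motifFlags <- function(guides) {
  guides <- normalizeGuides(guides)
  data.frame(
    repetitive = grepl("AAAAA|CCCCC|GGGG|UUUU", guides),
    gggg = grepl("GGGG", guides),
    uuuSeed = grepl("UUU", substr(guides, 15, 20))
  )
}

#' Position-specific one-hot encoding of a guide
#'
#' @param guide a single 20-nt guide.
#' @return 20 x 4 binary matrix; row i encodes the base at position i
#'   (1-based from the 5' end, position 20 adjacent to the PAM), columns
#'   A, C, G, U.
#' @export
positionOneHot <- function(guide) {
  guide <- normalizeGuides(guide)
  stopifnot(length(guide) == 1L)
  bases <- strsplit(guide, "")[[1]]
  m <- matrix(0L, nrow = 20, ncol = 4,
              dimnames = list(paste0("pos", 1:20), c("A", "C", "G", "U")))
  m[cbind(1:20, match(bases, colnames(m)))] <- 1L
  m
}

# vectorized one-hot: n x 80 matrix, columns pos01.A .. pos20.U
posOneHotMatrix <- function(guides) {
  guides <- normalizeGuides(guides)
  n <- length(guides)
  ab <- c("A", "C", "G", "U")
  m <- matrix(0L, nrow = n, ncol = 80)
  colnames(m) <- paste0("pos", sprintf("%02d", rep(1:20, each = 4)), ".",
                        rep(ab, 20))
  for (p in 1:20) {
    b <- match(substr(guides, p, p), ab)
    m[cbind(seq_len(n), (p - 1L) * 4L + b)] <- 1L
  }
  m
}

#' Enrichment statistics for one feature between potency classes
#'
#' Compares a feature between functional and non-functional guides.
#' Continuous features (counts, free energies) use Welch's two-sample
#' t-test and report the ratio of class means; binary flags use the
#' chi-squared test and report the ratio of class proportions.
#'
#' @param functional,nonfunctional feature values (numeric or logical) for
#'   the two classes; both non-empty.
#' @param test `"auto"` (logical or 0/1 input chooses chi-squared),
#'   `"t"` or `"chisq"`.
#' @param featureName label carried into the output.
#' @return one-row data.frame: `feature`, `enrichment_ratio`
#'   (mean functional / mean non-functional), `p_value`, `test`.
#' @export
featureStats <- function(functional, nonfunctional, test = "auto",
                         featureName = "") {
  if (length(functional) == 0L || length(nonfunctional) == 0L)
    stop("both groups must be non-empty")
  test <- match.arg(test, c("auto", "t", "chisq"))
  f <- as.numeric(functional)
  nf <- as.numeric(nonfunctional)
  if (test == "auto") {
    binary <- is.logical(functional) ||
      all(c(f, nf) %in% c(0, 1))
    test <- if (binary) "chisq" else "t"
  }
  mnf <- mean(nf)
  if (mnf == 0)
    stop("non-functional mean is zero; enrichment ratio undefined for '",
         featureName, "'")
  ratio <- mean(f) / mnf
  if (test == "t") {
    if (sd(f) == 0 && sd(nf) == 0) {
      p <- if (mean(f) == mnf) 1 else 0
    } else {
      p <- t.test(f, nf)$p.value
    }
  } else {
    tab <- rbind(functional = c(sum(f == 1), sum(f != 1)),
                 nonfunctional = c(sum(nf == 1), sum(nf != 1)))
    p <- if (identical(prop.table(tab, 1)[1, ], prop.table(tab, 1)[2, ])) 1
         else suppressWarnings(chisq.test(tab)$p.value)
  }
  data.frame(feature = featureName, enrichment_ratio = ratio,
             p_value = p, test = if (test == "t") "t-test" else "chi-squared",
             stringsAsFactors = FALSE)
}

#' Class-wise enrichment table over standard guide features
#'
#' Convenience audit: computes [featureStats()] for mononucleotide counts,
#' GC content, the motif flags, self-folding ΔG and duplex ΔG on a labeled
#' screen.
#'
#' @param screen a labeled [GuideScreen-class].
#' @return data.frame of enrichment statistics, one row per feature.
#' @export
screenFeatureStats <- function(screen) {
  tr <- trainingRecords(screen)
  g <- guideSeqs(tr)
  pos <- guideLabels(tr) == "functional"
  mono <- kmerCounts(g, 1)
  flags <- motifFlags(g)
  feats <- cbind(as.data.frame(mono),
                 gc = gcContent(g),
                 flags,
                 selfFoldDG = guideSelfFoldDG(g),
                 duplexDG = duplexDG(g))
  do.call(rbind, lapply(names(feats), function(nm) {
    tryCatch(featureStats(feats[[nm]][pos], feats[[nm]][!pos],
                          featureName = nm),
             error = function(e)
               data.frame(feature = nm, enrichment_ratio = NA_real_,
                          p_value = NA_real_, test = NA_character_,
                          stringsAsFactors = FALSE))
  }))
}
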