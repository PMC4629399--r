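#' Enumerate PAM-adjacent guide candidates in target sequences
#'
#' Finds every 20-mer immediately 5' of an `NGG` PAM on both strands of
#' each input record.  Candidates whose protospacer or PAM contains `N`
#' are dropped.  `start` is the 0-based plus-strand offset of the
#' protospacer: on the plus strand `input[start..start+20)` equals the
#' guide as DNA, on the minus strand it equals its reverse complement.
#'
#' @param targets FASTA path, named character vector, or `DNAStringSet`.
#' @return data.frame: `source_id`, `start` (0-based), `strand`, `guide`
#'   (RNA alphabet), `pam`.  Sequences shorter than 23 nt contribute no
#'   candidates (with a warning).
#' @export
scanPamSites <- function(targets) {
  targets <- .asExons(targets)
  rows <- list()
  for (i in seq_along(targets)) {
    s <- as.character(targets[[i]])
    L <- nchar(s)
    id <- names(targets)[i]
    if (L < 23L) {
      warning("sequence '", id, "' is shorter than 23 nt; no candidates")
      next
    }
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") s else revcompDNA(s)
      gg <- Biostrings::start(
        Biostrings::matchPattern("GG", Biostrings::DNAString(sc)))
      for (t in gg) {
        # GG at scan positions t..t+1 is the PAM core; protospacer is the
        # 20-mer ending 2 positions before it
        protoStart <- t - 21L
        if (protoStart < 1L) next
        proto <- substr(sc, protoStart, protoStart + 19L)
        pam <- substr(sc, protoStart + 20L, protoStart + 22L)
        if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) next
        start0 <- if (strand == "+") protoStart - 1L
                  else L - (protoStart - 1L) - 20L
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = id, start = start0, strand = strand,
          guide = chartr("T", "U", proto), pam = pam,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(source_id = character(), start = integer(),
                      strand = character(), guide = character(),
                      pam = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$source_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design configuration
#'
#' @param thresholds pre-filter cutoffs, see [prefilterThresholds()].
#' @param maxMismatches similarity-scan budget (default 3, i.e. the 85 %
#'   identity boundary).
#' @param scaffold scaffold for structural features.
#' @return named list.
#' @export
designConfig <- function(thresholds = prefilterThresholds(),
                         maxMismatches = 3,
                         scaffold = defaultScaffold()) {
  list(thresholds = thresholds, maxMismatches = maxMismatches,
       scaffold = scaffold)
}

#' Read a design configuration from YAML
#'
#' Recognized keys: a `thresholds` block (`selfFoldDG`, `duplexDG`,
#' `gcMax`), `maxMismatches`, and `scaffold`; anything omitted keeps its
#' default.
#'
#' @param path YAML file.
#' @return configuration list as from [designConfig()].
#' @export
readDesignConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- designConfig()
  for (k in names(raw$thresholds))
    cfg$thresholds[[k]] <- raw$thresholds[[k]]
  if (!is.null(raw$maxMismatches)) cfg$maxMismatches <- raw$maxMismatches
  if (!is.null(raw$scaffold))
    cfg$scaffold <- normalizeGuides(raw$scaffold, length = NA)
  cfg
}

#' End-to-end guide design
#'
#' Runs the full pipeline on user target sequences: PAM-site scan, hard
#' pre-filters, SVM potency scoring of the survivors, exon-restricted
#' off-target filtering, and ranking.  Cheap pre-filters run before the
#' SVM so unpromising candidates are eliminated without scoring, and
#' candidates already eliminated are not off-target-screened.  Every
#' enumerated candidate appears in the report with either its rank or its
#' elimination reason.
#'
#' @param targets target sequence(s): FASTA path, character, or
#'   `DNAStringSet`.
#' @param model a trained [GuideModel-class].
#' @param exonIndex optional [ExonIndex-class] for off-target screening;
#'   `NULL` disables the specificity step.
#' @param config list from [designConfig()] / [readDesignConfig()].
#' @param verbose log per-stage candidate counts.
#' @return data.frame, one row per enumerated candidate, ordered by rank
#'   then coordinate: `source_id`, `start` (1-based), `strand`, `guide`,
#'   `pam`, `gc`, `self_fold_dg`, `duplex_dg`, `prefilter_failures`,
#'   `seed_pam_hits`, `similarity_hits`, `svm_score`, `rank`.  Ranks are
#'   dense from 1 over candidates passing every filter, ordered by
#'   descending score, then fewer similarity hits, then 5'-most start.
#' @export
designGuides <- function(targets, model, exonIndex = NULL,
                         config = designConfig(), verbose = FALSE) {
  stopifnot(is(model, "GuideModel"))
  cand <- scanPamSites(targets)
  n <- nrow(cand)
  if (n == 0L) {
    warning("no guide candidates found")
    return(.emptyReport())
  }
  pf <- applyPrefilters(cand$guide, config$thresholds)
  if (verbose)
    message(sprintf("scanned %d candidates; %d pass pre-filters",
                    n, sum(pf$passed)))
  score <- rep(NA_real_, n)
  if (any(pf$passed))
    score[pf$passed] <- predictScores(model, cand$guide[pf$passed])
  seedHits <- rep(NA_integer_, n)
  simHits <- rep(NA_integer_, n)
  if (!is.null(exonIndex) && any(pf$passed)) {
    idx <- which(pf$passed)
    ot <- lapply(idx, function(i)
      list(exon_id = cand$source_id[i], start = cand$start[i],
           strand = cand$strand[i]))
    offt <- filterOffTargets(cand$guide[idx], exonIndex,
                             maxMismatches = config$maxMismatches,
                             onTargets = ot)
    seedHits[idx] <- offt$report$seed_pam_hits
    simHits[idx] <- offt$report$similarity_hits
    if (verbose)
      message(sprintf("%d candidates pass off-target screening",
                      sum(!offt$report$excluded)))
  } else if (any(pf$passed)) {
    seedHits[pf$passed] <- 0L
    simHits[pf$passed] <- 0L
  }
  eligible <- pf$passed & !is.na(score) &
    (is.na(seedHits) | seedHits == 0L) &
    (is.na(simHits) | simHits == 0L)
  rank <- rep(NA_integer_, n)
  if (any(eligible)) {
    e <- which(eligible)
    ord <- e[order(-score[e], simHits[e], cand$start[e])]
    rank[ord] <- seq_along(ord)
  }
  out <- data.frame(
    source_id = cand$source_id, start = cand$start + 1L,
    strand = cand$strand, guide = cand$guide, pam = cand$pam,
    gc = pf$gc, self_fold_dg = pf$selfFoldDG, duplex_dg = pf$duplexDG,
    prefilter_failures = pf$failed_rules,
    seed_pam_hits = seedHits, similarity_hits = simHits,
    svm_score = score, rank = rank, stringsAsFactors = FALSE)
  out <- out[order(is.na(out$rank), out$rank, out$source_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.REPORT_COLUMNS <- c("source_id", "start", "strand", "guide", "pam", "gc",
                     "self_fold_dg", "duplex_dg", "prefilter_failures",
                     "seed_pam_hits", "similarity_hits", "svm_score",
                     "rank")

.emptyReport <- function() {
  out <- data.frame(source_id = character(), start = integer(),
                    strand = character(), guide = character(),
                    pam = character(), gc = numeric(),
                    self_fold_dg = numeric(), duplex_dg = numeric(),
                    prefilter_failures = character(),
                    seed_pam_hits = integer(), similarity_hits = integer(),
                    svm_score = numeric(), rank = integer(),
                    stringsAsFactors = FALSE)
  out
}

#' Write / read a design report
#'
#' Fixed column order, tab-separated, deterministic row order (ranked
#' candidates by descending score first, score ties broken by smaller
#' start coordinate; unranked candidates after, by coordinate).
#'
#' @param report data.frame from [designGuides()].
#' @param path TSV path.
#' @export
writeDesignReport <- function(report, path) {
  stopifnot(all(.REPORT_COLUMNS %in% names(report)))
  write.table(report[, .REPORT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignReport
#' @export
readDesignReport <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(prefilter_failures = "character",
                            svm_score = "numeric", rank = "integer",
                            seed_pam_hits = "integer",
                            similarity_hits = "integer"))
}
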