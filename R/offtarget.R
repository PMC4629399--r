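# coerce exon input (FASTA path, character vector or DNAStringSet) to a
# named DNAStringSet
.asExons <- function(exons) {
  if (is.character(exons) && length(exons) == 1L && file.exists(exons))
    exons <- Biostrings::readDNAStringSet(exons)
  if (is.character(exons))
    exons <- Biostrings::DNAStringSet(toupper(exons))
  stopifnot(is(exons, "DNAStringSet"))
  if (length(exons) == 0L) stop("exon set is empty")
  if (is.null(names(exons)) || any(!nzchar(names(exons))))
    names(exons) <- paste0("exon", seq_along(exons))
  exons
}

# 1-based starts of GG and AG dinucleotides in a DNA character string
.pamCoreStarts <- function(s) {
  subject <- Biostrings::DNAString(s)
  starts <- c(Biostrings::start(Biostrings::matchPattern("GG", subject)),
              Biostrings::start(Biostrings::matchPattern("AG", subject)))
  sort(starts)
}

#' Build the exon seed+PAM index
#'
#' Indexes every 16-nt window of the exon set -- on both strands -- whose
#' last three bases match `NGG` or `NAG`, keyed by the window itself
#' (13-nt seed + 3-nt PAM).  A guide's 3' 13-nt seed followed by a
#' tolerated PAM can then be located by exact lookup.  Windows containing
#' `N` are never indexed.
#'
#' @param exons FASTA path, named character vector, or
#'   [Biostrings::DNAStringSet] of exon sequences (DNA).
#' @return an [ExonIndex-class].
#' @export
buildExonIndex <- function(exons) {
  exons <- .asExons(exons)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  addWindows <- function(s, id, L, strand) {
    # PAM core (GG/AG) occupies window positions 15-16
    for (t in .pamCoreStarts(s)) {
      w <- t - 14L
      if (w < 1L) next
      key <- substr(s, w, w + 15L)
      if (grepl("[^ACGT]", key)) next
      offset <- if (strand == "+") w - 1L else L - w - 12L
      env[[key]] <- c(env[[key]],
                      list(list(exon_id = id, offset = offset,
                                strand = strand)))
    }
  }
  for (i in seq_along(exons)) {
    s <- as.character(exons[[i]])
    id <- names(exons)[i]
    addWindows(s, id, nchar(s), "+")
    addWindows(revcompDNA(s), id, nchar(s), "-")
  }
  new("ExonIndex", index = env, exons = exons)
}

.emptyHits <- function() {
  data.frame(exon_id = character(), offset = integer(),
             strand = character(), kind = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

# on-target seed start (0-based, plus-strand coordinates) for a declared
# protospacer location
.onTargetSeedStart <- function(onTarget) {
  if (onTarget$strand == "+") onTarget$start + 7L else onTarget$start
}

#' Exact seed+PAM off-target hits for a guide
#'
#' Looks up every exonic occurrence (either strand) of the guide's 3' 13
#' nucleotides, as DNA, immediately followed by an `NGG` or `NAG` PAM.
#' Any such occurrence outside the intended target disqualifies the guide.
#'
#' @param guide a 20-nt guide.
#' @param index an [ExonIndex-class].
#' @param onTarget optional declared target as
#'   `list(exon_id=, start=, strand=)` with `start` the 0-based
#'   plus-strand protospacer start; that single location is excluded from
#'   the hits.
#' @return data.frame of hits: `exon_id`, `offset` (0-based seed start on
#'   the exon plus strand), `strand`, `kind = "seed_pam"`, `mismatches`
#'   (`NA`; seed matches are exact).
#' @export
seedPamHits <- function(guide, index, onTarget = NULL) {
  stopifnot(is(index, "ExonIndex"))
  guide <- normalizeGuides(guide)
  seed <- guideToDNA(substr(guide, 8, 20))
  keys <- paste0(seed,
                 rep(c("A", "C", "G", "T"), 2),
                 rep(c("GG", "AG"), each = 4))
  entries <- unlist(lapply(keys, function(k) index@index[[k]]),
                    recursive = FALSE)
  if (is.null(entries) || length(entries) == 0L) return(.emptyHits())
  hits <- data.frame(
    exon_id = vapply(entries, `[[`, "", "exon_id"),
    offset = vapply(entries, `[[`, 1L, "offset"),
    strand = vapply(entries, `[[`, "", "strand"),
    kind = "seed_pam", mismatches = NA_integer_,
    stringsAsFactors = FALSE)
  if (!is.null(onTarget)) {
    keep <- !(hits$exon_id == onTarget$exon_id &
              hits$offset == .onTargetSeedStart(onTarget) &
              hits$strand == onTarget$strand)
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$exon_id, hits$offset, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# mismatch count between equal-length DNA strings (vectorized over windows)
.countMismatches <- function(windows, pattern) {
  pm <- strsplit(pattern, "")[[1]]
  vapply(strsplit(windows, ""), function(w) sum(w != pm), 1L)
}

#' Similarity-based off-target hits for a guide
#'
#' Scans every 20-mer window of the exon set, both strands, for ungapped
#' matches to the guide with at most `maxMismatches` substitutions
#' (3 mismatches = 17/20 = 85 % identity, the exclusion boundary).
#' Windows containing `N` never match.  PAM presence is not required for
#' similarity hits.
#'
#' @param guide a 20-nt guide.
#' @param exons exon sequences (path, character, or `DNAStringSet`).
#' @param maxMismatches maximum substitutions, default 3.
#' @param onTarget optional declared target location (see [seedPamHits()]);
#'   when absent, a unique exact match flanked by an `NGG` PAM is treated
#'   as the on-target and excluded.
#' @return data.frame of hits: `exon_id`, `offset` (0-based start of the
#'   matched 20-mer on the exon plus strand), `strand`,
#'   `kind = "similarity"`, `mismatches`.
#' @export
similarityHits <- function(guide, exons, maxMismatches = 3,
                           onTarget = NULL) {
  exons <- .asExons(exons)
  guide <- normalizeGuides(guide)
  gdna <- guideToDNA(guide)
  patterns <- c("+" = gdna, "-" = revcompDNA(gdna))
  out <- .emptyHits()
  for (i in seq_along(exons)) {
    s <- as.character(exons[[i]])
    subject <- Biostrings::DNAString(s)
    for (strand in names(patterns)) {
      m <- Biostrings::matchPattern(patterns[[strand]], subject,
                                    max.mismatch = maxMismatches,
                                    fixed = TRUE)
      starts <- Biostrings::start(m)
      if (length(starts) == 0L) next
      wins <- substring(s, starts, starts + 19L)
      keep <- !grepl("[^ACGT]", wins)
      starts <- starts[keep]
      wins <- wins[keep]
      if (length(starts) == 0L) next
      mm <- .countMismatches(wins, patterns[[strand]])
      out <- rbind(out, data.frame(
        exon_id = names(exons)[i], offset = starts - 1L,
        strand = strand, kind = "similarity", mismatches = mm,
        stringsAsFactors = FALSE))
    }
  }
  out <- out[out$mismatches <= maxMismatches, , drop = FALSE]
  if (!is.null(onTarget)) {
    keep <- !(out$exon_id == onTarget$exon_id &
              out$offset == onTarget$start &
              out$strand == onTarget$strand)
    out <- out[keep, , drop = FALSE]
  } else {
    out <- .dropUniqueExact(out, exons)
  }
  out <- out[order(out$exon_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# drop the single exact (0-mismatch) hit with a valid NGG PAM, if unique:
# the undeclared on-target
.dropUniqueExact <- function(hits, exons) {
  exact <- which(hits$mismatches == 0L)
  if (length(exact) == 0L) return(hits)
  hasPam <- vapply(exact, function(j) {
    s <- as.character(exons[[hits$exon_id[j]]])
    if (hits$strand[j] == "+") {
      pam <- substr(s, hits$offset[j] + 21L, hits$offset[j] + 23L)
      grepl("^[ACGT]GG$", pam)
    } else {
      pam <- substr(s, hits$offset[j] - 2L, hits$offset[j])
      grepl("^CC[ACGT]$", pam)
    }
  }, logical(1))
  if (sum(hasPam) == 1L)
    hits <- hits[-exact[hasPam], , drop = FALSE]
  hits
}

#' Off-target filtering of guide candidates
#'
#' A candidate is excluded if it has at least one exact seed+PAM hit or at
#' least one >= 85 %-similarity hit outside its intended target.
#'
#' @param guides character vector of 20-nt guides.
#' @param index an [ExonIndex-class] built over the design space.
#' @param maxMismatches similarity budget, default 3.
#' @param onTargets optional list (one element per guide) of declared
#'   target locations, see [seedPamHits()].
#' @return list with `report` (data.frame: `guide`, `seed_pam_hits`,
#'   `similarity_hits`, `excluded`) and `hits` (per-guide data.frames of
#'   all hits).
#' @export
filterOffTargets <- function(guides, index, maxMismatches = 3,
                             onTargets = NULL) {
  stopifnot(is(index, "ExonIndex"))
  guides <- normalizeGuides(guides)
  hitList <- lapply(seq_along(guides), function(i) {
    ot <- if (is.null(onTargets)) NULL else onTargets[[i]]
    rbind(seedPamHits(guides[i], index, onTarget = ot),
          similarityHits(guides[i], index@exons,
                         maxMismatches = maxMismatches, onTarget = ot))
  })
  report <- data.frame(
    guide = guides,
    seed_pam_hits = vapply(hitList, function(h)
      sum(h$kind == "seed_pam"), 1L),
    similarity_hits = vapply(hitList, function(h)
      sum(h$kind == "similarity"), 1L),
    stringsAsFactors = FALSE)
  report$excluded <- report$seed_pam_hits + report$similarity_hits > 0L
  list(report = report, hits = hitList)
}

#' Export off-target hits as BED
#'
#' BED6 (0-based, half-open) with the hit kind in the name column and the
#' mismatch count in the score column (seed hits score 0).
#'
#' @param hits hit data.frame as returned by [seedPamHits()] or
#'   [similarityHits()].
#' @param path output path.
#' @export
writeHitsBED <- function(hits, path) {
  width <- ifelse(hits$kind == "seed_pam", 13L, 20L)
  bed <- data.frame(chrom = hits$exon_id,
                    start = hits$offset,
                    end = hits$offset + width,
                    name = hits$kind,
                    score = ifelse(is.na(hits$mismatches), 0L,
                                   hits$mismatches),
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
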