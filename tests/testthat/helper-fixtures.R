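# shared fixtures and independent oracles, all generated in code

randGuides <- function(n, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE),
          collapse = ""), ""))
}

randDNA <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

rcDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# O(n^2) pairwise AUC oracle, ties counted one half
bruteAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# duplex free energy by direct position-wise summation of the shipped
# parameter table (read independently of the package accessor)
bruteDuplexDG <- function(guide) {
  path <- system.file("extdata", "rna_dna_nn_dg37.tsv",
                      package = "sgSelect")
  tab <- utils::read.delim(path, comment.char = "#")
  par <- stats::setNames(tab$dg37, tab$pair)
  total <- par[["init"]]
  for (i in 1:19)
    total <- total + par[[substr(guide, i, i + 1)]]
  total
}

# character-level scan for seed+PAM occurrences (both strands) of a guide
# in a set of exon sequences; plus-strand coordinates, 0-based seed start
bruteSeedPamScan <- function(guide, exons) {
  seed <- chartr("U", "T", guide)
  seed <- substr(seed, 8, 20)
  out <- list()
  scanOne <- function(s, id) {
    L <- nchar(s)
    # plus strand: seed then NGG/NAG
    for (w in seq_len(max(L - 15, 0))) {
      win <- substr(s, w, w + 15)
      if (grepl("N", win, fixed = TRUE)) next
      if (substr(win, 1, 13) == seed &&
          substr(win, 15, 16) %in% c("GG", "AG"))
        out[[length(out) + 1]] <<- data.frame(
          exon_id = id, offset = w - 1L, strand = "+",
          stringsAsFactors = FALSE)
    }
    # minus strand: revcomp(PAM) then revcomp(seed) on the plus strand
    rcseed <- rcDNA(seed)
    for (w in seq_len(max(L - 15, 0))) {
      win <- substr(s, w, w + 15)
      if (grepl("N", win, fixed = TRUE)) next
      if (substr(win, 4, 16) == rcseed &&
          substr(win, 1, 2) %in% c("CC", "CT"))
        out[[length(out) + 1]] <<- data.frame(
          exon_id = id, offset = w + 2L, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(exons)) scanOne(as.character(exons[[i]]),
                                      names(exons)[i])
  if (length(out) == 0L)
    return(data.frame(exon_id = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$exon_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# sliding-window mismatch scan (both strands), 0-based window starts
bruteSimilarityScan <- function(guide, exons, maxMismatches = 3) {
  pats <- c("+" = chartr("U", "T", guide))
  pats["-"] <- rcDNA(pats[["+"]])
  out <- list()
  for (i in seq_along(exons)) {
    s <- as.character(exons[[i]])
    L <- nchar(s)
    if (L < 20) next
    for (w in seq_len(L - 19)) {
      win <- substr(s, w, w + 19)
      if (grepl("N", win, fixed = TRUE)) next
      wc <- strsplit(win, "")[[1]]
      for (strand in c("+", "-")) {
        mm <- sum(wc != strsplit(pats[[strand]], "")[[1]])
        if (mm <= maxMismatches)
          out[[length(out) + 1]] <- data.frame(
            exon_id = names(exons)[i], offset = w - 1L, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(exon_id = character(), offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$exon_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# small screen with hand-set activities for labeling tests
makeScreen <- function(activities, seed = 99) {
  GuideScreen(randGuides(length(activities), seed),
              paste0("g", rep_len(1:3, length(activities))),
              activities)
}
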