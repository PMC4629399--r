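#' Minimum-free-energy RNA folding
#'
#' Folds RNA sequences with the ViennaRNA `RNAfold` program (default energy
#' parameters, 37 degrees C) and returns the MFE dot-bracket structure and
#' free energy for each.  Sequences with no stable structure fold to the
#' open chain (all dots, 0.0 kcal/mol); reported MFE is clamped to <= 0.
#'
#' @param seqs character vector of RNA sequences (`T` accepted, converted).
#' @return data.frame with columns `sequence`, `structure`, `mfe` (kcal/mol).
#' @examples
#' \dontrun{foldRNA("GGGGAAAACCCC")}
#' @export
foldRNA <- function(seqs) {
  seqs <- normalizeGuides(seqs, length = NA)
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric()))
  if (any(!nzchar(seqs))) stop("empty sequence")
  infile <- tempfile("fold", fileext = ".seq")
  on.exit(unlink(infile))
  writeLines(seqs, infile)
  out <- system2(.checkRNAfold(), c("--noPS"), stdin = infile, stdout = TRUE)
  res <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(res, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", res))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable RNAfold output: ", res[which(bad)[1]])
  structure <- vapply(m, `[`, "", 2L)
  mfe <- as.numeric(vapply(m, `[`, "", 3L))
  stopifnot(nchar(structure) == nchar(seqs))
  open <- mfe >= 0
  mfe[open] <- 0
  structure[open] <- strrep(".", nchar(seqs[open]))
  data.frame(sequence = seqs, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Default S. pyogenes sgRNA scaffold
#'
#' The 80-nt constant tracrRNA-derived scaffold appended 3' of the guide.
#' In the assembled sgRNA (guide positions 1-20, scaffold 21-100) this
#' scaffold places `AAG` at positions 51-53 -- the bases that can pair with
#' a C/U-rich guide 3' end and extend the repeat:anti-repeat stem-loop,
#' burying the seed region.
#'
#' @return an 80-character RNA string.
#' @export
defaultScaffold <- function() {
  paste0("GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGG",
         "CACCGAGUCGGUGCUUUU")
}

#' Assemble a single guide RNA
#'
#' @param guide 20-nt guide sequence (RNA or DNA alphabet).
#' @param scaffold scaffold RNA, default [defaultScaffold()]; must be at
#'   least 33 nt so sgRNA positions 51-53 exist.
#' @return an [SgRNA-class] object.
#' @export
assembleSgRNA <- function(guide, scaffold = defaultScaffold()) {
  guide <- normalizeGuides(guide)
  scaffold <- normalizeGuides(scaffold, length = NA)
  stopifnot(length(guide) == 1L, length(scaffold) == 1L)
  new("SgRNA", guide = guide, scaffold = scaffold,
      fullSeq = paste0(guide, scaffold))
}

#' Per-position accessibility from a dot-bracket structure
#'
#' A position is accessible iff it is unpaired (a dot) in the MFE
#' structure.  This is a pure function of the structure string.
#'
#' @param structure dot-bracket string(s).
#' @param positions 1-based positions to report (default the seed 18-20 and
#'   scaffold 51-53 positions).
#' @return logical matrix, one row per structure, one column per position.
#' @export
accessibilityFromStructure <- function(structure,
                                       positions = c(18:20, 51:53)) {
  if (any(nchar(structure) < max(positions)))
    stop("structure shorter than requested positions")
  m <- vapply(positions,
              function(p) substr(structure, p, p) == ".",
              logical(length(structure)))
  m <- matrix(m, nrow = length(structure))
  colnames(m) <- paste0("acc", positions)
  m
}

#' Seed and scaffold accessibility of an assembled sgRNA
#'
#' Folds the full sgRNA and reports whether positions 18-20 (the 3' end of
#' the guide seed) and 51-53 (the scaffold bases they can pair with) are
#' unpaired in the MFE structure.
#'
#' @param sgrna an [SgRNA-class] object.
#' @return named logical vector `acc18`..`acc53`.
#' @export
sgRNAAccessibility <- function(sgrna) {
  stopifnot(is(sgrna, "SgRNA"))
  fr <- foldRNA(sgrna@fullSeq)
  drop(accessibilityFromStructure(fr$structure))
}

#' Self-folding free energy of guide sequences
#'
#' MFE of the isolated 20-mer guide; 0 if it forms no stable structure.
#' Strong self-structure (ΔG below about -8 kcal/mol) is a hallmark of
#' non-functional guides, whose seed region is sequestered intramolecularly.
#'
#' @param guides character vector of 20-nt guides.
#' @return numeric vector of ΔG values (kcal/mol, <= 0).
#' @export
guideSelfFoldDG <- function(guides) {
  guides <- normalizeGuides(guides)
  foldRNA(guides)$mfe
}

.nnEnv <- new.env(parent = emptyenv())

#' Nearest-neighbor parameters for RNA/DNA hybrid duplexes
#'
#' The Sugimoto et al. (1995) ΔG37 stacking parameters for RNA/DNA hybrids,
#' keyed by the RNA dinucleotide read 5'->3', plus the `init` initiation
#' term.  Shipped as a plain-text table so independent checks can sum the
#' same source values.
#'
#' @return named numeric vector (16 stacks + `init`), kcal/mol.
#' @export
nnParameters <- function() {
  if (is.null(.nnEnv$params)) {
    path <- system.file("extdata", "rna_dna_nn_dg37.tsv",
                        package = "sgSelect", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .nnEnv$params <- setNames(tab$dg37, tab$pair)
  }
  .nnEnv$params
}

#' RNA/DNA duplex free energy of a guide against its target
#'
#' Nearest-neighbor free energy (37 degrees C) of the duplex formed by the
#' RNA guide and its complementary DNA target strand: the sum of the 19
#' stacking terms over consecutive guide dinucleotides plus the initiation
#' penalty.  Only perfectly complementary pairs are supported; mismatch
#' energetics are out of scope.
#'
#' @param guides character vector of 20-nt RNA guides.
#' @param targets optional DNA targets, 5'->3'; each must be the reverse
#'   complement of the corresponding guide.  Defaults to the perfect target.
#' @return numeric vector of ΔG values (kcal/mol).
#' @export
duplexDG <- function(guides, targets = NULL) {
  guides <- normalizeGuides(guides)
  perfect <- revcompDNA(guideToDNA(guides))
  if (!is.null(targets)) {
    targets <- toupper(targets)
    if (any(targets != perfect))
      stop("target is not the perfect complement of the guide at index ",
           which(targets != perfect)[1])
  }
  par <- nnParameters()
  vapply(guides, function(g) {
    stacks <- substring(g, 1:19, 2:20)
    unname(par["init"] + sum(par[stacks]))
  }, numeric(1), USE.NAMES = FALSE)
}
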