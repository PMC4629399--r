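#' Normalize guide sequences to the internal RNA alphabet
#'
#' Uppercases, converts `T` to `U` and validates length and alphabet.
#'
#' @param x character vector of guide sequences (DNA or RNA).
#' @param length required sequence length (default 20; `NA` skips the check).
#' @return character vector over `{A,C,G,U}`.
#' @export
normalizeGuides <- function(x, length = 20L) {
  x <- chartr("t", "T", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  if (!is.na(length) && any(nchar(x) != length))
    stop("sequence(s) not of length ", length, ": ",
         paste(head(which(nchar(x) != length), 5), collapse = ", "))
  x
}

# RNA guide -> DNA protospacer (same strand, U->T)
guideToDNA <- function(x) chartr("U", "T", toupper(x))

# reverse complement of a DNA character vector
revcompDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run a block with a private, seeded RNG stream and restore the caller's
withPrivateSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.checkRNAfold <- function() {
  p <- Sys.which("RNAfold")
  if (!nzchar(p))
    stop("RNAfold (ViennaRNA) was not found on the PATH; ",
         "secondary-structure features require it")
  p
}

#' Version of the folding engine in use
#'
#' @return character scalar, e.g. `"RNAfold 2.7.2"`.
#' @export
foldEngineVersion <- function() {
  out <- system2(.checkRNAfold(), "--version", stdout = TRUE)
  trimws(out[1])
}
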