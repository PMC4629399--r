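guideFix <- "AUGGCUAAGCUGACCGGUAA"
seedFix <- substr(chartr("U", "T", guideFix), 8, 20)

test_that("the exon index finds seed+PAM occurrences with NGG/NAG tolerance", {
  exons <- c(e1 = paste0(randDNA(50, 81), seedFix, "TGG", randDNA(30, 82)),
             e2 = paste0(randDNA(20, 83), seedFix, "TAG", randDNA(10, 84)),
             e3 = paste0(randDNA(20, 85), seedFix, "TTT", randDNA(10, 86)))
  idx <- buildExonIndex(exons)
  h <- seedPamHits(guideFix, idx)
  expect_identical(h$exon_id, c("e1", "e2"))      # NGG and NAG hit, TTT not
  expect_identical(h$offset, c(50L, 20L))
  expect_identical(h$strand, c("+", "+"))
  expect_identical(unique(h$kind), "seed_pam")
})

test_that("indexing is strand-symmetric", {
  fwd <- paste0(randDNA(40, 87), seedFix, "CGG", randDNA(25, 88))
  idx <- buildExonIndex(c(x = fwd))
  idxRC <- buildExonIndex(c(x = rcDNA(fwd)))
  h <- seedPamHits(guideFix, idx)
  hRC <- seedPamHits(guideFix, idxRC)
  expect_identical(nrow(h), nrow(hRC))
  expect_identical(hRC$strand, rep("-", nrow(hRC)))
  # mirrored coordinates: a 13-mer at offset o maps to L - 13 - o
  L <- nchar(fwd)
  expect_setequal(hRC$offset, L - 13L - h$offset)
})

test_that("PAM-free and empty inputs behave", {
  expect_equal(length(buildExonIndex(c(a = strrep("A", 80)))), 0L)
  expect_error(buildExonIndex(Biostrings::DNAStringSet()), "empty")
  emptyHits <- seedPamHits(guideFix, buildExonIndex(c(a = strrep("A", 80))))
  expect_equal(nrow(emptyHits), 0L)
})

test_that("similarity hits respect the 85 % identity boundary", {
  gdna <- chartr("U", "T", guideFix)
  mutate <- function(x, at) {
    for (i in at)
      substr(x, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(x, i, i))[1]
    x
  }
  ex <- c(mm3 = paste0(randDNA(15, 89), mutate(gdna, c(2, 9, 15)),
                       randDNA(15, 90)),
          mm4 = paste0(randDNA(15, 91), mutate(gdna, c(2, 9, 15, 18)),
                       randDNA(15, 92)))
  h <- similarityHits(guideFix, ex)
  expect_identical(h$exon_id, "mm3")     # 17/20 reported, 16/20 absent
  expect_identical(h$mismatches, 3L)
  expect_identical(h$offset, 15L)
  # windows containing N never match: N inside an otherwise 1-mismatch hit
  nWin <- mutate(gdna, 5)
  substr(nWin, 10, 10) <- "N"
  withN <- c(n1 = paste0(randDNA(10, 93), nWin, randDNA(10, 94)))
  expect_equal(nrow(similarityHits(guideFix, withN)), 0L)
})

test_that("seed and similarity scans agree with brute-force on random sequence", {
  exons <- Biostrings::DNAStringSet(c(
    chunk1 = paste0(randDNA(1200, 95), seedFix, "AGG",
                    randDNA(800, 96)),
    chunk2 = randDNA(1000, 97)))
  idx <- buildExonIndex(exons)
  h <- seedPamHits(guideFix, idx)
  expect_identical(h[, c("exon_id", "offset", "strand")],
                   bruteSeedPamScan(guideFix, exons))
  hs <- similarityHits(guideFix, exons)
  expect_identical(hs[, c("exon_id", "offset", "strand", "mismatches")],
                   bruteSimilarityScan(guideFix, exons))
})

test_that("declared on-targets are excluded exactly once", {
  target <- paste0(randDNA(30, 98), chartr("U", "T", guideFix), "TGG",
                   randDNA(20, 99))
  idx <- buildExonIndex(c(gene = target))
  ot <- list(exon_id = "gene", start = 30L, strand = "+")
  withOT <- seedPamHits(guideFix, idx, onTarget = ot)
  noOT <- seedPamHits(guideFix, idx)
  expect_equal(nrow(noOT) - nrow(withOT), 1L)
  # similarity scan also drops the unique exact PAM-flanked match on its own
  simAuto <- similarityHits(guideFix, c(gene = target))
  expect_false(any(simAuto$mismatches == 0 & simAuto$offset == 30))
})

test_that("off-target filtering is decisive and order-invariant", {
  dirty <- guideFix
  cleanG <- "AAUAAUAAUAAUAAUAAUGA"
  exons <- c(e1 = paste0(randDNA(25, 100), seedFix, "GGG", randDNA(25, 101)),
             e2 = randDNA(60, 102))
  res <- filterOffTargets(c(dirty, cleanG), buildExonIndex(exons))
  expect_identical(res$report$excluded, c(TRUE, FALSE))
  # shuffling exon record order changes nothing
  res2 <- filterOffTargets(c(dirty, cleanG),
                           buildExonIndex(exons[c(2, 1)]))
  expect_identical(res2$report$excluded, res$report$excluded)
  expect_identical(res2$report$seed_pam_hits, res$report$seed_pam_hits)
})

test_that("hits export as BED with 0-based half-open coordinates", {
  exons <- c(e1 = paste0(randDNA(10, 103), seedFix, "TGG", randDNA(5, 104)))
  h <- seedPamHits(guideFix, buildExonIndex(exons))
  path <- withr::local_tempfile(fileext = ".bed")
  writeHitsBED(h, path)
  bed <- read.delim(path, header = FALSE)
  expect_identical(bed$V2, 10L)
  expect_identical(bed$V3, 23L)
  expect_identical(bed$V4, "seed_pam")
})
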