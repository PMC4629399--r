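# one small trained model shared by the pipeline tests
pipelineModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scr <- labelByPercentile(
        generateSyntheticScreen(n = 300, seed = 7, effectSize = 2))
      cache <<- trainGuideModel(scr, grid = list(cost = 8, gamma = 2^-9),
                                prefilter = FALSE, seed = 1)
    }
    cache
  }
})

test_that("PAM scanning enumerates both strands and drops N candidates", {
  # 23-mer ending in AGG: one plus-strand candidate
  plus <- scanPamSites(c(s = paste0(randDNA(20, 111), "AGG")))
  expect_equal(nrow(plus), 1L)
  expect_identical(plus$strand, "+")
  expect_identical(plus$start, 0L)
  expect_identical(plus$pam, "AGG")
  expect_identical(chartr("U", "T", plus$guide), randDNA(20, 111))

  # 23-mer starting with CCT: one minus-strand candidate
  minus <- scanPamSites(c(s = paste0("CCT", randDNA(20, 112))))
  expect_equal(nrow(minus), 1L)
  expect_identical(minus$strand, "-")
  expect_identical(minus$start, 3L)
  expect_identical(chartr("U", "T", minus$guide),
                   rcDNA(randDNA(20, 112)))

  expect_equal(nrow(scanPamSites(c(a = strrep("A", 100)))), 0L)
  expect_warning(short <- scanPamSites(c(s = "ACGTACGT")), "23")
  expect_equal(nrow(short), 0L)

  withN <- scanPamSites(c(s = paste0(randDNA(10, 113), "N",
                                     randDNA(9, 114), "AGG")))
  expect_equal(nrow(withN), 0L)
})

test_that("a planted clean guide ranks first and eliminations are reported", {
  goodGuide <- "AUGUCUUUAAACUAAUAGCG"   # passes every pre-filter, aperiodic
  goodDNA <- chartr("U", "T", goodGuide)
  gcPad <- function(n, seed) {           # GC-rich context fails pre-filters
    withr::with_seed(seed, paste(
      sample(c("G", "C"), n, replace = TRUE), collapse = ""))
  }
  target <- c(myGene = paste0(gcPad(120, 115), goodDNA, "TGG",
                              gcPad(120, 116)))
  m <- pipelineModel()
  rep1 <- designGuides(target, m)
  expect_identical(rep1$guide[1], goodGuide)
  expect_identical(rep1$rank[1], 1L)
  expect_identical(rep1$start[1], 121L)     # 1-based in reports
  # every enumerated candidate appears exactly once
  expect_identical(nrow(rep1), nrow(scanPamSites(target)))
  expect_true(all(is.na(rep1$svm_score[!rep1$prefilter_failures == ""])))
  # ranks are dense from 1
  r <- rep1$rank[!is.na(rep1$rank)]
  expect_identical(r, seq_along(r))
})

test_that("off-target screening removes seed-matched candidates from the ranking", {
  goodGuide <- "AUGUCUUUAAACUAAUAGCG"
  goodDNA <- chartr("U", "T", goodGuide)
  gcPad <- withr::with_seed(117, paste(
    sample(c("G", "C"), 100, replace = TRUE), collapse = ""))
  gcPad2 <- withr::with_seed(118, paste(
    sample(c("G", "C"), 100, replace = TRUE), collapse = ""))
  target <- c(myGene = paste0(gcPad, goodDNA, "TGG", gcPad2))
  # an unrelated exon carrying the guide's seed next to an NAG PAM
  decoy <- paste0(randDNA(30, 119), substr(goodDNA, 8, 20), "TAG",
                  randDNA(30, 120))
  idx <- buildExonIndex(c(myGene = target[["myGene"]], offTarget = decoy))
  m <- pipelineModel()
  rep2 <- designGuides(target, m, exonIndex = idx)
  row <- rep2[rep2$guide == goodGuide, ]
  expect_identical(row$seed_pam_hits, 1L)
  expect_true(is.na(row$rank))
  # without the decoy the same guide is ranked: its own site is on-target
  # and does not count against it
  idxClean <- buildExonIndex(c(myGene = target[["myGene"]]))
  rep3 <- designGuides(target, m, exonIndex = idxClean)
  row3 <- rep3[rep3$guide == goodGuide, ]
  expect_false(is.na(row3$rank))
  expect_identical(row3$seed_pam_hits, 0L)
  expect_identical(row3$similarity_hits, 0L)
})

test_that("design reports are deterministic and round trip through TSV", {
  target <- c(g = paste0(randDNA(150, 121)))
  m <- pipelineModel()
  rep1 <- designGuides(target, m)
  rep2 <- designGuides(target, m)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeDesignReport(rep1, p1); writeDesignReport(rep2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- readDesignReport(p1)
  expect_identical(back$guide, rep1$guide)
  expect_equal(back$svm_score, rep1$svm_score, tolerance = 1e-12)
  # header-only file for an empty report
  pe <- withr::local_tempfile()
  suppressWarnings(writeDesignReport(
    designGuides(c(a = strrep("A", 100)), m), pe))
  expect_length(readLines(pe), 1L)
})

test_that("YAML configuration overrides thresholds and is honored", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("thresholds:",
               "  gcMax: 0.5",
               "  duplexDG: -30",
               "maxMismatches: 2"), path)
  cfg <- readDesignConfig(path)
  expect_equal(cfg$thresholds$gcMax, 0.5)
  expect_equal(cfg$thresholds$duplexDG, -30)
  expect_equal(cfg$thresholds$selfFoldDG, -8)   # default retained
  expect_equal(cfg$maxMismatches, 2)
  # gc = 0.6 exceeds the tightened 0.5 cutoff but not the default 0.8
  g <- "GCGCGCGCGCGCAAUAAUAA"
  expect_true(grepl("GC", applyPrefilters(g, cfg$thresholds)$failed_rules))
  expect_false(grepl("GC", applyPrefilters(g)$failed_rules))
})
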