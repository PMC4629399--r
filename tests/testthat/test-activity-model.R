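# a small labeled screen with a planted signal, shared across tests
smallPlanted <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- labelByPercentile(
        generateSyntheticScreen(n = 300, seed = 7, effectSize = 2))
    cache
  }
})

test_that("feature vectors are deterministic, named and 176 long", {
  g <- randGuides(3, 61)
  x <- assembleFeatures(g)
  expect_identical(dim(x), c(3L, 176L))
  expect_identical(colnames(x), featureManifest())
  expect_identical(x, assembleFeatures(g))
  expect_identical(x[1, ], assembleFeatures(g[1])[1, ])

  allA <- assembleFeatures("AAAAAAAAAAAAAAAAAAAA")[1, ]
  expect_equal(unname(allA["monoA"]), 20)
  expect_equal(unname(allA["gc"]), 0)
  expect_equal(unname(allA["selfFoldDG"]), 0)
  expect_equal(unname(allA["pos01.A"]), 1)
})

test_that("a separable screen is fit perfectly and scores separate the classes", {
  scr <- withr::with_seed(8, {
    au <- vapply(1:30, function(i) paste(
      sample(c("A", "U"), 20, replace = TRUE, prob = c(0.7, 0.3)),
      collapse = ""), "")
    gcg <- vapply(1:30, function(i) paste(
      sample(c("G", "C", "A"), 20, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
      collapse = ""), "")
    GuideScreen(c(au, gcg), paste0("g", rep_len(1:3, 60)), c(31:60, 1:30))
  })
  scr <- labelByPercentile(scr, top = 0.5, bottom = 0.5)
  m <- trainGuideModel(scr, grid = list(cost = 2, gamma = 2^-7),
                       prefilter = FALSE, seed = 1)
  sc <- predictScores(m, guideSeqs(scr))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(rocAUC(sc, guideLabels(scr) == "functional"), 1)
})

test_that("models refuse degenerate training input", {
  scr <- smallPlanted()
  onlyPos <- scr[guideLabels(scr) == "functional"]
  expect_error(trainGuideModel(onlyPos, prefilter = FALSE), "single class")
  tiny <- trainingRecords(scr)[c(1:5, 56:60)]
  expect_error(trainGuideModel(tiny, prefilter = FALSE), "at least 10")
})

test_that("scores are reproducible across serialization and record order", {
  scr <- smallPlanted()
  m <- trainGuideModel(scr, grid = list(cost = 8, gamma = 2^-9),
                       prefilter = FALSE, seed = 2)
  g <- guideSeqs(trainingRecords(scr))[1:20]
  sc <- predictScores(m, g)
  path <- withr::local_tempfile(fileext = ".rds")
  saveGuideModel(m, path)
  expect_identical(predictScores(readGuideModel(path), g), sc)
  perm <- withr::with_seed(4, sample(20))
  expect_equal(predictScores(m, g[perm]), sc[perm])
  # scoring refuses a manifest that does not match the assembler
  m2 <- m
  m2@featureNames[1] <- "renamed"
  expect_error(predictScores(m2, g), "manifest")
})

test_that("cross-validation partitions records as promised", {
  scr <- smallPlanted()
  cv <- crossValidate(scr, "tenfold", seed = 3, cost = 8, gamma = 2^-9)
  n <- length(trainingRecords(scr))
  expect_length(cv@scores, n)
  expect_true(all(table(cv@fold) >= 1))
  expect_equal(length(unique(cv@fold)), 10L)
  # identical seed reproduces the partition
  cv2 <- crossValidate(scr, "tenfold", seed = 3, cost = 8, gamma = 2^-9)
  expect_identical(cv@fold, cv2@fold)
  expect_equal(cv@scores, cv2@scores)

  # gene mode: one fold per gene, genes never span folds
  cvg <- crossValidate(scr, "gene", cost = 8, gamma = 2^-9)
  expect_equal(length(unique(cvg@fold)), 9L)
  genes <- geneIds(trainingRecords(scr))
  expect_true(all(vapply(split(cvg@fold, genes),
                         function(f) length(unique(f)) == 1L, logical(1))))
  oneGene <- scr[geneIds(scr) == "gene1"]
  expect_error(crossValidate(oneGene, "gene", cost = 8, gamma = 2^-9),
               "at least 2 genes")
  # the planted signal is learnable out of fold
  expect_gt(cvAUC(cv), 0.8)
})

test_that("ROC AUC equals the pairwise probability and its invariances hold", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(rocAUC(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # discretized scores force ties; exact agreement with the O(n^2) oracle
  scores <- withr::with_seed(71, round(runif(150), 1))
  labels <- withr::with_seed(72, runif(150) < 0.4)
  expect_equal(rocAUC(scores, labels), bruteAUC(scores, labels))
  # monotone transform invariance
  expect_equal(rocAUC(qlogis((scores + 1) / 3), labels),
               rocAUC(scores, labels))
  # label conventions: factor with 'functional' level matches logical
  expect_equal(rocAUC(scores, factor(ifelse(labels, "functional",
                                            "non-functional"))),
               rocAUC(scores, labels))
})

test_that("precision-recall machinery reports thresholds and baseline", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  pr <- prCurve(scores, labels)
  expect_equal(pr$precision[pr$recall == 1][1], 1)
  expect_true(all(pr$precision[seq_len(3)] == 1))
  expect_equal(attr(pr, "baseline"), 0.6)
  expect_true(all(diff(pr$recall) >= 0))

  # random scores hover near the baseline precision
  sc <- withr::with_seed(73, runif(400))
  lb <- rep(c(TRUE, FALSE), 200)
  pr2 <- prCurve(sc, lb)
  half <- pr2[pr2$n_selected >= 100, ]
  expect_lt(max(abs(half$precision - 0.5)), 0.15)
  expect_error(prCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
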