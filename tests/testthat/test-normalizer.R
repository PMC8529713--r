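miniIndex <- function(dim = 2048) {
  buildConceptIndex(expandEntries(parseOBO(miniOboText())),
                    mockEmbedding(dim))
}

test_that("feature vectors are zero-padded to exactly five components", {
  fv <- featureVector(0.9281, 0.815)
  expect_identical(unname(fv), c(0.9281, 0.815, 0, 0, 0))
  expect_identical(names(fv),
                   c("name_sim", "def_sim", paste0("hier_sim", 1:3)))

  expect_identical(unname(featureVector(0.9, 0.8, 0.5)),
                   c(0.9, 0.8, 0.5, 0, 0))
  for (nc in 0:3) {
    expect_length(featureVector(0.1, 0.2, rep(0.3, nc)), 5L)
  }
  expect_error(featureVector(0.1, 0.2, rep(0.3, 4)))
  expect_error(featureVector(1.5, 0), "\\[-1, 1\\]")
})

test_that("a mention identical to an entry surface has name similarity exactly 1", {
  idx <- miniIndex()
  f <- mentionFeatures(idx, "alpha alpha")
  entries <- indexEntries(idx)
  expect_equal(unname(f[entries$surface == "alpha alpha", "name_sim"]), 1)
  # all features bounded, matrix shaped entries x 5
  expect_identical(dim(f), c(nrow(entries), 5L))
  expect_true(all(f >= -1 - 1e-12 & f <= 1 + 1e-12))
  # empty-definition concept contributes def_sim 0 (zero-vector convention)
  expect_identical(unname(f[entries$concept_id == "T:0003", "def_sim"]), 0)
})

test_that("candidate generation is exhaustive by default with id tie-breaks", {
  idx <- miniIndex()
  all <- generateCandidates(idx, "alpha alpha")
  expect_identical(nrow(all), nrow(indexEntries(idx)))

  top1 <- generateCandidates(idx, "alpha alpha", topN = 1)
  expect_identical(top1$surface, "alpha alpha")

  # two concepts with byte-identical surfaces tie on name_sim; the lower
  # concept id survives the cutoff
  tied <- data.frame(surface = c("same words", "same words", "other stuff"),
                     concept_id = c("Z:2", "Z:1", "Z:3"),
                     definition = "", ctx1 = "", ctx2 = "", ctx3 = "",
                     stringsAsFactors = FALSE)
  tidx <- buildConceptIndex(tied, mockEmbedding(512))
  got <- generateCandidates(tidx, "same words", topN = 1)
  expect_identical(got$concept_id, "Z:1")
})

test_that("training sets count positives and negatives and are seed-stable", {
  p <- fixtureParams(nConcepts = 12, seed = 2)
  g <- parseOBO(generateOntology(p))
  idx <- buildConceptIndex(expandEntries(g), mockEmbedding(256))
  leaves <- unique(indexEntries(idx)$concept_id)
  gold <- data.frame(text = vapply(leaves[1:10], function(id)
                       getConcept(g, id)$name, character(1)),
                     concept_id = leaves[1:10], stringsAsFactors = FALSE)

  ts <- makeTrainingSet(gold, idx, negativesPerPositive = 5, seed = 11)
  expect_identical(nrow(ts$features), 60L)          # 10 + 10 * 5
  expect_identical(sum(ts$labels), 10L)
  expect_identical(ncol(ts$features), 5L)

  ts0 <- makeTrainingSet(gold, idx, negativesPerPositive = 0, seed = 11)
  expect_true(all(ts0$labels == 1L))

  ts2 <- makeTrainingSet(gold, idx, negativesPerPositive = 5, seed = 11)
  expect_identical(ts2$features, ts$features)

  badGold <- rbind(gold, data.frame(text = "ghost", concept_id = "NO:SUCH"))
  expect_warning(ts3 <- makeTrainingSet(badGold, idx, 5, seed = 11),
                 "skipped")
  expect_identical(ts3$skipped, 1L)
  expect_identical(nrow(ts3$features), 60L)
})

test_that("the cosine strategy scores by the exact unweighted feature sum", {
  m <- fitRanker(strategy = "cosine")
  f <- matrix(runif(40, -1, 1), ncol = 5)
  expect_identical(rankerScores(m, f), rowSums(f))
  expect_identical(rankerScores(m, f[1, ]), sum(f[1, ]))
})

test_that("the logistic ranker separates a constructed dataset", {
  set.seed(5)
  n <- 400
  pos <- cbind(runif(n, 0.8, 1), matrix(runif(4 * n), ncol = 4))
  neg <- cbind(runif(n, 0, 0.5), matrix(runif(4 * n), ncol = 4))
  x <- rbind(pos, neg)
  colnames(x) <- c("name_sim", "def_sim", paste0("hier_sim", 1:3))
  y <- rep(c(1L, 0L), each = n)
  m <- fitRanker(x, y, strategy = "regression")
  expect_identical(rankerStrategy(m), "regression")
  expect_gt(rankerWeights(m)["name_sim"], 0)
  acc <- mean((rankerScores(m, x) > 0) == (y == 1))
  expect_gte(acc, 0.99)

  expect_error(fitRanker(x, rep(1L, nrow(x)), strategy = "regression"),
               "both positive and negative")
})

test_that("ranking collapses synonym entries to their concept's best score", {
  idx <- miniIndex()
  m <- fitRanker(strategy = "cosine")
  r <- normalizeMention("aalph alpha", m, idx)    # a synonym surface
  expect_identical(r$concept_id[1], "T:0001")
  expect_identical(anyDuplicated(r$concept_id), 0L)
  expect_true(all(diff(r$score) <= 1e-12))

  empty <- buildConceptIndex(expandEntries(parseOBO(character(0))),
                             mockEmbedding(64))
  expect_identical(nrow(normalizeMention("anything", m, empty)), 0L)
})

test_that("a definition-weighted regression model can overturn name similarity", {
  # candidate structure of a worked mitotic-spindle example: B's name is the
  # closest string, but A's definition fits the mention better; with enough
  # weight on definition similarity the ranker prefers A
  entries <- data.frame(
    surface = c("qqq www", "formation of the spindle"),
    concept_id = c("M:A", "M:B"),
    definition = c("formation of the mitotic spindle structure", "unrelated"),
    ctx1 = "", ctx2 = "", ctx3 = "", stringsAsFactors = FALSE)
  idx <- buildConceptIndex(entries, mockEmbedding(2048))
  mention <- "formation of the mitotic spindle"
  f <- mentionFeatures(idx, mention)
  expect_gt(f[2, "name_sim"], f[1, "name_sim"])
  expect_gt(f[1, "def_sim"], f[2, "def_sim"])

  defHeavy <- new("RankerModel", strategy = "regression",
                  weights = c(name_sim = 0.5, def_sim = 8, hier_sim1 = 0,
                              hier_sim2 = 0, hier_sim3 = 0),
                  intercept = 0,
                  featureNames = c("name_sim", "def_sim",
                                   paste0("hier_sim", 1:3)))
  expect_identical(normalizeMention(mention, defHeavy, idx)$concept_id[1],
                   "M:A")
  expect_identical(
    normalizeMention(mention, fitRanker(strategy = "cosine"),
                     idx, topN = 1)$concept_id[1], "M:B")
})

test_that("top-1 matches a brute-force score over every entry on small indices", {
  m <- list(fitRanker(strategy = "cosine"),
            new("RankerModel", strategy = "regression",
                weights = c(2, 1, 0.5, 0.25, 0.1), intercept = -0.3,
                featureNames = c("name_sim", "def_sim",
                                 paste0("hier_sim", 1:3))))
  for (s in 1:5) {
    p <- fixtureParams(nConcepts = 8, seed = s)
    g <- parseOBO(generateOntology(p))
    idx <- buildConceptIndex(expandEntries(g), mockEmbedding(256))
    entries <- indexEntries(idx)
    expect_lte(nrow(entries), 20L)
    mention <- getConcept(g, sample(conceptIds(g), 1))$name
    for (model in m) {
      f <- mentionFeatures(idx, mention)
      scores <- rankerScores(model, f)
      bestByConcept <- tapply(scores, entries$concept_id, max)
      want <- names(bestByConcept)[order(-bestByConcept,
                                         names(bestByConcept))][1]
      expect_identical(normalizeMention(mention, model, idx)$concept_id[1],
                       want)
    }
  }
})

test_that("ranking under the cosine strategy survives order-preserving rescaling", {
  idx <- miniIndex()
  m <- fitRanker(strategy = "cosine")
  f <- mentionFeatures(idx, "zzz qqq")
  base <- order(-rankerScores(m, f))
  expect_identical(order(-rankerScores(m, 3.7 * f)), base)
})

test_that("models serialize to JSON and restore identically", {
  set.seed(1)
  x <- matrix(runif(500, -1, 1), ncol = 5)
  colnames(x) <- c("name_sim", "def_sim", paste0("hier_sim", 1:3))
  y <- rbinom(100, 1, plogis(2 * x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  m <- fitRanker(x, y, strategy = "regression", backend = mockEmbedding(64))
  path <- tempfile(fileext = ".json")
  writeRankerModel(m, path)
  m2 <- readRankerModel(path)
  expect_identical(rankerStrategy(m2), "regression")
  expect_equal(rankerWeights(m2), rankerWeights(m))
  expect_equal(rankerIntercept(m2), rankerIntercept(m))
  expect_identical(m2@backendName, "mock-trigram")
  expect_identical(m2@embeddingDim, 64L)
})
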