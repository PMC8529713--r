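## Synthetic ontology + corpus generator: download-free inputs whose
## controlled surface variation (reordering, synonym substitution, filler
## insertion) emulates how multi-token biological concepts vary in text.

# words of 6-11 characters only: a very long word's trigram mass would
# dominate the mock backend's cosine between any two phrases sharing it, and
# a very short word would contribute almost none
.conceptWordPool <- c(
  "regulation", "activation", "signaling", "membrane", "protein", "kinase",
  "transport", "binding", "response", "pathway", "division", "growth",
  "assembly", "repair", "synthesis", "splicing", "folding", "receptor",
  "nuclear", "mitotic", "spindle", "chromosome", "metabolic", "oxidative",
  "stress", "immune", "apoptosis", "adhesion", "migration", "enzyme",
  "ligand", "secretion", "vesicle", "junction", "polarity", "fusion",
  "checkpoint", "damage", "glucose", "channel", "calcium", "gradient",
  "matrix", "tissue", "cascade", "motility", "granule", "turnover",
  "autophagy", "elongation")

# connective vocabulary is disjoint from the concept word pool so that entry
# surfaces can never match across a mention boundary
.openerPhrases <- c(
  "we observed that", "our assay indicated that", "it was noted that",
  "the data suggested that", "further work confirmed that")

.closerPhrases <- c(
  "was altered in these samples .", "appeared reduced under treatment .",
  "remained unchanged across replicates .", "was strongly affected here .",
  "varied between both groups .")

.fillerWords <- c("of", "the", "in")

#' Parameters for the synthetic fixture generators
#'
#' Bundles the knobs shared by [generateOntology()] and [generateCorpus()].
#' Defaults describe the standard end-to-end study condition: a 30-concept
#' acyclic ontology with multi-token names, synonyms on roughly half the
#' concepts, and a 10-document corpus of 5 mentions each with all four
#' surface-variation operators active.
#'
#' @param nConcepts number of `[Term]` stanzas to generate.
#' @param maxParents maximum direct parents per non-root concept.
#' @param synonymRate probability that a concept gets a reordered synonym.
#' @param nDocs,mentionsPerDoc corpus shape.
#' @param variationOps subset of
#'   `c("identity", "synonym_swap", "token_shuffle", "filler_insert")`; one is
#'   drawn per mention.
#' @param seed integer fixing all randomness of both generators.
#' @return a named list of validated parameters.
#' @export
fixtureParams <- function(nConcepts = 30L, maxParents = 2L,
                          synonymRate = 0.5, nDocs = 10L,
                          mentionsPerDoc = 5L,
                          variationOps = c("identity", "synonym_swap",
                                           "token_shuffle", "filler_insert"),
                          seed = 7L) {
  stopifnot(nConcepts >= 1L, maxParents >= 1L,
            synonymRate >= 0, synonymRate <= 1,
            nDocs >= 1L, mentionsPerDoc >= 1L,
            length(variationOps) >= 1L,
            all(variationOps %in% c("identity", "synonym_swap",
                                    "token_shuffle", "filler_insert")))
  list(nConcepts = as.integer(nConcepts), maxParents = as.integer(maxParents),
       synonymRate = synonymRate, nDocs = as.integer(nDocs),
       mentionsPerDoc = as.integer(mentionsPerDoc),
       variationOps = variationOps, seed = as.integer(seed))
}

#' Generate a random acyclic ontology in OBO format
#'
#' Concept `i` may only take parents among concepts `1..i-1`, so the graph is
#' acyclic by construction. Names are unique multi-token phrases (2-4 words)
#' drawn from a fixed ~50-word pool; definitions are short template sentences
#' dominated by the name's own content words (stated twice) plus two
#' distractor words, so definition similarity correlates with the concept the
#' mention actually denotes; synonyms are word-order permutations of the
#' name, emitted at `synonymRate`. Output is byte-stable for a fixed seed.
#'
#' @param params a [fixtureParams()] list.
#' @return OBO text as a single string; parse with [parseOBO()].
#' @export
generateOntology <- function(params = fixtureParams()) {
  .withSeed(params$seed, {
    n <- params$nConcepts
    ids <- sprintf("SYN:%07d", seq_len(n))
    usedSurfaces <- character(0)
    wordSets <- list()
    concepts <- vector("list", n)
    for (i in seq_len(n)) {
      # every non-root takes the same number of parents (when enough exist),
      # so candidates carry comparable hierarchical-context mass; the primary
      # parent is listed first and lends the child one name word, the way a
      # GO child term typically shares a head word with a parent
      is_a <- character(0); part_of <- character(0)
      primaryWords <- character(0)
      if (i >= 2L) {
        np <- min(params$maxParents, i - 1L)
        parentIdx <- sample(seq_len(i - 1L), np)
        parents <- ids[parentIdx]
        isa <- c(TRUE, stats::runif(np - 1L) < 0.75)
        is_a <- parents[isa]
        part_of <- parents[!isa]
        primaryWords <- strsplit(concepts[[parentIdx[1]]]$name, " ",
                                 fixed = TRUE)[[1]]
      }
      # no two concepts may share more than one content word: mentions stay
      # uniquely decodable, which a controlled recovery experiment requires
      for (try in 1:200) {
        len <- sample(3:4, 1L, prob = c(0.6, 0.4))
        fresh <- sample(setdiff(.conceptWordPool, primaryWords), len)
        if (length(primaryWords)) fresh[sample.int(len, 1L)] <-
          sample(primaryWords, 1L)
        name <- paste(fresh, collapse = " ")
        overlapOK <- all(vapply(wordSets, function(ws)
          length(intersect(ws, fresh)) <= 1L, logical(1)))
        if (!(name %in% usedSurfaces) && overlapOK) break
      }
      usedSurfaces <- c(usedSurfaces, name)
      wordSets[[length(wordSets) + 1L]] <- fresh
      words <- strsplit(name, " ", fixed = TRUE)[[1]]
      distract <- sample(setdiff(.conceptWordPool, words), 2L)
      definition <- paste0(name, " : the ", name, " process , affecting ",
                           paste(distract, collapse = " and "), " .")
      synonyms <- data.frame(label = character(0), scope = character(0),
                             stringsAsFactors = FALSE)
      if (length(words) >= 2L && stats::runif(1) < params$synonymRate) {
        for (try in 1:10) {
          perm <- paste(sample(words), collapse = " ")
          if (perm != name && !(perm %in% usedSurfaces)) {
            synonyms <- data.frame(label = perm, scope = "EXACT",
                                   stringsAsFactors = FALSE)
            usedSurfaces <- c(usedSurfaces, perm)
            break
          }
        }
      }
      concepts[[i]] <- list(id = ids[i], name = name,
                            definition = definition, synonyms = synonyms,
                            is_a = is_a, part_of = part_of, obsolete = FALSE)
    }
    names(concepts) <- ids
    writeOBO(new("OntologyGraph", concepts = concepts,
                 dangling = character(0)))
  })
}

# one surface realization of a concept under a variation operator
.varyMention <- function(co, op) {
  name <- co$name
  words <- strsplit(name, " ", fixed = TRUE)[[1]]
  if (op == "synonym_swap") {
    if (nrow(co$synonyms)) return(co$synonyms$label[sample.int(nrow(co$synonyms), 1L)])
    return(name)
  }
  if (op == "token_shuffle") {
    if (length(words) >= 4L) {
      mid <- 2:(length(words) - 1L)
      words[mid] <- sample(words[mid])
    }
    return(paste(words, collapse = " "))
  }
  if (op == "filler_insert") {
    pos <- if (length(words) >= 2L) sample.int(length(words) - 1L, 1L) else 1L
    return(paste(c(words[seq_len(pos)], sample(.fillerWords, 1L),
                   words[-seq_len(pos)]), collapse = " "))
  }
  name
}

#' Generate an annotated corpus with controlled surface variation
#'
#' Each document embeds `mentionsPerDoc` mentions between connective phrases
#' whose vocabulary is disjoint from the concept word pool. Every mention is a
#' concept surface transformed by one variation operator drawn per mention:
#' `identity` (the primary name verbatim), `synonym_swap` (a synonym label),
#' `token_shuffle` (interior word order permuted), or `filler_insert` (one
#' stop word injected). Gold annotations carry the true spans and concept
#' ids, and every span is verified against the emitted text.
#'
#' Mention concepts are drawn uniformly from the leaf concepts of the graph
#' (those no other concept lists as a parent). A non-leaf concept's name is,
#' verbatim, the hierarchical-context string of each of its children, so a
#' mention of it is exactly ambiguous between "this concept" and "a child of
#' this concept" for any scorer that weights all context features equally;
#' leaves keep the fixture's gold standard uniquely resolvable by
#' construction, which is what a controlled recovery experiment needs.
#'
#' @param graph an [OntologyGraph-class] (typically
#'   `parseOBO(generateOntology(params))`).
#' @param params a [fixtureParams()] list; `seed` fixes the corpus.
#' @return list of documents, each a list with `doc_id`, `text`, and
#'   `annotations` (gold annotation data.frame).
#' @export
generateCorpus <- function(graph, params = fixtureParams()) {
  stopifnot(is(graph, "OntologyGraph"), length(graph) >= 1L)
  parents <- unique(unlist(lapply(graph@concepts,
                                  function(co) c(co$is_a, co$part_of))))
  active <- Filter(function(co) !co$obsolete && !(co$id %in% parents),
                   graph@concepts)
  if (length(active) == 0L) {           # degenerate graphs: fall back to all
    active <- Filter(function(co) !co$obsolete, graph@concepts)
  }
  stopifnot(length(active) >= 1L)
  .withSeed(params$seed, {
    docs <- vector("list", params$nDocs)
    for (d in seq_len(params$nDocs)) {
      text <- ""
      starts <- integer(0); ends <- integer(0)
      mtexts <- character(0); cids <- character(0)
      for (m in seq_len(params$mentionsPerDoc)) {
        co <- active[[sample.int(length(active), 1L)]]
        op <- params$variationOps[sample.int(length(params$variationOps), 1L)]
        mention <- .varyMention(co, op)
        opener <- .openerPhrases[sample.int(length(.openerPhrases), 1L)]
        closer <- .closerPhrases[sample.int(length(.closerPhrases), 1L)]
        if (nzchar(text)) text <- paste0(text, " ")
        text <- paste0(text, opener, " ")
        starts <- c(starts, nchar(text))
        text <- paste0(text, mention)
        ends <- c(ends, nchar(text))
        text <- paste0(text, " ", closer)
        mtexts <- c(mtexts, mention)
        cids <- c(cids, co$id)
      }
      docId <- sprintf("doc%03d", d)
      ann <- annotationFrame(starts, ends, mtexts, concept_id = cids,
                             doc_id = rep(docId, length(starts)))
      .checkAnnotations(ann, text = text, requireDisjoint = TRUE,
                        what = sprintf("generated gold (%s)", docId))
      docs[[d]] <- list(doc_id = docId, text = text, annotations = ann)
    }
    docs
  })
}

#' End-to-end benchmark on a synthetic fixture
#'
#' Runs the full pipeline under one seeded study condition: generate an
#' ontology and a training corpus, build the concept index, fit the
#' regression ranker from the training corpus's gold pairs, tag a fresh
#' evaluation corpus with the gazetteer, normalize every found span under
#' both ranking strategies, and score against the gold annotations.
#'
#' @param params evaluation-corpus condition, a [fixtureParams()] list.
#' @param trainParams training-corpus condition; defaults to `params` with
#'   `seed + 1` and twice the documents.
#' @param backend embedding backend (default [mockEmbedding()]).
#' @param negativesPerPositive,lambda passed to [makeTrainingSet()] /
#'   [fitRanker()].
#' @return list with per-strategy `metrics` (from [evaluateAnnotations()]),
#'   per-strategy `top1Accuracy` on spans the tagger recovered exactly,
#'   `nMentions` (gold mentions), and `nFound` (exactly recovered spans).
#' @export
fixtureBenchmark <- function(params = fixtureParams(), trainParams = NULL,
                             backend = mockEmbedding(),
                             negativesPerPositive = 10L, lambda = 1e-3) {
  if (is.null(trainParams)) {
    trainParams <- params
    trainParams$seed <- params$seed + 1L
    trainParams$nDocs <- 2L * params$nDocs
  }
  graph <- parseOBO(generateOntology(params))
  entries <- expandEntries(graph)
  index <- buildConceptIndex(entries, backend)

  trainDocs <- generateCorpus(graph, trainParams)
  gold <- do.call(rbind, lapply(trainDocs, function(d)
    d$annotations[, c("text", "concept_id")]))
  ts <- makeTrainingSet(gold, index,
                        negativesPerPositive = negativesPerPositive,
                        seed = params$seed)
  models <- list(cosine = fitRanker(strategy = "cosine", backend = backend),
                 regression = fitRanker(ts$features, ts$labels,
                                        strategy = "regression",
                                        lambda = lambda, backend = backend))

  evalDocs <- generateCorpus(graph, params)
  refs <- lapply(evalDocs, function(d) d$annotations)
  spans <- lapply(evalDocs, function(d)
    gazetteerTag(d$text, entries, doc_id = d$doc_id))

  metrics <- list(); top1 <- c()
  for (nm in names(models)) {
    preds <- mapply(function(sp, d) normalizeAnnotations(sp, models[[nm]], index),
                    spans, evalDocs, SIMPLIFY = FALSE)
    metrics[[nm]] <- evaluateAnnotations(preds, refs)
    hit <- 0L; found <- 0L
    for (i in seq_along(preds)) {
      ref <- refs[[i]]; pr <- preds[[i]]
      key <- paste(ref$start, ref$end)
      pkey <- paste(pr$start, pr$end)
      j <- match(pkey, key)
      ok <- !is.na(j)
      found <- found + sum(ok)
      hit <- hit + sum(pr$concept_id[ok] == ref$concept_id[j[ok]])
    }
    top1[nm] <- if (found) hit / found else NA_real_
  }
  list(metrics = metrics, top1Accuracy = top1,
       nMentions = sum(vapply(refs, nrow, integer(1))),
       nFound = found, models = models)
}
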