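.featureNames <- c("name_sim", "def_sim", "hier_sim1", "hier_sim2", "hier_sim3")

#' Build a concept index with cached embeddings
#'
#' Embeds every entry surface, definition, and hierarchical-context slot once
#' with the given backend and stores the row-normalized matrices, so candidate
#' scoring reduces to a matrix product against the (normalized) mention
#' vector. Empty strings (missing definitions, padded context slots) embed to
#' zero rows and contribute similarity 0.
#'
#' @param entries entry table from [expandEntries()].
#' @param backend an [EmbeddingBackend-class] (default [mockEmbedding()]).
#' @return a [ConceptIndex-class].
#' @export
buildConceptIndex <- function(entries, backend = mockEmbedding()) {
  k <- attr(entries, "k")
  if (is.null(k)) k <- sum(grepl("^ctx[0-9]+$", names(entries)))
  stopifnot(k >= 1L)
  surfaceVecs <- .l2normRows(embedText(backend, entries$surface))
  defVecs <- .l2normRows(embedText(backend, entries$definition))
  ctxVecs <- lapply(seq_len(k), function(s) {
    .l2normRows(embedText(backend, entries[[paste0("ctx", s)]]))
  })
  new("ConceptIndex", entries = entries, backend = backend, k = as.integer(k),
      surfaceVecs = surfaceVecs, defVecs = defVecs, ctxVecs = ctxVecs)
}

#' @rdname accessors
#' @export
setMethod("indexEntries", "ConceptIndex", function(x) x@entries)

#' @describeIn ConceptIndex number of entries in the index.
#' @param x a `ConceptIndex`.
#' @export
setMethod("length", "ConceptIndex", function(x) nrow(x@entries))

setMethod("show", "ConceptIndex", function(object) {
  cat(sprintf("ConceptIndex: %d entries over %d concepts (k = %d, backend %s, dim %d)\n",
              nrow(object@entries), length(unique(object@entries$concept_id)),
              object@k, object@backend@name, object@backend@dim))
})

#' Assemble a similarity feature vector
#'
#' The normalization features for one mention-candidate pair: cosine of the
#' mention against the entry surface, against the concept definition, and
#' against up to three hierarchical contexts, zero-padded to exactly five
#' components.
#'
#' @param nameSim,defSim cosine similarities in `[-1, 1]`.
#' @param hierSims numeric vector of 0 to `k` hierarchical-context
#'   similarities.
#' @param k number of hierarchical slots (default 3).
#' @return named numeric vector of length `2 + k`.
#' @examples
#' featureVector(0.9281, 0.815)   # no hierarchy contexts supplied
#' @export
featureVector <- function(nameSim, defSim, hierSims = numeric(0), k = 3L) {
  stopifnot(length(hierSims) <= k)
  v <- c(nameSim, defSim, hierSims, rep(0, k - length(hierSims)))
  if (any(!is.finite(v)) || any(v < -1 - 1e-9) || any(v > 1 + 1e-9)) {
    stop("similarity components must be finite and lie in [-1, 1]")
  }
  names(v) <- c("name_sim", "def_sim", paste0("hier_sim", seq_len(k)))
  v
}

# mention vector (normalized) against every entry: n x (2 + k) feature matrix
.featureMatrix <- function(index, mentionVec) {
  m <- .l2norm(mentionVec)
  cols <- cbind(index@surfaceVecs %*% m, index@defVecs %*% m)
  for (s in seq_len(index@k)) cols <- cbind(cols, index@ctxVecs[[s]] %*% m)
  colnames(cols) <- c("name_sim", "def_sim",
                      paste0("hier_sim", seq_len(index@k)))
  cols
}

#' Feature matrix for a mention against all index entries
#'
#' @param index a [ConceptIndex-class].
#' @param mention a mention string (embedded with the index backend) or a
#'   numeric embedding vector.
#' @return numeric matrix, one row per entry, columns
#'   `name_sim`, `def_sim`, `hier_sim1..k`.
#' @export
mentionFeatures <- function(index, mention) {
  v <- if (is.character(mention)) embedText(index@backend, mention)[1, ]
       else mention
  if (length(v) != index@backend@dim) {
    stop("mention vector dimensionality does not match the index backend")
  }
  .featureMatrix(index, v)
}

#' Candidate generation
#'
#' Selects candidate entries for a mention. By default every entry is a
#' candidate (exhaustive scoring); with finite `topN` only the `topN` entries
#' by surface similarity are kept, ties broken by ascending concept id then
#' entry order.
#'
#' @param index a [ConceptIndex-class].
#' @param mention mention string or embedding vector.
#' @param topN number of candidates, or `Inf` for all.
#' @return the candidate rows of the entry table; the integer entry indices
#'   are available as `attr(, "indices")`.
#' @export
generateCandidates <- function(index, mention, topN = Inf) {
  n <- nrow(index@entries)
  if (n == 0L) {
    out <- index@entries
    attr(out, "indices") <- integer(0)
    return(out)
  }
  idx <- seq_len(n)
  if (is.finite(topN) && topN < n) {
    f <- mentionFeatures(index, mention)
    ord <- order(-f[, "name_sim"], index@entries$concept_id, idx)
    idx <- sort(ord[seq_len(topN)])
  }
  out <- index@entries[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Build a training set from gold mention-concept pairs
#'
#' For each gold pair the positive example is the best-scoring entry (by
#' surface similarity) of the gold concept; `negativesPerPositive` negatives
#' are drawn uniformly without replacement from entries of other concepts,
#' using a seeded generator so the set is reproducible. Gold ids absent from
#' the index are skipped with a warning.
#'
#' @param gold data.frame with columns `text` (mention string) and
#'   `concept_id`.
#' @param index a [ConceptIndex-class].
#' @param negativesPerPositive negatives sampled per gold pair (default 10).
#' @param seed integer seed for the negative sampler.
#' @return list with `features` (matrix), `labels` (0/1 integer vector), and
#'   `skipped` (number of gold pairs whose concept was absent).
#' @export
makeTrainingSet <- function(gold, index, negativesPerPositive = 10L,
                            seed = 1L) {
  stopifnot(all(c("text", "concept_id") %in% names(gold)),
            negativesPerPositive >= 0L)
  entConcept <- index@entries$concept_id
  uniqTexts <- unique(gold$text)
  vecs <- embedText(index@backend, uniqTexts)
  feats <- list(); labels <- integer(0); skipped <- 0L
  .withSeed(seed, {
    for (r in seq_len(nrow(gold))) {
      gid <- gold$concept_id[r]
      own <- which(entConcept == gid)
      if (length(own) == 0L) {
        skipped <- skipped + 1L
        next
      }
      f <- .featureMatrix(index, vecs[match(gold$text[r], uniqTexts), ])
      pos <- own[which.max(f[own, "name_sim"])]
      pool <- which(entConcept != gid)
      negs <- if (length(pool)) {
        pool[sample.int(length(pool),
                        min(negativesPerPositive, length(pool)))]
      } else integer(0)
      feats[[length(feats) + 1L]] <- f[c(pos, negs), , drop = FALSE]
      labels <- c(labels, 1L, rep(0L, length(negs)))
    }
  })
  if (skipped > 0L) {
    warning(sprintf("%d gold pair(s) skipped: concept id not in the index",
                    skipped))
  }
  features <- if (length(feats)) do.call(rbind, feats)
              else matrix(numeric(0), ncol = 2L + index@k)
  rownames(features) <- NULL
  list(features = features, labels = labels, skipped = skipped)
}

#' Fit a candidate-ranking model
#'
#' `strategy = "cosine"` returns the fixed unweighted model: the score of a
#' feature vector is the plain sum of its five similarities, no training data
#' needed. `strategy = "regression"` fits a ridge-penalized logistic
#' regression of the binary labels on the five features (via
#' \pkg{glmnet}, `alpha = 0`), deterministic for fixed inputs; ranking then
#' uses the linear predictor.
#'
#' @param features numeric matrix of feature vectors (rows = examples).
#' @param labels 0/1 vector, required for `"regression"` with both classes
#'   present.
#' @param strategy `"regression"` or `"cosine"`.
#' @param lambda ridge penalty (default `1e-3`, a weak regularizer that
#'   stabilizes separable data without materially shrinking coefficients).
#' @param backend optional [EmbeddingBackend-class] whose name/dim are
#'   recorded in the model metadata.
#' @return a [RankerModel-class].
#' @export
fitRanker <- function(features = NULL, labels = NULL,
                      strategy = c("regression", "cosine"),
                      lambda = 1e-3, backend = NULL) {
  strategy <- match.arg(strategy)
  k <- if (!is.null(features)) ncol(features) - 2L else 3L
  fn <- c("name_sim", "def_sim", paste0("hier_sim", seq_len(k)))
  bname <- if (is.null(backend)) NA_character_ else backend@name
  bdim <- if (is.null(backend)) NA_integer_ else backend@dim
  if (strategy == "cosine") {
    return(new("RankerModel", strategy = "cosine",
               weights = setNames(rep(1, length(fn)), fn), intercept = 0,
               featureNames = fn, backendName = bname, embeddingDim = bdim))
  }
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  if (length(unique(labels)) < 2L) {
    stop("regression ranker needs both positive and negative examples")
  }
  fit <- glmnet::glmnet(features, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, thresh = 1e-10,
                        maxit = 1e6)
  co <- as.numeric(stats::coef(fit, s = lambda))
  new("RankerModel", strategy = "regression",
      weights = setNames(co[-1], fn), intercept = co[1],
      featureNames = fn, backendName = bname, embeddingDim = bdim)
}

#' Score feature vectors with a ranker
#'
#' @param model a [RankerModel-class].
#' @param features numeric matrix (or single feature vector).
#' @return numeric score per row: `features %*% weights + intercept`. For the
#'   cosine strategy this is exactly the unweighted feature sum.
#' @export
rankerScores <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(model@weights)) {
    stop("feature width does not match the model")
  }
  drop(features %*% model@weights) + model@intercept
}

#' @rdname accessors
#' @export
setMethod("rankerWeights", "RankerModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("rankerIntercept", "RankerModel", function(x) x@intercept)

#' @rdname accessors
#' @export
setMethod("rankerStrategy", "RankerModel", function(x) x@strategy)

setMethod("show", "RankerModel", function(object) {
  cat(sprintf("RankerModel (%s strategy)\n", object@strategy))
  cat("  weights: ",
      paste(sprintf("%s = %.4f", object@featureNames, object@weights),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  intercept: %.4f\n", object@intercept))
})

#' Normalize one mention to a ranked list of concepts
#'
#' Embeds the mention text, scores every candidate entry with the ranker,
#' collapses entries to concepts keeping each concept's best-scoring entry (a
#' synonym entry winning means its concept is predicted), and returns concepts
#' sorted by score descending with ascending-concept-id tie break. The top row
#' is the predicted normalization.
#'
#' @param mention mention string, or an annotation row whose `text` is used.
#' @param model a [RankerModel-class].
#' @param index a [ConceptIndex-class].
#' @param topN candidate prefilter passed to [generateCandidates()].
#' @return data.frame with columns `concept_id`, `score`, best first (zero
#'   rows when the index is empty).
#' @export
normalizeMention <- function(mention, model, index, topN = Inf) {
  if (is.data.frame(mention)) mention <- mention$text[1]
  if (nrow(index@entries) == 0L) {
    return(data.frame(concept_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  f <- mentionFeatures(index, mention)
  idx <- seq_len(nrow(f))
  if (is.finite(topN) && topN < length(idx)) {
    ord <- order(-f[, "name_sim"], index@entries$concept_id, idx)
    idx <- sort(ord[seq_len(topN)])
  }
  scores <- rankerScores(model, f[idx, , drop = FALSE])
  cid <- index@entries$concept_id[idx]
  best <- tapply(scores, cid, max)
  out <- data.frame(concept_id = names(best), score = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize every annotation in a data.frame
#'
#' Convenience wrapper assigning each span its top-1 concept.
#'
#' @param ann annotation data.frame (as from [gazetteerTag()]).
#' @inheritParams normalizeMention
#' @return `ann` with `concept_id` filled in (NA where the index is empty).
#' @export
normalizeAnnotations <- function(ann, model, index, topN = Inf) {
  if (nrow(ann) == 0L) return(ann)
  cache <- new.env(parent = emptyenv())
  ann$concept_id <- vapply(ann$text, function(t) {
    key <- paste0("m:", t)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- normalizeMention(t, model, index, topN = topN)
    res <- if (nrow(r)) r$concept_id[1] else NA_character_
    cache[[key]] <- res
    res
  }, character(1), USE.NAMES = FALSE)
  ann
}

#' Serialize / restore a ranker model
#'
#' Models are stored as flat JSON (strategy, weights, intercept, backend
#' metadata) so they survive across sessions and the command-line interface.
#'
#' @param model a [RankerModel-class].
#' @param path file path.
#' @return `readRankerModel` returns the restored [RankerModel-class].
#' @export
writeRankerModel <- function(model, path) {
  jsonlite::write_json(
    list(strategy = model@strategy,
         weights = as.list(setNames(as.numeric(model@weights),
                                    model@featureNames)),
         intercept = model@intercept,
         backend = model@backendName,
         dim = model@embeddingDim),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRankerModel
#' @export
readRankerModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(x$weights)
  new("RankerModel", strategy = x$strategy, weights = w,
      intercept = as.numeric(x$intercept), featureNames = names(w),
      backendName = if (is.null(x$backend)) NA_character_ else x$backend,
      embeddingDim = if (is.null(x$dim) || is.na(x$dim)) NA_integer_
                     else as.integer(x$dim))
}
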