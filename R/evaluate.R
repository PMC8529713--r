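#' Construct an EvalCounts object
#'
#' @param C,S,D,I non-negative counts of correct slots, substitutions,
#'   deletions, and insertions.
#' @return an [EvalCounts-class].
#' @export
evalCounts <- function(C = 0L, S = 0L, D = 0L, I = 0L) {
  # Class= must be named exactly: a bare `C =` would partially match it
  new(Class = "EvalCounts", C = as.integer(C), S = as.integer(S),
      D = as.integer(D), I = as.integer(I))
}

#' @describeIn evalCounts extract the counts as a named vector
#'   `c(C =, S =, D =, I =)`.
#' @param x an [EvalCounts-class].
#' @export
countsVector <- function(x) {
  stopifnot(is(x, "EvalCounts"))
  c(C = x@C, S = x@S, D = x@D, I = x@I)
}

setMethod("show", "EvalCounts", function(object) {
  cat(sprintf("EvalCounts: C = %d, S = %d, D = %d, I = %d\n",
              object@C, object@S, object@D, object@I))
})

#' @describeIn evalCounts sum counts across documents (micro-averaging).
#' @param counts list of [EvalCounts-class] objects.
#' @export
combineCounts <- function(counts) {
  evalCounts(C = sum(vapply(counts, function(x) x@C, integer(1))),
             S = sum(vapply(counts, function(x) x@S, integer(1))),
             D = sum(vapply(counts, function(x) x@D, integer(1))),
             I = sum(vapply(counts, function(x) x@I, integer(1))))
}

# forced exact pairs: same (start, end, concept_id); spans within a list are
# disjoint, so a span value occurs at most once per side and pairing is unique
.exactKeys <- function(ann) {
  ifelse(is.na(ann$concept_id), NA_character_,
         paste(ann$start, ann$end, ann$concept_id, sep = "|"))
}

#' Align predicted against reference annotations
#'
#' Pairs predictions with references in two stages. Exact agreements on
#' `(start, end, concept_id)` are counted as correct slots `C`; because spans
#' within each list are non-overlapping these pairs are uniquely determined.
#' The remaining annotations are then paired one-to-one whenever their spans
#' overlap by at least one character, using a maximum-cardinality bipartite
#' matching on the overlap graph, and counted as substitutions `S`. Leftover
#' predictions are insertions `I`; leftover references are deletions `D`. The
#' counts are invariant across maximum matchings, so the result is
#' deterministic, and the matching provably minimizes the total slot error
#' `S + D + I` for the fixed `C`.
#'
#' @param predicted,reference annotation data.frames for one document;
#'   within-list spans must be non-overlapping.
#' @return an [EvalCounts-class].
#' @examples
#' p <- annotationFrame(c(0, 10), c(5, 15), c("aaaaa", "bbbbb"),
#'                      c("GO:1", "GO:2"))
#' r <- annotationFrame(0, 5, "aaaaa", "GO:1")
#' alignAnnotations(p, r)   # C = 1, I = 1
#' @export
alignAnnotations <- function(predicted, reference) {
  .checkAnnotations(predicted, what = "predicted")
  .checkAnnotations(reference, what = "reference")
  pk <- .exactKeys(predicted)
  rk <- .exactKeys(reference)
  exact <- intersect(pk[!is.na(pk)], rk[!is.na(rk)])
  C <- length(exact)
  p <- predicted[!(pk %in% exact), , drop = FALSE]
  r <- reference[!(rk %in% exact), , drop = FALSE]
  nP <- nrow(p); nR <- nrow(r)
  S <- 0L
  if (nP > 0L && nR > 0L) {
    ov <- outer(seq_len(nP), seq_len(nR), function(i, j) {
      pmin(p$end[i], r$end[j]) - pmax(p$start[i], r$start[j])
    })
    edges <- which(ov >= 1L, arr.ind = TRUE)
    if (nrow(edges) > 0L) {
      g <- igraph::make_empty_graph(n = nP + nR, directed = FALSE)
      g <- igraph::add_edges(g, rbind(edges[, 1], nP + edges[, 2]))
      types <- c(rep(FALSE, nP), rep(TRUE, nR))
      S <- igraph::max_bipartite_match(g, types = types)$matching_size
    }
  }
  evalCounts(C = C, S = S, D = nR - S, I = nP - S)
}

#' Slot Error Rate
#'
#' `SER = (S + D + I) / (C + S + D)`: total slot errors over the number of
#' reference slots. Undefined (an error) for an empty reference.
#'
#' @param counts an [EvalCounts-class].
#' @return non-negative number; 0 iff predictions equal the reference exactly.
#' @examples
#' slotErrorRate(evalCounts(C = 2, S = 1, D = 1, I = 1))  # 0.75
#' @export
slotErrorRate <- function(counts) {
  stopifnot(is(counts, "EvalCounts"))
  ref <- counts@C + counts@S + counts@D
  if (ref == 0L) {
    stop("slot error rate is undefined for an empty reference")
  }
  (counts@S + counts@D + counts@I) / ref
}

#' Exact-span precision, recall, and F1
#'
#' A prediction counts as a true positive only when both character boundaries
#' and the concept id match a reference annotation. Precision is 0 when there
#' are no predictions; F1 is 0 when precision and recall are both 0.
#'
#' @inheritParams alignAnnotations
#' @return list with `tp`, `precision`, `recall`, `f1`.
#' @export
exactMatchPRF <- function(predicted, reference) {
  .checkAnnotations(predicted, what = "predicted")
  .checkAnnotations(reference, what = "reference")
  pk <- .exactKeys(predicted)
  rk <- .exactKeys(reference)
  tp <- length(intersect(pk[!is.na(pk)], rk[!is.na(rk)]))
  precision <- if (nrow(predicted) == 0L) 0 else tp / nrow(predicted)
  recall <- if (nrow(reference) == 0L) 0 else tp / nrow(reference)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, precision = precision, recall = recall, f1 = f1)
}

#' Evaluate predictions over one or more documents
#'
#' Aligns each document's predictions against its reference, micro-averages
#' the counts (summing C/S/D/I before computing rates), and reports SER and
#' exact-span precision/recall/F1.
#'
#' @param predicted,reference either single-document annotation data.frames or
#'   lists of them (paired by position).
#' @return list with `counts` ([EvalCounts-class]), `ser`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluateAnnotations <- function(predicted, reference) {
  if (is.data.frame(predicted)) predicted <- list(predicted)
  if (is.data.frame(reference)) reference <- list(reference)
  stopifnot(length(predicted) == length(reference))
  counts <- combineCounts(mapply(alignAnnotations, predicted, reference,
                                 SIMPLIFY = FALSE))
  tp <- sum(mapply(function(p, r) exactMatchPRF(p, r)$tp,
                   predicted, reference))
  nPred <- sum(vapply(predicted, nrow, integer(1)))
  nRef <- sum(vapply(reference, nrow, integer(1)))
  precision <- if (nPred == 0L) 0 else tp / nPred
  recall <- if (nRef == 0L) 0 else tp / nRef
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(counts = counts, ser = slotErrorRate(counts),
       precision = precision, recall = recall, f1 = f1)
}
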