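#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

#' OntologyGraph: a parsed OBO ontology
#'
#' Container for the concepts of an OBO 1.2 flat file. Each concept record
#' carries its identifier, primary name, definition, synonyms (label plus
#' scope tag), direct `is_a` and `part_of` parents, and an obsolete flag.
#' Parent identifiers that do not resolve within the graph are retained on
#' the concept but listed in the `dangling` slot; they are skipped when
#' hierarchical contexts are extracted.
#'
#' Validity requires unique non-empty identifiers, a non-empty name for every
#' non-obsolete concept, no self-parenting, and acyclic `is_a` and `part_of`
#' relations.
#'
#' @slot concepts named list of concept records (one per `[Term]` stanza, in
#'   file order), each a list with elements `id`, `name`, `definition`,
#'   `synonyms` (data.frame with columns `label`, `scope`), `is_a`,
#'   `part_of`, `obsolete`.
#' @slot dangling character vector of parent ids referenced but not defined.
#'
#' @seealso [parseOBO()], [hierarchyContexts()], [expandEntries()]
#' @export
setClass("OntologyGraph",
  representation(concepts = "list", dangling = "character"),
  prototype(concepts = list(), dangling = character(0)))

.relationCycleNodes <- function(edges, ids) {
  # nodes left over after repeatedly stripping sinks lie on a cycle
  if (nrow(edges) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (igraph::is_dag(g)) return(character(0))
  repeat {
    deg <- igraph::degree(g, mode = "out")
    sinks <- names(deg)[deg == 0L]
    if (length(sinks) == 0L) break
    g <- igraph::delete_vertices(g, sinks)
  }
  igraph::V(g)$name
}

setValidity("OntologyGraph", function(object) {
  cs <- object@concepts
  if (length(cs) == 0L) return(TRUE)
  ids <- unname(vapply(cs, function(co) co$id, character(1)))
  if (any(!nzchar(ids))) return("concept ids must be non-empty")
  if (anyDuplicated(ids)) {
    return(sprintf("duplicated concept id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!identical(names(cs), ids)) return("concepts list must be named by id")
  for (co in cs) {
    if (!co$obsolete && !nzchar(co$name)) {
      return(sprintf("non-obsolete concept %s has an empty name", co$id))
    }
    if (co$id %in% c(co$is_a, co$part_of)) {
      return(sprintf("concept %s lists itself as a parent", co$id))
    }
  }
  for (rel in c("is_a", "part_of")) {
    edges <- do.call(rbind, lapply(cs, function(co) {
      p <- intersect(co[[rel]], ids)
      if (length(p)) data.frame(from = co$id, to = p) else NULL
    }))
    if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0))
    cyc <- .relationCycleNodes(edges, ids)
    if (length(cyc)) {
      return(sprintf("%s relation contains a cycle through: %s",
                     rel, paste(cyc, collapse = " -> ")))
    }
  }
  TRUE
})

#' Sentence-embedding backend contract
#'
#' Virtual class for embedding backends. A backend maps a character vector of
#' texts to a numeric matrix with one row per text and `dim(backend)` columns.
#' Embedding a fixed string must be deterministic within a backend instance.
#' The packaged implementation is [mockEmbedding()], a hashed character-trigram
#' bag; a pretrained sentence-transformer can be plugged in behind the same
#' generic.
#'
#' @slot name backend identifier string.
#' @slot dim embedding dimensionality (positive integer).
#' @export
setClass("EmbeddingBackend",
  representation("VIRTUAL", name = "character", dim = "integer"))

#' @describeIn EmbeddingBackend deterministic hashed character-trigram backend.
#' @export
setClass("MockEmbedding", contains = "EmbeddingBackend")

#' ConceptIndex: an entry table with cached embeddings
#'
#' Normalization-ready view of an ontology: one row per surface entry (primary
#' name or synonym) together with row-normalized embedding matrices for the
#' entry surfaces, the shared definitions, and each hierarchical-context slot.
#' Built once by [buildConceptIndex()]; all candidate scoring works off the
#' cached matrices, so only mention texts are embedded at query time.
#'
#' @slot entries data.frame as returned by [expandEntries()].
#' @slot backend the [EmbeddingBackend-class] used for all cached vectors.
#' @slot k number of hierarchical-context slots (columns `ctx1` ... `ctxk`).
#' @slot surfaceVecs,defVecs numeric matrices, one row per entry, L2-normalized
#'   (all-zero rows are kept as zero and contribute similarity 0).
#' @slot ctxVecs list of `k` matrices, one per context slot.
#' @export
setClass("ConceptIndex",
  representation(entries = "data.frame", backend = "EmbeddingBackend",
                 k = "integer", surfaceVecs = "matrix", defVecs = "matrix",
                 ctxVecs = "list"))

setValidity("ConceptIndex", function(object) {
  n <- nrow(object@entries)
  if (nrow(object@surfaceVecs) != n || nrow(object@defVecs) != n) {
    return("cached embedding matrices must have one row per entry")
  }
  if (length(object@ctxVecs) != object@k) {
    return("ctxVecs must hold one matrix per context slot")
  }
  TRUE
})

#' RankerModel: scoring model over the 5 similarity features
#'
#' Scores a mention-candidate feature vector
#' `(name_sim, def_sim, hier_sim1..3)` as `weights . features + intercept`.
#' Two strategies exist: `"cosine"` (fixed unit weights, zero intercept — the
#' unweighted similarity sum) and `"regression"` (ridge logistic coefficients
#' fitted by [fitRanker()]). Scores are a monotone transform of the logistic
#' probability, so ranking uses the linear predictor directly.
#'
#' @slot strategy `"cosine"` or `"regression"`.
#' @slot weights numeric coefficient vector (length 5).
#' @slot intercept numeric scalar.
#' @slot featureNames names of the feature components.
#' @slot backendName,embeddingDim metadata recording the embedding backend the
#'   model was trained against (informational).
#' @export
setClass("RankerModel",
  representation(strategy = "character", weights = "numeric",
                 intercept = "numeric", featureNames = "character",
                 backendName = "character", embeddingDim = "integer"),
  prototype(backendName = NA_character_, embeddingDim = NA_integer_))

setValidity("RankerModel", function(object) {
  if (!object@strategy %in% c("cosine", "regression")) {
    return("strategy must be 'cosine' or 'regression'")
  }
  if (length(object@weights) != length(object@featureNames)) {
    return("weights and featureNames lengths differ")
  }
  if (length(object@intercept) != 1L || !is.finite(object@intercept)) {
    return("intercept must be a single finite number")
  }
  TRUE
})

#' EvalCounts: slot-alignment tallies
#'
#' Counts from aligning predicted against reference annotations: `C` correct
#' slots (exact span and concept id), `S` substitutions (overlapping but not
#' exact), `D` deletions (unpaired references), `I` insertions (unpaired
#' predictions). They satisfy `C + S + D = |reference|` and
#' `C + S + I = |predicted|`.
#'
#' @slot C,S,D,I non-negative integer counts.
#' @seealso [alignAnnotations()], [slotErrorRate()]
#' @export
setClass("EvalCounts",
  representation(C = "integer", S = "integer", D = "integer", I = "integer"))

setValidity("EvalCounts", function(object) {
  v <- c(object@C, object@S, object@D, object@I)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L)) {
    return("C, S, D, I must be single non-negative integers")
  }
  TRUE
})
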