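#' Embed a batch of texts
#'
#' Maps texts to embedding vectors. One row per input text, order preserved;
#' identical texts yield identical rows. Texts that are empty or whitespace-only
#' embed to the zero vector (which contributes cosine similarity 0 downstream).
#'
#' @param backend an [EmbeddingBackend-class] instance.
#' @param texts character vector (may be empty).
#' @return numeric matrix, `length(texts)` rows by `embeddingDim(backend)`
#'   columns.
#' @examples
#' be <- mockEmbedding(64)
#' v <- embedText(be, c("blood clotting", "blood clotting"))
#' stopifnot(identical(v[1, ], v[2, ]))
#' @export
setGeneric("embedText", function(backend, texts) standardGeneric("embedText"))

#' @rdname accessors
#' @export
setGeneric("conceptIds", function(x) standardGeneric("conceptIds"))

#' @rdname accessors
#' @export
setGeneric("getConcept", function(x, id) standardGeneric("getConcept"))

#' @rdname accessors
#' @export
setGeneric("danglingParents", function(x) standardGeneric("danglingParents"))

#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname accessors
#' @export
setGeneric("backendName", function(x) standardGeneric("backendName"))

#' @rdname accessors
#' @export
setGeneric("indexEntries", function(x) standardGeneric("indexEntries"))

#' @rdname accessors
#' @export
setGeneric("rankerWeights", function(x) standardGeneric("rankerWeights"))

#' @rdname accessors
#' @export
setGeneric("rankerIntercept", function(x) standardGeneric("rankerIntercept"))

#' @rdname accessors
#' @export
setGeneric("rankerStrategy", function(x) standardGeneric("rankerStrategy"))
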