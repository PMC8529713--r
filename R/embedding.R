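#' Deterministic hashed-trigram embedding backend
#'
#' A download-free stand-in for a pretrained sentence embedder: each text is
#' lower-cased, padded with `##` on both sides, decomposed into character
#' trigrams, and the trigram counts are hashed into `dim` buckets and
#' L2-normalized. Identical strings therefore embed identically (cosine 1),
#' strings sharing no trigram are orthogonal barring hash collisions, and
#' surface variants of a phrase keep most of their trigrams and so stay close
#' in cosine — the property the normalization pipeline relies on. The hash is
#' a fixed multiplicative scheme, so the backend is fully deterministic.
#'
#' @param dim number of hash buckets / embedding dimensionality (default 512).
#' @return a `MockEmbedding` backend for use with [embedText()].
#' @examples
#' be <- mockEmbedding()
#' cosineSimilarity(embedText(be, "blood clotting")[1, ],
#'                  embedText(be, "blood clotting")[1, ])
#' @export
mockEmbedding <- function(dim = 512L) {
  stopifnot(dim >= 1L)
  new("MockEmbedding", name = "mock-trigram", dim = as.integer(dim))
}

# hash each character trigram of "##text##" into a bucket in 1..dim
.trigramBuckets <- function(text, dim) {
  x <- utf8ToInt(paste0("##", tolower(text), "##"))
  n <- length(x)
  h <- x[1:(n - 2L)] * 17161 + x[2:(n - 1L)] * 131 + x[3:n]
  h <- (h * 2654435761) %% 4294967296
  as.integer(h %% dim) + 1L
}

#' @rdname embedText
#' @export
setMethod("embedText", "MockEmbedding", function(backend, texts) {
  stopifnot(is.character(texts))
  d <- backend@dim
  out <- matrix(0, nrow = length(texts), ncol = d)
  for (i in seq_along(texts)) {
    t <- texts[i]
    if (is.na(t) || !nzchar(trimws(t))) next
    v <- tabulate(.trigramBuckets(t, d), nbins = d)
    out[i, ] <- v / sqrt(sum(v^2))
  }
  rownames(out) <- NULL
  out
})

#' @rdname accessors
#' @export
setMethod("embeddingDim", "EmbeddingBackend", function(x) x@dim)

#' @rdname accessors
#' @export
setMethod("backendName", "EmbeddingBackend", function(x) x@name)

setMethod("show", "EmbeddingBackend", function(object) {
  cat(sprintf("<%s embedding backend, dim = %d>\n", object@name, object@dim))
})

#' Cosine similarity between two vectors
#'
#' `u . v / (|u| |v|)`, with the convention that any similarity involving a
#' zero vector is 0 (neutral evidence — empty definitions embed to zero).
#'
#' @param u,v numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @examples
#' cosineSimilarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop(sprintf("dimension mismatch: length(u) = %d, length(v) = %d",
                 length(u), length(v)))
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}
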