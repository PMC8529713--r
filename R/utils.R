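## internal helpers shared across modules

# evaluate expr under a fixed RNG state, restoring the caller's state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.l2normRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

.l2norm <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v else v / nrm
}

# read lines from a path, a connection, a single string with newlines,
# or a character vector that already holds lines
.asLines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  stopifnot(is.character(x))
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  x
}

#' Construct an annotation data.frame
#'
#' Annotations are plain data.frames with one row per mention: 0-based,
#' half-open character offsets (`start`, `end`), the covered surface `text`,
#' the normalized `concept_id` (`NA` before normalization), and a `doc_id`.
#'
#' @param start,end integer character offsets, 0-based half-open.
#' @param text covered surface strings.
#' @param concept_id ontology ids, or `NA` for unnormalized spans.
#' @param doc_id document identifiers.
#' @return data.frame with columns `doc_id`, `start`, `end`, `text`,
#'   `concept_id`.
#' @export
annotationFrame <- function(start = integer(0), end = integer(0),
                            text = character(0),
                            concept_id = rep(NA_character_, length(start)),
                            doc_id = rep(NA_character_, length(start))) {
  stopifnot(length(start) == length(end), length(start) == length(text))
  data.frame(doc_id = as.character(doc_id), start = as.integer(start),
             end = as.integer(end), text = as.character(text),
             concept_id = as.character(concept_id),
             stringsAsFactors = FALSE)
}

# check span sanity against the document and in-list disjointness
.checkAnnotations <- function(ann, text = NULL, requireDisjoint = TRUE,
                              what = "annotations") {
  if (nrow(ann) == 0L) return(invisible(ann))
  if (any(ann$start < 0L) || any(ann$end <= ann$start)) {
    stop(sprintf("%s: offsets must satisfy 0 <= start < end", what))
  }
  if (!is.null(text)) {
    if (any(ann$end > nchar(text))) {
      stop(sprintf("%s: span extends past the document end", what))
    }
    covered <- substring(text, ann$start + 1L, ann$end)
    bad <- which(covered != ann$text)
    if (length(bad)) {
      stop(sprintf("%s: row %d text %s does not match document substring %s",
                   what, bad[1], dQuote(ann$text[bad[1]]),
                   dQuote(covered[bad[1]])))
    }
  }
  if (requireDisjoint) {
    o <- order(ann$start, ann$end)
    s <- ann$start[o]; e <- ann$end[o]
    if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
      stop(sprintf("%s: spans overlap within one list", what))
    }
  }
  invisible(ann)
}
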