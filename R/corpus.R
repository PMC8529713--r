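#' Offset-preserving tokenizer
#'
#' Splits a document into maximal alphanumeric runs and single punctuation
#' characters, recording 0-based half-open character offsets. This is plumbing
#' for BIO encoding and gazetteer matching; subword tokenization used inside
#' neural taggers is their own internal concern.
#'
#' @param text a single document string.
#' @return data.frame with columns `text`, `start`, `end`, tokens sorted and
#'   non-overlapping.
#' @examples
#' tokenize("GO:0007596")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             start = starts - 1L, end = starts - 1L + lens,
             stringsAsFactors = FALSE)
}

#' Encode spans as a BIO label sequence
#'
#' Inverse of [decodeBIO()]: tokens inside a span get `B` (first) and `I`
#' (rest); everything else is `O`. Span boundaries must coincide with token
#' boundaries and spans must be non-overlapping.
#'
#' @param tokens data.frame from [tokenize()].
#' @param spans annotation data.frame (only `start`/`end` are used).
#' @return character vector of labels in `{"B","I","O"}`, one per token.
#' @export
encodeBIO <- function(tokens, spans) {
  .checkAnnotations(spans, requireDisjoint = TRUE, what = "spans")
  labels <- rep("O", nrow(tokens))
  for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]; e <- spans$end[r]
    sel <- which(tokens$start >= s & tokens$end <= e)
    crossing <- which(tokens$start < e & tokens$end > s)
    if (length(sel) == 0L || !setequal(sel, crossing) ||
        tokens$start[sel[1]] != s || tokens$end[sel[length(sel)]] != e) {
      stop(sprintf("span [%d,%d) does not align with token boundaries", s, e))
    }
    labels[sel] <- c("B", rep("I", length(sel) - 1L))
  }
  labels
}

#' Decode a BIO label sequence into spans
#'
#' Each maximal `B` followed by zero or more `I` becomes one annotation from
#' the first token's start to the last token's end. An orphan `I` (sequence
#' initial, or following an `O`) is repaired by treating it as `B`: real
#' taggers emit such illegal sequences and dropping them would silently delete
#' recall.
#'
#' @param tokens data.frame from [tokenize()].
#' @param labels character vector over `{"B","I","O"}`, same length as
#'   `tokens`.
#' @param text optional document string used to fill the annotations' `text`
#'   column.
#' @param doc_id optional document id for the output rows.
#' @return annotation data.frame (see [annotationFrame()]) with `concept_id`
#'   all `NA`.
#' @export
decodeBIO <- function(tokens, labels, text = NULL, doc_id = NA_character_) {
  if (length(labels) != nrow(tokens)) {
    stop(sprintf("length(labels) = %d but %d tokens supplied",
                 length(labels), nrow(tokens)))
  }
  stopifnot(all(labels %in% c("B", "I", "O")))
  starts <- integer(0); ends <- integer(0)
  open <- FALSE
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (lb == "B" || (lb == "I" && !open)) {       # orphan I repaired to B
      starts <- c(starts, tokens$start[i])
      ends <- c(ends, tokens$end[i])
      open <- TRUE
    } else if (lb == "I") {
      ends[length(ends)] <- tokens$end[i]
    } else {
      open <- FALSE
    }
  }
  txt <- if (is.null(text)) rep(NA_character_, length(starts))
         else substring(rep(text, length(starts)), starts + 1L, ends)
  annotationFrame(starts, ends, txt, doc_id = rep(doc_id, length(starts)))
}

#' Gazetteer baseline tagger
#'
#' Case-insensitive longest-match search for entry surfaces at token
#' boundaries, resolving overlaps leftmost-longest. This is the dictionary
#' baseline standing in for a neural span tagger: any function mapping text to
#' spans satisfies the same contract and can replace it upstream of
#' normalization. Returned annotations carry no concept id — linking them to
#' concepts is [normalizeMention()]'s job.
#'
#' @param text a document string.
#' @param entries entry table from [expandEntries()] (only `surface` is used).
#' @param doc_id optional document id for the output rows.
#' @return annotation data.frame with non-overlapping spans, `concept_id` all
#'   `NA`.
#' @export
gazetteerTag <- function(text, entries, doc_id = NA_character_) {
  stopifnot(nrow(entries) > 0L)
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(annotationFrame())
  low <- tolower(toks$text)

  surfToks <- lapply(entries$surface, function(s) tolower(tokenize(s)$text))
  keep <- lengths(surfToks) > 0L
  surfToks <- unique(surfToks[keep])
  if (length(surfToks) == 0L) return(annotationFrame())
  byFirst <- split(seq_along(surfToks),
                   vapply(surfToks, `[`, character(1), 1L))

  starts <- integer(0); ends <- integer(0)
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    cands <- byFirst[[low[i]]]
    best <- 0L
    if (!is.null(cands)) {
      for (ci in cands) {
        st <- surfToks[[ci]]
        len <- length(st)
        if (len > best && i + len - 1L <= n &&
            all(low[i:(i + len - 1L)] == st)) {
          best <- len
        }
      }
    }
    if (best > 0L) {
      starts <- c(starts, toks$start[i])
      ends <- c(ends, toks$end[i + best - 1L])
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  annotationFrame(starts, ends,
                  substring(rep(text, length(starts)), starts + 1L, ends),
                  doc_id = rep(doc_id, length(starts)))
}

#' Read brat-style standoff annotations
#'
#' Parses the brat dialect used for gold annotations: text-bound lines
#' `T<n>\t<TYPE> <start> <end>\t<text>` plus normalization lines
#' `N<n>\tReference T<n> <concept_id>`. Every span is checked against the
#' document; a text mismatch or out-of-range offset is an integrity error
#' naming the offending line.
#'
#' @param text the document string the annotations refer to.
#' @param ann a path, connection, or character vector of standoff lines.
#' @param doc_id optional document id for the output rows.
#' @return annotation data.frame ordered by `start`.
#' @export
readStandoff <- function(text, ann, doc_id = NA_character_) {
  lines <- .asLines(ann)
  lines <- lines[nzchar(trimws(lines))]
  tPat <- "^(T[0-9]+)\t(\\S+) ([0-9]+) ([0-9]+)\t(.*)$"
  nPat <- "^(N[0-9]+)\t\\S+ (T[0-9]+) (\\S+)\\s*$"
  spans <- list()
  links <- character(0)
  for (ln in lines) {
    if (grepl(tPat, ln)) {
      m <- regmatches(ln, regexec(tPat, ln))[[1]]
      tid <- m[2]
      start <- as.integer(m[4]); end <- as.integer(m[5])
      covered <- substring(text, start + 1L, end)
      if (end > nchar(text) || start >= end) {
        stop(sprintf("standoff line %s: offsets [%d,%d) outside document",
                     dQuote(ln), start, end))
      }
      if (covered != m[6]) {
        stop(sprintf("standoff line %s: text does not match document substring %s",
                     dQuote(ln), dQuote(covered)))
      }
      spans[[tid]] <- list(start = start, end = end, text = m[6])
    } else if (grepl(nPat, ln)) {
      m <- regmatches(ln, regexec(nPat, ln))[[1]]
      links[m[3]] <- m[4]
    }
  }
  if (length(spans) == 0L) return(annotationFrame())
  tids <- names(spans)
  out <- annotationFrame(
    start = vapply(spans, function(s) s$start, integer(1)),
    end = vapply(spans, function(s) s$end, integer(1)),
    text = vapply(spans, function(s) s$text, character(1)),
    concept_id = ifelse(tids %in% names(links), links[tids], NA_character_),
    doc_id = rep(doc_id, length(spans)))
  out[order(out$start, out$end), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write annotations as brat-style standoff lines
#'
#' Emits `T`-lines for every span and `N`-lines for spans that carry a concept
#' id, in a form [readStandoff()] parses back identically.
#'
#' @param ann annotation data.frame.
#' @param type entity type label for the `T`-lines (default `"GO_BP"`).
#' @param file optional path to write to.
#' @return character vector of standoff lines (invisibly when `file` given).
#' @export
writeStandoff <- function(ann, type = "GO_BP", file = NULL) {
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  out <- character(0)
  nIdx <- 0L
  for (r in seq_len(nrow(ann))) {
    out <- c(out, sprintf("T%d\t%s %d %d\t%s", r, type,
                          ann$start[r], ann$end[r], ann$text[r]))
    if (!is.na(ann$concept_id[r])) {
      nIdx <- nIdx + 1L
      out <- c(out, sprintf("N%d\tReference T%d %s", nIdx, r,
                            ann$concept_id[r]))
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
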