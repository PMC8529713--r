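#' Parse an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas into an [OntologyGraph-class]. The fields consumed
#' are `id`, `name`, `def`, `synonym`, `is_a`, `relationship: part_of`, and
#' `is_obsolete`; everything else (xrefs, subsets, other relationship types,
#' `[Typedef]` stanzas) is ignored. Definition strings are stripped of their
#' surrounding quotes and of the trailing provenance bracket; `! comment` text
#' after parent ids is discarded. Obsolete terms are retained in the graph but
#' flagged, so they can still serve as parents while never becoming
#' normalization entries.
#'
#' @param x a file path, connection, single string containing the OBO text, or
#'   character vector of lines.
#' @return an [OntologyGraph-class]. Unresolved parent ids are reported by
#'   [danglingParents()].
#' @examples
#' obo <- system.file("extdata", "blood_coagulation.obo", package = "ontoNorm")
#' g <- parseOBO(obo)
#' getConcept(g, "GO:0007596")$name
#' @export
parseOBO <- function(x) {
  lines <- .asLines(x)
  lines <- sub("\r$", "", lines)

  concepts <- list()
  cur <- NULL
  curStart <- NA_integer_
  inTerm <- FALSE

  newConcept <- function() {
    list(id = "", name = "", definition = "",
         synonyms = data.frame(label = character(0), scope = character(0),
                               stringsAsFactors = FALSE),
         is_a = character(0), part_of = character(0), obsolete = FALSE)
  }
  flush <- function() {
    if (is.null(cur)) return()
    if (!nzchar(cur$id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   curStart))
    }
    concepts[[length(concepts) + 1L]] <<- cur
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      flush()
      inTerm <- identical(ln, "[Term]")
      if (inTerm) {
        cur <- newConcept()
        curStart <- i
      }
      next
    }
    if (!inTerm || is.null(cur)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L) next
    key <- m[2]; value <- m[3]
    if (key == "id") {
      cur$id <- .stripTagComment(value)
    } else if (key == "name") {
      cur$name <- trimws(value)
    } else if (key == "def") {
      cur$definition <- .parseQuoted(value)$label
    } else if (key == "synonym") {
      q <- .parseQuoted(value)
      scope <- regmatches(q$rest, regexpr("^[A-Z_]+", q$rest))
      if (length(scope) == 0L) scope <- "RELATED"
      cur$synonyms <- rbind(cur$synonyms,
                            data.frame(label = q$label, scope = scope,
                                       stringsAsFactors = FALSE))
    } else if (key == "is_a") {
      cur$is_a <- c(cur$is_a, .stripTagComment(value))
    } else if (key == "relationship") {
      parts <- strsplit(.stripTagComment(value), "\\s+")[[1]]
      if (length(parts) >= 2L && parts[1] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[2])
      }
    } else if (key == "is_obsolete") {
      cur$obsolete <- tolower(trimws(value)) == "true"
    }
  }
  flush()

  ids <- vapply(concepts, function(co) co$id, character(1))
  names(concepts) <- ids
  referenced <- unique(unlist(lapply(concepts,
                                     function(co) c(co$is_a, co$part_of))))
  dangling <- setdiff(referenced, ids)
  new("OntologyGraph", concepts = concepts,
      dangling = if (is.null(dangling)) character(0) else dangling)
}

# first quoted string of an OBO value, plus whatever follows the close quote
.parseQuoted <- function(value) {
  value <- trimws(value)
  m <- regmatches(value, regexec('^"(.*)"', value))[[1]]  # greedy: last quote
  if (length(m) == 0L) {
    # tolerate unquoted values; strip any trailing bracket block
    return(list(label = sub("\\s*\\[[^]]*\\]\\s*$", "", value), rest = ""))
  }
  rest <- trimws(substring(value, nchar(m[1]) + 1L))
  list(label = m[2], rest = rest)
}

.stripTagComment <- function(value) trimws(sub("\\s*!.*$", "", value))

#' Serialize an OntologyGraph back to OBO text
#'
#' Writes the subset of fields the parser reads, in canonical order, so that
#' `parseOBO(writeOBO(g))` reproduces `g` exactly.
#'
#' @param graph an [OntologyGraph-class].
#' @param file optional path; when given, the text is also written there.
#' @return the OBO text as a single string (invisibly when `file` is given).
#' @export
writeOBO <- function(graph, file = NULL) {
  stopifnot(is(graph, "OntologyGraph"))
  out <- c("format-version: 1.2", "")
  for (co in graph@concepts) {
    stanza <- c("[Term]", paste0("id: ", co$id), paste0("name: ", co$name))
    if (nzchar(co$definition)) {
      stanza <- c(stanza, sprintf('def: "%s" []', co$definition))
    }
    if (nrow(co$synonyms)) {
      stanza <- c(stanza, sprintf('synonym: "%s" %s []',
                                  co$synonyms$label, co$synonyms$scope))
    }
    for (p in co$is_a) stanza <- c(stanza, paste0("is_a: ", p))
    for (p in co$part_of) {
      stanza <- c(stanza, paste0("relationship: part_of ", p))
    }
    if (co$obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(text))
  }
  text
}

#' Hierarchical contexts of a concept
#'
#' Returns the primary names of a concept's direct parents, `is_a` parents
#' first and then `part_of` parents, each group in stanza order, truncated to
#' the first `k`. Parent ids that do not resolve in the graph are skipped.
#' These strings are the hierarchical evidence embedded alongside the concept
#' name and definition during normalization.
#'
#' @param graph an [OntologyGraph-class].
#' @param conceptId concept identifier present in `graph`.
#' @param k maximum number of contexts (default 3).
#' @return character vector of length `<= k`.
#' @examples
#' g <- parseOBO(system.file("extdata", "blood_coagulation.obo",
#'                           package = "ontoNorm"))
#' hierarchyContexts(g, "GO:0007596")
#' @export
hierarchyContexts <- function(graph, conceptId, k = 3L) {
  stopifnot(is(graph, "OntologyGraph"), k >= 1L)
  co <- graph@concepts[[conceptId]]
  if (is.null(co)) stop(sprintf("unknown concept id: %s", conceptId))
  parents <- c(co$is_a, co$part_of)
  parents <- parents[parents %in% names(graph@concepts)]
  if (length(parents) == 0L) return(character(0))
  ctx <- vapply(graph@concepts[parents], function(p) p$name, character(1))
  unname(utils::head(ctx, k))
}

#' Expand a graph into normalization entries
#'
#' Every synonym is treated as an individual entry sharing the concept's
#' definition: each non-obsolete concept contributes one row for its primary
#' name plus one per synonym. Rows are ordered by concept id, primary name
#' before synonyms, synonyms in stanza order. Hierarchical contexts fill the
#' `ctx1..ctxk` columns, padded with `""`.
#'
#' @param graph an [OntologyGraph-class].
#' @param k number of hierarchical-context columns (default 3).
#' @return data.frame with columns `surface`, `concept_id`, `is_synonym`,
#'   `definition`, `ctx1` ... `ctxk`.
#' @examples
#' g <- parseOBO(system.file("extdata", "blood_coagulation.obo",
#'                           package = "ontoNorm"))
#' subset(expandEntries(g), concept_id == "GO:0007596")$surface
#' @export
expandEntries <- function(graph, k = 3L) {
  stopifnot(is(graph, "OntologyGraph"), k >= 1L)
  k <- as.integer(k)
  ids <- sort(names(graph@concepts))
  rows <- list()
  for (id in ids) {
    co <- graph@concepts[[id]]
    if (co$obsolete) next
    ctx <- hierarchyContexts(graph, id, k)
    ctx <- c(ctx, rep("", k - length(ctx)))
    surfaces <- c(co$name, co$synonyms$label)
    for (j in seq_along(surfaces)) {
      row <- data.frame(surface = surfaces[j], concept_id = id,
                        is_synonym = j > 1L, definition = co$definition,
                        stringsAsFactors = FALSE)
      for (s in seq_len(k)) row[[paste0("ctx", s)]] <- ctx[s]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(surface = character(0), concept_id = character(0),
                      is_synonym = logical(0), definition = character(0),
                      stringsAsFactors = FALSE)
    for (s in seq_len(k)) out[[paste0("ctx", s)]] <- character(0)
    attr(out, "k") <- k
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "k") <- k
  out
}

#' @describeIn OntologyGraph number of concepts.
#' @param x an `OntologyGraph`.
#' @export
setMethod("length", "OntologyGraph", function(x) length(x@concepts))

#' Accessors
#'
#' Small accessors for the package's S4 containers: concept ids and records
#' and dangling parent ids of an [OntologyGraph-class]; name and
#' dimensionality of an [EmbeddingBackend-class]; the entry table of a
#' [ConceptIndex-class]; strategy, weights, and intercept of a
#' [RankerModel-class].
#'
#' @param x the object.
#' @param id a concept identifier.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("conceptIds", "OntologyGraph", function(x) names(x@concepts))

#' @rdname accessors
#' @export
setMethod("getConcept", "OntologyGraph", function(x, id) {
  co <- x@concepts[[id]]
  if (is.null(co)) stop(sprintf("unknown concept id: %s", id))
  co
})

#' @rdname accessors
#' @export
setMethod("danglingParents", "OntologyGraph", function(x) x@dangling)

setMethod("show", "OntologyGraph", function(object) {
  n <- length(object@concepts)
  nObs <- sum(vapply(object@concepts, function(co) co$obsolete, logical(1)))
  nSyn <- sum(vapply(object@concepts, function(co) nrow(co$synonyms),
                     integer(1)))
  cat(sprintf("OntologyGraph with %d concept(s) (%d obsolete, %d synonym(s))\n",
              n, nObs, nSyn))
  if (length(object@dangling)) {
    cat(sprintf("  dangling parent id(s): %s\n",
                paste(object@dangling, collapse = ", ")))
  }
})
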