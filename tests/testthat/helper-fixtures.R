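# shared fixtures and small independent oracles

bloodOboPath <- function() {
  system.file("extdata", "blood_coagulation.obo", package = "ontoNorm")
}

# the blood-coagulation stanza alone (parents left dangling)
bloodStanzaOnly <- function() {
  lines <- readLines(bloodOboPath(), warn = FALSE)
  stanzas <- split(lines, cumsum(lines == "[Term]"))
  paste(stanzas[["1"]], collapse = "\n")
}

# tiny ontology with trigram-disjoint surfaces, for unambiguous ranking tests
miniOboText <- function() {
  paste(
    "[Term]",
    "id: T:0001",
    "name: alpha alpha",
    'def: "alpha alpha only." []',
    'synonym: "aalph alpha" EXACT []',
    "",
    "[Term]",
    "id: T:0002",
    "name: zzz qqq",
    'def: "zzz qqq only." []',
    "is_a: T:0001",
    "",
    "[Term]",
    "id: T:0003",
    "name: mmm www",
    'def: "" []',
    "relationship: part_of T:0001",
    sep = "\n")
}

# random non-overlapping spans over a document of `len` characters
randomSpanFrame <- function(maxN = 6L, len = 60L, idPool = c("A", "B", "C"),
                            withIds = TRUE) {
  n <- sample(0:maxN, 1L)
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  for (i in seq_len(n)) {
    gap <- sample(0:4, 1L)
    w <- sample(1:7, 1L)
    if (pos + gap + w > len) break
    starts <- c(starts, pos + gap)
    ends <- c(ends, pos + gap + w)
    pos <- pos + gap + w
  }
  k <- length(starts)
  annotationFrame(starts, ends, strrep("x", ends - starts),
                  concept_id = if (withIds) sample(idPool, k, replace = TRUE)
                               else rep(NA_character_, k))
}

# exhaustive alignment oracle: over all one-to-one pairings, maximize exact
# matches first, then the total number of pairs (which minimizes S + D + I);
# independent of the package's matching route
oracleAlign <- function(pred, ref) {
  nP <- nrow(pred); nR <- nrow(ref)
  exactEdge <- function(i, j) {
    pred$start[i] == ref$start[j] && pred$end[i] == ref$end[j] &&
      !is.na(pred$concept_id[i]) && !is.na(ref$concept_id[j]) &&
      pred$concept_id[i] == ref$concept_id[j]
  }
  overlapEdge <- function(i, j) {
    min(pred$end[i], ref$end[j]) - max(pred$start[i], ref$start[j]) >= 1L
  }
  best <- c(-1L, -1L)  # (C, total pairs)
  recurse <- function(i, used, C, tot) {
    if (i > nP) {
      if (C > best[1] || (C == best[1] && tot > best[2])) best <<- c(C, tot)
      return()
    }
    recurse(i + 1L, used, C, tot)  # pred i unpaired
    for (j in seq_len(nR)) {
      if (!used[j] && overlapEdge(i, j)) {
        used[j] <- TRUE
        recurse(i + 1L, used, C + as.integer(exactEdge(i, j)), tot + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nR), 0L, 0L)
  C <- best[1]; tot <- best[2]
  S <- tot - C
  list(C = C, S = S, D = nR - tot, I = nP - tot)
}
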