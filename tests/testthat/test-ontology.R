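test_that("the blood-coagulation stanza parses with all consumed fields", {
  g <- parseOBO(bloodOboPath())
  expect_s4_class(g, "OntologyGraph")
  expect_length(g, 4L)
  expect_length(danglingParents(g), 0L)

  co <- getConcept(g, "GO:0007596")
  expect_identical(co$name, "blood coagulation")
  expect_identical(co$synonyms$label, "blood clotting")
  expect_identical(co$synonyms$scope, "EXACT")
  expect_identical(co$is_a, c("GO:0007599", "GO:0050817"))
  expect_identical(co$part_of, "GO:0042060")
  expect_match(co$definition, "^The sequential process in which")
  # quotes and the trailing provenance bracket are stripped
  expect_false(grepl('"', co$definition))
  expect_false(grepl("\\[", co$definition))
  expect_false(co$obsolete)
})

test_that("degenerate streams parse to the documented graphs", {
  expect_length(parseOBO(character(0)), 0L)
  expect_length(parseOBO("format-version: 1.2"), 0L)

  g <- parseOBO(c("[Term]", "id: X:1", "name: lone concept"))
  co <- getConcept(g, "X:1")
  expect_identical(co$definition, "")
  expect_identical(nrow(co$synonyms), 0L)
  expect_length(c(co$is_a, co$part_of), 0L)

  # parent comments after "!" are discarded; unresolved parents are flagged
  g2 <- parseOBO(c("[Term]", "id: X:1", "name: a",
                   "is_a: X:9 ! something else"))
  expect_identical(getConcept(g2, "X:1")$is_a, "X:9")
  expect_identical(danglingParents(g2), "X:9")

  g3 <- parseOBO(c("[Term]", "id: X:1", "name: gone", "is_obsolete: true"))
  expect_true(getConcept(g3, "X:1")$obsolete)
})

test_that("malformed stanzas and cycles are rejected with informative errors", {
  expect_error(parseOBO(c("[Term]", "name: no id here")), "line 1")
  expect_error(
    parseOBO(c("[Term]", "id: X:1", "name: a", "is_a: X:2",
               "", "[Term]", "id: X:2", "name: b", "is_a: X:1")),
    "cycle.*X:")
  expect_error(
    parseOBO(c("[Term]", "id: X:1", "name: a",
               "relationship: part_of X:2",
               "", "[Term]", "id: X:2", "name: b",
               "relationship: part_of X:1")),
    "part_of.*cycle")
  expect_error(parseOBO(c("[Term]", "id: X:1", "name: a", "is_a: X:1")),
               "itself")
})

test_that("hierarchy contexts order is_a before part_of and truncate to k", {
  g <- parseOBO(bloodOboPath())
  expect_identical(hierarchyContexts(g, "GO:0007596", k = 3),
                   c("hemostasis", "coagulation", "wound healing"))
  expect_identical(hierarchyContexts(g, "GO:0007596", k = 2),
                   c("hemostasis", "coagulation"))
  expect_identical(hierarchyContexts(g, "GO:0007599"), character(0))
  expect_error(hierarchyContexts(g, "GO:9999999"), "unknown concept")

  # five parents in known stanza order, truncated to the first 3
  lines <- c("[Term]", "id: P:0", "name: child",
             "is_a: P:1", "is_a: P:2", "is_a: P:3",
             "relationship: part_of P:4", "relationship: part_of P:5")
  for (i in 1:5) {
    lines <- c(lines, "", "[Term]", sprintf("id: P:%d", i),
               sprintf("name: parent%d", i))
  }
  g5 <- parseOBO(lines)
  expect_identical(hierarchyContexts(g5, "P:0", k = 3),
                   c("parent1", "parent2", "parent3"))
  expect_identical(hierarchyContexts(g5, "P:0", k = 5),
                   paste0("parent", 1:5))
  # deterministic: repeated calls agree
  expect_identical(hierarchyContexts(g5, "P:0"), hierarchyContexts(g5, "P:0"))

  # dangling parents are skipped, resolvable ones kept
  gd <- parseOBO(bloodStanzaOnly())
  expect_identical(hierarchyContexts(gd, "GO:0007596"), character(0))
})

test_that("synonym expansion yields one entry per surface with shared definition", {
  g <- parseOBO(bloodOboPath())
  e <- expandEntries(g)
  e96 <- e[e$concept_id == "GO:0007596", ]
  expect_identical(e96$surface, c("blood coagulation", "blood clotting"))
  expect_identical(e96$is_synonym, c(FALSE, TRUE))
  expect_identical(unique(e96$definition), e96$definition[1])
  expect_identical(e96$ctx1, rep("hemostasis", 2))
  expect_identical(e96$ctx3, rep("wound healing", 2))

  # the stanza alone still yields exactly 2 entries (contexts dangle away)
  expect_identical(nrow(subset(expandEntries(parseOBO(bloodStanzaOnly())),
                               concept_id == "GO:0007596")), 2L)

  # 0-, 1-, 2-synonym concepts give 1 + 2 + 3 = 6 entries, ordered by id
  lines <- c("[Term]", "id: A:1", "name: one",
             "", "[Term]", "id: A:2", "name: two",
             'synonym: "deux" EXACT []',
             "", "[Term]", "id: A:3", "name: three",
             'synonym: "trois" EXACT []', 'synonym: "drei" BROAD []')
  e3 <- expandEntries(parseOBO(lines))
  expect_identical(nrow(e3), 6L)
  expect_identical(e3$surface,
                   c("one", "two", "deux", "three", "trois", "drei"))

  # obsolete concepts contribute no entries but may still be parents
  gob <- parseOBO(c("[Term]", "id: B:1", "name: dead", "is_obsolete: true",
                    "", "[Term]", "id: B:2", "name: live", "is_a: B:1"))
  eob <- expandEntries(gob)
  expect_identical(eob$concept_id, "B:2")
  expect_identical(eob$ctx1, "dead")

  expect_identical(nrow(expandEntries(parseOBO(character(0)))), 0L)
})

test_that("entry count matches a line-count oracle over the OBO source", {
  lines <- readLines(bloodOboPath(), warn = FALSE)
  nTerms <- sum(lines == "[Term]")
  nSyn <- sum(grepl("^synonym:", lines))
  e <- expandEntries(parseOBO(lines))
  expect_identical(nrow(e), nTerms + nSyn)

  obo <- generateOntology(fixtureParams(nConcepts = 15, seed = 3))
  gl <- strsplit(obo, "\n")[[1]]
  expect_identical(nrow(expandEntries(parseOBO(gl))),
                   sum(gl == "[Term]") + sum(grepl("^synonym:", gl)))
})

test_that("serializing and re-parsing a graph is the identity on parsed fields", {
  for (src in list(bloodOboPath(),
                   generateOntology(fixtureParams(nConcepts = 12, seed = 5)))) {
    g <- parseOBO(src)
    g2 <- parseOBO(writeOBO(g))
    expect_identical(g2@concepts, g@concepts)
    expect_identical(danglingParents(g2), danglingParents(g))
  }
  # round trip preserves obsolete flags too
  gob <- parseOBO(c("[Term]", "id: B:1", "name: dead", "is_obsolete: true"))
  expect_identical(parseOBO(writeOBO(gob))@concepts, gob@concepts)
})
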