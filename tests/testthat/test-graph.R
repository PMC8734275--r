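test_that("prov_graph expands CURIEs, deduplicates, and summarises", {
  pf <- c(prov_prefixes(), ex = "https://example.org/")
  g <- prov_graph(tibble::tibble(
    subject = c("ex:a", "ex:a"), predicate = c("rdf:type", "rdf:type"),
    object = c("prov:Entity", "prov:Entity"),
    literal = FALSE, datatype = NA_character_, lang = NA_character_
  ), prefixes = pf)
  expect_equal(n_triples(g), 1L)
  expect_equal(g$triples$subject, "https://example.org/a")
  expect_equal(glance(g)$n_subjects, 1L)
  td <- tidy(g)
  expect_equal(td$object, "prov:Entity")  # compacted back for display
})

test_that("curie expansion and compaction are inverse on vocabulary terms", {
  reg <- build_registry()
  expect_equal(compact_iri(expand_curie(reg$curie)), reg$curie)
  # full IRIs with path-like locals survive untouched
  iri <- "https://example.org/exp1/step-1"
  expect_equal(expand_curie(iri), iri)
})

test_that("match_bgp joins patterns on shared variables", {
  pf <- c(prov_prefixes(), ex = "https://example.org/")
  g <- prov_graph(tibble::tibble(
    subject = c("ex:m", "ex:m", "ex:s1", "ex:other"),
    predicate = c("rdfs:label", "p-plan:isInputVarOf", "p-plan:isStepOfPlan",
                  "p-plan:isStepOfPlan"),
    object = c("DAPI", "ex:s1", "ex:plan", "ex:plan"),
    literal = c(TRUE, FALSE, FALSE, FALSE),
    datatype = NA_character_, lang = NA_character_
  ), prefixes = pf)
  sol <- match_bgp(g, tibble::tibble(
    s = c("?m", "?m", "?step"),
    p = c("rdfs:label", "p-plan:isInputVarOf", "p-plan:isStepOfPlan"),
    o = c("DAPI", "?step", "?plan")
  ))
  expect_equal(nrow(sol), 1L)
  expect_equal(sol$step, "https://example.org/s1")
  expect_equal(sol$plan, "https://example.org/plan")
  # no-solution pattern
  none <- match_bgp(g, tibble::tibble(s = "?x", p = "rdfs:label", o = "missing"))
  expect_equal(nrow(none), 0L)
})

test_that("graph isomorphism ignores blank-node labels but not structure", {
  a <- prov_graph(tibble::tibble(
    subject = c("_:x", "_:x"), predicate = c("rdf:type", "rdfs:label"),
    object = c("prov:Entity", "thing"), literal = c(FALSE, TRUE),
    datatype = NA_character_, lang = NA_character_
  ))
  b <- prov_graph(tibble::tibble(
    subject = c("_:y", "_:y"), predicate = c("rdf:type", "rdfs:label"),
    object = c("prov:Entity", "thing"), literal = c(FALSE, TRUE),
    datatype = NA_character_, lang = NA_character_
  ))
  expect_true(graph_isomorphic(a, b))
  c <- add_triples(b, tibble::tibble(subject = "_:y", predicate = "rdfs:comment",
                                     object = "extra", literal = TRUE,
                                     datatype = NA_character_, lang = NA_character_))
  expect_false(graph_isomorphic(a, c))
})

test_that("graph_union merges triples and prefixes", {
  g1 <- prov_graph(tibble::tibble(subject = "prov:a", predicate = "rdf:type",
                                  object = "prov:Entity", literal = FALSE,
                                  datatype = NA_character_, lang = NA_character_))
  g2 <- prov_graph(tibble::tibble(subject = "x:b", predicate = "rdf:type",
                                  object = "prov:Entity", literal = FALSE,
                                  datatype = NA_character_, lang = NA_character_),
                   prefixes = c(prov_prefixes(), x = "https://x.org/"))
  u <- graph_union(g1, g2)
  expect_equal(n_triples(u), 2L)
  expect_true("x" %in% names(u$prefixes))
})
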