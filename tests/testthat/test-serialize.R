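# Round-trip behaviour of the three serializations over representative
# graphs, including literals that stress the writers (newlines, quotes,
# backslashes, typed and tagged literals).

awkward_graph <- function() {
  prov_graph(dplyr::bind_rows(
    tibble::tibble(subject = "https://example.org/a", predicate = "rdfs:comment",
                   object = "line1\nline2 \"quoted\" back\\slash\ttab",
                   literal = TRUE, datatype = NA_character_, lang = NA_character_),
    tibble::tibble(subject = "https://example.org/a", predicate = "repr:executionTime",
                   object = "5.25", literal = TRUE,
                   datatype = "xsd:decimal", lang = NA_character_),
    tibble::tibble(subject = "https://example.org/a", predicate = "rdfs:label",
                   object = "ein Experiment", literal = TRUE,
                   datatype = NA_character_, lang = "de"),
    tibble::tibble(subject = "https://example.org/a", predicate = "rdf:type",
                   object = "prov:Entity", literal = FALSE,
                   datatype = NA_character_, lang = NA_character_)
  ))
}

test_that("all three dialects round-trip representative graphs isomorphically", {
  graphs <- list(
    awkward = awkward_graph(),
    fixture = fixture_colocalization(),
    empty = prov_graph()
  )
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    for (d in c("turtle", "rdfxml", "n3")) {
      doc <- rdf_serialize(g, d)
      back <- rdf_parse(doc, d)
      expect_true(graph_isomorphic(g, back),
                  label = sprintf("%s via %s", nm, d))
      expect_equal(n_triples(back), n_triples(g))
    }
  }
})

test_that("the three dialects of one graph agree pairwise", {
  g <- fixture_colocalization()
  parsed <- lapply(c("turtle", "rdfxml", "n3"), function(d) {
    rdf_parse(rdf_serialize(g, d), d)
  })
  expect_true(graph_isomorphic(parsed[[1]], parsed[[2]]))
  expect_true(graph_isomorphic(parsed[[2]], parsed[[3]]))
})

test_that("empty graphs serialize to prefix declarations only", {
  doc <- rdf_serialize(prov_graph(), "turtle")
  lines <- strsplit(doc, "\n")[[1]]
  expect_true(all(grepl("^@prefix|^$", lines)))
})

test_that("a larger synthetic graph survives a serialization round trip", {
  gen <- generate_provenance(gen_config(seed = 99, n_experiments = 5,
                                        steps_range = c(4L, 6L)))
  expect_gt(n_triples(gen$graph), 400)
  for (d in c("turtle", "rdfxml")) {
    expect_true(graph_isomorphic(gen$graph, rdf_parse(rdf_serialize(gen$graph, d), d)))
  }
})

test_that("malformed documents fail with positioned errors", {
  expect_error(rdf_parse("ex:a rdfs:label", "turtle"), "parse error")
  expect_error(rdf_parse("qq:a rdfs:label \"x\" .", "turtle"), "unbound prefix")
  expect_error(rdf_parse("<rdf:RDF", "rdfxml"), "parse error")
  expect_error(rdf_serialize(prov_graph(), "jsonld"), "arg")
})

test_that("turtle parser handles comments, numbers, booleans and 'a'", {
  doc <- paste(
    "@prefix ex: <https://example.org/> .",
    "# a comment with \"quotes\" and ex:things",
    "ex:a a ex:Thing ;",
    "  ex:count 42 ;",
    "  ex:ratio 1.5 ;",
    "  ex:flag true .",
    sep = "\n"
  )
  g <- rdf_parse(doc, "turtle")
  expect_equal(n_triples(g), 4L)
  tr <- g$triples
  expect_true(any(tr$object == "42" & grepl("integer$", tr$datatype)))
  expect_true(any(tr$object == "1.5" & grepl("decimal$", tr$datatype)))
  expect_true(any(tr$object == "true" & grepl("boolean$", tr$datatype)))
})
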