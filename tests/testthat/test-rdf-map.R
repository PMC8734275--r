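test_that("the graph uses the model's property vocabulary", {
  e <- as_experiment(tiny_manifest())
  td <- tidy(experiment_to_graph(e))
  has <- function(s, p, o) any(td$subject == s & td$predicate == p & td$object == o)
  # instrument part in both directions
  expect_true(has("ex:mic1", "repr:hasPart", "ex:obj1"))
  expect_true(has("ex:obj1", "repr:isPartOf", "ex:mic1"))
  # variables related to steps
  expect_true(has("ex:d2", "p-plan:isOutputVarOf", "ex:s3"))
  expect_true(has("ex:mat1", "p-plan:isInputVarOf", "ex:s1"))
  # steps and plans
  expect_true(has("ex:s1", "p-plan:isStepOfPlan", "ex:exp1"))
  expect_true(has("ex:prot1", "p-plan:isSubPlanOfPlan", "ex:exp1"))
  expect_true(has("ex:s2", "repr:usedMethod", "ex:meth1"))
  expect_true(has("ex:s2", "p-plan:isPrecededBy", "ex:s1"))
  # agents with ORCID, publications with DOI, timestamps
  expect_true(has("ex:exp1", "prov:wasAttributedTo", "ex:a1"))
  expect_true(any(td$subject == "ex:a1" & td$predicate == "repr:orcid" &
                    td$object == "0000-0001-2345-678X"))
  expect_true(any(td$subject == "ex:d1" & td$predicate == "repr:doi"))
  expect_true(any(td$subject == "ex:exp1" & td$predicate == "prov:generatedAtTime"))
  # settings via hasSetting
  expect_true(has("ex:mic1", "repr:hasSetting", "ex:set1"))
})

test_that("an empty experiment yields only the typed experiment node", {
  e <- as_experiment(list(experiment = list(id = "bare")))
  td <- tidy(experiment_to_graph(e))
  expect_setequal(unique(td$subject), "ex:bare")
  expect_true(all(c("repr:Experiment", "p-plan:Plan") %in%
                    td$object[td$predicate == "rdf:type"]))
})

test_that("graph construction is deterministic", {
  e <- as_experiment(tiny_manifest())
  expect_identical(rdf_serialize(experiment_to_graph(e), "turtle"),
                   rdf_serialize(experiment_to_graph(e), "turtle"))
})

test_that("model -> graph -> model round trips hold for generator output", {
  for (seed in c(3, 17)) {
    gen <- generate_provenance(gen_config(seed = seed, n_experiments = 3))
    for (e in gen$records) {
      g <- experiment_to_graph(e)
      expect_true(experiment_equal(e, experiment_from_graph(g)),
                  label = sprintf("seed %d %s", seed, e$meta$id))
      # and through a serialization in each dialect
      for (d in c("turtle", "rdfxml", "n3")) {
        e2 <- experiment_from_graph(rdf_parse(rdf_serialize(g, d), d))
        expect_true(experiment_equal(e, e2),
                    label = sprintf("seed %d %s via %s", seed, e$meta$id, d))
      }
    }
  }
})

test_that("unknown repr terms are rejected with their names", {
  g <- experiment_to_graph(as_experiment(tiny_manifest()))
  g <- add_triples(g, tibble::tibble(
    subject = "ex:x", predicate = "rdf:type", object = "repr:Teleporter",
    literal = FALSE, datatype = NA_character_, lang = NA_character_
  ))
  expect_error(experiments_from_graph(g), "Teleporter")
})

test_that("both variable-direction conventions parse to the same inputs", {
  g <- experiment_to_graph(as_experiment(tiny_manifest()))
  # rewrite one isInputVarOf edge to the inverse hasInputVar direction
  tr <- g$triples
  pf <- g$prefixes
  i <- which(tr$predicate == expand_curie("p-plan:isInputVarOf", pf) &
               tr$subject == expand_curie("ex:mat1", pf) &
               tr$object == expand_curie("ex:s1", pf))
  flipped <- tr
  flipped$subject[i] <- tr$object[i]
  flipped$predicate[i] <- expand_curie("p-plan:hasInputVar", pf)
  flipped$object[i] <- tr$subject[i]
  g2 <- prov_graph(flipped, pf)
  expect_true(experiment_equal(experiment_from_graph(g),
                               experiment_from_graph(g2)))
})

test_that("the colocalization fixture recovers two experiments", {
  recs <- experiments_from_graph(fixture_colocalization())
  expect_length(recs, 2L)
  expect_setequal(vapply(recs, function(r) r$meta$label, character(1)),
                  c("Colocalization of EGFP-RAD51",
                    "Colocalization of EGFP-RAD52 / mCherry-RAD54"))
  expect_error(experiment_from_graph(fixture_colocalization()), "exactly 1")
})
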