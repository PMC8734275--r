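test_that("a run-manifest builds a trial graph covering every supplied component", {
  built <- build_trial(tiny_trial_manifest())
  td <- tidy(built$graph)
  types <- td$object[td$predicate == "rdf:type"]
  # prospective components
  expect_true(all(c("repr:Script", "repr:Function", "repr:ProgrammingLanguage",
                    "repr:Author", "repr:Experiment") %in% types))
  # retrospective components
  expect_true(all(c("repr:Trial", "repr:FunctionActivation", "repr:Version",
                    "repr:Module", "repr:OperatingSystem", "repr:File",
                    "repr:Experimenter", "prov:Location", "repr:Argument",
                    "repr:Output") %in% types))
  for (p in c("prov:startedAtTime", "prov:endedAtTime", "p-plan:isPrecededBy",
              "prov:atLocation", "prov:wasAssociatedWith", "prov:generated")) {
    expect_true(p %in% td$predicate, label = p)
  }
})

test_that("activation order follows the manifest as isPrecededBy edges", {
  built <- build_trial(tiny_trial_manifest())
  td <- tidy(built$graph)
  edges <- td[td$predicate == "p-plan:isPrecededBy", ]
  expect_equal(nrow(edges), 2L)
  expect_true(any(edges$subject == "ex:fa2" & edges$object == "ex:fa1"))
  expect_true(any(edges$subject == "ex:fa3" & edges$object == "ex:fa2"))
  # oracle: manifest index order
  expect_equal(built$trial$activations$position, 1:3)
})

test_that("modules carry version setting nodes", {
  td <- tidy(build_trial(tiny_trial_manifest())$graph)
  mod <- td$subject[td$predicate == "rdfs:label" & td$object == "numlib"]
  ver <- td$object[td$subject == mod & td$predicate == "repr:hasSetting"]
  expect_length(ver, 1L)
  expect_true(any(td$subject == ver & td$predicate == "rdf:value" & td$object == "1.2"))
  expect_true(any(td$subject == ver & td$predicate == "rdf:type" &
                    td$object == "repr:Version"))
})

test_that("schema violations and empty trials are handled", {
  expect_error(build_trial(list(trial = list(id = "t"))), "no script id")
  expect_error(build_trial(list(script = list(id = "s"))), "no trial id")
  m <- tiny_trial_manifest()
  m$trial$activations <- list()
  expect_warning(built <- build_trial(m), "no function activations")
  expect_true("repr:Trial" %in% tidy(built$graph)$object)
  m2 <- tiny_trial_manifest()
  m2$trial$activations[[1]]$`function` <- "undeclared"
  expect_error(build_trial(m2), "undeclared function")
})

test_that("script derivation enumerates the chain and environment in order", {
  g <- build_trial(tiny_trial_manifest())$graph
  rep <- script_derivation(g, "ex:res1")
  expect_equal(rep$section[1], "trial")
  acts <- rep[rep$section == "activation", ]
  expect_equal(acts$label, c("load_data", "normalize", "fit_model"))
  expect_equal(rep$value[rep$section == "language"], "3.9.7")
  expect_equal(rep$value[rep$section == "os"], "7")
  expect_setequal(rep$label[rep$section == "module"], c("numlib", "plotlib"))
  expect_equal(rep$label[rep$section == "file"], "measurements.csv")
  expect_equal(rep$label[rep$section == "experimenter"], "Alice")
  expect_match(rep$label[rep$section == "location"], "workstation-7")
  # sections appear in the documented order
  expect_equal(unique(rep$section),
               c("trial", "activation", "language", "os", "module", "file",
                 "experimenter", "location"))
})

test_that("derivation picks the generating trial and warns when none exists", {
  m1 <- tiny_trial_manifest()
  m2 <- tiny_trial_manifest()
  m2$trial$id <- "trial2"
  m2$trial$result <- list(id = "res2", value = "0.99")
  m2$trial$activations <- lapply(m2$trial$activations, function(a) {
    a$id <- paste0(a$id, "-t2"); a
  })
  g <- graph_union(build_trial(m1)$graph, build_trial(m2)$graph)
  rep <- script_derivation(g, "ex:res2")
  expect_equal(rep$node[rep$section == "trial"],
               "https://example.org/provpath/trial2")
  expect_true(all(grepl("-t2$", rep$node[rep$section == "activation"])))
  # a file node exists but nothing generated it
  expect_warning(rep0 <- script_derivation(g, "ex:trial1/file/measurements.csv"),
                 "no trial generated")
  expect_equal(nrow(rep0), 0L)
  expect_error(script_derivation(g, "ex:missing"), "not present")
})

test_that("run-manifests load from JSON files", {
  path <- system.file("extdata", "trial-example.json", package = "provpath")
  built <- build_trial(read_trial_manifest(path))
  expect_gt(n_triples(built$graph), 30)
})
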