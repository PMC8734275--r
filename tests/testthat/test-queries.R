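test_that("the material-usage question reproduces the worked example", {
  g <- fixture_colocalization()
  res <- steps_using_material(g, "pCherry-RAD54")
  expect_equal(dplyr::n_distinct(res$experiment), 2L)
  expect_setequal(unique(res$step_label), c("Preparation", "Transfection"))
  expect_setequal(unique(res$experiment_label),
                  c("Colocalization of EGFP-RAD51",
                    "Colocalization of EGFP-RAD52 / mCherry-RAD54"))
  # unknown material -> empty table
  expect_equal(nrow(steps_using_material(g, "pEGFP-XYZ")), 0L)
  # case-insensitive flag
  expect_equal(nrow(steps_using_material(g, "PCHERRY-RAD54", ignore_case = TRUE)),
               nrow(res))
})

test_that("material usage is found through sub-plan nesting", {
  m <- tiny_manifest()   # step s3 lives in sub-plan prot1
  m$steps[[3]]$inputs <- list("mat1")
  g <- experiment_to_graph(as_experiment(m))
  res <- steps_using_material(g, "pCherry-RAD54")
  expect_true("ex:s3" %in% compact_iri(res$step, g$prefixes))
  expect_equal(unique(compact_iri(res$experiment, g$prefixes)), "ex:exp1")
})

test_that("the notebook complete path lists executions in sequence order", {
  fix <- tiny_notebook_with_log()
  g <- notebook_to_graph(fix$nb, fix$log)
  res <- notebook_complete_path(g, "ex:nb1")
  expect_equal(nrow(res[!is.na(res$execution), ]), 3L)
  expect_equal(res$seq[!is.na(res$seq)], 1:3)
  expect_equal(sum(is.na(res$execution)), 0L)  # both cells were executed
  expect_true(all(c("source", "started_at", "generated") %in% names(res)))
  # a never-executed notebook still reports cells and sources
  nb2 <- read_notebook(tiny_notebook_json(n_code = 2), id = "fresh")
  res2 <- notebook_complete_path(notebook_to_graph(nb2), "ex:fresh")
  expect_equal(nrow(res2), 2L)
  expect_true(all(is.na(res2$execution)))
  expect_false(any(is.na(res2$source)))
  # absent notebook warns and returns an empty table
  expect_warning(res3 <- notebook_complete_path(g, "ex:nowhere"), "not found")
  expect_equal(nrow(res3), 0L)
})

test_that("notebook path rows are identical whichever dialect carried the graph", {
  fix <- tiny_notebook_with_log()
  g <- notebook_to_graph(fix$nb, fix$log)
  via_ttl <- notebook_complete_path(rdf_parse(rdf_serialize(g, "turtle"), "turtle"),
                                    "ex:nb1")
  via_xml <- notebook_complete_path(rdf_parse(rdf_serialize(g, "rdfxml"), "rdfxml"),
                                    "ex:nb1")
  expect_equal(via_ttl, via_xml)
})

test_that("the experiment complete path assembles every element group", {
  g <- experiment_to_graph(as_experiment(tiny_manifest()))
  cp <- experiment_complete_path(g, "ex:exp1")
  expect_equal(cp$agents$role, "Experimenter")
  expect_setequal(compact_iri(cp$plans$plan, g$prefixes), c("ex:prot1", "ex:meth1"))
  expect_setequal(cp$steps$label, c("Preparation", "Transfection", "Image Acquisition"))
  # both computational and non-computational steps are linked
  expect_setequal(unique(cp$steps$subtype),
                  c("NonComputationalStep", "ComputationalStep"))
  expect_true(any(cp$step_io$direction == "input" & cp$step_io$label == "pCherry-RAD54"))
  expect_true(any(cp$step_io$direction == "output" & cp$step_io$label == "image"))
  expect_setequal(cp$instruments$setting_key, c("laser power", "zoom"))
  expect_error(experiment_complete_path(g, "ex:ghost"), "not present")
})

test_that("experiments without instruments report empty instrument sections only", {
  m <- tiny_manifest()
  m$instruments <- NULL
  m$settings <- NULL
  g <- experiment_to_graph(as_experiment(m))
  cp <- experiment_complete_path(g, "ex:exp1")
  expect_equal(nrow(cp$instruments), 0L)
  expect_gt(nrow(cp$steps), 0L)
  expect_gt(nrow(cp$agents), 0L)
})

test_that("split sub-queries agree with a monolithic pattern on small graphs", {
  g <- experiment_to_graph(as_experiment(tiny_manifest()))
  cp <- experiment_complete_path(g, "ex:exp1")
  mono <- match_bgp(g, tibble::tibble(
    s = c("ex:exp1", "?step", "ex:exp1", "?instr"),
    p = c("prov:wasAttributedTo", "p-plan:isStepOfPlan", "prov:used", "rdf:type"),
    o = c("?agent", "ex:exp1", "?instr", "repr:Microscope")
  ))
  expect_setequal(unique(mono$agent), cp$agents$agent)
  # the monolithic cross-product contains exactly the section contents
  expect_setequal(unique(mono$step),
                  cp$steps$step[cp$steps$plan == expand_curie("ex:exp1", g$prefixes)])
  expect_true(all(unique(mono$instr) %in% cp$instruments$instrument))
})

test_that("planted-answer queries are sound and complete over generator seeds", {
  for (seed in c(2, 5, 8)) {
    gen <- generate_provenance(gen_config(seed = seed, n_experiments = 3))
    tu <- gen$truth$material_usage
    for (lab in unique(tu$material_label)) {
      got <- steps_using_material(gen$graph, lab)
      want <- dplyr::arrange(
        dplyr::distinct(tu[tu$material_label == lab,
                           c("experiment", "experiment_label", "step", "step_label")]),
        experiment, step
      )
      expect_equal(as.data.frame(got), as.data.frame(want),
                   label = sprintf("seed %d material %s", seed, lab))
    }
  }
})
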