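# The term registry against the printed vocabulary: the script/notebook
# provenance component map, the eight model components, and the enumerated
# subtype classifications.

reg <- build_registry()

test_that("the experiment model exposes exactly eight components", {
  expect_setequal(model_components(),
                  c("Data", "Agent", "Activity", "Plan", "Step", "Setting",
                    "Instrument", "Material"))
  expect_length(model_components(), 8L)
})

test_that("every script/notebook provenance component resolves with its printed superclass", {
  map <- provenance_term_map()
  expect_equal(nrow(map), 25L)  # one row per printed component
  # repr:Version backs module, language and OS versions
  expect_equal(sum(map$term == "repr:Version"), 3L)
  for (i in seq_len(nrow(map))) {
    term <- term_lookup(reg, map$term[i])
    expect_equal(term$provenance, map$provenance[i], label = map$term[i])
    remark_is_class <- map$remark[i] %in% reg$curie &&
      term_lookup(reg, map$remark[i])$kind == "class"
    if (term$kind == "class" && remark_is_class) {
      expect_true(map$remark[i] %in% term$superclasses[[1]],
                  label = sprintf("%s subClassOf %s", map$term[i], map$remark[i]))
    }
  }
})

test_that("lookup returns exact terms and errors on unknown names", {
  cell <- term_lookup(reg, "Cell")
  expect_equal(cell$kind, "class")
  expect_equal(cell$provenance, "prospective")
  expect_true("p-plan:Step" %in% cell$superclasses[[1]])
  expect_match(cell$description, "multiline text input field")

  trial <- term_lookup(reg, "Trial")
  expect_equal(trial$provenance, "retrospective")
  expect_true("prov:Activity" %in% trial$superclasses[[1]])

  expect_true("p-plan:Plan" %in% term_lookup(reg, "Notebook")$superclasses[[1]])

  ce <- term_lookup(reg, "CellExecution")
  expect_equal(ce$provenance, "retrospective")
  expect_true("p-plan:Activity" %in% ce$superclasses[[1]])
  # the imported hierarchy bridges the printed superclass to prov:Activity
  expect_true("prov:Activity" %in% superclass_closure(reg, "CellExecution"))

  expect_error(term_lookup(reg, "nonexistent"), "nonexistent")
  # lookup is case-sensitive
  expect_error(term_lookup(reg, "cell"), "unknown term")
})

test_that("the enumerated subtype lists match the printed classifications", {
  expect_setequal(component_subtypes(reg, "Plan")$local_name,
                  c("Experiment", "Protocol", "StandardOperatingProcedure",
                    "Method", "Algorithm", "Study", "Script", "Notebook"))
  expect_setequal(component_subtypes(reg, "Step")$local_name,
                  c("ComputationalStep", "NonComputationalStep",
                    "IntermediateStep", "FinalStep"))
  expect_setequal(component_subtypes(reg, "Setting")$local_name,
                  c("ExecutionEnvironment", "Context", "InstrumentSettings",
                    "ComputationalTools", "Packages", "Libraries", "Software"))
  expect_setequal(component_subtypes(reg, "Instrument")$local_name,
                  c("Microscope", "Detector", "LightSource", "FilterSet",
                    "Objective", "Dichroic", "Laser"))
  expect_setequal(component_subtypes(reg, "Material")$local_name,
                  c("Chemical", "Solution", "Specimen", "Plasmid"))
  expect_setequal(component_subtypes(reg, "Agent")$local_name,
                  c("Experimenter", "Manufacturer", "CopyrightHolder",
                    "Distributor", "Author", "PrincipalInvestigator",
                    "ContactPerson", "Owner", "Organization",
                    "ResearchProject", "ResearchGroup", "FundingAgency"))
  data_cats <- component_subtypes(reg, "Data")$local_name
  expect_true(all(c("Metadata", "Annotation", "InputData", "Parameter",
                    "Result", "FinalResult", "IntermediateResult",
                    "PositiveResult", "NegativeResult", "RawData",
                    "ProcessedData", "Measurement", "Publication",
                    "ModifiedVersion", "LicenseDocument",
                    "RightsAndPermissionsDocument") %in% data_cats))
})

test_that("no duplicate repr local names and every repr class reaches a PROV/P-Plan root", {
  repr_names <- reg$local_name[reg$prefix == "repr"]
  expect_equal(anyDuplicated(repr_names), 0L)
  roots_ok <- c("prov:Entity", "prov:Activity", "prov:Agent", "prov:Person",
                "prov:Organization", "prov:Plan",
                "p-plan:Plan", "p-plan:Step", "p-plan:Variable", "p-plan:Activity")
  for (cls in reg$curie[reg$prefix == "repr" & reg$kind == "class"]) {
    expect_true(any(superclass_closure(reg, cls) %in% roots_ok), label = cls)
  }
})

test_that("prospective and retrospective terms split over the expected roots", {
  map <- provenance_term_map()
  for (i in seq_len(nrow(map))) {
    term <- term_lookup(reg, map$term[i])
    if (term$kind != "class") next
    closure <- c(term$curie, superclass_closure(reg, map$term[i]))
    if (map$provenance[i] == "prospective") {
      # prospective terms root in plans, steps, persons or (for the language
      # component) settings, exactly as the printed remarks state
      expect_true(any(c("p-plan:Plan", "p-plan:Step", "prov:Person",
                        "repr:Setting") %in% closure),
                  label = paste("prospective", map$term[i]))
    } else {
      expect_true(any(c("p-plan:Variable", "repr:Setting", "p-plan:Step",
                        "prov:Activity", "prov:Person", "prov:Location") %in% closure),
                  label = paste("retrospective", map$term[i]))
    }
  }
})

test_that("subclass closure supports instance queries through intermediate classes", {
  expect_true("repr:Plasmid" %in% subclass_closure(reg, "ExperimentalMaterial"))
  expect_true("repr:FinalResult" %in% subclass_closure(reg, "Data"))
  expect_true("p-plan:Variable" %in% superclass_closure(reg, "Plasmid"))
})
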