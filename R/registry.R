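# The term registry: every class and property of the experiment-provenance
# vocabulary (namespace https://w3id.org/reproduceme#, prefix "repr") held as
# data, together with the PROV-O / P-Plan terms it builds on. The registry is
# the single source of truth for the ontology emitter, the RDF mapping, the
# validator (rule R5) and the subclass reasoning used by the queries.

REPR <- "https://w3id.org/reproduceme#"

term_row <- function(local_name, prefix, kind, superclasses, provenance,
                     description, component = NA_character_) {
  tibble(
    local_name = local_name, prefix = prefix,
    kind = kind, superclasses = list(superclasses),
    provenance = provenance, description = description,
    component = component
  )
}

# shorthand builders
cls <- function(name, super, desc, component = NA, prov_cat = "not-applicable",
                prefix = "repr") {
  term_row(name, prefix, "class", super, prov_cat, desc, component)
}
oprop <- function(name, desc, prov_cat = "not-applicable", prefix = "repr") {
  term_row(name, prefix, "object-property", character(0), prov_cat, desc)
}
dprop <- function(name, desc, prov_cat = "not-applicable", prefix = "repr") {
  term_row(name, prefix, "data-property", character(0), prov_cat, desc)
}

#' Build the provenance term registry
#'
#' Constructs the full machine-readable vocabulary: the eight experiment-model
#' components (Data, Agent, Activity, Plan, Step, Setting, Instrument,
#' Material) with their enumerated subtypes, the script/notebook provenance
#' terms with their prospective/retrospective classification, the repr object
#' and data properties, and the imported PROV-O / P-Plan terms (with their
#' own hierarchy) needed for subclass reasoning.
#'
#' @return A tibble of class `term_registry` with columns `local_name`,
#'   `prefix`, `iri`, `curie`, `kind` (class / object-property /
#'   data-property), `superclasses` (list of CURIEs), `provenance`
#'   (prospective / retrospective / not-applicable), `description`, and
#'   `component` (which model component a class enumerates, or NA).
#'   Attributes `namespace` and `ns_prefix` carry the repr binding.
#' @export
#' @examples
#' reg <- build_registry()
#' term_lookup(reg, "Cell")$provenance
build_registry <- function() {
  rows <- bind_rows(
    ## ---- core component classes -----------------------------------------
    cls("Experiment", "p-plan:Plan",
        "Denotes the scientific experiment in which the script was used to perform data computation to produce result",
        component = "Plan", prov_cat = "prospective"),
    cls("Protocol", "p-plan:Plan", "A written procedural plan of an experiment.", "Plan"),
    cls("StandardOperatingProcedure", "p-plan:Plan",
        "A standard operating procedure followed in an experiment.", "Plan"),
    cls("Method", "p-plan:Plan", "A method followed to achieve the goal of an experiment.", "Plan"),
    cls("Algorithm", "p-plan:Plan", "An algorithm used in an experiment.", "Plan"),
    cls("Study", "p-plan:Plan", "A study grouping one or more experiments.", "Plan"),
    cls("Script", "p-plan:Plan",
        "Program or code that is used in a scientific experiment",
        component = "Plan", prov_cat = "prospective"),
    cls("Notebook", "p-plan:Plan", "A computational notebook used in an experiment",
        component = "Plan", prov_cat = "prospective"),

    cls("ComputationalStep", "p-plan:Step",
        "A step performed using computational agents or resources.", "Step"),
    cls("NonComputationalStep", "p-plan:Step",
        "A step performed without using any computational agents or resources.", "Step"),
    cls("IntermediateStep", "p-plan:Step", "An intermediate step of a plan.", "Step"),
    cls("FinalStep", "p-plan:Step", "The final step of a plan.", "Step"),

    cls("Setting", "prov:Entity",
        "A configuration or parameter involved in an experiment."),
    cls("ExecutionEnvironment", "repr:Setting",
        "The environment in which a computational step is executed.", "Setting"),
    cls("Context", "repr:Setting", "The context in which an experiment is performed.", "Setting"),
    cls("InstrumentSettings", "repr:Setting",
        "The configurations made in an instrument during the experiment.", "Setting"),
    cls("ComputationalTools", "repr:Setting", "Computational tools used in an experiment.", "Setting"),
    cls("Packages", "repr:Setting", "Software packages used in an experiment.", "Setting"),
    cls("Libraries", "repr:Setting", "Software libraries used in an experiment.", "Setting"),
    cls("Software", "repr:Setting", "Software used in an experiment.", "Setting"),

    cls("Instrument", "prov:Entity", "A device used in an experiment."),
    cls("Microscope", "repr:Instrument", "A microscope used in an imaging experiment.", "Instrument"),
    cls("Detector", "repr:Instrument", "A detector attached to an instrument.", "Instrument"),
    cls("LightSource", "repr:Instrument", "A light source of an instrument.", "Instrument"),
    cls("FilterSet", "repr:Instrument", "A filter set of an instrument.", "Instrument"),
    cls("Objective", "repr:Instrument", "An objective of a microscope.", "Instrument"),
    cls("Dichroic", "repr:Instrument", "A dichroic of an instrument.", "Instrument"),
    cls("Laser", "repr:Instrument", "A laser of an instrument.", "Instrument"),

    cls("ExperimentalMaterial", c("prov:Entity", "p-plan:Variable"),
        "A physical or digital material used in an experiment."),
    cls("Chemical", "repr:ExperimentalMaterial", "A chemical used in an experiment.", "Material"),
    cls("Solution", "repr:ExperimentalMaterial", "A solution used in an experiment.", "Material"),
    cls("Specimen", "repr:ExperimentalMaterial", "A specimen used in an experiment.", "Material"),
    cls("Plasmid", "repr:ExperimentalMaterial", "A plasmid used in an experiment.", "Material"),

    ## ---- data classification --------------------------------------------
    cls("Data", "prov:Entity", "An item used or generated in a scientific experiment."),
    cls("ExperimentData", c("repr:Data", "p-plan:Variable"),
        "A data element of an experiment, usable as an input or output variable."),
    cls("Metadata", "repr:ExperimentData", "Metadata describing experiment data.", "Data"),
    cls("Annotation", "repr:ExperimentData", "An annotation attached to experiment data.", "Data"),
    cls("InputData", "repr:ExperimentData", "Data used as an input of an experiment.", "Data"),
    cls("Parameter", "repr:ExperimentData", "A parameter of a step or computation.", "Data"),
    cls("Result", "repr:ExperimentData", "A result of an experiment.", "Data"),
    cls("FinalResult", "repr:Result", "The final result of an experiment.", "Data"),
    cls("IntermediateResult", "repr:Result", "An intermediate result of an experiment.", "Data"),
    cls("PositiveResult", "repr:Result", "A positive result of an experiment.", "Data"),
    cls("NegativeResult", "repr:Result", "A negative result of an experiment.", "Data"),
    cls("RawData", "repr:ExperimentData", "Unprocessed data from an experiment.", "Data"),
    cls("ProcessedData", "repr:ExperimentData", "Data after processing steps.", "Data"),
    cls("Measurement", "repr:ExperimentData", "A measurement recorded in an experiment.", "Data"),
    cls("Publication", "repr:ExperimentData",
        "A publication used by or resulting from an experiment.", "Data"),
    cls("ModifiedVersion", "repr:ExperimentData", "A modified version of a data item.", "Data"),
    cls("LicenseDocument", "repr:ExperimentData", "A license document for data.", "Data"),
    cls("RightsAndPermissionsDocument", "repr:ExperimentData",
        "A rights and permissions document for data.", "Data"),
    cls("File", c("prov:Entity", "p-plan:Variable"),
        "Denotes the files that are accessed during the script execution",
        prov_cat = "retrospective"),

    ## ---- agent roles ------------------------------------------------------
    cls("Experimenter", "prov:Person", "Denotes the person who is executing the script",
        component = "Agent", prov_cat = "retrospective"),
    cls("Manufacturer", "prov:Agent", "The manufacturer of an instrument or material.", "Agent"),
    cls("CopyrightHolder", "prov:Agent", "The copyright holder of a resource.", "Agent"),
    cls("Distributor", "prov:Agent", "The distributor of a material or device.", "Agent"),
    cls("Author", "prov:Person", "The person who is the author of the script",
        component = "Agent", prov_cat = "prospective"),
    cls("PrincipalInvestigator", "prov:Agent", "The principal investigator of a project.", "Agent"),
    cls("ContactPerson", "prov:Agent", "The contact person for an experiment.", "Agent"),
    cls("Owner", "prov:Agent", "The owner of a resource.", "Agent"),
    cls("Organization", "prov:Organization", "An organization involved in an experiment.", "Agent"),
    cls("ResearchProject", "prov:Agent", "A research project in which an experiment is conducted.", "Agent"),
    cls("ResearchGroup", "prov:Agent", "A research group conducting experiments.", "Agent"),
    cls("FundingAgency", "prov:Agent", "A funding agency supporting an experiment.", "Agent"),

    ## ---- script / notebook provenance classes -----------------------------
    cls("Function", "p-plan:Plan", "A programming language code snippet",
        prov_cat = "prospective"),
    cls("Module", "p-plan:Plan",
        "A part of a computer program or software which provides declarations and functions",
        prov_cat = "prospective"),
    cls("Version", "repr:Setting",
        "The version of a module, programming language or operating system",
        prov_cat = "retrospective"),
    cls("Argument", "p-plan:Variable",
        "The parameter taken as an input, or declared/used in a script",
        prov_cat = "retrospective"),
    cls("Input", "p-plan:Variable",
        "The variable used as an input to a script or a function",
        prov_cat = "retrospective"),
    cls("Output", "p-plan:Variable",
        "The variable generated as an output of a script or a function",
        prov_cat = "retrospective"),
    cls("ProgrammingLanguage", "repr:Setting",
        "The programming language in which a script is written",
        prov_cat = "prospective"),
    cls("OperatingSystem", "repr:Setting",
        "The operating system where the script is run",
        prov_cat = "retrospective"),
    cls("FunctionActivation", "p-plan:Step",
        "Denotes when a function is activated or run",
        prov_cat = "retrospective"),
    cls("Trial", "prov:Activity", "Denotes a run or execution of a script",
        component = "Activity", prov_cat = "retrospective"),
    cls("Cell", "p-plan:Step", "A multiline text input field in a computational notebook",
        prov_cat = "prospective"),
    cls("Source", "p-plan:Variable", "The input of each cell",
        prov_cat = "retrospective"),
    cls("CellExecution", "p-plan:Activity", "Denotes an execution of a cell",
        component = "Activity", prov_cat = "retrospective"),

    ## ---- repr properties ---------------------------------------------------
    oprop("hasPart", "Relates an instrument to one of its parts."),
    oprop("isPartOf", "Relates a part to the instrument it belongs to."),
    oprop("hasSetting", "Relates an instrument, part or computational plan to a setting."),
    oprop("usedMethod", "Relates a step of an experiment to the method it used."),
    dprop("executionTime", "The total time taken for an execution, in seconds.",
          prov_cat = "retrospective"),
    dprop("orcid", "The ORCID identifier of an agent."),
    dprop("doi", "The DOI identifying a publication."),
    dprop("pubmedid", "The PubMed identifier of a publication."),
    dprop("pmcid", "The PubMed Central identifier of a publication."),
    dprop("modifiedAtTime", "The time at which a resource was last modified."),
    dprop("precondition", "A condition that must be fulfilled before performing an activity."),
    # toolkit extension terms (documented as such in the package vignette)
    dprop("goal", "A goal the experiment is performed to achieve."),
    dprop("hypothesis", "The hypothesis the experiment validates or refutes."),
    dprop("sequenceNumber", "Monotonic per-trial sequence number of an execution."),
    dprop("index", "Zero-based position of a cell within its notebook."),

    ## ---- imported PROV-O terms --------------------------------------------
    cls("Entity", character(0), "A physical, digital or conceptual thing.", prefix = "prov"),
    cls("Activity", character(0), "Something that occurs over a period of time.", prefix = "prov"),
    cls("Agent", character(0), "Something that bears responsibility.", prefix = "prov"),
    cls("Person", "prov:Agent", "A person agent.", prefix = "prov"),
    cls("Organization", "prov:Agent", "An organization agent.", prefix = "prov"),
    cls("Plan", "prov:Entity", "A set of actions or steps intended by agents.", prefix = "prov"),
    cls("Location", character(0),
        "Denotes the location where the script is executed",
        prov_cat = "retrospective", prefix = "prov"),
    dprop("startedAtTime", "Denotes the time when the script is started to execute",
          prov_cat = "retrospective", prefix = "prov"),
    dprop("endedAtTime", "Denotes the time when the script finishes its execution",
          prov_cat = "retrospective", prefix = "prov"),
    dprop("generatedAtTime", "The time at which an entity was generated.", prefix = "prov"),
    oprop("used", "An activity used an entity.", prefix = "prov"),
    oprop("generated", "An activity generated an entity.", prefix = "prov"),
    oprop("wasAttributedTo", "Ascribes an entity to an agent.", prefix = "prov"),
    oprop("wasAssociatedWith", "Assigns responsibility for an activity to an agent.",
          prefix = "prov"),
    oprop("atLocation", "Relates a resource to a location.", prefix = "prov"),
    oprop("wasDerivedFrom", "A transformation of one entity into another.", prefix = "prov"),

    ## ---- imported P-Plan terms --------------------------------------------
    cls("Plan", "prov:Plan", "A plan with steps and variables.", prefix = "p-plan"),
    cls("Step", "prov:Entity", "A planned execution activity.", prefix = "p-plan"),
    cls("Variable", "prov:Entity", "An input or output variable of a step.", prefix = "p-plan"),
    cls("Activity", "prov:Activity", "The execution of a step of a plan.", prefix = "p-plan"),
    oprop("isStepOfPlan", "Relates a step to the plan it belongs to.", prefix = "p-plan"),
    oprop("isSubPlanOfPlan", "Relates a sub-plan to its containing plan.", prefix = "p-plan"),
    oprop("isInputVarOf", "Relates an input variable to a step.", prefix = "p-plan"),
    oprop("isOutputVarOf", "Relates an output variable to a step.", prefix = "p-plan"),
    oprop("hasInputVar", "Relates a step to an input variable.", prefix = "p-plan"),
    oprop("isPrecededBy", "Denotes how the functions are executed inside a script",
          prov_cat = "retrospective", prefix = "p-plan"),
    oprop("correspondsToStep", "Relates an activity to the step it executes.", prefix = "p-plan"),
    oprop("correspondsToVariable", "Relates a variable to an experiment-level variable.",
          prefix = "p-plan"),

    ## ---- RDF plumbing ------------------------------------------------------
    dprop("value", "The literal value of a resource.", prefix = "rdf")
  )

  pf <- prov_prefixes()
  rows$iri <- paste0(pf[rows$prefix], rows$local_name)
  rows$curie <- paste0(rows$prefix, ":", rows$local_name)
  dup <- rows$local_name[rows$prefix == "repr"][duplicated(rows$local_name[rows$prefix == "repr"])]
  if (length(dup) > 0) abort(paste("duplicate repr local names:", paste(dup, collapse = ", ")))
  structure(rows, class = c("term_registry", class(rows)),
            namespace = REPR, ns_prefix = "repr",
            imported_prefixes = pf[c("prov", "p-plan", "rdf", "rdfs", "owl")])
}

#' Look up a term in the registry
#'
#' @param registry A [build_registry()] result.
#' @param name A local name (case-sensitive; `repr` terms take precedence) or
#'   a qualified CURIE such as `"p-plan:Activity"` to disambiguate imported
#'   terms.
#' @return A one-row tibble describing the term.
#' @export
term_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "term_registry"))
  if (grepl(":", name, fixed = TRUE)) {
    hit <- registry[registry$curie == name, ]
  } else {
    hit <- registry[registry$local_name == name, ]
    if (nrow(hit) > 1) {
      pref <- hit[hit$prefix == "repr", ]
      if (nrow(pref) == 1) hit <- pref
      else abort(sprintf("term '%s' is ambiguous: %s", name,
                         paste(hit$curie, collapse = ", ")))
    }
  }
  if (nrow(hit) == 0) {
    abort(sprintf("unknown term '%s': not registered in the provenance vocabulary", name))
  }
  hit
}

#' Enumerated subtypes of a model component
#'
#' @param registry A [build_registry()] result.
#' @param component One of `"Plan"`, `"Step"`, `"Setting"`, `"Instrument"`,
#'   `"Material"`, `"Agent"`, `"Data"`, `"Activity"`.
#' @return Tibble of the classes enumerating that component.
#' @export
component_subtypes <- function(registry, component) {
  component <- match.arg(component, c("Plan", "Step", "Setting", "Instrument",
                                      "Material", "Agent", "Data", "Activity"))
  registry[!is.na(registry$component) & registry$component == component &
             registry$kind == "class", ]
}

#' The eight components of the experiment model
#'
#' @return Character vector of the component names of the experiment n-tuple.
#' @export
model_components <- function() {
  c("Data", "Agent", "Activity", "Plan", "Step", "Setting", "Instrument", "Material")
}

#' Script and notebook provenance term map
#'
#' One row per component of the script/notebook provenance vocabulary: the
#' component name, the ontology term it maps to, its prospective or
#' retrospective classification, and the printed superclass (or property
#' remark). `repr:Version` backs three components (module, language and OS
#' versions), so terms repeat while components do not.
#'
#' @return A tibble with columns `component`, `term`, `provenance`, `remark`.
#' @export
provenance_term_map <- function() {
  tibble::tribble(
    ~component,                       ~term,                     ~provenance,     ~remark,
    "Script",                         "repr:Script",             "prospective",   "p-plan:Plan",
    "Function",                       "repr:Function",           "prospective",   "p-plan:Plan",
    "Module",                         "repr:Module",             "prospective",   "p-plan:Plan",
    "Module Version",                 "repr:Version",            "retrospective", "repr:Setting",
    "Argument",                       "repr:Argument",           "retrospective", "p-plan:Variable",
    "Input",                          "repr:Input",              "retrospective", "p-plan:Variable",
    "Output",                         "repr:Output",             "retrospective", "p-plan:Variable",
    "Programming Language",           "repr:ProgrammingLanguage","prospective",   "repr:Setting",
    "Programming Language Version",   "repr:Version",            "retrospective", "repr:Setting",
    "Operating System",               "repr:OperatingSystem",    "retrospective", "repr:Setting",
    "Operating System Version",       "repr:Version",            "retrospective", "repr:Setting",
    "Author",                         "repr:Author",             "prospective",   "prov:Person",
    "Function Activation",            "repr:FunctionActivation", "retrospective", "p-plan:Step",
    "Trial",                          "repr:Trial",              "retrospective", "prov:Activity",
    "Start Time",                     "prov:startedAtTime",      "retrospective", "data property",
    "Finish Time",                    "prov:endedAtTime",        "retrospective", "data property",
    "Experimenter",                   "repr:Experimenter",       "retrospective", "prov:Person",
    "Location",                       "prov:Location",           "retrospective", "prov:atLocation",
    "Accessed File",                  "repr:File",               "retrospective", "p-plan:Variable",
    "Order of execution",             "p-plan:isPrecededBy",     "retrospective", "object property",
    "Experiment",                     "repr:Experiment",         "prospective",   "p-plan:Plan",
    "Notebook",                       "repr:Notebook",           "prospective",   "p-plan:Plan",
    "Cell",                           "repr:Cell",               "prospective",   "p-plan:Step",
    "Source",                         "repr:Source",             "retrospective", "p-plan:Variable",
    "CellExecution",                  "repr:CellExecution",      "retrospective", "p-plan:Activity"
  )
}

# --- subclass reasoning -----------------------------------------------------

#' Superclass closure of a term
#'
#' Walks the registered `superclasses` chains transitively.
#'
#' @param registry A [build_registry()] result.
#' @param name Local name or CURIE of a class.
#' @return Character vector of superclass CURIEs (not including the class).
#' @export
superclass_closure <- function(registry, name) {
  start <- term_lookup(registry, name)$curie
  seen <- character(0)
  frontier <- start
  while (length(frontier) > 0) {
    supers <- unlist(registry$superclasses[registry$curie %in% frontier])
    supers <- setdiff(unique(supers), c(seen, start))
    seen <- c(seen, supers)
    frontier <- supers[supers %in% registry$curie]
  }
  seen
}

#' Subclass closure of a class
#'
#' @inheritParams superclass_closure
#' @return Character vector of CURIEs: the class and all registered
#'   subclasses, transitively.
#' @export
subclass_closure <- function(registry, name) {
  start <- term_lookup(registry, name)$curie
  seen <- start
  repeat {
    more <- registry$curie[vapply(registry$superclasses,
                                  function(s) any(s %in% seen), logical(1))]
    more <- setdiff(more, seen)
    if (length(more) == 0) break
    seen <- c(seen, more)
  }
  seen
}

# instances of a class (by rdf:type, honouring registered subclasses)
instances_of <- function(g, class_curie, registry) {
  classes <- expand_curie(subclass_closure(registry, class_curie), g$prefixes)
  tr <- g$triples
  unique(tr$subject[tr$predicate == expand_curie("rdf:type", g$prefixes) &
                      !tr$literal & tr$object %in% classes])
}
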