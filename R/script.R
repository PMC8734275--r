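# Script-run provenance from run manifests. The manifest is the capture
# boundary (interpreter tracers can produce them); building a trial emits the
# prospective side (Script, Function, ProgrammingLanguage, Author,
# Experiment) and the retrospective side (Trial, FunctionActivation,
# Module + Version, OS + Version, arguments, returns, accessed files,
# Experimenter, Location, times, activation order).

#' Read a script run-manifest
#'
#' @param path Path to a JSON run-manifest with top-level `script` and
#'   `trial` blocks; see `vignette("provenance-model")` for the schema.
#' @return The parsed manifest list.
#' @export
read_trial_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Build a script trial record and its provenance graph
#'
#' @param manifest A run-manifest list (see [read_trial_manifest()]).
#' @param base_iri Base IRI for minted nodes.
#' @return A list with `trial` (tibbles describing the run) and `graph`
#'   (a [prov_graph()] holding every manifest-supplied component:
#'   activations with arguments and return values, trial times, modules and
#'   versions, language and version, OS and version, accessed files,
#'   activation order, experimenter, location, and the final result).
#' @export
build_trial <- function(manifest, base_iri = "https://example.org/provpath/") {
  sc <- manifest$script
  tl <- manifest$trial
  if (is.null(sc) || is.null(sc$id)) abort("manifest violates schema: no script id")
  if (is.null(tl) || is.null(tl$id)) abort("manifest violates schema: no trial id")
  iri <- function(id) paste0(base_iri, id)
  S <- iri(sc$id); T <- iri(tl$id)

  tr <- list(
    spo(S, "rdf:type", c("repr:Script", "p-plan:Plan")),
    spv(S, "rdfs:label", sc$label %||% sc$id),
    spo(T, "rdf:type", c("repr:Trial", "prov:Activity")),
    spo(T, "prov:used", S)
  )
  if (!is.null(tl$started)) tr <- c(tr, list(spv(T, "prov:startedAtTime", tl$started, "xsd:dateTime")))
  if (!is.null(tl$ended)) tr <- c(tr, list(spv(T, "prov:endedAtTime", tl$ended, "xsd:dateTime")))
  if (!is.null(tl$started) && !is.null(tl$ended)) {
    tr <- c(tr, list(spv(T, "repr:executionTime",
                         parse_time(tl$ended) - parse_time(tl$started), "xsd:decimal")))
  }

  if (!is.null(sc$experiment)) {
    E <- iri(sc$experiment)
    tr <- c(tr, list(spo(E, "rdf:type", c("repr:Experiment", "p-plan:Plan")),
                     spo(S, "p-plan:isSubPlanOfPlan", E)))
  }
  if (!is.null(sc$author)) {
    A <- iri(sc$author$id %||% "author")
    tr <- c(tr, list(spo(A, "rdf:type", c("repr:Author", "prov:Agent")),
                     spv(A, "rdfs:label", sc$author$name %||% sc$author$id),
                     spo(S, "prov:wasAttributedTo", A)))
    if (!is.null(sc$author$orcid)) tr <- c(tr, list(spv(A, "repr:orcid", sc$author$orcid)))
  }
  if (!is.null(sc$language)) {
    L <- iri(paste0(sc$id, "/language"))
    tr <- c(tr, list(spo(L, "rdf:type", "repr:ProgrammingLanguage"),
                     spv(L, "rdfs:label", sc$language$name %||% "language"),
                     spo(S, "repr:hasSetting", L)))
    if (!is.null(sc$language$version)) {
      tr <- c(tr, list(version_setting(L, sc$language$version)))
    }
  }

  funs <- sc$functions %||% list()
  fun_iris <- character(0)
  for (f in funs) {
    Fi <- iri(f$id)
    fun_iris <- c(fun_iris, Fi)
    tr <- c(tr, list(spo(Fi, "rdf:type", c("repr:Function", "p-plan:Plan")),
                     spv(Fi, "rdfs:label", f$label %||% f$id),
                     spo(Fi, "p-plan:isSubPlanOfPlan", S)))
  }

  if (!is.null(tl$experimenter)) {
    Ex <- iri(tl$experimenter$id %||% "experimenter")
    tr <- c(tr, list(spo(Ex, "rdf:type", c("repr:Experimenter", "prov:Agent")),
                     spv(Ex, "rdfs:label", tl$experimenter$name %||% tl$experimenter$id),
                     spo(T, "prov:wasAssociatedWith", Ex)))
  }
  if (!is.null(tl$location)) {
    Loc <- iri(paste0(tl$id, "/location"))
    tr <- c(tr, list(spo(Loc, "rdf:type", "prov:Location"),
                     spv(Loc, "rdfs:label", tl$location),
                     spo(T, "prov:atLocation", Loc)))
  }
  if (!is.null(tl$os)) {
    OS <- iri(paste0(tl$id, "/os"))
    tr <- c(tr, list(spo(OS, "rdf:type", "repr:OperatingSystem"),
                     spv(OS, "rdfs:label", tl$os$name %||% "os"),
                     spo(T, "repr:hasSetting", OS)))
    if (!is.null(tl$os$version)) tr <- c(tr, list(version_setting(OS, tl$os$version)))
  }
  for (m in tl$modules %||% list()) {
    M <- iri(paste0(tl$id, "/module/", m$name))
    tr <- c(tr, list(spo(M, "rdf:type", c("repr:Module", "p-plan:Plan")),
                     spv(M, "rdfs:label", m$name),
                     spo(T, "prov:used", M)))
    if (!is.null(m$version)) tr <- c(tr, list(version_setting(M, m$version)))
  }
  for (f in tl$accessed_files %||% list()) {
    Fi <- iri(paste0(tl$id, "/file/", gsub("[^A-Za-z0-9._-]", "_", f)))
    tr <- c(tr, list(spo(Fi, "rdf:type", c("repr:File", "p-plan:Variable")),
                     spv(Fi, "rdfs:label", f),
                     spo(T, "prov:used", Fi)))
  }

  acts <- tl$activations %||% list()
  if (length(acts) == 0) {
    warn(sprintf("trial '%s' has no function activations; emitting times only", tl$id))
  }
  act_rows <- list()
  prev <- NA_character_
  for (k in seq_along(acts)) {
    a <- acts[[k]]
    FA <- iri(a$id %||% paste0(tl$id, "/activation-", k))
    fn <- if (!is.null(a$`function`)) iri(a$`function`) else NA_character_
    if (!is.na(fn) && !fn %in% fun_iris) {
      abort(sprintf("activation %d references undeclared function '%s'", k, a$`function`))
    }
    tr <- c(tr, list(spo(FA, "rdf:type", c("repr:FunctionActivation", "p-plan:Step")),
                     spo(FA, "dcterms:isPartOf", T)))
    if (!is.na(fn)) tr <- c(tr, list(spo(FA, "p-plan:isStepOfPlan", fn)))
    if (!is.na(prev)) tr <- c(tr, list(spo(FA, "p-plan:isPrecededBy", prev)))
    if (!is.null(a$start)) tr <- c(tr, list(spv(FA, "prov:startedAtTime", a$start, "xsd:dateTime")))
    if (!is.null(a$end)) tr <- c(tr, list(spv(FA, "prov:endedAtTime", a$end, "xsd:dateTime")))
    for (arg in a$arguments %||% list()) {
      Ar <- paste0(FA, "/arg/", arg$name)
      tr <- c(tr, list(spo(Ar, "rdf:type", c("repr:Argument", "p-plan:Variable")),
                       spv(Ar, "rdfs:label", arg$name),
                       spo(Ar, "p-plan:isInputVarOf", FA)))
      if (!is.null(arg$value)) tr <- c(tr, list(spv(Ar, "rdf:value", as.character(arg$value))))
    }
    if (!is.null(a$returned)) {
      Rt <- paste0(FA, "/return")
      tr <- c(tr, list(spo(Rt, "rdf:type", c("repr:Output", "p-plan:Variable")),
                       spo(Rt, "p-plan:isOutputVarOf", FA),
                       spv(Rt, "rdf:value", as.character(a$returned))))
    }
    act_rows[[k]] <- tibble(id = FA, fun = fn, position = k)
    prev <- FA
  }

  if (!is.null(tl$result)) {
    Rs <- iri(tl$result$id %||% paste0(tl$id, "/result"))
    tr <- c(tr, list(spo(Rs, "rdf:type", c("repr:Output", "p-plan:Variable")),
                     spo(T, "prov:generated", Rs)))
    if (!is.null(tl$result$value)) tr <- c(tr, list(spv(Rs, "rdf:value", as.character(tl$result$value))))
    if (!is.null(tl$result$label)) tr <- c(tr, list(spv(Rs, "rdfs:label", tl$result$label)))
  }

  graph <- prov_graph(bind_rows(tr), prefixes = c(prov_prefixes(), ex = base_iri))
  trial <- list(
    id = T, script = S,
    activations = if (length(act_rows)) bind_rows(act_rows) else
      tibble(id = character(), fun = character(), position = integer())
  )
  list(trial = trial, graph = graph)
}

version_setting <- function(node_iri, version) {
  V <- paste0(node_iri, "/version")
  bind_rows(
    spo(V, "rdf:type", "repr:Version"),
    spv(V, "rdf:value", as.character(version)),
    spo(node_iri, "repr:hasSetting", V)
  )
}

#' Complete derivation of a script output
#'
#' Starting from a result entity, reports in order: the trial that generated
#' it, the chain of function activations in execution order, the environment
#' (language, OS and modules with their versions), the accessed files, the
#' experimenter, and the location. When two trials of the same script exist,
#' only the generating trial is reported.
#'
#' @param g A [prov_graph()] (e.g. from [build_trial()]).
#' @param entity Result entity IRI or CURIE.
#' @return A tibble with `section`, `node`, `label`, `value`, `position`.
#' @export
script_derivation <- function(g, entity) {
  stopifnot(inherits(g, "prov_graph"))
  entity <- expand_curie(entity, g$prefixes)
  tr <- g$triples
  if (!entity %in% c(tr$subject, tr$object[!tr$literal])) {
    abort(sprintf("entity <%s> is not present in the graph", entity))
  }
  pf <- g$prefixes
  gen_by <- tr$subject[tr$predicate == expand_curie("prov:generated", pf) &
                         !tr$literal & tr$object == entity]
  trials <- intersect(gen_by, subjects_of_type(g, "repr:Trial"))
  if (length(trials) == 0) {
    warn(sprintf("no trial generated entity <%s>", entity))
    return(tibble(section = character(), node = character(), label = character(),
                  value = character(), position = integer()))
  }
  T <- trials[[1]]
  lab <- function(n) obj_of1(g, n, "rdfs:label", TRUE)
  val <- function(n) obj_of1(g, n, "rdf:value", TRUE)
  version_of <- function(n) {
    vs <- intersect(obj_of(g, n, "repr:hasSetting", FALSE),
                    subjects_of_type(g, "repr:Version"))
    if (length(vs) == 0) NA_character_ else val(vs[[1]])
  }
  rows <- list(tibble(section = "trial", node = T,
                      label = obj_of1(g, T, "prov:startedAtTime", TRUE),
                      value = obj_of1(g, T, "repr:executionTime", TRUE)))

  # activation chain of this trial, ordered by isPrecededBy
  fas <- tr$subject[tr$predicate == expand_curie("dcterms:isPartOf", pf) &
                      !tr$literal & tr$object == T]
  fas <- intersect(fas, subjects_of_type(g, "repr:FunctionActivation"))
  pred <- vapply(fas, function(f) obj_of1(g, f, "p-plan:isPrecededBy", FALSE), character(1))
  ordered <- topo_order(fas, ifelse(pred %in% fas, pred, NA_character_))
  for (f in ordered) {
    fn <- obj_of1(g, f, "p-plan:isStepOfPlan", FALSE)
    rows[[length(rows) + 1]] <- tibble(section = "activation", node = f,
                                       label = if (!is.na(fn)) lab(fn) else NA_character_,
                                       value = NA_character_)
  }

  used <- obj_of(g, T, "prov:used", FALSE)
  script <- intersect(used, subjects_of_type(g, "repr:Script"))
  if (length(script) == 1) {
    langs <- intersect(obj_of(g, script, "repr:hasSetting", FALSE),
                       subjects_of_type(g, "repr:ProgrammingLanguage"))
    for (l in langs) {
      rows[[length(rows) + 1]] <- tibble(section = "language", node = l,
                                         label = lab(l), value = version_of(l))
    }
  }
  oss <- intersect(obj_of(g, T, "repr:hasSetting", FALSE),
                   subjects_of_type(g, "repr:OperatingSystem"))
  for (o in oss) {
    rows[[length(rows) + 1]] <- tibble(section = "os", node = o,
                                       label = lab(o), value = version_of(o))
  }
  mods <- intersect(used, subjects_of_type(g, "repr:Module"))
  for (m in sort(mods)) {
    rows[[length(rows) + 1]] <- tibble(section = "module", node = m,
                                       label = lab(m), value = version_of(m))
  }
  files <- intersect(used, subjects_of_type(g, "repr:File"))
  for (f in sort(files)) {
    rows[[length(rows) + 1]] <- tibble(section = "file", node = f,
                                       label = lab(f), value = NA_character_)
  }
  exps <- obj_of(g, T, "prov:wasAssociatedWith", FALSE)
  for (x in exps) {
    rows[[length(rows) + 1]] <- tibble(section = "experimenter", node = x,
                                       label = lab(x), value = NA_character_)
  }
  locs <- obj_of(g, T, "prov:atLocation", FALSE)
  for (l in locs) {
    rows[[length(rows) + 1]] <- tibble(section = "location", node = l,
                                       label = lab(l), value = NA_character_)
  }
  out <- bind_rows(rows)
  out$position <- seq_len(nrow(out))
  out
}

subjects_of_type <- function(g, class_curie) {
  tr <- g$triples
  unique(tr$subject[tr$predicate == expand_curie("rdf:type", g$prefixes) &
                      !tr$literal &
                      tr$object == expand_curie(class_curie, g$prefixes)])
}
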