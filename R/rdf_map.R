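# Mapping between experiment records and RDF graphs, using the modeling
# patterns of the underlying ontology: steps linked to plans with
# p-plan:isStepOfPlan, sub-plans with p-plan:isSubPlanOfPlan, input/output
# variables with p-plan:isInputVarOf / isOutputVarOf, methods with
# repr:usedMethod, instrument parts with repr:hasPart / repr:isPartOf (both
# directions materialized), settings with repr:hasSetting, agents with
# prov:wasAttributedTo and repr:orcid, publications with doi / pubmedid /
# pmcid, and timestamps with prov:generatedAtTime / repr:modifiedAtTime.
# Blank nodes are never minted: every record gets an IRI under the record's
# base so round trips and query joins are stable.

iri_of <- function(e, id) paste0(attr(e, "base_iri"), id)

lit_if <- function(s, p, v, datatype = NA_character_) {
  keep <- !is.na(v)
  spv(s[keep], p, v[keep], datatype)
}

obj_if <- function(s, p, o) {
  keep <- !is.na(o)
  spo(s[keep], p, o[keep])
}

#' Convert an experiment record to a provenance graph
#'
#' @param e An `experiment_record` (see [as_experiment()]).
#' @param registry Term registry; conversion refuses to emit a repr term that
#'   is not registered.
#' @return A [prov_graph()] with the record's base IRI bound to the `ex`
#'   prefix.
#' @export
experiment_to_graph <- function(e, registry = build_registry()) {
  stopifnot(inherits(e, "experiment_record"))
  base <- attr(e, "base_iri")
  E <- iri_of(e, e$meta$id)
  id2iri <- function(x) ifelse(is.na(x), NA_character_, paste0(base, x))

  tr <- list(
    spo(E, "rdf:type", c("repr:Experiment", "p-plan:Plan")),
    spv(E, "rdfs:label", e$meta$label),
    lit_if(E, "repr:hypothesis", e$meta$hypothesis),
    lit_if(E, "prov:generatedAtTime", e$meta$created_at, "xsd:dateTime"),
    lit_if(E, "repr:modifiedAtTime", e$meta$modified_at, "xsd:dateTime")
  )
  if (length(e$goals) > 0) tr <- c(tr, list(spv(E, "repr:goal", e$goals)))

  if (nrow(e$plans) > 0) {
    P <- id2iri(e$plans$id)
    parent <- ifelse(is.na(e$plans$parent_plan), E, id2iri(e$plans$parent_plan))
    tr <- c(tr, list(
      spo(P, "rdf:type", check_repr_terms(paste0("repr:", e$plans$subtype), registry)),
      spo(P, "rdf:type", "p-plan:Plan"),
      spv(P, "rdfs:label", e$plans$label),
      spo(P, "p-plan:isSubPlanOfPlan", parent)
    ))
  }

  if (nrow(e$steps) > 0) {
    S <- id2iri(e$steps$id)
    tr <- c(tr, list(
      spo(S, "rdf:type", check_repr_terms(paste0("repr:", e$steps$subtype), registry)),
      spo(S, "rdf:type", "p-plan:Step"),
      spv(S, "rdfs:label", e$steps$label),
      spo(S, "p-plan:isStepOfPlan", id2iri(e$steps$plan)),
      obj_if(S, "p-plan:isPrecededBy", id2iri(e$steps$preceded_by)),
      obj_if(S, "repr:usedMethod", id2iri(e$steps$method_used))
    ))
    for (i in seq_len(nrow(e$steps))) {
      ins <- e$steps$inputs[[i]]
      outs <- e$steps$outputs[[i]]
      if (length(ins) > 0) tr <- c(tr, list(spo(id2iri(ins), "p-plan:isInputVarOf", S[i])))
      if (length(outs) > 0) tr <- c(tr, list(spo(id2iri(outs), "p-plan:isOutputVarOf", S[i])))
    }
  }

  if (nrow(e$agents) > 0) {
    A <- id2iri(e$agents$id)
    tr <- c(tr, list(
      spo(A, "rdf:type", check_repr_terms(paste0("repr:", e$agents$role), registry)),
      spo(A, "rdf:type", "prov:Agent"),
      spv(A, "rdfs:label", e$agents$name),
      lit_if(A, "repr:orcid", e$agents$orcid),
      spo(E, "prov:wasAttributedTo", A)
    ))
  }

  if (nrow(e$activities) > 0) {
    Act <- id2iri(e$activities$id)
    tr <- c(tr, list(
      spo(Act, "rdf:type", "prov:Activity"),
      spo(Act, "dcterms:isPartOf", E),
      lit_if(Act, "prov:startedAtTime", e$activities$start, "xsd:dateTime"),
      lit_if(Act, "prov:endedAtTime", e$activities$end, "xsd:dateTime"),
      lit_if(Act, "repr:sequenceNumber", e$activities$execution_order, "xsd:integer")
    ))
    for (i in seq_len(nrow(e$activities))) {
      used <- e$activities$used[[i]]
      gen <- e$activities$generated[[i]]
      pre <- e$activities$preconditions[[i]]
      if (length(used) > 0) tr <- c(tr, list(spo(Act[i], "prov:used", id2iri(used))))
      if (length(gen) > 0) tr <- c(tr, list(spo(Act[i], "prov:generated", id2iri(gen))))
      if (length(pre) > 0) tr <- c(tr, list(spv(Act[i], "repr:precondition", pre)))
    }
  }

  if (nrow(e$instruments) > 0) {
    I <- id2iri(e$instruments$id)
    tr <- c(tr, list(
      spo(I, "rdf:type", check_repr_terms(paste0("repr:", e$instruments$subtype), registry)),
      spv(I, "rdfs:label", e$instruments$label),
      spo(E, "prov:used", I),
      obj_if(I, "repr:isPartOf", id2iri(e$instruments$part_of))
    ))
    has_parent <- !is.na(e$instruments$part_of)
    if (any(has_parent)) {
      tr <- c(tr, list(spo(id2iri(e$instruments$part_of[has_parent]),
                           "repr:hasPart", I[has_parent])))
    }
    for (i in seq_len(nrow(e$instruments))) {
      sids <- e$instruments$settings[[i]]
      if (length(sids) > 0) tr <- c(tr, list(spo(I[i], "repr:hasSetting", id2iri(sids))))
    }
  }

  if (nrow(e$materials) > 0) {
    M <- id2iri(e$materials$id)
    tr <- c(tr, list(
      spo(M, "rdf:type", check_repr_terms(paste0("repr:", e$materials$subtype), registry)),
      spv(M, "rdfs:label", e$materials$label),
      spo(E, "prov:used", M)
    ))
  }

  if (nrow(e$settings) > 0) {
    St <- id2iri(e$settings$id)
    tr <- c(tr, list(
      spo(St, "rdf:type", check_repr_terms(paste0("repr:", e$settings$subtype), registry)),
      spv(St, "rdfs:label", e$settings$key),
      lit_if(St, "rdf:value", e$settings$value),
      spo(E, "repr:hasSetting", St)
    ))
  }

  if (nrow(e$data) > 0) {
    D <- id2iri(e$data$id)
    tr <- c(tr, list(
      spo(D, "rdf:type", check_repr_terms(paste0("repr:", e$data$category), registry)),
      spo(D, "rdf:type", "p-plan:Variable"),
      spv(D, "rdfs:label", e$data$label),
      lit_if(D, "rdf:value", e$data$value),
      lit_if(D, "repr:doi", e$data$doi),
      lit_if(D, "repr:pubmedid", e$data$pubmedid),
      lit_if(D, "repr:pmcid", e$data$pmcid),
      spo(D, "p-plan:correspondsToVariable", E)
    ))
  }

  prov_graph(bind_rows(tr), prefixes = c(prov_prefixes(), ex = base))
}

check_repr_terms <- function(curies, registry) {
  unknown <- setdiff(unique(curies), registry$curie)
  if (length(unknown) > 0) {
    abort(paste("unregistered term:", paste(unknown, collapse = ", ")))
  }
  curies
}

# --- graph -> model ---------------------------------------------------------

#' Recover experiment records from a provenance graph
#'
#' The inverse of [experiment_to_graph()]: every node typed
#' `repr:Experiment` becomes a record. Both variable-to-step directions
#' (`p-plan:isInputVarOf` and `p-plan:hasInputVar`) are accepted. repr-
#' namespace terms not present in the registry raise an error naming them.
#'
#' @param g A [prov_graph()].
#' @param base_iri Base IRI stripped from node IRIs to recover ids; defaults
#'   to the graph's `ex` prefix binding when present.
#' @param registry Term registry.
#' @return A list of `experiment_record` objects (possibly empty).
#' @export
experiments_from_graph <- function(g, base_iri = NULL,
                                   registry = build_registry()) {
  stopifnot(inherits(g, "prov_graph"))
  check_graph_terms(g, registry)
  base_iri <- base_iri %||% g$prefixes[["ex"]] %||% ""
  exps <- instances_of(g, "repr:Experiment", registry)
  lapply(sort(exps), function(E) one_experiment_from_graph(g, E, base_iri, registry))
}

#' Recover exactly one experiment record from a graph
#'
#' @inheritParams experiments_from_graph
#' @return A single `experiment_record`; errors unless the graph holds
#'   exactly one experiment.
#' @export
experiment_from_graph <- function(g, base_iri = NULL,
                                  registry = build_registry()) {
  out <- experiments_from_graph(g, base_iri, registry)
  if (length(out) != 1) {
    abort(sprintf("expected exactly 1 experiment in graph, found %d", length(out)))
  }
  out[[1]]
}

check_graph_terms <- function(g, registry) {
  used <- unique(c(g$triples$predicate,
                   g$triples$object[!g$triples$literal &
                                      g$triples$predicate == expand_curie("rdf:type", g$prefixes)]))
  repr_used <- used[startsWith(used, REPR)]
  unknown <- setdiff(repr_used, registry$iri)
  if (length(unknown) > 0) {
    abort(paste("graph uses unregistered repr terms:",
                paste(compact_iri(unknown, g$prefixes), collapse = ", ")))
  }
  invisible(TRUE)
}

one_experiment_from_graph <- function(g, E, base_iri, registry) {
  pf <- g$prefixes
  strip <- function(x) {
    if (length(x) == 0) return(character(0))
    ifelse(is.na(x), NA_character_,
           ifelse(startsWith(x, base_iri), substring(x, nchar(base_iri) + 1L), x))
  }
  type_of <- function(nodes, among) {
    classes <- expand_curie(paste0("repr:", among), pf)
    vapply(nodes, function(n) {
      t <- obj_of(g, n, "rdf:type", literal = FALSE)
      hit <- t[t %in% classes]
      if (length(hit) == 0) NA_character_ else sub(REPR, "", hit[[1]], fixed = TRUE)
    }, character(1))
  }
  subjects_with <- function(p, o) {
    tr <- g$triples
    sort(unique(tr$subject[tr$predicate == expand_curie(p, pf) & !tr$literal &
                             tr$object == o]))
  }

  meta <- tibble(
    id = strip(E),
    label = obj_of1(g, E, "rdfs:label", TRUE) %|NA|% strip(E),
    hypothesis = obj_of1(g, E, "repr:hypothesis", TRUE),
    created_at = obj_of1(g, E, "prov:generatedAtTime", TRUE),
    modified_at = obj_of1(g, E, "repr:modifiedAtTime", TRUE)
  )
  goals <- sort(obj_of(g, E, "repr:goal", TRUE))

  # plans: transitive isSubPlanOfPlan into E
  plan_nodes <- character(0)
  frontier <- E
  while (length(frontier) > 0) {
    kids <- unlist(lapply(frontier, function(p) subjects_with("p-plan:isSubPlanOfPlan", p)))
    kids <- setdiff(unique(kids), c(plan_nodes, E))
    plan_nodes <- c(plan_nodes, kids)
    frontier <- kids
  }
  plan_nodes <- sort(plan_nodes)
  plan_sub <- component_subtypes(registry, "Plan")$local_name
  plans <- tibble(
    id = strip(plan_nodes),
    label = vapply(plan_nodes, function(p) obj_of1(g, p, "rdfs:label", TRUE), character(1)),
    subtype = type_of(plan_nodes, setdiff(plan_sub, "Experiment")),
    parent_plan = vapply(plan_nodes, function(p) {
      par <- obj_of1(g, p, "p-plan:isSubPlanOfPlan", FALSE)
      if (identical(par, E)) NA_character_ else strip(par)
    }, character(1))
  )

  step_nodes <- sort(unique(unlist(lapply(c(E, plan_nodes), function(p) {
    subjects_with("p-plan:isStepOfPlan", p)
  }))))
  step_sub <- component_subtypes(registry, "Step")$local_name
  steps <- tibble(
    id = strip(step_nodes),
    label = vapply(step_nodes, function(s) obj_of1(g, s, "rdfs:label", TRUE), character(1)),
    subtype = type_of(step_nodes, step_sub),
    plan = vapply(step_nodes, function(s) strip(obj_of1(g, s, "p-plan:isStepOfPlan", FALSE)), character(1)),
    preceded_by = vapply(step_nodes, function(s) strip(obj_of1(g, s, "p-plan:isPrecededBy", FALSE)), character(1)),
    method_used = vapply(step_nodes, function(s) strip(obj_of1(g, s, "repr:usedMethod", FALSE)), character(1)),
    inputs = lapply(step_nodes, function(s) {
      sort(strip(c(subjects_with("p-plan:isInputVarOf", s),
                   obj_of(g, s, "p-plan:hasInputVar", FALSE))))
    }),
    outputs = lapply(step_nodes, function(s) sort(strip(subjects_with("p-plan:isOutputVarOf", s))))
  )

  agent_nodes <- sort(obj_of(g, E, "prov:wasAttributedTo", FALSE))
  agents <- tibble(
    id = strip(agent_nodes),
    name = vapply(agent_nodes, function(a) obj_of1(g, a, "rdfs:label", TRUE), character(1)),
    role = type_of(agent_nodes, component_subtypes(registry, "Agent")$local_name),
    orcid = vapply(agent_nodes, function(a) obj_of1(g, a, "repr:orcid", TRUE), character(1))
  )

  act_nodes <- sort(intersect(subjects_with("dcterms:isPartOf", E),
                              instances_of(g, "prov:Activity", registry_with_prov(registry))))
  activities <- tibble(
    id = strip(act_nodes),
    start = vapply(act_nodes, function(a) obj_of1(g, a, "prov:startedAtTime", TRUE), character(1)),
    end = vapply(act_nodes, function(a) obj_of1(g, a, "prov:endedAtTime", TRUE), character(1)),
    used = lapply(act_nodes, function(a) sort(strip(obj_of(g, a, "prov:used", FALSE)))),
    generated = lapply(act_nodes, function(a) sort(strip(obj_of(g, a, "prov:generated", FALSE)))),
    execution_order = vapply(act_nodes, function(a) {
      v <- obj_of1(g, a, "repr:sequenceNumber", TRUE)
      if (is.na(v)) NA_integer_ else as.integer(v)
    }, integer(1)),
    preconditions = lapply(act_nodes, function(a) sort(obj_of(g, a, "repr:precondition", TRUE)))
  )

  used_nodes <- obj_of(g, E, "prov:used", FALSE)
  instr_nodes <- sort(intersect(used_nodes, instances_of(g, "repr:Instrument", registry)))
  instruments <- tibble(
    id = strip(instr_nodes),
    label = vapply(instr_nodes, function(i) obj_of1(g, i, "rdfs:label", TRUE), character(1)),
    subtype = type_of(instr_nodes, component_subtypes(registry, "Instrument")$local_name),
    part_of = vapply(instr_nodes, function(i) strip(obj_of1(g, i, "repr:isPartOf", FALSE)), character(1)),
    settings = lapply(instr_nodes, function(i) sort(strip(obj_of(g, i, "repr:hasSetting", FALSE))))
  )

  mat_nodes <- sort(intersect(used_nodes, instances_of(g, "repr:ExperimentalMaterial", registry)))
  materials <- tibble(
    id = strip(mat_nodes),
    label = vapply(mat_nodes, function(m) obj_of1(g, m, "rdfs:label", TRUE), character(1)),
    subtype = type_of(mat_nodes, component_subtypes(registry, "Material")$local_name)
  )

  set_nodes <- sort(obj_of(g, E, "repr:hasSetting", FALSE))
  settings <- tibble(
    id = strip(set_nodes),
    subtype = type_of(set_nodes, c(component_subtypes(registry, "Setting")$local_name, "Version")),
    key = vapply(set_nodes, function(s) obj_of1(g, s, "rdfs:label", TRUE), character(1)),
    value = vapply(set_nodes, function(s) obj_of1(g, s, "rdf:value", TRUE), character(1))
  )

  data_nodes <- sort(subjects_with("p-plan:correspondsToVariable", E))
  data_cls <- c(component_subtypes(registry, "Data")$local_name, "ExperimentData", "File")
  data <- tibble(
    id = strip(data_nodes),
    label = vapply(data_nodes, function(d) obj_of1(g, d, "rdfs:label", TRUE), character(1)),
    category = type_of(data_nodes, data_cls),
    value = vapply(data_nodes, function(d) obj_of1(g, d, "rdf:value", TRUE), character(1)),
    doi = vapply(data_nodes, function(d) obj_of1(g, d, "repr:doi", TRUE), character(1)),
    pubmedid = vapply(data_nodes, function(d) obj_of1(g, d, "repr:pubmedid", TRUE), character(1)),
    pmcid = vapply(data_nodes, function(d) obj_of1(g, d, "repr:pmcid", TRUE), character(1))
  )

  structure(
    list(meta = meta, goals = goals, plans = plans, steps = steps,
         agents = agents, activities = activities, instruments = instruments,
         materials = materials, settings = settings, data = data),
    class = "experiment_record", base_iri = base_iri
  )
}

registry_with_prov <- function(registry) registry  # prov:Activity is registered

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Compare two experiment records up to ordering
#'
#' Graph round trips preserve content but not row or list order; this
#' comparator sorts every component table by id (and every id list) before
#' comparing.
#'
#' @param a,b `experiment_record` objects.
#' @return TRUE when the records describe the same experiment.
#' @export
experiment_equal <- function(a, b) {
  norm <- function(e) {
    sort_lists <- function(tb) {
      for (col in names(tb)) if (is.list(tb[[col]])) {
        tb[[col]] <- lapply(tb[[col]], function(v) if (is.character(v)) sort(v) else v)
      }
      tb[order(tb$id), , drop = FALSE]
    }
    list(
      meta = as.data.frame(e$meta), goals = sort(e$goals),
      plans = sort_lists(as.data.frame(e$plans)),
      steps = sort_lists(as.data.frame(e$steps)),
      agents = sort_lists(as.data.frame(e$agents)),
      activities = sort_lists(as.data.frame(e$activities)),
      instruments = sort_lists(as.data.frame(e$instruments)),
      materials = sort_lists(as.data.frame(e$materials)),
      settings = sort_lists(as.data.frame(e$settings)),
      data = sort_lists(as.data.frame(e$data))
    )
  }
  na <- norm(a); nb <- norm(b)
  isTRUE(all.equal(na, nb, check.attributes = FALSE))
}
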