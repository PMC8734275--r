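# Competency questions as parameterized graph-pattern queries. Each query is
# a basic graph pattern (the fragment the corresponding SPARQL queries use)
# matched with match_bgp() and post-processed with dplyr. The complete-path
# question is answered by sub-queries merged in code rather than one
# monolithic pattern — the same splitting a large knowledge base forces on
# the SPARQL side — and the two strategies are equivalent on the patterns
# used here (a test asserts it).

label_of <- function(g, nodes) {
  unname(vapply(nodes, function(n) obj_of1(g, n, "rdfs:label", TRUE), character(1)))
}

# ascend isSubPlanOfPlan links from a plan node to the experiments above it
ascend_to_experiments <- function(g, plans, registry) {
  exps <- expand_curie(instances_of(g, "repr:Experiment", registry), g$prefixes)
  out <- stats::setNames(vector("list", length(plans)), plans)
  for (p in plans) {
    seen <- character(0)
    frontier <- p
    hits <- character(0)
    while (length(frontier) > 0) {
      hits <- c(hits, intersect(frontier, exps))
      nxt <- unique(unlist(lapply(frontier, function(x) {
        obj_of(g, x, "p-plan:isSubPlanOfPlan", FALSE)
      })))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    out[[p]] <- unique(hits)
  }
  out
}

#' Steps of experiments that used a material
#'
#' Answers: which steps of which experiments used the material with the given
#' label (e.g. a plasmid)? A step "uses" a material when the material is one
#' of its input variables.
#'
#' @param g A [prov_graph()].
#' @param material_label Exact material label to match (e.g.
#'   `"pCherry-RAD54"`).
#' @param ignore_case Match the label case-insensitively.
#' @param registry Term registry (for material subclass reasoning).
#' @return A tibble with columns `experiment`, `experiment_label`, `step`,
#'   `step_label`, sorted by all columns; zero rows when the material is
#'   unused or unknown.
#' @export
#' @examples
#' g <- fixture_colocalization()
#' steps_using_material(g, "pCherry-RAD54")
steps_using_material <- function(g, material_label, ignore_case = FALSE,
                                 registry = build_registry()) {
  stopifnot(inherits(g, "prov_graph"))
  mats <- instances_of(g, "repr:ExperimentalMaterial", registry)
  labs <- label_of(g, mats)
  hit <- if (ignore_case) tolower(labs) == tolower(material_label) else labs == material_label
  mats <- mats[!is.na(hit) & hit]
  if (length(mats) == 0) return(empty_usage_table())
  sol <- bind_rows(lapply(mats, function(m) {
    match_bgp(g, tibble(
      s = c(paste0("<", m, ">"), "?step"),
      p = c("p-plan:isInputVarOf", "p-plan:isStepOfPlan"),
      o = c("?step", "?plan")
    ))
  }))
  if (nrow(sol) == 0) return(empty_usage_table())
  exp_map <- ascend_to_experiments(g, unique(sol$plan), registry)
  rows <- tidyr::unnest(
    mutate(sol, experiment = unname(exp_map[.data$plan])), "experiment"
  )
  if (nrow(rows) == 0) return(empty_usage_table())
  out <- distinct(tibble(
    experiment = rows$experiment,
    experiment_label = label_of(g, rows$experiment),
    step = rows$step,
    step_label = label_of(g, rows$step)
  ))
  arrange(out, .data$experiment, .data$step)
}

empty_usage_table <- function() {
  tibble(experiment = character(), experiment_label = character(),
         step = character(), step_label = character())
}

#' Complete path of a computational notebook
#'
#' Answers: what is the complete path taken for a notebook experiment? One
#' row per cell execution (cells never executed still appear, with NA
#' execution fields), carrying the cell, its source text, the execution with
#' its start/end times and duration, and the entity it generated. Rows are
#' ordered by execution sequence number, then cell index.
#'
#' @param g A [prov_graph()].
#' @param notebook Notebook IRI or CURIE.
#' @return A tibble with columns `cell`, `cell_index`, `source`, `execution`,
#'   `started_at`, `ended_at`, `execution_time`, `seq`, `generated`. Empty
#'   (with a warning) when the notebook is absent from the graph.
#' @export
notebook_complete_path <- function(g, notebook) {
  stopifnot(inherits(g, "prov_graph"))
  N <- expand_curie(notebook, g$prefixes)
  cells <- match_bgp(g, tibble(
    s = c("?cell", "?cell"),
    p = c("p-plan:isStepOfPlan", "rdf:type"),
    o = c(paste0("<", N, ">"), "repr:Cell")
  ))
  if (nrow(cells) == 0) {
    warn(sprintf("notebook <%s> not found in graph (or has no cells)", N))
    return(tibble(cell = character(), cell_index = integer(), source = character(),
                  execution = character(), started_at = character(),
                  ended_at = character(), execution_time = numeric(),
                  seq = integer(), generated = character()))
  }
  cell_tbl <- tibble(
    cell = cells$cell,
    cell_index = as.integer(vapply(cells$cell, function(c) obj_of1(g, c, "repr:index", TRUE), character(1))),
    source = unname(vapply(cells$cell, function(c) {
      srcs <- g$triples$subject[
        g$triples$predicate == expand_curie("p-plan:isInputVarOf", g$prefixes) &
          !g$triples$literal & g$triples$object == c]
      if (length(srcs) == 0) NA_character_ else obj_of1(g, srcs[[1]], "rdf:value", TRUE)
    }, character(1)))
  )
  execs <- match_bgp(g, tibble(
    s = c("?exec", "?exec"),
    p = c("rdf:type", "p-plan:correspondsToStep"),
    o = c("repr:CellExecution", "?cell")
  ))
  exec_tbl <- if (nrow(execs) == 0) {
    tibble(cell = character(), execution = character(), started_at = character(),
           ended_at = character(), execution_time = numeric(), seq = integer(),
           generated = character())
  } else {
    tibble(
      cell = execs$cell, execution = execs$exec,
      started_at = unname(vapply(execs$exec, function(x) obj_of1(g, x, "prov:startedAtTime", TRUE), character(1))),
      ended_at = unname(vapply(execs$exec, function(x) obj_of1(g, x, "prov:endedAtTime", TRUE), character(1))),
      execution_time = as.numeric(vapply(execs$exec, function(x) obj_of1(g, x, "repr:executionTime", TRUE), character(1))),
      seq = as.integer(vapply(execs$exec, function(x) obj_of1(g, x, "repr:sequenceNumber", TRUE), character(1))),
      generated = unname(vapply(execs$exec, function(x) obj_of1(g, x, "prov:generated", FALSE), character(1)))
    )
  }
  out <- left_join(cell_tbl, exec_tbl, by = "cell")
  arrange(out, !is.na(.data$seq), .data$seq, .data$cell_index)
}

#' Complete path of an experiment
#'
#' Answers: what is the complete path taken for a scientific experiment —
#' its agents and their roles, the plans and steps involved, the input and
#' output of each step, the order of steps, and the instruments with their
#' settings? Assembled from sub-queries merged on the experiment, one
#' section per element group.
#'
#' @param g A [prov_graph()].
#' @param experiment Experiment IRI or CURIE.
#' @param registry Term registry.
#' @return An object of class `path_table`: a named list of tibbles
#'   `agents`, `plans`, `steps`, `step_io`, `instruments`.
#' @export
experiment_complete_path <- function(g, experiment, registry = build_registry()) {
  stopifnot(inherits(g, "prov_graph"))
  E <- expand_curie(experiment, g$prefixes)
  if (!E %in% instances_of(g, "repr:Experiment", registry)) {
    abort(sprintf("experiment <%s> is not present in the graph", E))
  }
  role_classes <- component_subtypes(registry, "Agent")$local_name

  agent_nodes <- sort(obj_of(g, E, "prov:wasAttributedTo", FALSE))
  agents <- tibble(
    agent = agent_nodes,
    name = label_of(g, agent_nodes),
    role = unname(vapply(agent_nodes, function(a) {
      t <- obj_of(g, a, "rdf:type", FALSE)
      hit <- t[t %in% expand_curie(paste0("repr:", role_classes), g$prefixes)]
      if (length(hit) == 0) NA_character_ else sub(REPR, "", hit[[1]], fixed = TRUE)
    }, character(1))),
    orcid = unname(vapply(agent_nodes, function(a) obj_of1(g, a, "repr:orcid", TRUE), character(1)))
  )

  plan_nodes <- character(0)
  frontier <- E
  repeat {
    kids <- unique(g$triples$subject[
      g$triples$predicate == expand_curie("p-plan:isSubPlanOfPlan", g$prefixes) &
        !g$triples$literal & g$triples$object %in% frontier])
    kids <- setdiff(kids, c(plan_nodes, E))
    if (length(kids) == 0) break
    plan_nodes <- c(plan_nodes, kids)
    frontier <- kids
  }
  plan_nodes <- sort(plan_nodes)
  plans <- tibble(plan = plan_nodes, label = label_of(g, plan_nodes))

  step_sol <- match_bgp(g, tibble(
    s = c("?step", "?step"),
    p = c("p-plan:isStepOfPlan", "rdf:type"),
    o = c("?plan", "p-plan:Step")
  ))
  step_sol <- step_sol[step_sol$plan %in% c(E, plan_nodes), , drop = FALSE]
  step_nodes <- sort(unique(step_sol$step))
  steps <- tibble(
    step = step_nodes,
    label = label_of(g, step_nodes),
    plan = unname(vapply(step_nodes, function(s) obj_of1(g, s, "p-plan:isStepOfPlan", FALSE), character(1))),
    subtype = unname(vapply(step_nodes, function(s) {
      t <- obj_of(g, s, "rdf:type", FALSE)
      hit <- t[t %in% expand_curie(paste0("repr:", component_subtypes(registry, "Step")$local_name), g$prefixes)]
      if (length(hit) == 0) NA_character_ else sub(REPR, "", hit[[1]], fixed = TRUE)
    }, character(1))),
    preceded_by = unname(vapply(step_nodes, function(s) obj_of1(g, s, "p-plan:isPrecededBy", FALSE), character(1)))
  )

  io <- list()
  for (s in step_nodes) {
    ins <- sort(unique(c(
      g$triples$subject[g$triples$predicate == expand_curie("p-plan:isInputVarOf", g$prefixes) &
                          !g$triples$literal & g$triples$object == s],
      obj_of(g, s, "p-plan:hasInputVar", FALSE)
    )))
    outs <- sort(g$triples$subject[
      g$triples$predicate == expand_curie("p-plan:isOutputVarOf", g$prefixes) &
        !g$triples$literal & g$triples$object == s])
    if (length(ins) > 0) io[[length(io) + 1]] <-
      tibble(step = s, direction = "input", variable = ins, label = label_of(g, ins))
    if (length(outs) > 0) io[[length(io) + 1]] <-
      tibble(step = s, direction = "output", variable = outs, label = label_of(g, outs))
  }
  step_io <- if (length(io)) bind_rows(io) else
    tibble(step = character(), direction = character(), variable = character(),
           label = character())

  instr_nodes <- sort(intersect(obj_of(g, E, "prov:used", FALSE),
                                instances_of(g, "repr:Instrument", registry)))
  instruments <- bind_rows(lapply(instr_nodes, function(i) {
    sets <- sort(obj_of(g, i, "repr:hasSetting", FALSE))
    if (length(sets) == 0) {
      tibble(instrument = i, instrument_label = label_of(g, i),
             setting = NA_character_, setting_key = NA_character_,
             setting_value = NA_character_)
    } else {
      tibble(instrument = i, instrument_label = label_of(g, i), setting = sets,
             setting_key = label_of(g, sets),
             setting_value = unname(vapply(sets, function(s) obj_of1(g, s, "rdf:value", TRUE), character(1))))
    }
  }))
  if (length(instr_nodes) == 0) {
    instruments <- tibble(instrument = character(), instrument_label = character(),
                          setting = character(), setting_key = character(),
                          setting_value = character())
  }

  structure(list(experiment = E, experiment_label = label_of(g, E),
                 agents = agents, plans = plans, steps = steps,
                 step_io = step_io, instruments = instruments),
            class = "path_table")
}

#' @export
print.path_table <- function(x, ...) {
  cat("Complete path:", x$experiment_label, "\n")
  for (sec in c("agents", "plans", "steps", "step_io", "instruments")) {
    cat("--", sec, "(", nrow(x[[sec]]), "rows )\n")
  }
  invisible(x)
}

#' Tidy an experiment path table into one long tibble
#' @param x An [experiment_complete_path()] result.
#' @param ... Unused.
#' @return A tibble with `section`, `node` and `label` columns.
#' @method tidy path_table
#' @export
tidy.path_table <- function(x, ...) {
  bind_rows(
    tibble(section = "agent", node = x$agents$agent, label = x$agents$name),
    tibble(section = "plan", node = x$plans$plan, label = x$plans$label),
    tibble(section = "step", node = x$steps$step, label = x$steps$label),
    tibble(section = "variable", node = x$step_io$variable, label = x$step_io$label),
    tibble(section = "instrument",
           node = unique(x$instruments$instrument),
           label = x$instruments$instrument_label[!duplicated(x$instruments$instrument)])
  )
}
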