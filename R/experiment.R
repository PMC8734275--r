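# The typed experiment record: the eight-component n-tuple
# (Data, Agent, Activity, Plan, Step, Setting, Instrument, Material) held as
# a set of tidy tibbles, built from a YAML/JSON manifest or programmatically.

#' Read an experiment manifest
#'
#' Manifests are YAML or JSON documents with a top-level `experiment` block
#' (id, label, hypothesis, goals, timestamps) and optional `plans`, `steps`,
#' `agents`, `activities`, `instruments`, `materials`, `settings`, `data`
#' lists. See `vignette("provenance-model")` for the schema.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` manifest.
#' @return An `experiment_record`; see [as_experiment()].
#' @export
read_experiment <- function(path) {
  manifest <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_experiment(manifest)
}

fld <- function(x, name, default = NA) {
  v <- x[[name]]
  if (is.null(v) || length(v) == 0) default else v
}

chr1 <- function(x, name, default = NA_character_) {
  v <- fld(x, name, default)
  if (length(v) != 1) abort(sprintf("field '%s' must be a single value", name))
  as.character(v)
}

chrvec <- function(x, name) as.character(unlist(x[[name]], use.names = FALSE))

records_tbl <- function(items, parse_row, empty) {
  if (is.null(items) || length(items) == 0) return(empty)
  bind_rows(lapply(items, parse_row))
}

#' Build an experiment record from a manifest list
#'
#' Validates the manifest against the model: every step must reference a
#' declared plan (or the experiment itself), `preceded_by` chains and
#' instrument part relations must be acyclic, step inputs/outputs must
#' resolve to declared data items or materials, subtypes must come from the
#' enumerated classifications, and ORCID identifiers must be syntactically
#' valid.
#'
#' @param manifest A nested list (e.g. parsed YAML/JSON).
#' @param registry Term registry used for subtype validation.
#' @return An object of class `experiment_record`: a list of tibbles
#'   (`meta`, `plans`, `steps`, `agents`, `activities`, `instruments`,
#'   `materials`, `settings`, `data`) plus a `goals` character vector.
#' @export
as_experiment <- function(manifest, registry = build_registry()) {
  ex <- manifest$experiment
  if (is.null(ex) || is.null(ex$id) || !nzchar(ex$id)) {
    abort("no experiment id: manifest must carry experiment$id")
  }
  meta <- tibble(
    id = chr1(ex, "id"), label = chr1(ex, "label", chr1(ex, "id")),
    hypothesis = chr1(ex, "hypothesis"),
    created_at = chr1(ex, "created_at"), modified_at = chr1(ex, "modified_at")
  )
  goals <- chrvec(ex, "goals")

  plan_sub <- component_subtypes(registry, "Plan")$local_name
  plans <- records_tbl(manifest$plans, function(p) tibble(
    id = chr1(p, "id"), label = chr1(p, "label", chr1(p, "id")),
    subtype = chr1(p, "subtype", "Protocol"),
    parent_plan = chr1(p, "parent_plan")
  ), tibble(id = character(), label = character(), subtype = character(),
            parent_plan = character()))

  steps <- records_tbl(manifest$steps, function(s) tibble(
    id = chr1(s, "id"), label = chr1(s, "label", chr1(s, "id")),
    subtype = canonical_step_subtype(chr1(s, "subtype", "NonComputational")),
    plan = chr1(s, "plan", meta$id), preceded_by = chr1(s, "preceded_by"),
    method_used = chr1(s, "method_used"),
    inputs = list(chrvec(s, "inputs")), outputs = list(chrvec(s, "outputs"))
  ), tibble(id = character(), label = character(), subtype = character(),
            plan = character(), preceded_by = character(),
            method_used = character(), inputs = list(), outputs = list()))

  agents <- records_tbl(manifest$agents, function(a) tibble(
    id = chr1(a, "id"), name = chr1(a, "name", chr1(a, "id")),
    role = chr1(a, "role", "Experimenter"), orcid = chr1(a, "orcid")
  ), tibble(id = character(), name = character(), role = character(),
            orcid = character()))

  activities <- records_tbl(manifest$activities, function(a) tibble(
    id = chr1(a, "id"), start = chr1(a, "start"), end = chr1(a, "end"),
    used = list(chrvec(a, "used")), generated = list(chrvec(a, "generated")),
    execution_order = as.integer(fld(a, "execution_order", NA_integer_)),
    preconditions = list(chrvec(a, "preconditions"))
  ), tibble(id = character(), start = character(), end = character(),
            used = list(), generated = list(), execution_order = integer(),
            preconditions = list()))

  instruments <- records_tbl(manifest$instruments, function(i) tibble(
    id = chr1(i, "id"), label = chr1(i, "label", chr1(i, "id")),
    subtype = chr1(i, "subtype", "Microscope"), part_of = chr1(i, "part_of"),
    settings = list(chrvec(i, "settings"))
  ), tibble(id = character(), label = character(), subtype = character(),
            part_of = character(), settings = list()))

  materials <- records_tbl(manifest$materials, function(m) tibble(
    id = chr1(m, "id"), label = chr1(m, "label", chr1(m, "id")),
    subtype = chr1(m, "subtype", "Chemical")
  ), tibble(id = character(), label = character(), subtype = character()))

  settings <- records_tbl(manifest$settings, function(s) tibble(
    id = chr1(s, "id"), subtype = chr1(s, "subtype", "InstrumentSettings"),
    key = chr1(s, "key", chr1(s, "id")), value = chr1(s, "value")
  ), tibble(id = character(), subtype = character(), key = character(),
            value = character()))

  data <- records_tbl(manifest$data, function(d) tibble(
    id = chr1(d, "id"), label = chr1(d, "label", chr1(d, "id")),
    category = chr1(d, "category", "InputData"), value = chr1(d, "value"),
    doi = chr1(d, "doi"), pubmedid = chr1(d, "pubmedid"),
    pmcid = chr1(d, "pmcid")
  ), tibble(id = character(), label = character(), category = character(),
            value = character(), doi = character(), pubmedid = character(),
            pmcid = character()))

  e <- structure(
    list(meta = meta, goals = goals, plans = plans, steps = steps,
         agents = agents, activities = activities, instruments = instruments,
         materials = materials, settings = settings, data = data),
    class = "experiment_record",
    base_iri = manifest$base_iri %||% "https://example.org/provpath/"
  )
  validate_experiment(e, registry)
  e
}

validate_experiment <- function(e, registry = build_registry()) {
  known_plans <- c(e$meta$id, e$plans$id)
  ids <- c(e$meta$id, e$plans$id, e$steps$id, e$agents$id, e$activities$id,
           e$instruments$id, e$materials$id, e$settings$id, e$data$id)
  if (anyDuplicated(ids)) {
    abort(paste("duplicate ids:", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  check_subtype(e$plans$subtype, component_subtypes(registry, "Plan")$local_name, "plan")
  check_subtype(e$steps$subtype,
                component_subtypes(registry, "Step")$local_name, "step")
  check_subtype(e$instruments$subtype,
                component_subtypes(registry, "Instrument")$local_name, "instrument")
  check_subtype(e$materials$subtype,
                component_subtypes(registry, "Material")$local_name, "material")
  check_subtype(e$settings$subtype,
                component_subtypes(registry, "Setting")$local_name, "setting")
  check_subtype(e$agents$role, component_subtypes(registry, "Agent")$local_name, "agent role")
  data_classes <- c(component_subtypes(registry, "Data")$local_name,
                    "ExperimentData", "File")
  check_subtype(e$data$category, data_classes, "data category")

  dangling <- function(refs, pool, what) {
    bad <- setdiff(stats::na.omit(refs), pool)
    if (length(bad) > 0) {
      abort(sprintf("dangling reference: %s not declared (%s)",
                    paste(bad, collapse = ", "), what))
    }
  }
  dangling(e$steps$plan, known_plans, "step plan")
  dangling(e$plans$parent_plan, known_plans, "parent plan")
  dangling(e$steps$preceded_by, e$steps$id, "step preceded_by")
  dangling(e$steps$method_used, known_plans, "step method")
  dangling(unlist(e$steps$inputs), c(e$data$id, e$materials$id), "step inputs")
  dangling(unlist(e$steps$outputs), c(e$data$id, e$materials$id), "step outputs")
  dangling(e$instruments$part_of, e$instruments$id, "instrument part")
  dangling(unlist(e$instruments$settings), e$settings$id, "instrument settings")
  dangling(unlist(e$activities$used), ids, "activity used")
  dangling(unlist(e$activities$generated), ids, "activity generated")

  topo_order(e$steps$id, e$steps$preceded_by)       # errors on cycles
  topo_order(e$instruments$id, e$instruments$part_of)

  bad_orcid <- e$agents$orcid[!is.na(e$agents$orcid) &
    !grepl("^\\d{4}-\\d{4}-\\d{4}-(\\d{4}|\\d{3}X)$", e$agents$orcid)]
  if (length(bad_orcid) > 0) {
    abort(paste("invalid ORCID syntax:", paste(bad_orcid, collapse = ", ")))
  }
  bad_time <- !is.na(e$activities$start) & !is.na(e$activities$end) &
    e$activities$start > e$activities$end
  if (any(bad_time)) {
    abort(paste("activity ends before it starts:",
                paste(e$activities$id[bad_time], collapse = ", ")))
  }
  invisible(e)
}

canonical_step_subtype <- function(x) {
  ifelse(grepl("Step$", x), x, paste0(x, "Step"))
}

check_subtype <- function(values, allowed, what) {
  bad <- setdiff(stats::na.omit(values), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s subtype: %s (allowed: %s)", what,
                  paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
}

# stable topological order honouring preceded_by edges; errors on cycles
topo_order <- function(ids, preceded_by) {
  if (length(ids) == 0) return(character(0))
  pred <- stats::setNames(preceded_by, ids)
  placed <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- pred[[i]]
      is.na(p) || p %in% placed || !(p %in% ids)
    }, logical(1))]
    if (length(ready) == 0) {
      abort(paste("cyclic preceded_by order among:", paste(remaining, collapse = ", ")))
    }
    placed <- c(placed, ready[[1]])
    remaining <- setdiff(remaining, ready[[1]])
  }
  placed
}

#' @export
print.experiment_record <- function(x, ...) {
  cat("<experiment_record> ", x$meta$id, " (", x$meta$label, ")\n", sep = "")
  counts <- vapply(x[c("plans", "steps", "agents", "activities", "instruments",
                       "materials", "settings", "data")], nrow, integer(1))
  cat(paste0("  ", names(counts), ": ", counts, collapse = "\n"), "\n")
  invisible(x)
}

#' One-row summary of an experiment record
#' @param x An `experiment_record`.
#' @param ... Unused.
#' @return Tibble of component counts.
#' @method glance experiment_record
#' @export
glance.experiment_record <- function(x, ...) {
  tibble(
    id = x$meta$id, label = x$meta$label,
    n_plans = nrow(x$plans), n_steps = nrow(x$steps),
    n_agents = nrow(x$agents), n_activities = nrow(x$activities),
    n_instruments = nrow(x$instruments), n_materials = nrow(x$materials),
    n_settings = nrow(x$settings), n_data = nrow(x$data),
    n_goals = length(x$goals)
  )
}

# --- complete path ----------------------------------------------------------

#' The complete path of an experiment
#'
#' Assembles the ordered path from an experiment to its results: the agents
#' and their roles, the plan hierarchy (sub-plans depth-first), the steps in
#' execution order (plan nesting first, then `preceded_by` within each plan)
#' with their inputs and outputs, and the instruments with their settings.
#'
#' @param e An `experiment_record`.
#' @return An object of class `complete_path`: a list of tibbles `agents`,
#'   `plans`, `steps` (with `position` giving the path order), and
#'   `instruments`.
#' @export
complete_path <- function(e) {
  stopifnot(inherits(e, "experiment_record"))
  # depth-first plan ordering rooted at the experiment
  plan_children <- function(pid) {
    kids <- e$plans$id[is.na(e$plans$parent_plan) & pid == e$meta$id |
                         (!is.na(e$plans$parent_plan) & e$plans$parent_plan == pid)]
    unique(kids)
  }
  ordered_plans <- character(0)
  walk <- function(pid, depth) {
    ordered_plans <<- c(ordered_plans, pid)
    for (k in plan_children(pid)) walk(k, depth + 1)
  }
  walk(e$meta$id, 0)

  steps_ordered <- unlist(lapply(ordered_plans, function(pid) {
    in_plan <- e$steps[e$steps$plan == pid, ]
    topo_order(in_plan$id, in_plan$preceded_by)
  }))
  steps <- e$steps[match(steps_ordered, e$steps$id), ]
  if (nrow(steps) > 0) steps$position <- seq_len(nrow(steps))
  else steps$position <- integer(0)

  labels <- c(stats::setNames(e$data$label, e$data$id),
              stats::setNames(e$materials$label, e$materials$id))
  steps$input_labels <- purrr::map(steps$inputs, ~ unname(labels[.x]))
  steps$output_labels <- purrr::map(steps$outputs, ~ unname(labels[.x]))

  instr <- e$instruments
  setting_tbl <- e$settings
  instr$setting_values <- purrr::map(instr$settings, function(sid) {
    setting_tbl[setting_tbl$id %in% sid, c("key", "value", "subtype")]
  })

  structure(
    list(experiment = e$meta, goals = e$goals, agents = e$agents,
         plans = tibble(id = ordered_plans)[-1, , drop = FALSE] |>
           left_join(e$plans, by = "id"),
         steps = steps, instruments = instr),
    class = "complete_path"
  )
}

#' @export
print.complete_path <- function(x, ...) {
  cat("Complete path of", x$experiment$id, "-", x$experiment$label, "\n")
  if (nrow(x$agents) > 0) {
    cat("Agents:\n")
    cat(paste0("  ", x$agents$name, " [", x$agents$role, "]", collapse = "\n"), "\n")
  }
  if (nrow(x$steps) > 0) {
    cat("Steps:\n")
    cat(paste0("  ", x$steps$position, ". ", x$steps$label,
               " (", x$steps$subtype, ")", collapse = "\n"), "\n")
  }
  if (nrow(x$instruments) > 0) {
    cat("Instruments:", paste(x$instruments$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a complete path into one row per step
#' @param x A [complete_path()] result.
#' @param ... Unused.
#' @return Tibble of ordered steps with plan, subtype and I/O labels.
#' @method tidy complete_path
#' @export
tidy.complete_path <- function(x, ...) {
  select(x$steps, "position", "id", "label", "subtype", "plan",
         "input_labels", "output_labels")
}

#' Plot the step order of a complete path
#'
#' @param object A [complete_path()] result.
#' @param ... Unused.
#' @return A ggplot showing steps in execution order, coloured by subtype.
#' @method autoplot complete_path
#' @export
autoplot.complete_path <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = stats::reorder(.data$label, -.data$position),
                                   fill = .data$subtype)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = "path position", y = NULL, fill = "step subtype",
                  title = paste("Complete path:", object$experiment$label)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
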