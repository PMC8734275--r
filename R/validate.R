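# Structural conformance of provenance graphs against the model's patterns.
# Rules are declarative objects (id, severity, check function) held in a
# list, so domain extensions can append their own; each check returns
# findings as rows. Missing optional metadata (attribution, instrument
# settings) warns rather than fails, mirroring how real knowledge bases have
# missing provenance on some elements.

finding <- function(rule_id, severity, subject, message) {
  tibble(rule_id = rule_id, severity = severity, subject = subject,
         message = message)
}

no_findings <- function() {
  tibble(rule_id = character(), severity = character(), subject = character(),
         message = character())
}

#' The built-in validation rule set
#'
#' R1 every cell is a step of a notebook; R2 every cell execution carries
#' exactly one start and one end time, in order; R3 step inputs/outputs are
#' typed as variables; R4 `isPrecededBy` targets exist and the order is
#' acyclic; R5 every repr-namespace term is registered; R6 (warning)
#' experiments should be attributed to an agent; R7 (warning) instruments and
#' their parts should have settings.
#'
#' @return A named list of rules; each rule has `id`, `severity` and a
#'   `check(g, registry)` function returning a findings tibble.
#' @export
validation_rules <- function() {
  list(
    R1 = list(id = "R1", severity = "error", check = function(g, registry) {
      cells <- subjects_of_type(g, "repr:Cell")
      notebooks <- instances_of(g, "repr:Notebook", registry)
      bad <- cells[!vapply(cells, function(c) {
        any(obj_of(g, c, "p-plan:isStepOfPlan", FALSE) %in% notebooks)
      }, logical(1))]
      if (length(bad) == 0) return(no_findings())
      finding("R1", "error", bad, "cell is not a step of any notebook")
    }),
    R2 = list(id = "R2", severity = "error", check = function(g, registry) {
      execs <- subjects_of_type(g, "repr:CellExecution")
      out <- list()
      for (x in execs) {
        st <- obj_of(g, x, "prov:startedAtTime", TRUE)
        en <- obj_of(g, x, "prov:endedAtTime", TRUE)
        if (length(st) != 1 || length(en) != 1) {
          out[[length(out) + 1]] <- finding("R2", "error", x,
            sprintf("cell execution must have exactly one start and one end time (found %d/%d)",
                    length(st), length(en)))
        } else if (parse_time(en) < parse_time(st)) {
          out[[length(out) + 1]] <- finding("R2", "error", x,
                                            "execution ends before it starts")
        }
      }
      if (length(out) == 0) no_findings() else bind_rows(out)
    }),
    R3 = list(id = "R3", severity = "error", check = function(g, registry) {
      tr <- g$triples
      pf <- g$prefixes
      vars <- unique(c(
        tr$subject[tr$predicate %in% expand_curie(c("p-plan:isInputVarOf", "p-plan:isOutputVarOf"), pf)],
        tr$object[!tr$literal & tr$predicate == expand_curie("p-plan:hasInputVar", pf)]
      ))
      typed <- instances_of(g, "p-plan:Variable", registry)
      bad <- setdiff(vars, typed)
      if (length(bad) == 0) return(no_findings())
      finding("R3", "error", bad, "step input/output is not typed as a variable")
    }),
    R4 = list(id = "R4", severity = "error", check = function(g, registry) {
      tr <- g$triples
      pf <- g$prefixes
      edges <- tr[tr$predicate == expand_curie("p-plan:isPrecededBy", pf) & !tr$literal, ]
      known <- unique(c(tr$subject, tr$object[!tr$literal]))
      missing <- setdiff(edges$object, tr$subject)
      out <- list()
      if (length(missing) > 0) {
        subj <- edges$subject[edges$object %in% missing]
        out[[1]] <- finding("R4", "error", subj,
                            "isPrecededBy target is not described in the graph")
      }
      # cycle detection over the order relation
      adj <- split(edges$object, edges$subject)
      color <- new.env(parent = emptyenv())
      cyclic <- FALSE
      visit <- function(n) {
        st <- get0(n, envir = color, ifnotfound = "white")
        if (st == "grey") { cyclic <<- TRUE; return() }
        if (st == "black") return()
        assign(n, "grey", envir = color)
        for (m in adj[[n]] %||% character(0)) visit(m)
        assign(n, "black", envir = color)
      }
      for (n in names(adj)) visit(n)
      if (cyclic) {
        out[[length(out) + 1]] <- finding("R4", "error", names(adj)[[1]],
                                          "isPrecededBy order contains a cycle")
      }
      if (length(out) == 0) no_findings() else bind_rows(out)
    }),
    R5 = list(id = "R5", severity = "error", check = function(g, registry) {
      tr <- g$triples
      used <- unique(c(tr$predicate,
                       tr$object[!tr$literal &
                                   tr$predicate == expand_curie("rdf:type", g$prefixes)]))
      unknown <- setdiff(used[startsWith(used, REPR)], registry$iri)
      if (length(unknown) == 0) return(no_findings())
      finding("R5", "error", unknown, "repr-namespace term is not registered")
    }),
    R6 = list(id = "R6", severity = "warning", check = function(g, registry) {
      exps <- instances_of(g, "repr:Experiment", registry)
      bad <- exps[vapply(exps, function(e) {
        length(obj_of(g, e, "prov:wasAttributedTo", FALSE)) == 0
      }, logical(1))]
      if (length(bad) == 0) return(no_findings())
      finding("R6", "warning", bad, "experiment is not attributed to any agent")
    }),
    R7 = list(id = "R7", severity = "warning", check = function(g, registry) {
      instr <- instances_of(g, "repr:Instrument", registry)
      bad <- instr[vapply(instr, function(i) {
        length(obj_of(g, i, "repr:hasSetting", FALSE)) == 0
      }, logical(1))]
      if (length(bad) == 0) return(no_findings())
      finding("R7", "warning", bad, "instrument has no setting linked via hasSetting")
    })
  )
}

#' Validate a provenance graph
#'
#' Runs the structural rule set (see [validation_rules()]) over a graph.
#'
#' @param g A [prov_graph()].
#' @param registry Term registry.
#' @param rules Rule list; defaults to the built-in R1-R7.
#' @return A tibble of class `prov_validation` with columns `rule_id`,
#'   `severity`, `subject`, `message`; zero rows iff the graph conforms.
#' @export
#' @examples
#' validate_graph(fixture_colocalization())
validate_graph <- function(g, registry = build_registry(),
                           rules = validation_rules()) {
  stopifnot(inherits(g, "prov_graph"))
  out <- bind_rows(lapply(rules, function(r) r$check(g, registry)))
  if (nrow(out) == 0) out <- no_findings()
  class(out) <- c("prov_validation", class(out))
  out
}

#' @export
print.prov_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Graph conforms: no findings.\n")
  } else {
    cat(nrow(x), "finding(s):\n")
    NextMethod()
  }
  invisible(x)
}

#' Summarize a validation report
#' @param x A [validate_graph()] report.
#' @param ... Unused.
#' @return One-row tibble with error/warning counts and conformance flag.
#' @method glance prov_validation
#' @export
glance.prov_validation <- function(x, ...) {
  tibble(n_findings = nrow(x),
         n_errors = sum(x$severity == "error"),
         n_warnings = sum(x$severity == "warning"),
         conforms = nrow(x) == 0L)
}

#' Plot findings per rule
#' @param object A [validate_graph()] report.
#' @param ... Unused.
#' @return A ggplot bar chart of findings by rule and severity.
#' @method autoplot prov_validation
#' @export
autoplot.prov_validation <- function(object, ...) {
  df <- dplyr::count(as_tibble(object), .data$rule_id, .data$severity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule_id, y = .data$n,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(error = "#b2182b", warning = "#ef8a62")) +
    ggplot2::labs(x = "rule", y = "findings", fill = "severity") +
    ggplot2::theme_minimal()
}
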