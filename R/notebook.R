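# Notebook provenance. Prospective side: a notebook is a plan whose cells
# are steps, each with its source text as an input variable. Retrospective
# side: each run of a cell is a CellExecution activity with the entity it
# used, the entity it generated, start/end times and the execution time.
# Executions are recorded through the API (replaying logged events); no live
# kernel is instrumented.

#' Read a computational notebook (nbformat v4)
#'
#' @param x Path to an `.ipynb` file, a JSON string, or an already-parsed
#'   nbformat list.
#' @param id Identifier for the notebook; defaults to the file name without
#'   extension (or `"notebook"` for raw JSON).
#' @return An object of class `notebook_record` with fields `id`, `cells`
#'   (tibble: `id`, `index`, `cell_type`, `source`) and `settings` (tibble of
#'   kernel/language settings drawn from the notebook metadata).
#' @export
read_notebook <- function(x, id = NULL) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    id <- id %||% sub("\\.ipynb$", "", basename(x))
    nb <- jsonlite::read_json(x, simplifyVector = FALSE)
  } else if (is.character(x)) {
    nb <- jsonlite::parse_json(paste(x, collapse = "\n"), simplifyVector = FALSE)
  } else {
    nb <- x
  }
  id <- id %||% "notebook"
  major <- nb$nbformat
  if (is.null(major)) abort("malformed notebook: no nbformat field")
  if (major != 4) {
    abort(sprintf("unsupported nbformat major version %s (only v4 is supported)", major))
  }
  cells <- nb$cells %||% list()
  cell_tbl <- if (length(cells) == 0) {
    tibble(id = character(), index = integer(), cell_type = character(),
           source = character())
  } else {
    bind_rows(lapply(seq_along(cells), function(i) {
      c <- cells[[i]]
      tibble(
        id = paste0(id, "/cell-", i - 1L),
        index = i - 1L,
        cell_type = c$cell_type %||% "code",
        source = paste(unlist(c$source), collapse = "")
      )
    }))
  }
  meta <- nb$metadata %||% list()
  settings <- list()
  ks <- meta$kernelspec
  if (!is.null(ks)) {
    settings <- c(settings, list(tibble(
      id = paste0(id, "/kernel"), subtype = "ComputationalTools",
      key = "kernel", value = ks$name %||% ks$display_name %||% NA_character_
    )))
  }
  li <- meta$language_info
  if (!is.null(li)) {
    settings <- c(settings, list(tibble(
      id = paste0(id, "/language"), subtype = "ProgrammingLanguage",
      key = li$name %||% "language", value = li$version %||% NA_character_
    )))
  }
  settings <- if (length(settings)) bind_rows(settings) else {
    tibble(id = character(), subtype = character(), key = character(),
           value = character())
  }
  structure(list(id = id, cells = cell_tbl, settings = settings),
            class = "notebook_record",
            base_iri = "https://example.org/provpath/")
}

#' @export
print.notebook_record <- function(x, ...) {
  cat("<notebook_record>", x$id, "-", nrow(x$cells), "cells\n")
  invisible(x)
}

#' Re-serialize a notebook record as an nbformat v4 list
#'
#' Parsing the result with [read_notebook()] yields an equal record, so
#' extraction is idempotent.
#'
#' @param nb A `notebook_record`.
#' @return A list matching the nbformat v4 JSON structure.
#' @export
as_nbformat <- function(nb) {
  stopifnot(inherits(nb, "notebook_record"))
  meta <- list()
  k <- nb$settings[nb$settings$subtype == "ComputationalTools", ]
  if (nrow(k) == 1) meta$kernelspec <- list(name = k$value)
  l <- nb$settings[nb$settings$subtype == "ProgrammingLanguage", ]
  if (nrow(l) == 1) meta$language_info <- list(name = l$key, version = l$value)
  list(
    nbformat = 4L, nbformat_minor = 5L, metadata = meta,
    cells = lapply(seq_len(nrow(nb$cells)), function(i) {
      list(cell_type = nb$cells$cell_type[i], metadata = list(),
           source = nb$cells$source[i])
    })
  )
}

empty_executions <- function() {
  tibble(id = character(), cell = character(), source = character(),
         used = character(), generated = character(),
         started_at = character(), ended_at = character(),
         execution_time = numeric(), seq = integer())
}

parse_time <- function(t) {
  if (is.numeric(t)) return(t)
  as.numeric(as.POSIXct(t, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
}

#' Record a cell execution
#'
#' Appends one retrospective execution event to an execution log. The
#' execution time is defined as the difference between the end and start
#' times, in seconds.
#'
#' @param executions An execution log tibble (or `NULL` to start one).
#' @param nb The `notebook_record` the cell belongs to.
#' @param cell Cell id or zero-based cell index.
#' @param used,generated Optional entity identifiers consumed / produced.
#' @param started_at,ended_at ISO-8601 timestamps (`ended_at` must not
#'   precede `started_at`).
#' @param seq Per-trial monotonic sequence number; defaults to one more than
#'   the current maximum.
#' @return The execution log with one row appended.
#' @export
record_execution <- function(executions, nb, cell, used = NA_character_,
                             generated = NA_character_,
                             started_at, ended_at, seq = NULL) {
  stopifnot(inherits(nb, "notebook_record"))
  if (is.null(executions)) executions <- empty_executions()
  if (is.numeric(cell)) {
    row <- nb$cells[nb$cells$index == cell, ]
  } else {
    row <- nb$cells[nb$cells$id == cell, ]
  }
  if (nrow(row) != 1) abort(sprintf("cell '%s' not found in notebook '%s'", cell, nb$id))
  t0 <- parse_time(started_at); t1 <- parse_time(ended_at)
  if (is.na(t0) || is.na(t1)) abort("unparseable execution timestamps")
  if (t1 < t0) abort("execution ends before it starts (ended_at < started_at)")
  seq <- seq %||% (if (nrow(executions) == 0) 1L else max(executions$seq) + 1L)
  if (nrow(executions) > 0 && seq <= max(executions$seq)) {
    abort("sequence numbers must be strictly increasing within a trial")
  }
  bind_rows(executions, tibble(
    id = paste0(row$id, "/exec-", seq), cell = row$id, source = row$source,
    used = as.character(used), generated = as.character(generated),
    started_at = as.character(started_at), ended_at = as.character(ended_at),
    execution_time = t1 - t0, seq = as.integer(seq)
  ))
}

#' Compare two executions of a cell
#'
#' @param a,b One-row execution tibbles (rows of a [record_execution()] log).
#' @param allow_different_cells Permit comparing executions of different
#'   cells (otherwise an error).
#' @return One-row tibble flagging source/used/generated changes and the
#'   execution-time delta in seconds.
#' @export
diff_executions <- function(a, b, allow_different_cells = FALSE) {
  a <- as_tibble(a); b <- as_tibble(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$cell != b$cell && !allow_different_cells) {
    abort("executions belong to different cells (set allow_different_cells = TRUE to override)")
  }
  tibble(
    cell_a = a$cell, cell_b = b$cell,
    source_changed = !identical(a$source, b$source),
    used_changed = !identical(a$used, b$used),
    generated_changed = !identical(a$generated, b$generated),
    time_delta = b$execution_time - a$execution_time
  )
}

#' Convert a notebook and its execution log to a provenance graph
#'
#' The notebook becomes a plan whose cells are steps (`p-plan:isStepOfPlan`),
#' each cell's source an input variable carrying its text as `rdf:value`.
#' Each execution becomes a `CellExecution` activity tied to its cell, with
#' `prov:used` / `prov:generated` entities, start and end times, and the
#' execution time in seconds.
#'
#' @param nb A `notebook_record`.
#' @param executions Optional execution log from [record_execution()].
#' @return A [prov_graph()].
#' @export
notebook_to_graph <- function(nb, executions = NULL) {
  stopifnot(inherits(nb, "notebook_record"))
  base <- attr(nb, "base_iri")
  N <- paste0(base, nb$id)
  tr <- list(
    spo(N, "rdf:type", c("repr:Notebook", "p-plan:Plan")),
    spv(N, "rdfs:label", nb$id)
  )
  if (nrow(nb$cells) > 0) {
    C <- paste0(base, nb$cells$id)
    Src <- paste0(C, "/source")
    tr <- c(tr, list(
      spo(C, "rdf:type", "repr:Cell"), spo(C, "rdf:type", "p-plan:Step"),
      spo(C, "p-plan:isStepOfPlan", N),
      spv(C, "repr:index", nb$cells$index, "xsd:integer"),
      spo(Src, "rdf:type", "repr:Source"), spo(Src, "rdf:type", "p-plan:Variable"),
      spo(Src, "p-plan:isInputVarOf", C),
      spv(Src, "rdf:value", nb$cells$source)
    ))
  }
  if (nrow(nb$settings) > 0) {
    St <- paste0(base, nb$settings$id)
    tr <- c(tr, list(
      spo(St, "rdf:type", paste0("repr:", nb$settings$subtype)),
      spv(St, "rdfs:label", nb$settings$key),
      lit_if(St, "rdf:value", nb$settings$value),
      spo(N, "repr:hasSetting", St)
    ))
  }
  if (!is.null(executions) && nrow(executions) > 0) {
    X <- paste0(base, executions$id)
    Cx <- paste0(base, executions$cell)
    tr <- c(tr, list(
      spo(X, "rdf:type", "repr:CellExecution"),
      spo(X, "p-plan:correspondsToStep", Cx),
      spv(X, "prov:startedAtTime", executions$started_at, "xsd:dateTime"),
      spv(X, "prov:endedAtTime", executions$ended_at, "xsd:dateTime"),
      spv(X, "repr:executionTime", executions$execution_time, "xsd:decimal"),
      spv(X, "repr:sequenceNumber", executions$seq, "xsd:integer")
    ))
    has_used <- !is.na(executions$used)
    if (any(has_used)) {
      U <- paste0(base, executions$used[has_used])
      tr <- c(tr, list(spo(U, "rdf:type", "prov:Entity"),
                       spo(X[has_used], "prov:used", U)))
    }
    has_gen <- !is.na(executions$generated)
    if (any(has_gen)) {
      Gn <- paste0(base, executions$generated[has_gen])
      tr <- c(tr, list(spo(Gn, "rdf:type", "prov:Entity"),
                       spo(X[has_gen], "prov:generated", Gn)))
    }
  }
  prov_graph(bind_rows(tr), prefixes = c(prov_prefixes(), ex = base))
}

#' Complete derivation of a notebook output
#'
#' Walks backwards from an entity: the execution(s) that generated it, the
#' cell each execution ran (with its source), the notebook the cell belongs
#' to, and the notebook's environment settings. Rows are ordered by the
#' executions' sequence numbers.
#'
#' @param g A [prov_graph()].
#' @param entity Entity IRI (or CURIE under the graph's prefixes).
#' @return A tibble with columns `role` (notebook / cell / execution /
#'   setting), `node`, `label`, `value` and `seq`. Zero execution rows (with
#'   a warning) when nothing generated the entity.
#' @export
derivation_of <- function(g, entity) {
  stopifnot(inherits(g, "prov_graph"))
  entity <- expand_curie(entity, g$prefixes)
  tr <- g$triples
  if (!entity %in% c(tr$subject, tr$object[!tr$literal])) {
    abort(sprintf("entity <%s> is not present in the graph", entity))
  }
  gens <- tr$subject[tr$predicate == expand_curie("prov:generated", g$prefixes) &
                       !tr$literal & tr$object == entity]
  if (length(gens) == 0) {
    warn(sprintf("entity <%s> has no generating activity", entity))
    return(tibble(role = character(), node = character(), label = character(),
                  value = character(), seq = integer()))
  }
  rows <- list()
  for (x in gens) {
    seq <- as.integer(obj_of1(g, x, "repr:sequenceNumber", TRUE))
    cell <- obj_of1(g, x, "p-plan:correspondsToStep", FALSE)
    nbk <- if (!is.na(cell)) obj_of1(g, cell, "p-plan:isStepOfPlan", FALSE) else NA_character_
    src_val <- NA_character_
    if (!is.na(cell)) {
      srcs <- tr$subject[tr$predicate == expand_curie("p-plan:isInputVarOf", g$prefixes) &
                           !tr$literal & tr$object == cell]
      if (length(srcs) > 0) src_val <- obj_of1(g, srcs[[1]], "rdf:value", TRUE)
    }
    rows[[length(rows) + 1]] <- bind_rows(
      if (!is.na(nbk)) tibble(role = "notebook", node = nbk,
                              label = obj_of1(g, nbk, "rdfs:label", TRUE),
                              value = NA_character_, seq = seq),
      if (!is.na(cell)) tibble(role = "cell", node = cell,
                               label = obj_of1(g, cell, "repr:index", TRUE),
                               value = src_val, seq = seq),
      tibble(role = "execution", node = x,
             label = obj_of1(g, x, "prov:startedAtTime", TRUE),
             value = obj_of1(g, x, "repr:executionTime", TRUE), seq = seq),
      if (!is.na(nbk)) {
        sets <- obj_of(g, nbk, "repr:hasSetting", FALSE)
        if (length(sets) > 0) tibble(
          role = "setting", node = sets,
          label = vapply(sets, function(s) obj_of1(g, s, "rdfs:label", TRUE), character(1)),
          value = vapply(sets, function(s) obj_of1(g, s, "rdf:value", TRUE), character(1)),
          seq = seq
        )
      }
    )
  }
  out <- bind_rows(rows)
  arrange(out, .data$seq, match(.data$role, c("notebook", "cell", "execution", "setting")))
}

#' Plot an execution log timeline
#'
#' @param object An execution log tibble from [record_execution()].
#' @param ... Unused.
#' @return A ggplot of execution time per sequence number, coloured by cell.
#' @export
plot_executions <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$seq, y = .data$execution_time,
                                       fill = .data$cell)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "execution sequence", y = "execution time [s]",
                  fill = "cell") +
    ggplot2::theme_minimal()
}
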