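test_that("nbformat v4 documents parse into ordered cell records", {
  nb <- read_notebook(tiny_notebook_json(n_code = 3), id = "nb")
  expect_equal(nrow(nb$cells), 3L)
  expect_equal(nb$cells$index, 0:2)
  expect_match(nb$cells$source[1], "x1 = 1")
  # file-based fixture
  path <- system.file("extdata", "notebook-example.ipynb", package = "provpath")
  nb2 <- read_notebook(path)
  expect_equal(nrow(nb2$cells), 3L)
  expect_equal(nb2$cells$index, 0:2)
})

test_that("empty and markdown-only notebooks are retained without executions", {
  empty <- read_notebook(list(nbformat = 4, cells = list()))
  expect_equal(nrow(empty$cells), 0L)
  md <- read_notebook(tiny_notebook_json(markdown_only = TRUE), id = "md")
  expect_equal(md$cells$cell_type, "markdown")
  g <- notebook_to_graph(md)
  td <- tidy(g)
  expect_true(any(td$predicate == "rdf:type" & td$object == "repr:Cell"))
  expect_false(any(td$object == "repr:CellExecution"))
})

test_that("unsupported nbformat versions and malformed documents error", {
  expect_error(read_notebook(list(nbformat = 3, cells = list())), "nbformat major")
  expect_error(read_notebook(list(cells = list())), "malformed")
})

test_that("notebook extraction is idempotent through re-serialization", {
  nb <- read_notebook(tiny_notebook_json(), id = "nb")
  nb2 <- read_notebook(as_nbformat(nb), id = "nb")
  expect_equal(nb$cells, nb2$cells)
  expect_equal(nb$settings, nb2$settings)
})

test_that("executions record timing arithmetic exactly", {
  nb <- read_notebook(tiny_notebook_json(n_code = 2), id = "nb")
  log <- record_execution(NULL, nb, 0L,
                          started_at = "2021-06-01T10:00:00",
                          ended_at = "2021-06-01T10:00:00")
  expect_equal(log$execution_time, 0)
  log <- record_execution(log, nb, 0L,
                          started_at = "2021-06-01T10:00:00",
                          ended_at = "2021-06-01T10:00:05")
  expect_equal(log$execution_time[2], 5)
  # invariant: execution_time always equals ended - started
  expect_equal(log$execution_time,
               as.numeric(as.POSIXct(log$ended_at, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")) -
                 as.numeric(as.POSIXct(log$started_at, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")))
  # two executions of one cell are distinct nodes linked to the same cell
  expect_equal(dplyr::n_distinct(log$id), 2L)
  expect_equal(unique(log$cell), "nb/cell-0")
  g <- notebook_to_graph(nb, log)
  td <- tidy(g)
  execs <- td$subject[td$predicate == "rdf:type" & td$object == "repr:CellExecution"]
  expect_length(execs, 2L)
  expect_equal(unique(td$object[td$predicate == "p-plan:correspondsToStep"]),
               "https://example.org/provpath/nb/cell-0")
})

test_that("invalid execution events are rejected", {
  nb <- read_notebook(tiny_notebook_json(n_code = 2), id = "nb")
  expect_error(record_execution(NULL, nb, 0L,
                                started_at = "2021-06-01T10:00:05",
                                ended_at = "2021-06-01T10:00:00"),
               "ends before")
  expect_error(record_execution(NULL, nb, 9L, started_at = "2021-06-01T10:00:00",
                                ended_at = "2021-06-01T10:00:01"), "not found")
  log <- record_execution(NULL, nb, 0L, started_at = "2021-06-01T10:00:00",
                          ended_at = "2021-06-01T10:00:01", seq = 5L)
  expect_error(record_execution(log, nb, 0L, started_at = "2021-06-01T10:00:02",
                                ended_at = "2021-06-01T10:00:03", seq = 5L),
               "strictly increasing")
})

test_that("execution deltas report what changed between two runs", {
  fix <- tiny_notebook_with_log()
  log <- fix$log
  same <- diff_executions(log[1, ], log[1, ])
  expect_false(any(same$source_changed, same$used_changed, same$generated_changed))
  expect_equal(same$time_delta, 0)
  d <- diff_executions(log[1, ], log[3, ])   # same cell, different generated
  expect_false(d$source_changed)
  expect_true(d$generated_changed)
  expect_true(d$used_changed)
  expect_equal(d$time_delta, 25)
  expect_error(diff_executions(log[1, ], log[2, ]), "different cells")
  d2 <- diff_executions(log[1, ], log[2, ], allow_different_cells = TRUE)
  expect_true(d2$source_changed)
})

test_that("derivation walks output <- execution <- cell <- notebook with settings", {
  fix <- tiny_notebook_with_log()
  g <- notebook_to_graph(fix$nb, fix$log)
  rep <- derivation_of(g, "ex:out-c")
  expect_equal(rep$role[1:3], c("notebook", "cell", "execution"))
  expect_true("setting" %in% rep$role)
  expect_equal(unique(rep$seq), 3L)
  expect_match(rep$value[rep$role == "cell"], "x2 = 2")
  # non-linear order: out-a came from cell 1's first run (seq 1), before cell 0
  rep_a <- derivation_of(g, "ex:out-a")
  expect_equal(unique(rep_a$seq), 1L)
  expect_error(derivation_of(g, "ex:nonexistent"), "not present")
  # an entity that exists but was never generated warns and yields no chain
  g2 <- add_triples(g, tibble::tibble(
    subject = "ex:orphan", predicate = "rdf:type", object = "prov:Entity",
    literal = FALSE, datatype = NA_character_, lang = NA_character_
  ))
  expect_warning(rep0 <- derivation_of(g2, "ex:orphan"), "no generating")
  expect_equal(nrow(rep0), 0L)
})

test_that("the notebook graph carries the retrospective pattern", {
  fix <- tiny_notebook_with_log()
  td <- tidy(notebook_to_graph(fix$nb, fix$log))
  for (p in c("prov:used", "prov:generated", "prov:startedAtTime",
              "prov:endedAtTime", "repr:executionTime")) {
    expect_true(p %in% td$predicate, label = p)
  }
  # source text attached as rdf:value of an input variable
  src <- td$subject[td$predicate == "rdf:type" & td$object == "repr:Source"]
  expect_true(all(src %in% td$subject[td$predicate == "rdf:value"]))
})
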