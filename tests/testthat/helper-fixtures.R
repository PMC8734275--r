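# Shared fixture builders. Everything is constructed in code so tests are
# self-contained; the few on-disk fixtures live under inst/extdata.

tiny_manifest <- function(id = "exp1") {
  list(
    experiment = list(id = id, label = "Colocalization test", hypothesis = "H1",
                      goals = list("measure colocalization"),
                      created_at = "2021-05-04T10:00:00"),
    plans = list(list(id = "prot1", subtype = "Protocol"),
                 list(id = "meth1", subtype = "Method", parent_plan = "prot1")),
    steps = list(
      list(id = "s1", label = "Preparation", subtype = "NonComputational",
           inputs = list("mat1", "d1")),
      list(id = "s2", label = "Transfection", subtype = "NonComputational",
           preceded_by = "s1", inputs = list("mat1"), method_used = "meth1"),
      list(id = "s3", label = "Image Acquisition", subtype = "Computational",
           plan = "prot1", preceded_by = "s2", outputs = list("d2"))
    ),
    agents = list(list(id = "a1", name = "Alice", role = "Experimenter",
                       orcid = "0000-0001-2345-678X")),
    activities = list(list(id = "act1", start = "2021-05-04T10:00:00",
                           end = "2021-05-04T11:00:00", used = list("d1"),
                           generated = list("d2"), execution_order = 1)),
    instruments = list(
      list(id = "mic1", label = "LSM 880", subtype = "Microscope",
           settings = list("set1")),
      list(id = "obj1", label = "63x", subtype = "Objective", part_of = "mic1",
           settings = list("set2"))
    ),
    materials = list(list(id = "mat1", label = "pCherry-RAD54", subtype = "Plasmid")),
    settings = list(
      list(id = "set1", subtype = "InstrumentSettings", key = "laser power", value = "0.5"),
      list(id = "set2", subtype = "InstrumentSettings", key = "zoom", value = "1.0")
    ),
    data = list(
      list(id = "d1", label = "protocol paper", category = "Publication",
           doi = "10.1000/xyz"),
      list(id = "d2", label = "image", category = "RawData")
    )
  )
}

tiny_notebook_json <- function(n_code = 3, markdown_only = FALSE) {
  cells <- if (markdown_only) {
    list(list(cell_type = "markdown", metadata = list(),
              source = list("# Analysis notes\n", "All manual.")))
  } else {
    lapply(seq_len(n_code), function(i) {
      list(cell_type = "code", metadata = list(), execution_count = NULL,
           outputs = list(),
           source = list(sprintf("x%d = %d\n", i, i), sprintf("print(x%d)", i)))
    })
  }
  jsonlite::toJSON(list(
    nbformat = 4, nbformat_minor = 5,
    metadata = list(kernelspec = list(name = "python3"),
                    language_info = list(name = "python", version = "3.9.7")),
    cells = cells
  ), auto_unbox = TRUE, null = "null")
}

tiny_trial_manifest <- function() {
  list(
    script = list(
      id = "analysis.py", label = "intensity analysis",
      experiment = "exp-coloc",
      language = list(name = "Python", version = "3.9.7"),
      author = list(id = "author1", name = "Bob", orcid = "0000-0002-1825-0097"),
      functions = list(list(id = "fn-load", label = "load_data"),
                       list(id = "fn-norm", label = "normalize"),
                       list(id = "fn-fit", label = "fit_model"))
    ),
    trial = list(
      id = "trial1", started = "2021-06-01T09:00:00", ended = "2021-06-01T09:05:00",
      experimenter = list(id = "exper1", name = "Alice"),
      location = "workstation-7:/home/alice/run",
      os = list(name = "CentOS Linux", version = "7"),
      modules = list(list(name = "numlib", version = "1.2"),
                     list(name = "plotlib", version = "0.4.1")),
      accessed_files = list("measurements.csv"),
      activations = list(
        list(id = "fa1", "function" = "fn-load",
             arguments = list(list(name = "path", value = "measurements.csv")),
             returned = "frame", start = "2021-06-01T09:00:01", end = "2021-06-01T09:00:02"),
        list(id = "fa2", "function" = "fn-norm",
             arguments = list(list(name = "frame", value = "frame")),
             returned = "norm", start = "2021-06-01T09:00:02", end = "2021-06-01T09:00:04"),
        list(id = "fa3", "function" = "fn-fit",
             arguments = list(list(name = "norm", value = "norm")),
             returned = "fit", start = "2021-06-01T09:00:04", end = "2021-06-01T09:04:59")
      ),
      result = list(id = "res1", label = "fitted coefficients", value = "0.83")
    )
  )
}

# a notebook record plus a 3-execution log over 2 cells (cell 1 run before
# cell 0, then cell 0 - a non-linear execution order)
tiny_notebook_with_log <- function() {
  nb <- read_notebook(tiny_notebook_json(n_code = 2), id = "nb1")
  log <- record_execution(NULL, nb, cell = 1L, generated = "out-a",
                          started_at = "2021-06-01T10:00:00",
                          ended_at = "2021-06-01T10:00:05", seq = 1L)
  log <- record_execution(log, nb, cell = 0L, generated = "out-b",
                          started_at = "2021-06-01T10:00:10",
                          ended_at = "2021-06-01T10:00:12", seq = 2L)
  log <- record_execution(log, nb, cell = 1L, used = "out-b", generated = "out-c",
                          started_at = "2021-06-01T10:01:00",
                          ended_at = "2021-06-01T10:01:30", seq = 3L)
  list(nb = nb, log = log)
}
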