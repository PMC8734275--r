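# Seeded generator of microscopy-flavored experiments, notebooks and script
# trials with known ground truth, plus the deterministic colocalization
# fixture. Label vocabularies follow the kinds of experiments the model was
# built around (plasmid transfection, confocal imaging) so fixtures read like
# a real knowledge base while staying tiny (well under 10^3 triples each).
# Ground truth is recorded while planting, never recomputed from the graph,
# so it is an independent oracle for the competency queries.

STEP_PALETTE <- tibble::tribble(
  ~label,               ~subtype,
  "Preparation",        "NonComputationalStep",
  "Transfection",       "NonComputationalStep",
  "Incubation",         "NonComputationalStep",
  "Staining",           "NonComputationalStep",
  "Fixation",           "NonComputationalStep",
  "Image Acquisition",  "NonComputationalStep",
  "Image Analysis",     "ComputationalStep",
  "Measurement Export", "ComputationalStep"
)

MATERIAL_PALETTE <- tibble::tribble(
  ~label,            ~subtype,
  "pEGFP-RAD51",     "Plasmid",
  "pCherry-RAD54",   "Plasmid",
  "pEGFP-C1",        "Plasmid",
  "DAPI",            "Chemical",
  "PFA 4%",          "Chemical",
  "PBS",             "Solution",
  "DMEM",            "Solution",
  "HeLa cells",      "Specimen",
  "U2OS cells",      "Specimen"
)

MICROSCOPE_PALETTE <- c("LSM 710", "LSM 880", "TCS SP8")
PART_PALETTE <- tibble::tribble(
  ~label,             ~subtype,
  "63x/1.40 Oil",     "Objective",
  "40x/1.20 W",       "Objective",
  "GaAsP detector",   "Detector",
  "PMT detector",     "Detector",
  "Argon 488",        "Laser",
  "DPSS 561",         "Laser"
)
SETTING_KEYS <- c("laser power", "gain", "pinhole", "zoom", "exposure time")
AGENT_NAMES <- c("A. Keller", "B. Novak", "C. Fischer", "D. Sato", "E. Weber")
CELL_SOURCES <- c(
  "import numpy as np\nimport pandas as pd",
  "df = pd.read_csv('measurements.csv')",
  "signal = df['intensity'].mean()\nprint(signal)",
  "import matplotlib.pyplot as plt\nplt.plot(df['t'], df['intensity'])",
  "result = signal / background\nresult"
)

#' Generator configuration
#'
#' @param seed Integer seed; the same seed and configuration always produce
#'   identical records, graphs and manifests.
#' @param n_experiments Number of experiments to generate.
#' @param steps_range Inclusive range of steps per experiment.
#' @param materials_range Range of materials per experiment.
#' @param agents_range Range of agents per experiment (the first is always an
#'   experimenter).
#' @param parts_range Range of instrument parts per microscope.
#' @param notebook_prob Probability an experiment carries a computational
#'   notebook.
#' @param cells_range Range of cells per notebook.
#' @param execs_range Range of cell executions per notebook.
#' @param base_iri Base IRI for minted identifiers.
#' @return A `gen_config` list.
#' @export
gen_config <- function(seed = 1L, n_experiments = 3L, steps_range = c(2L, 5L),
                       materials_range = c(1L, 3L), agents_range = c(1L, 2L),
                       parts_range = c(1L, 2L), notebook_prob = 0.5,
                       cells_range = c(2L, 4L), execs_range = c(1L, 4L),
                       base_iri = "https://example.org/synth/") {
  ranges <- list(steps_range = steps_range, materials_range = materials_range,
                 agents_range = agents_range, parts_range = parts_range,
                 cells_range = cells_range, execs_range = execs_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      abort(sprintf("invalid range for %s: [%s]", nm, paste(r, collapse = ", ")))
    }
  }
  if (n_experiments < 0) abort("invalid ranges: n_experiments must be >= 0")
  structure(list(seed = as.integer(seed), n_experiments = as.integer(n_experiments),
                 steps_range = steps_range, materials_range = materials_range,
                 agents_range = agents_range, parts_range = parts_range,
                 notebook_prob = notebook_prob, cells_range = cells_range,
                 execs_range = execs_range, base_iri = base_iri),
            class = "gen_config")
}

rint <- function(r) if (r[1] == r[2]) as.integer(r[1]) else sample(r[1]:r[2], 1)

#' Generate synthetic experiments with ground truth
#'
#' Produces seeded microscopy-style experiments (ordered steps, agents with
#' roles, a microscope with parts and settings, planted materials) and,
#' for some experiments, a computational notebook with recorded cell
#' executions. The ground-truth tables are kept alongside the records while
#' planting and are never derived from the RDF graph, so they can serve as an
#' independent oracle for the competency queries.
#'
#' @param config A [gen_config()].
#' @return A list with `records` (experiment records), `notebooks` (lists of
#'   `nb` + `executions` + owning experiment), `graph` (the union
#'   [prov_graph()]), and `truth` (tibbles `material_usage`,
#'   `notebook_paths`, `complete_paths`).
#' @export
generate_provenance <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  records <- list()
  notebooks <- list()
  graphs <- list()
  usage <- list()
  nb_truth <- list()
  path_truth <- list()

  for (i in seq_len(config$n_experiments)) {
    ex_id <- paste0("exp", i)
    E <- paste0(config$base_iri, ex_id)
    n_steps <- rint(config$steps_range)
    step_rows <- STEP_PALETTE[sample(nrow(STEP_PALETTE), min(n_steps, nrow(STEP_PALETTE))), ]
    n_mat <- rint(config$materials_range)
    mat_rows <- MATERIAL_PALETTE[sample(nrow(MATERIAL_PALETTE), n_mat), ]
    n_agents <- rint(config$agents_range)
    roles <- c("Experimenter",
               sample(c("PrincipalInvestigator", "Manufacturer", "Author",
                        "ResearchGroup", "FundingAgency"), max(0, n_agents - 1)))

    steps <- lapply(seq_len(nrow(step_rows)), function(k) {
      list(id = paste0(ex_id, "-s", k), label = step_rows$label[k],
           subtype = step_rows$subtype[k],
           preceded_by = if (k > 1) paste0(ex_id, "-s", k - 1) else NULL,
           inputs = list(), outputs = list())
    })
    # plant each material into one or two steps and record the ground truth
    for (m in seq_len(nrow(mat_rows))) {
      mat_id <- paste0(ex_id, "-mat", m)
      into <- sort(sample(length(steps), min(length(steps), sample(1:2, 1))))
      for (k in into) {
        steps[[k]]$inputs <- c(steps[[k]]$inputs, list(mat_id))
        usage[[length(usage) + 1]] <- tibble(
          material_label = mat_rows$label[m],
          experiment = E, experiment_label = paste("Experiment", i),
          step = paste0(config$base_iri, ex_id, "-s", k),
          step_label = steps[[k]]$label
        )
      }
    }
    # final step produces an image
    steps[[length(steps)]]$outputs <- list(paste0(ex_id, "-img"))

    n_parts <- rint(config$parts_range)
    part_rows <- PART_PALETTE[sample(nrow(PART_PALETTE), n_parts), ]
    instruments <- c(
      list(list(id = paste0(ex_id, "-mic"),
                label = sample(MICROSCOPE_PALETTE, 1), subtype = "Microscope",
                settings = list(paste0(ex_id, "-set0")))),
      lapply(seq_len(n_parts), function(p) {
        list(id = paste0(ex_id, "-part", p), label = part_rows$label[p],
             subtype = part_rows$subtype[p], part_of = paste0(ex_id, "-mic"),
             settings = list(paste0(ex_id, "-set", p)))
      })
    )
    settings <- lapply(0:n_parts, function(p) {
      list(id = paste0(ex_id, "-set", p), subtype = "InstrumentSettings",
           key = sample(SETTING_KEYS, 1),
           value = as.character(round(stats::runif(1, 0.1, 100), 2)))
    })
    agents <- lapply(seq_along(roles), function(a) {
      list(id = paste0(ex_id, "-agent", a), name = sample(AGENT_NAMES, 1),
           role = roles[a],
           orcid = sprintf("0000-%04d-%04d-%04d", sample(0:9999, 1),
                           sample(0:9999, 1), sample(0:9999, 1)))
    })

    manifest <- list(
      base_iri = config$base_iri,
      experiment = list(
        id = ex_id, label = paste("Experiment", i),
        hypothesis = paste("Hypothesis", i),
        goals = list(paste("Goal", i)),
        created_at = sprintf("2021-03-%02dT09:00:00", (i %% 27) + 1)
      ),
      steps = steps,
      agents = agents,
      instruments = instruments,
      materials = lapply(seq_len(nrow(mat_rows)), function(m) {
        list(id = paste0(ex_id, "-mat", m), label = mat_rows$label[m],
             subtype = mat_rows$subtype[m])
      }),
      settings = settings,
      data = list(list(id = paste0(ex_id, "-img"), label = "confocal image",
                       category = "RawData"))
    )
    e <- as_experiment(manifest)
    records[[ex_id]] <- e
    graphs[[length(graphs) + 1]] <- experiment_to_graph(e)

    path_truth[[length(path_truth) + 1]] <- tibble(
      experiment = E,
      agents = list(paste0(config$base_iri, vapply(agents, `[[`, "", "id"))),
      steps = list(paste0(config$base_iri, vapply(steps, `[[`, "", "id"))),
      instruments = list(paste0(config$base_iri, vapply(instruments, `[[`, "", "id")))
    )

    if (stats::runif(1) < config$notebook_prob) {
      nb_id <- paste0(ex_id, "-nb")
      n_cells <- rint(config$cells_range)
      nb <- read_notebook(list(
        nbformat = 4L, nbformat_minor = 5L,
        metadata = list(language_info = list(name = "python", version = "3.9.7")),
        cells = lapply(seq_len(n_cells), function(c) {
          list(cell_type = "code",
               source = CELL_SOURCES[[((c - 1) %% length(CELL_SOURCES)) + 1]])
        })
      ), id = nb_id)
      attr(nb, "base_iri") <- config$base_iri
      n_exec <- rint(config$execs_range)
      execs <- NULL
      t0 <- as.POSIXct(sprintf("2021-03-%02d 10:00:00", (i %% 27) + 1), tz = "UTC")
      for (k in seq_len(n_exec)) {
        cell_idx <- sample(n_cells, 1) - 1L
        dur <- sample(1:30, 1)
        execs <- record_execution(
          execs, nb, cell_idx, generated = paste0(nb_id, "-out", k),
          started_at = format(t0, "%Y-%m-%dT%H:%M:%S"),
          ended_at = format(t0 + dur, "%Y-%m-%dT%H:%M:%S"), seq = k
        )
        t0 <- t0 + dur + sample(5:60, 1)
      }
      g_nb <- notebook_to_graph(nb, execs)
      g_nb <- add_triples(g_nb, spo(paste0(config$base_iri, nb_id),
                                    "p-plan:isSubPlanOfPlan", E))
      graphs[[length(graphs) + 1]] <- g_nb
      notebooks[[nb_id]] <- list(nb = nb, executions = execs, experiment = E)
      # the notebook is a sub-plan of the experiment, so its cells belong to
      # the experiment's complete path
      path_truth[[length(path_truth)]]$steps[[1]] <-
        c(path_truth[[length(path_truth)]]$steps[[1]],
          paste0(config$base_iri, nb$cells$id))
      nb_truth[[length(nb_truth) + 1]] <- tibble(
        notebook = paste0(config$base_iri, nb_id),
        n_cells = n_cells,
        executions = list(tibble(
          execution = paste0(config$base_iri, execs$id),
          cell = paste0(config$base_iri, execs$cell),
          seq = execs$seq
        ))
      )
    }
  }

  graph <- if (length(graphs) == 0) {
    prov_graph(prefixes = c(prov_prefixes(), ex = config$base_iri))
  } else {
    Reduce(graph_union, graphs)
  }
  truth <- list(
    material_usage = if (length(usage)) {
      arrange(distinct(bind_rows(usage)), .data$material_label,
              .data$experiment, .data$step)
    } else {
      tibble(material_label = character(), experiment = character(),
             experiment_label = character(), step = character(),
             step_label = character())
    },
    notebook_paths = if (length(nb_truth)) bind_rows(nb_truth) else
      tibble(notebook = character(), n_cells = integer(), executions = list()),
    complete_paths = if (length(path_truth)) bind_rows(path_truth) else
      tibble(experiment = character(), agents = list(), steps = list(),
             instruments = list())
  )
  list(config = config, records = records, notebooks = notebooks,
       graph = graph, truth = truth)
}

#' Re-serialize an experiment record as a manifest list
#'
#' The inverse of [as_experiment()]; useful for writing generated
#' experiments back out as YAML manifests.
#'
#' @param e An `experiment_record`.
#' @return A nested manifest list.
#' @export
as_manifest <- function(e) {
  stopifnot(inherits(e, "experiment_record"))
  drop_na <- function(l) l[!vapply(l, function(v) length(v) == 0 ||
                                     (length(v) == 1 && is.na(v)), logical(1))]
  rows_as_list <- function(tb) {
    lapply(seq_len(nrow(tb)), function(i) {
      drop_na(lapply(as.list(tb[i, ]), function(v) {
        if (is.list(v)) as.list(v[[1]]) else v
      }))
    })
  }
  drop_na(list(
    base_iri = attr(e, "base_iri"),
    experiment = drop_na(list(
      id = e$meta$id, label = e$meta$label, hypothesis = e$meta$hypothesis,
      goals = as.list(e$goals), created_at = e$meta$created_at,
      modified_at = e$meta$modified_at
    )),
    plans = rows_as_list(e$plans), steps = rows_as_list(e$steps),
    agents = rows_as_list(e$agents), activities = rows_as_list(e$activities),
    instruments = rows_as_list(e$instruments),
    materials = rows_as_list(e$materials), settings = rows_as_list(e$settings),
    data = rows_as_list(e$data)
  ))
}

#' The colocalization fixture
#'
#' A deterministic two-experiment graph reproducing the worked material-usage
#' example: the experiments "Colocalization of EGFP-RAD51" and
#' "Colocalization of EGFP-RAD52 / mCherry-RAD54" each use the plasmid
#' "pCherry-RAD54" in their "Preparation" and "Transfection" steps, followed
#' by image acquisition on a configured confocal microscope.
#'
#' @return A [prov_graph()] that validates with zero findings.
#' @export
#' @examples
#' g <- fixture_colocalization()
#' steps_using_material(g, "pCherry-RAD54")
fixture_colocalization <- function() {
  base <- "https://example.org/coloc/"
  one <- function(ex_id, label, mic) {
    manifest <- list(
      base_iri = base,
      experiment = list(
        id = ex_id, label = label,
        hypothesis = "The tagged proteins colocalize at DNA damage sites",
        goals = list("Measure colocalization of the tagged repair proteins"),
        created_at = "2019-04-21T09:00:00"
      ),
      steps = list(
        list(id = paste0(ex_id, "-prep"), label = "Preparation",
             subtype = "NonComputational",
             inputs = list(paste0(ex_id, "-plasmid"), paste0(ex_id, "-cells"))),
        list(id = paste0(ex_id, "-transfection"), label = "Transfection",
             subtype = "NonComputational",
             preceded_by = paste0(ex_id, "-prep"),
             inputs = list(paste0(ex_id, "-plasmid"))),
        list(id = paste0(ex_id, "-acq"), label = "Image Acquisition",
             subtype = "NonComputational",
             preceded_by = paste0(ex_id, "-transfection"),
             outputs = list(paste0(ex_id, "-img")))
      ),
      agents = list(list(id = paste0(ex_id, "-agent1"), name = "A. Keller",
                         role = "Experimenter", orcid = "0000-0002-1825-0097")),
      instruments = list(
        list(id = paste0(ex_id, "-mic"), label = mic, subtype = "Microscope",
             settings = list(paste0(ex_id, "-set1"))),
        list(id = paste0(ex_id, "-obj"), label = "63x/1.40 Oil",
             subtype = "Objective", part_of = paste0(ex_id, "-mic"),
             settings = list(paste0(ex_id, "-set2")))
      ),
      materials = list(
        list(id = paste0(ex_id, "-plasmid"), label = "pCherry-RAD54",
             subtype = "Plasmid"),
        list(id = paste0(ex_id, "-cells"), label = "HeLa cells",
             subtype = "Specimen")
      ),
      settings = list(
        list(id = paste0(ex_id, "-set1"), subtype = "InstrumentSettings",
             key = "laser power", value = "2.5"),
        list(id = paste0(ex_id, "-set2"), subtype = "InstrumentSettings",
             key = "zoom", value = "1.0")
      ),
      data = list(list(id = paste0(ex_id, "-img"), label = "confocal image",
                       category = "RawData"))
    )
    experiment_to_graph(as_experiment(manifest))
  }
  graph_union(
    one("coloc-rad51", "Colocalization of EGFP-RAD51", "LSM 710"),
    one("coloc-rad52", "Colocalization of EGFP-RAD52 / mCherry-RAD54", "LSM 880")
  )
}
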