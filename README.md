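# provpath

End-to-end provenance for scientific experiments in R: a typed model of an
experiment's *complete path* — its computational **and** non-computational
steps, data, agents, instruments, settings and materials — expressed as
linked provenance under the REPRODUCE-ME extension of the W3C
[PROV-O](https://www.w3.org/TR/prov-o/) and
[P-Plan](http://purl.org/net/p-plan) ontologies
(namespace `https://w3id.org/reproduceme#`, prefix `repr`).

It is written for researchers and data stewards who need to describe how a
result was obtained — from specimen preparation on the bench through
notebook or script executions — in an interoperable, queryable form, and to
ask whether a second run of an experiment is a *repetition*, a
*reproduction* or a *reuse* of the first.

## What the package models

An experiment is the eight-component tuple

*E* = (Data, Agent, Activity, Plan, Step, Setting, Instrument, Material),

and a run of it is the variable tuple (CS, NCS, D, SP, S, EE, A, O, T, R, G,
H): computational/non-computational steps, data, procedures, settings,
execution environment, agents, order of execution, time, results, goal,
hypothesis. Repetition demands every condition except the time T unchanged;
reproduction is a change in one or more of {CS, NCS, D, S, EE, A, O}; reuse
is consumption of a run's data and results under a different goal.

The package provides:

* a machine-readable **term registry** of the full vocabulary (with the
  prospective/retrospective split for script and notebook provenance) and an
  **ontology emitter** (Turtle, RDF/XML, N3);
* an **experiment model** built from YAML/JSON manifests, with the
  **change classifier** and ordered complete-path reports;
* **RDF graphs as tibbles** of triples with serialization, parsing, and a
  basic-graph-pattern matcher used as the query engine;
* **notebook provenance** (nbformat v4 cells as plan steps; cell executions
  with timings as retrospective activities) and **script-run provenance**
  from JSON run-manifests (trials, function activations, module/OS/language
  versions, accessed files);
* **competency queries** (which steps used a material; the complete path of
  a notebook or an experiment), **structural validation** (rules R1–R7), and
  a **seeded synthetic generator** with independent ground truth;
* a CLI (`exec/provpath`) over the same functions.

## Worked example

The packaged colocalization fixture holds two plasmid-transfection imaging
experiments. Which steps of which experiments used the plasmid
`pCherry-RAD54`?

```r
library(provpath)
g <- fixture_colocalization()
steps_using_material(g, "pCherry-RAD54")[, c("experiment_label", "step_label")]
#> # A tibble: 4 × 2
#>   experiment_label                             step_label
#>   <chr>                                        <chr>
#> 1 Colocalization of EGFP-RAD51                 Preparation
#> 2 Colocalization of EGFP-RAD51                 Transfection
#> 3 Colocalization of EGFP-RAD52 / mCherry-RAD54 Preparation
#> 4 Colocalization of EGFP-RAD52 / mCherry-RAD54 Transfection
```

Two distinct experiments use the plasmid, in two distinct steps
(Preparation and Transfection) — the material is traceable through
`p-plan:isInputVarOf` links from the material node to the steps and up the
plan hierarchy to the experiments.

An experiment manifest builds a record whose path is ordered by plan nesting
and `preceded_by` chains:

```r
e <- read_experiment(system.file("extdata", "experiment-example.yaml",
                                 package = "provpath"))
complete_path(e)
#> Complete path of exp1 - Colocalization test
#> Agents:
#>   Alice [Experimenter]
#> Steps:
#>   1. Preparation (NonComputationalStep)
#>   2. Transfection (NonComputationalStep)
#>   3. Image Acquisition (ComputationalStep)
#> Instruments: LSM 880, 63x
```

`experiment_to_graph(e)` turns the record into RDF (and
`experiments_from_graph()` inverts it exactly):

```turtle
ex:a1 a prov:Agent, repr:Experimenter ;
    rdfs:label "Alice" ;
    repr:orcid "0000-0001-2345-678X" .
```

The methods vignette (`vignettes/provenance-model.Rmd`) documents the model,
the mapping patterns, the classifier semantics, validation rules, the
generator's stated world, and the design decisions taken where the model was
open.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the colocalization fixture with the package's own functions, runs
the material-usage competency query for `pCherry-RAD54`, and writes the
number of distinct experiments returned (with the fixture's triple count as
problem size) as JSON.

## CLI

```sh
exec/provpath ontology emit -f turtle
exec/provpath convert inst/extdata/experiment-example.yaml -o exp.ttl
exec/provpath validate exp.ttl
exec/provpath query steps_using_material --bind label=pCherry-RAD54 exp.ttl
exec/provpath notebook extract inst/extdata/notebook-example.ipynb
exec/provpath script build inst/extdata/trial-example.json -o trial.ttl
exec/provpath generate --seed 1 --experiments 3 -o out/
```
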