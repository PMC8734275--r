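---
title: "Modelling the complete path of a scientific experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the complete path of a scientific experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provpath)
library(dplyr)
```

## The problem

Reproducing a laboratory experiment requires far more than the script and the
data: the specimen and its origin, the plasmid transfected, the microscope and
its objective, the laser power, the order of bench steps, the people involved
and their roles, and — for the computational part — the notebook cells or
script functions that ran, in which order, under which language, module and OS
versions. provpath represents this *complete path* as linked provenance under
the REPRODUCE-ME extension of the W3C PROV-O and P-Plan ontologies
(namespace `https://w3id.org/reproduceme#`, prefix `repr`), and makes the
resulting graphs queryable and checkable from R.

## The experiment model

An experiment is an eight-component tuple:

\[
E = (\mathit{Data}, \mathit{Agent}, \mathit{Activity}, \mathit{Plan},
     \mathit{Step}, \mathit{Setting}, \mathit{Instrument}, \mathit{Material})
\]

`as_experiment()` builds a typed record of these components from a YAML/JSON
manifest and enforces the structural invariants: steps reference declared
plans, `preceded_by` chains and instrument part relations are acyclic, step
inputs/outputs resolve to declared data items or materials, subtypes come from
the enumerated classifications (8 plan kinds, 4 step kinds, 7 settings,
7 instruments, 4 materials, 12 agent roles, the data classification with its
result subtypes), ORCIDs are syntactically valid, and activities end no
earlier than they start.

The RDF mapping (`experiment_to_graph()`) follows the ontology's patterns:
`p-plan:isStepOfPlan` and `p-plan:isSubPlanOfPlan` for structure,
`p-plan:isInputVarOf` / `p-plan:isOutputVarOf` for step variables,
`repr:usedMethod` for methods, `repr:hasPart`/`repr:isPartOf` (both
directions materialized) for instrument parts, `repr:hasSetting` for
settings, `prov:wasAttributedTo` plus the `repr:orcid` literal for agents,
`repr:doi`/`repr:pubmedid`/`repr:pmcid` for publications, and
`prov:generatedAtTime` / `repr:modifiedAtTime` for timestamps. Blank nodes
are never minted — every record receives an IRI under the record's base —
which keeps round trips exact and query joins stable.

```{r}
e <- read_experiment(system.file("extdata", "experiment-example.yaml",
                                 package = "provpath"))
glance(e)
complete_path(e)
```

## Reproducibility, repeatability, reuse

A *run* is the variable tuple (CS, NCS, D, SP, S, EE, A, O, T, R, G, H):
computational and non-computational steps, data, procedures, settings,
execution environment, agents, order, time, results, goal, hypothesis.
`classify_change()` compares two runs variable by variable:

* **repetition** — every condition except the time T unchanged;
* **reproduction** — one or more of {CS, NCS, D, S, EE, A, O} changed
  (T alone never triggers it: time may always vary);
* **reuse** — the goal differs but the first run's data and results are
  consumed by the second;
* **incomparable** — no goals or hypotheses on either side and disjoint
  results.

Because the model does not define equality for steps, settings or
environments, members are compared by canonical fingerprint: lists are
key-sorted recursively and hashed, sets are compared order-insensitively.
This makes the comparison deterministic and insensitive to serialization
order, at the price of treating any textual difference as a change. *Result
closeness is deliberately not judged*: whether results are "the same or
similar" is a scientific question the caller must answer; the classifier only
reports which variables changed.

```{r}
a <- experiment_run(cs = "sha1:9f2c", data = "idr0041", ee = list(os = "CentOS 7"),
                    time = "2021-05-04", goal = "measure colocalization")
b <- a; b$ee$os <- "Ubuntu 22.04"; class(b) <- "experiment_run"
classify_change(a, b)
```

## Notebook and script provenance

The prospective side of a computational notebook is its plan: the notebook is
a `p-plan:Plan`, each cell a step (`repr:Cell`), and each cell's source text
an input variable (`repr:Source`) carrying the text as `rdf:value`. The
retrospective side records what actually happened: each run of a cell is a
`repr:CellExecution` with `prov:used` / `prov:generated` entities,
`prov:startedAtTime`, `prov:endedAtTime`, and `repr:executionTime` — defined
as end minus start. **Units of `repr:executionTime` are seconds** (stored as
`xsd:decimal`); the ontology leaves the unit undeclared, so the choice is
documented here and applied consistently.

No live kernel is instrumented: executions are recorded through
`record_execution()` by replaying logged events, which keeps the module
deterministic and testable. Each execution carries a per-trial monotonic
sequence number (`repr:sequenceNumber`, a toolkit extension term) because
notebook execution counts can repeat across sessions and cells can run in any
order — `derivation_of()` orders chains by sequence number, not cell index.

Script runs follow the same split from a JSON run-manifest
(`build_trial()`): `repr:Script` and `repr:Function` are plans;
`repr:Trial` is the activity that `prov:used` the script; function
activations are steps ordered by `p-plan:isPrecededBy` exactly as the
manifest lists them; modules, the language and the OS carry `repr:Version`
setting nodes; accessed files, the experimenter (`prov:wasAssociatedWith`)
and the location (`prov:atLocation`, stored verbatim — host paths and
geographic names are both legal) complete the environment.

## Queries

The competency questions are parameterized basic-graph-pattern queries over
the triples tibble (`match_bgp()` joins patterns on shared variables exactly
as a SPARQL engine would; no SPARQL engine for R exists in this stack, so the
package carries its own matcher). The complete-path question is assembled
from sub-queries merged in code rather than one monolithic pattern — the
same splitting that large knowledge bases force on the SPARQL side to avoid
cross-product row explosions — and a test asserts the two strategies agree.
Material labels are matched exactly, with an opt-in case-insensitive flag.

```{r}
g <- fixture_colocalization()
steps_using_material(g, "pCherry-RAD54")
```

## Validation

`validate_graph()` checks the structural shapes the patterns imply: cells
belong to notebooks (R1), executions carry exactly one ordered start/end pair
(R2), step I/O nodes are typed as variables through the registered subclass
closure (R3), the step order is grounded and acyclic (R4), and every
repr-namespace term is registered (R5). Missing attribution (R6) and
instruments without settings (R7) *warn* rather than fail — real knowledge
bases routinely miss optional provenance, and a hard failure there would
reject usable graphs. Rules are held as declarative objects (id, severity,
check) in a list, so domain extensions can append rules without touching the
package.

## Design choices where the model was open

* **`CellExecution`'s superclass** is printed as `p-plan:Activity` while PROV
  defines `Activity`; the registry records the printed superclass and relies
  on the (genuine) P-Plan axiom `p-plan:Activity ⊑ prov:Activity` as the
  bridge, so closure-based queries accept both readings without asserting
  either as the model's intent.
* **`repr:Version` is one class** backing module, language and OS versions;
  context comes from the node linked via `repr:hasSetting`, matching the
  printed term table.
* **No domain/range for `repr:hasSetting`.** The prose statement "each
  instrument and its parts have settings" describes usage, not an axiom;
  asserting `rdfs:domain repr:Instrument` would make every module or language
  with a version an inferred instrument. The emitter therefore leaves
  domain/range off where the model is not explicit, avoiding
  over-axiomatization.
* **Experiment–instrument and experiment–activity links.** The model states
  instruments and activities belong to an experiment but prints no linking
  property; the mapping uses `prov:used` from the experiment node for
  instruments/materials and `dcterms:isPartOf` for activities — both standard
  vocabulary, both documented here rather than minted ad hoc.
* **Extension terms.** `repr:goal`, `repr:hypothesis`, `repr:sequenceNumber`,
  `repr:index` and `repr:precondition` are registered as toolkit extensions
  (provenance category "not-applicable") because the model names these
  attributes without printing properties for them.
* **Both variable directions parse.** The patterns use `isInputVarOf` in one
  place and `hasInputVar` in another; the mapping emits the former
  canonically and accepts both on parse, materializing the inverse.

## The synthetic generator

`generate_provenance()` emulates what a microscopy knowledge base holds:
experiments with 2–5 ordered bench/analysis steps, 1–2 agents (always
including an experimenter with an ORCID), one confocal microscope with 1–2
parts where every instrument node carries a setting (laser power, gain,
pinhole ... with numeric values), 1–3 materials drawn from a
plasmid/chemical/solution/specimen palette, a raw image output, and — for
about half the experiments — a Python notebook with 2–4 cells and 1–4 timed
cell executions. These defaults are the package's stated world: small enough
that every fixture stays well under 10³ triples and sub-second, rich enough
to exercise every modelling pattern. Labels reuse the vocabulary of the
model's own worked examples (plasmid transfection and confocal imaging) so
fixtures read like real records.

Ground truth (which material was planted into which step, which executions a
notebook holds, which agents/steps/instruments an experiment carries) is
recorded *while planting* and never recomputed from the graph, so it is an
independent oracle for the queries. What a green test establishes is
soundness and completeness of the pipeline on well-formed, fully-described
records; the generator deliberately does not emulate the messiness of real
repositories — missing metadata, free-text labels, multi-plan step sharing —
so query behaviour on degraded data is exercised separately by the planted
violation fixtures, not by the generator.

The deterministic `fixture_colocalization()` rebuilds the worked example: two
experiments ("Colocalization of EGFP-RAD51" and "Colocalization of
EGFP-RAD52 / mCherry-RAD54") each using the plasmid "pCherry-RAD54" in their
"Preparation" and "Transfection" steps, so the material-usage query returns
two distinct experiments and two distinct step labels.

## Numerical and procedural notes

* Timestamps are ISO-8601 strings typed `xsd:dateTime`; durations are
  seconds as `xsd:decimal`. Time parsing assumes UTC.
* Serializations: Turtle, RDF/XML and N3 (emitted as the Turtle-compatible
  subset, so every N3 document is also valid Turtle). Round trips are
  graph-isomorphic; blank nodes, if present in foreign input, are compared by
  iterative signature refinement, which is exact for tree-shaped blank
  structures.
* Step ordering in `complete_path()` is plan-nesting depth-first, then
  `preceded_by` within each plan, with manifest order as the stable
  tie-break — the model shows both sub-plan nesting and step order without
  stating their interleaving.
* The ontology consistency check is an RDFS-level closure (transitive
  subclass reachability into `owl:Nothing`), not a DL reasoner; the emitted
  ontology stays inside the subclass/annotation fragment where that check is
  complete.

## Limitations

* SPARQL endpoints, OBDA mappings and named-graph bundles are out of scope;
  graphs live in memory at desk scale.
* The serializers cover the syntax subset the package emits plus common
  variants (comments, numeric/boolean literals, language tags, long strings,
  both `rdf:Description` and typed-node RDF/XML); they are not a
  full-specification RDF stack.
* Understandability of an experiment is reported only as metadata presence
  (validation warnings); whether provenance suffices for a human to
  understand a result is community-defined and not mechanically checkable.
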