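# Repetition / reproduction / reuse classification of experiment runs.
#
# A run is the variable tuple of the experiment definition: computational
# steps CS, non-computational steps NCS, data D, standardized procedures SP,
# settings S, execution environment EE, agents A, order O, time T, results R,
# goal G and hypothesis H. Repetition demands every condition except T
# unchanged; reproduction is a change in one or more of
# {CS, NCS, D, S, EE, A, O}; reuse is consumption of a run's data and results
# under a different goal. Equality of steps, data and settings is not defined
# by the model, so members are compared by canonical fingerprint
# (key-sorted serialization, hashed) — deterministic and order-insensitive.

#' Construct an experiment run
#'
#' @param cs Character set of computational-step fingerprints (e.g. script
#'   content hashes or step identifiers).
#' @param ncs Character set of non-computational-step fingerprints.
#' @param data Character set identifying the data items used.
#' @param procedures Character set of standardized-procedure identifiers.
#' @param settings Named list (or character set) of settings.
#' @param ee Named list describing the execution environment (OS, versions,
#'   hardware ...).
#' @param agents Character set of agent identities.
#' @param order Character vector: the step sequence actually performed.
#' @param time Timestamp of the run (any scalar; compared by identity).
#' @param results Character set identifying the results generated.
#' @param goal Goal of the run (scalar string or NA).
#' @param hypothesis Hypothesis (scalar string or NA).
#' @return An object of class `experiment_run`.
#' @export
experiment_run <- function(cs = character(), ncs = character(),
                           data = character(), procedures = character(),
                           settings = list(), ee = list(),
                           agents = character(), order = character(),
                           time = NA, results = character(),
                           goal = NA_character_, hypothesis = NA_character_) {
  structure(
    list(cs = as.character(cs), ncs = as.character(ncs),
         data = as.character(data), procedures = as.character(procedures),
         settings = settings, ee = ee, agents = as.character(agents),
         order = as.character(order), time = time,
         results = as.character(results),
         goal = goal, hypothesis = hypothesis),
    class = "experiment_run"
  )
}

# canonical fingerprint: recursively sort names, then hash
canonical_fingerprint <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else if (is.null(names(v)) && length(v) > 1 && is.atomic(v)) {
      sort(as.character(v))
    } else {
      v
    }
  }
  digest::digest(canon(x))
}

#' Classify the change between two experiment runs
#'
#' Compares the runs variable by variable over
#' \{CS, NCS, D, S, EE, A, O, T\} and applies the definitional semantics:
#' `repetition` when nothing but the time differs, `reuse` when the goal
#' differs but the first run's data and results are consumed by the second,
#' `incomparable` when goals and hypotheses are absent on both sides and the
#' results are disjoint, otherwise `reproduction`. Result closeness is not
#' judged: the classifier reports which variables changed, never whether the
#' outcome is scientifically equivalent.
#'
#' @param a,b [experiment_run()] objects.
#' @return An object of class `repro_verdict` with fields `classification`,
#'   `changed_variables` and `notes`.
#' @export
#' @examples
#' a <- experiment_run(cs = "c1", data = "d1", time = 1, goal = "g")
#' classify_change(a, a)$classification  # "repetition"
classify_change <- function(a, b) {
  stopifnot(inherits(a, "experiment_run"), inherits(b, "experiment_run"))
  changed <- character(0)
  if (!setequal(a$cs, b$cs)) changed <- c(changed, "CS")
  if (!setequal(a$ncs, b$ncs)) changed <- c(changed, "NCS")
  if (!setequal(a$data, b$data)) changed <- c(changed, "D")
  if (canonical_fingerprint(a$settings) != canonical_fingerprint(b$settings)) {
    changed <- c(changed, "S")
  }
  if (canonical_fingerprint(a$ee) != canonical_fingerprint(b$ee)) {
    changed <- c(changed, "EE")
  }
  if (!setequal(a$agents, b$agents)) changed <- c(changed, "A")
  if (!identical(a$order, b$order)) changed <- c(changed, "O")
  if (!identical(a$time, b$time)) changed <- c(changed, "T")

  goal_differs <- !identical(a$goal, b$goal)
  consumes <- length(intersect(union(a$data, a$results), b$data)) > 0
  nothing_to_compare <- is.na(a$goal) && is.na(b$goal) &&
    is.na(a$hypothesis) && is.na(b$hypothesis) &&
    length(intersect(a$results, b$results)) == 0

  if (length(setdiff(changed, "T")) == 0) {
    cls <- "repetition"
    note <- "all conditions except time unchanged"
  } else if (goal_differs && consumes) {
    cls <- "reuse"
    note <- "data and results consumed under a different goal"
  } else if (nothing_to_compare) {
    cls <- "incomparable"
    note <- "no goal or hypothesis on either side and results are disjoint"
  } else {
    cls <- "reproduction"
    note <- paste("variables changed:", paste(setdiff(changed, "T"), collapse = ", "))
  }
  structure(
    list(classification = cls, changed_variables = sort(changed), notes = note),
    class = "repro_verdict"
  )
}

#' @export
print.repro_verdict <- function(x, ...) {
  cat("<repro_verdict>", x$classification, "\n")
  cat("  changed: {", paste(x$changed_variables, collapse = ", "), "}\n")
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Tidy a reproducibility verdict
#' @param x A [classify_change()] result.
#' @param ... Unused.
#' @return One-row tibble with the classification and changed variables.
#' @method tidy repro_verdict
#' @export
tidy.repro_verdict <- function(x, ...) {
  tibble(classification = x$classification,
         changed_variables = list(x$changed_variables),
         n_changed = length(x$changed_variables),
         notes = x$notes)
}
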