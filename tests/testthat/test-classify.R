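# The change classifier against the definitional semantics: repetition iff
# nothing but time differs, reproduction on any change among the eight
# variables, reuse under a changed goal with consumed data/results.

base_run <- function(...) {
  args <- list(...)
  defaults <- list(
    cs = c("script-hash-1"), ncs = c("prep", "transfect"),
    data = c("d1", "d2"), procedures = "sop-1",
    settings = list(laser = 0.5, gain = 2), ee = list(os = "CentOS 7", r = "4.3"),
    agents = "alice", order = c("prep", "transfect", "analyse"),
    time = "2021-05-04T10:00:00", results = c("r1"),
    goal = "measure colocalization", hypothesis = "H1"
  )
  defaults[names(args)] <- args
  do.call(experiment_run, defaults)
}

# single-variable mutations of the base run
mutations <- list(
  CS = function(r) { r$cs <- "script-hash-2"; r },
  NCS = function(r) { r$ncs <- c("prep", "stain"); r },
  D = function(r) { r$data <- c("d1", "d3"); r },
  S = function(r) { r$settings$laser <- 0.9; r },
  EE = function(r) { r$ee$os <- "Ubuntu 22.04"; r },
  A = function(r) { r$agents <- "bob"; r },
  O = function(r) { r$order <- c("transfect", "prep", "analyse"); r },
  T = function(r) { r$time <- "2022-01-01T08:00:00"; r }
)

test_that("identity and time-only changes are repetitions", {
  a <- base_run()
  v <- classify_change(a, a)
  expect_equal(v$classification, "repetition")
  expect_length(v$changed_variables, 0L)

  b <- mutations$T(base_run())
  v <- classify_change(a, b)
  expect_equal(v$classification, "repetition")
  expect_equal(v$changed_variables, "T")
})

test_that("each single condition change yields a reproduction naming that variable", {
  a <- base_run()
  for (var in setdiff(names(mutations), "T")) {
    b <- mutations[[var]](base_run())
    v <- classify_change(a, b)
    expect_equal(v$classification, "reproduction", label = var)
    expect_equal(v$changed_variables, var)
  }
})

test_that("the classifier reproduces the definitional truth table on all variable pairs", {
  # brute-force oracle: the expected changed set is the set of mutations
  # applied; classification follows directly from that set
  a <- base_run()
  vars <- names(mutations)
  combos <- c(lapply(vars, identity), combn(vars, 2, simplify = FALSE))
  for (combo in combos) {
    b <- base_run()
    for (var in combo) b <- mutations[[var]](b)
    v <- classify_change(a, b)
    expect_setequal(v$changed_variables, combo)
    expected <- if (length(setdiff(combo, "T")) == 0) "repetition" else "reproduction"
    expect_equal(v$classification, expected,
                 label = paste(combo, collapse = "+"))
  }
})

test_that("changed_variables is symmetric and empty on self-comparison", {
  for (seed in 1:5) {
    set.seed(seed)
    b <- base_run()
    for (var in sample(names(mutations), sample(3, 1))) b <- mutations[[var]](b)
    a <- base_run()
    expect_setequal(classify_change(a, b)$changed_variables,
                    classify_change(b, a)$changed_variables)
  }
  r <- base_run()
  expect_equal(classify_change(r, r)$classification, "repetition")
})

test_that("consuming data and results under a different goal is reuse", {
  a <- base_run()
  b <- base_run(goal = "benchmark segmentation pipeline",
                data = c("d1", "r1"),      # consumes a's data and results
                agents = "carol", ee = list(os = "Ubuntu"))
  v <- classify_change(a, b)
  expect_equal(v$classification, "reuse")
  expect_true(all(c("D", "A", "EE") %in% v$changed_variables))
})

test_that("runs with no goals, hypotheses or shared results are incomparable", {
  a <- base_run(goal = NA_character_, hypothesis = NA_character_, results = "r1")
  b <- base_run(goal = NA_character_, hypothesis = NA_character_,
                results = "r9", data = "other")
  expect_equal(classify_change(a, b)$classification, "incomparable")
})

test_that("verdicts tidy into one-row summaries", {
  td <- tidy(classify_change(base_run(), mutations$EE(base_run())))
  expect_equal(td$n_changed, 1L)
  expect_equal(td$changed_variables[[1]], "EE")
})
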