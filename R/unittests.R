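#' Generate replay unit tests from a completed run
#'
#' For every executed rule, one test case is emitted: a directory bundling
#' copies of one representative job's input files, the concrete action
#' text, and the expected outputs, plus a runnable testthat file that
#' replays the action in a sandbox and compares every output byte-by-byte
#' against the expectation. Dropping a `compare.R` file into a case
#' directory (defining `compare(actual, expected)` returning `TRUE`/
#' `FALSE`) overrides the byte comparison for that rule. Target rules
#' (no outputs) yield no test.
#'
#' @param report an `fk_run_report` from a successful [run_workflow()];
#'   inputs and outputs must still be on disk.
#' @param output_dir directory the suite is written to.
#' @param workdir working directory of the run the report came from.
#' @return invisibly, a character vector of the emitted test file paths.
#' @export
generate_unit_tests <- function(report, output_dir, workdir = ".") {
  stopifnot(inherits(report, "fk_run_report"), !isTRUE(report$dry_run))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  emitted <- character(0)
  seen_rules <- character(0)
  for (rec in report$provenance) {
    if (rec$rule %in% seen_rules) next
    if (!length(rec$outputs)) next  # target rule
    if (isTRUE(rec$cache_hit)) next
    seen_rules <- c(seen_rules, rec$rule)
    case_dir <- file.path(output_dir, paste0("case-", rec$rule))
    dir.create(file.path(case_dir, "expected"), recursive = TRUE,
               showWarnings = FALSE)
    for (f in c(rec$inputs, rec$outputs)) {
      src <- file.path(workdir, f)
      if (!file.exists(src))
        stop("cannot generate test for rule '", rec$rule, "': file '", f,
             "' is no longer on disk", call. = FALSE)
    }
    for (f in rec$inputs) {
      dst <- file.path(case_dir, "inputs", f)
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      file.copy(file.path(workdir, f), dst)
    }
    for (f in rec$outputs) {
      dst <- file.path(case_dir, "expected", f)
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      file.copy(file.path(workdir, f), dst)
    }
    writeLines(rec$action, file.path(case_dir, "cmd.sh"))
    writeLines(jsonlite::toJSON(list(rule = rec$rule, inputs = rec$inputs,
                                     outputs = rec$outputs),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(case_dir, "case.json"))
    test_file <- file.path(output_dir, paste0("test-", rec$rule, ".R"))
    writeLines(.replay_test_source(rec$rule), test_file)
    emitted <- c(emitted, test_file)
  }
  writeLines(.replay_helper_source(), file.path(output_dir, "helper-replay.R"))
  invisible(emitted)
}

.replay_helper_source <- function() {
  c("# generated replay harness: executes a recorded rule action in a",
    "# sandbox and compares outputs byte-by-byte (override with a",
    "# compare.R in the case directory defining compare(actual, expected))",
    "replay_case <- function(case_dir) {",
    "  case <- jsonlite::read_json(file.path(case_dir, 'case.json'))",
    "  sandbox <- file.path(tempfile('replay-'))",
    "  dir.create(sandbox, recursive = TRUE)",
    "  on.exit(unlink(sandbox, recursive = TRUE))",
    "  for (f in unlist(case$inputs)) {",
    "    dst <- file.path(sandbox, f)",
    "    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)",
    "    file.copy(file.path(case_dir, 'inputs', f), dst)",
    "  }",
    "  cmd <- paste(readLines(file.path(case_dir, 'cmd.sh')),",
    "               collapse = '\\n')",
    "  for (f in unlist(case$outputs))",
    "    dir.create(file.path(sandbox, dirname(f)), recursive = TRUE,",
    "               showWarnings = FALSE)",
    "  status <- run_in_dir(sandbox, cmd)",
    "  cmp_path <- file.path(case_dir, 'compare.R')",
    "  cmp <- NULL",
    "  if (file.exists(cmp_path)) {",
    "    e <- new.env(); sys.source(cmp_path, e); cmp <- e$compare",
    "  }",
    "  results <- logical(0)",
    "  for (f in unlist(case$outputs)) {",
    "    actual <- file.path(sandbox, f)",
    "    expected <- file.path(case_dir, 'expected', f)",
    "    results[[f]] <- if (!file.exists(actual)) FALSE",
    "    else if (!is.null(cmp)) isTRUE(cmp(actual, expected))",
    "    else identical(readBin(actual, 'raw', file.size(actual)),",
    "                   readBin(expected, 'raw', file.size(expected)))",
    "  }",
    "  list(status = status, outputs = results)",
    "}",
    "run_in_dir <- function(dir, cmd) {",
    "  old <- setwd(dir)",
    "  on.exit(setwd(old))",
    "  system2('sh', c('-c', shQuote(cmd)), stdout = FALSE, stderr = FALSE)",
    "}")
}

.replay_test_source <- function(rule) {
  c(sprintf("test_that(\"rule %s reproduces its recorded outputs\", {", rule),
    sprintf("  res <- replay_case(file.path(test_path(), 'case-%s'))", rule),
    "  expect_identical(res$status, 0L)",
    "  for (f in names(res$outputs))",
    "    expect_true(res$outputs[[f]], label = paste('output', f))",
    "})")
}

#' Run a generated replay suite outside testthat
#'
#' Convenience runner: replays every case in `dir` and returns a
#' data.frame of per-rule pass/fail, independent of the testthat harness.
#'
#' @param dir directory written by [generate_unit_tests()].
#' @return data.frame with columns `rule` and `pass`.
#' @export
run_replay_suite <- function(dir) {
  helper <- file.path(dir, "helper-replay.R")
  e <- new.env()
  sys.source(helper, e)
  cases <- list.dirs(dir, recursive = FALSE)
  cases <- cases[grepl("case-", basename(cases))]
  out <- data.frame(rule = sub("^case-", "", basename(cases)),
                    pass = NA, stringsAsFactors = FALSE)
  for (i in seq_along(cases)) {
    res <- e$replay_case(cases[i])
    out$pass[i] <- identical(res$status, 0L) && all(unlist(res$outputs))
  }
  out
}
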