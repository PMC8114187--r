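test_that("the example workflow runs end-to-end with temp cleanup", {
  wd <- local_workdir()
  fx <- generate_fig3_like(3, seed = 7, dir = wd)
  planned <- run_workflow(fx$workflow, "all", workdir = wd, dry_run = TRUE)
  expect_true(planned$dry_run)
  # dry run created nothing beyond the fixture data
  expect_false(dir.exists(file.path(wd, "results")))
  plan_jobs <- unlist(lapply(planned$plan, `[[`, "jobs"))
  expect_equal(anyDuplicated(plan_jobs), 0)  # every job exactly once
  expect_length(plan_jobs, fx$n_jobs)

  rep <- run_workflow(fx$workflow, "all", capacities = c(cores = 2L),
                      workdir = wd)
  expect_true(rep$ok)
  for (cc in fx$countries)
    expect_true(file.exists(file.path(wd, sprintf("plots/%s.pdf", cc))))
  # executed DAG matches the planned DAG
  expect_identical(dag_to_dot(rep$dag), dag_to_dot(planned$dag))
  expect_setequal(names(rep$status), plan_jobs)
  # temporary per-country extracts were deleted once consumed
  expect_setequal(rep$deleted_temporaries,
                  sprintf("results/by-country/%s.csv", fx$countries))
  expect_false(any(file.exists(file.path(
    wd, sprintf("results/by-country/%s.csv", fx$countries)))))
})

test_that("provenance records carry the executed action text verbatim", {
  wd <- local_workdir()
  fx <- generate_fig3_like(2, seed = 3, dir = wd)
  rep <- run_workflow(fx$workflow, "all", workdir = wd)
  for (jid in names(rep$status)[rep$status == "finished"]) {
    job <- rep$dag$jobs[[jid]]
    if (!nzchar(job$action)) next
    expect_identical(rep$provenance[[jid]]$action, job$action)
  }
  # the provenance document validates against the shipped schema
  path <- file.path(wd, "prov.json")
  write_provenance(rep, path)
  doc <- jsonlite::read_json(path)
  schema <- system.file("schema", "provenance.schema.json",
                        package = "flowkern")
  expect_length(schema_violations(doc, schema), 0)
  expect_length(doc$jobs, sum(rep$status %in% c("finished", "cached")))
})

test_that("job failures cancel dependents and leave no partial outputs", {
  wd <- local_workdir()
  wf <- parse_workflow("
rules:
  boom:
    output: x.txt
    shell: 'echo partial > {output}; exit 1'
  down:
    input: x.txt
    output: y.txt
    shell: 'cp {input} {output}'
")
  expect_error(run_workflow(wf, "y.txt", workdir = wd), "boom")
  expect_false(file.exists(file.path(wd, "x.txt")))
  expect_false(file.exists(file.path(wd, "y.txt")))
  # keep-going mode: independent work still completes
  wf2 <- parse_workflow("
rules:
  all: {input: [good.txt, bad_dep.txt]}
  bad: {output: badfile.txt, shell: 'exit 1'}
  baddep: {input: badfile.txt, output: bad_dep.txt,
           shell: 'cp {input} {output}'}
  good: {output: good.txt, shell: 'echo fine > {output}'}
")
  rep <- run_workflow(wf2, "all", workdir = wd, keep_going = TRUE)
  expect_false(rep$ok)
  expect_true(file.exists(file.path(wd, "good.txt")))
  expect_equal(unname(rep$status[["bad"]]), "failed")
  expect_equal(unname(rep$status[["baddep"]]), "cancelled")
})

test_that("benchmark records report wall-clock seconds per job", {
  wd <- local_workdir()
  wf <- parse_workflow("
rules:
  slow:
    output: s.txt
    shell: 'sleep 0.2; echo done > {output}'
")
  rep <- run_workflow(wf, "s.txt", workdir = wd)
  bm <- rep$benchmarks[["slow"]]
  expect_gte(bm$seconds, 0.2)
  expect_lt(bm$seconds, 30)
})

test_that("log declarations capture a job's output stream", {
  wd <- local_workdir()
  wf <- parse_workflow("
rules:
  noisy:
    output: 'o/{x}.txt'
    log: 'logs/{x}.log'
    shell: 'echo to-log; echo payload > {output}'
")
  rep <- run_workflow(wf, "o/a.txt", workdir = wd)
  expect_true(rep$ok)
  expect_identical(readLines(file.path(wd, "logs/a.log")), "to-log")
})

test_that("checkpoints expand the DAG mid-run", {
  wd <- local_workdir()
  cp <- generate_checkpoint_workflow(dir = wd, n_rows = 5,
                                     pass_fraction = 0.4, seed = 3)
  rep <- run_workflow(cp$workflow, "results/summary.txt", workdir = wd)
  expect_true(rep$ok)
  expect_equal(sum(grepl("^process", names(rep$status))), 2)
  expect_equal(length(readLines(file.path(wd, "results/summary.txt"))), 2)
})

test_that("temporary files survive while any consumer is unfinished", {
  # three consumers of one temp file: after two finish it must persist
  jobs <- list(
    mk_job("src", outputs = "t.dat", temp = TRUE),
    mk_job("c1", inputs = "t.dat", outputs = "o1"),
    mk_job("c2", inputs = "t.dat", outputs = "o2"),
    mk_job("c3", inputs = "t.dat", outputs = "o3"))
  edges <- data.frame(parent = "src", child = c("c1", "c2", "c3"),
                      file = "t.dat", stringsAsFactors = FALSE)
  dag <- mk_dag(jobs, edges)
  st <- flowkern:::.new_state(dag, c(cores = 1L))
  st$status[c("src", "c1", "c2")] <- "finished"
  st$temp[["t.dat"]]$present <- TRUE
  expect_length(delete_eligible_temporaries(st, dag, physical = FALSE), 0)
  st$status[["c3"]] <- "finished"
  expect_equal(delete_eligible_temporaries(st, dag, physical = FALSE),
               "t.dat")
  # repeated calls do not re-delete
  expect_length(delete_eligible_temporaries(st, dag, physical = FALSE), 0)
})

test_that("randomized concurrent simulations never delete prematurely", {
  t0 <- Sys.time()
  for (s in 1:100) {
    dag <- generate_random_dag(sample(5:14, 1), seed = s,
                               temp_density = 0.5)
    cap <- c(cores = 2L + s %% 3)
    sim <- simulate_run(dag, capacities = cap, seed = s + 1000)
    expect_true(all(sim$status == "finished"))
    oracle <- replay_events(sim$events, dag, cap)
    expect_true(oracle$ok, info = paste("seed", s,
                                        paste(oracle$violations,
                                              collapse = "; ")))
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})

test_that("generated unit tests replay and detect perturbations", {
  t0 <- Sys.time()
  wd <- local_workdir()
  fx <- generate_fig3_like(2, seed = 7, dir = wd, temps = FALSE)
  rep <- run_workflow(fx$workflow, "all", workdir = wd)
  suite <- file.path(wd, "unit-tests")
  generate_unit_tests(rep, suite, workdir = wd)
  # one case per executed rule with outputs; the target rule yields none
  expect_setequal(basename(list.files(suite, pattern = "^test-.*\\.R$")),
                  paste0("test-", c("get_data", "select_by_country",
                                    "plot_histogram", "convert_to_pdf"),
                         ".R"))
  res <- run_replay_suite(suite)
  expect_true(all(res$pass))
  # perturb one rule's action: exactly that rule's test fails
  cmd_file <- file.path(suite, "case-plot_histogram", "cmd.sh")
  writeLines(sub("250000", "50000", readLines(cmd_file)), cmd_file)
  res2 <- run_replay_suite(suite)
  expect_equal(res2$rule[!res2$pass], "plot_histogram")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})

test_that("scheduling rounds respect capacities end to end", {
  # replay oracle over a simulated grouped execution
  dag <- generate_random_dag(12, seed = 2, temp_density = 0.3)
  sim <- simulate_run(dag, capacities = c(cores = 3L), seed = 5)
  oracle <- replay_events(sim$events, dag, c(cores = 3L))
  expect_true(oracle$ok)
  # every temp file was deleted by run end
  produced_temps <- names(sim$temp)[vapply(sim$temp, `[[`, NA, "present")]
  expect_true(all(vapply(sim$temp[produced_temps], `[[`, NA, "deleted")))
})
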