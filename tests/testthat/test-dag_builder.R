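test_that("producer resolution follows the ambiguity cascade", {
  wf <- parse_workflow("
ruleorder: [[special, generic]]
rules:
  generic:
    output: '{name}.txt'
    shell: 'echo g > {output}'
  special:
    output: a.txt
    shell: 'echo s > {output}'
")
  # ruleorder decides first
  expect_equal(resolve_producer("a.txt", wf)$rule$name, "special")
  # without ruleorder: higher priority, then fewer wildcards, then order
  wf2 <- parse_workflow("
rules:
  generic:
    output: '{name}.txt'
    priority: 5
    shell: 'echo g > {output}'
  special:
    output: a.txt
    shell: 'echo s > {output}'
")
  expect_equal(resolve_producer("a.txt", wf2)$rule$name, "generic")
  wf3 <- parse_workflow("
rules:
  generic:
    output: '{name}.txt'
    shell: 'echo g > {output}'
  special:
    output: a.txt
    shell: 'echo s > {output}'
")
  expect_equal(resolve_producer("a.txt", wf3)$rule$name, "special")
  # no producer: pre-existing file wins over failure
  expect_equal(resolve_producer("data.bin", wf,
                                existing_files = "data.bin")$kind,
               "existing")
  expect_equal(resolve_producer("data.bin", wf)$kind, "unresolvable")
})

test_that("a three-rule chain yields three jobs and two edges", {
  wf <- parse_workflow("
rules:
  a: {output: a.txt, shell: 'touch {output}'}
  b: {input: a.txt, output: b.txt, shell: 'cp {input} {output}'}
  c: {input: b.txt, output: c.txt, shell: 'cp {input} {output}'}
")
  dag <- build_dag(wf, "c.txt")
  expect_length(dag$jobs, 3)
  expect_equal(nrow(unique(dag$edges[, c("parent", "child")])), 2)
  expect_equal(topological_order(dag), c("a", "b", "c"))
})

test_that("the inflated example DAG matches the enumeration oracle", {
  # independent oracle: enumerate the jobs the five transcribed rules must
  # yield for n countries -- one source, one select/plot/convert per
  # country, one target
  oracle_count <- function(n) 1L + 3L * n + 1L
  for (n in c(1, 3, 5)) {
    fx <- generate_fig3_like(n, seed = 11)
    dag <- build_dag(fx$workflow, "all", existing_files = names(fx$files))
    expect_length(dag$jobs, oracle_count(n))
    expect_equal(fx$n_jobs, oracle_count(n))
    # every input of every job is produced by a parent or pre-existing
    produced <- unlist(lapply(dag$jobs, `[[`, "outputs"))
    for (j in dag$jobs)
      expect_true(all(j$inputs %in% c(produced, dag$existing_files)))
  }
})

test_that("job counts are an exact affine function of the replication", {
  sizes <- c(1, 5, 10, 50, 100)
  counts <- vapply(sizes, function(n) {
    fx <- generate_fig3_like(n, seed = 2)
    length(build_dag(fx$workflow, "all",
                     existing_files = names(fx$files))$jobs)
  }, 0L)
  fit <- stats::lm(counts ~ sizes)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), 2, tolerance = 1e-12)
  expect_equal(counts, 3L * sizes + 2L)
})

test_that("rebuilding the same DAG is deterministic", {
  fx <- generate_fig3_like(4, seed = 9)
  d1 <- build_dag(fx$workflow, "all", existing_files = names(fx$files))
  d2 <- build_dag(fx$workflow, "all", existing_files = names(fx$files))
  expect_identical(sort(names(d1$jobs)), sort(names(d2$jobs)))
  expect_identical(d1$edges[order(d1$edges$parent, d1$edges$child), ],
                   d2$edges[order(d2$edges$parent, d2$edges$child), ])
})

test_that("cycles and unresolvable inputs are reported", {
  wf <- parse_workflow("
rules:
  loop:
    input: '{x}.spin'
    output: '{x}.spin'
    shell: 'touch {output}'
")
  expect_error(build_dag(wf, "a.spin"), "cycle")
  wf2 <- parse_workflow("
rules:
  b: {input: missing.txt, output: b.txt, shell: 'cp {input} {output}'}
")
  expect_error(build_dag(wf2, "b.txt"), "missing.txt")
})

test_that("no job in a built graph is an orphan", {
  fx <- generate_fig3_like(3, seed = 5)
  dag <- build_dag(fx$workflow, "all", existing_files = names(fx$files))
  # removing any job breaks the derivation of some target: every job has a
  # path to the target job
  target_job <- "all"
  reaches <- function(id) target_job %in% descendants_of(dag, id)
  expect_true(all(vapply(names(dag$jobs), reaches, NA)))
})

test_that("checkpoint re-evaluation adds exactly the surviving samples", {
  wd <- local_workdir()
  cp <- generate_checkpoint_workflow(dir = wd, n_rows = 5,
                                     pass_fraction = 0.4, seed = 3)
  dag <- build_dag(cp$workflow, "results/summary.txt", workdir = wd)
  expect_length(dag$deferred, 1)
  expect_length(dag$jobs, 2)  # qc + aggregate; process jobs are deferred
  # run qc by hand, then re-evaluate
  dir.create(file.path(wd, "results"), showWarnings = FALSE)
  file.copy(file.path(wd, "data/qc_raw.tsv"),
            file.path(wd, "results/qc.tsv"))
  dag2 <- update_after_checkpoint(dag, "qc")
  process_jobs <- grep("^process", names(dag2$jobs), value = TRUE)
  expect_length(process_jobs, 2)  # 2 of 5 rows exceed 90
  expect_length(dag2$deferred, 0)
  agg <- dag2$jobs[["aggregate"]]
  expect_length(agg$inputs, 2)
  expect_match(agg$action, "results/processed/S[0-9]+\\.txt")
})

test_that("a resolver selecting zero samples adds no jobs", {
  wd <- local_workdir()
  cp <- generate_checkpoint_workflow(dir = wd, n_rows = 4,
                                     pass_fraction = 0, seed = 1)
  dag <- build_dag(cp$workflow, "results/summary.txt", workdir = wd)
  dir.create(file.path(wd, "results"), showWarnings = FALSE)
  file.copy(file.path(wd, "data/qc_raw.tsv"),
            file.path(wd, "results/qc.tsv"))
  dag2 <- update_after_checkpoint(dag, "qc")
  expect_length(grep("^process", names(dag2$jobs)), 0)
  expect_length(dag2$jobs[["aggregate"]]$inputs, 0)
})

test_that("DOT export names every job", {
  fx <- generate_fig3_like(2, seed = 1)
  dag <- build_dag(fx$workflow, "all", existing_files = names(fx$files))
  dot <- dag_to_dot(dag)
  expect_match(dot, "^digraph")
  for (r in c("get_data", "select_by_country", "plot_histogram",
              "convert_to_pdf"))
    expect_match(dot, r)
  expect_equal(length(gregexpr("->", dot)[[1]]),
               nrow(unique(dag$edges[, c("parent", "child")])))
})
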