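#' Synthetic workflows, data, and scheduler instances
#'
#' Generators for everything the engine can be exercised on without any
#' external download: a download-free analogue of the canonical
#' "city-population histograms per country" example workflow (whose input
#' dataset can be inflated by replicating countries, giving an exactly
#' affine job-count scaling family), random scheduling instances for
#' verifying the exact solver against the enumeration oracle, random job
#' DAGs for concurrency simulations and provenance-propagation checks, and
#' quality-control tables for checkpoint tests. All generators are pure
#' functions of their arguments plus a seed; the caller's RNG state is
#' left untouched.
#'
#' @name fixtures
NULL

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate the inflatable example workflow
#'
#' One source rule materializes a CSV of `n_units` synthetic "countries"
#' with random city populations (from a pre-generated raw file, so no
#' network is involved); a per-country select rule extracts the country's
#' rows into a temporary file, a plot rule renders a text histogram, and a
#' convert rule produces the final per-country file, aggregated by a
#' target rule. The job count is exactly `3 * n_units + 2`.
#'
#' @param n_units number of countries (>= 1).
#' @param seed RNG seed for the synthetic populations.
#' @param dir if non-`NULL`, the workflow document and data file are
#'   written beneath it.
#' @param grouped assign the select and plot rules to a common group label
#'   `"viz"`.
#' @param cacheable flag every producing rule as cacheable.
#' @param temps mark the per-country select output as temporary (default);
#'   disable to keep every intermediate on disk (e.g. for generating
#'   replay tests).
#' @return list with `workflow` (parsed `fk_workflow`), `doc` (YAML text),
#'   `files` (named character vector path -> content), `countries`,
#'   `targets`, and `n_jobs`.
#' @export
generate_fig3_like <- function(n_units, seed = 1L, dir = NULL,
                               grouped = FALSE, cacheable = FALSE,
                               temps = TRUE) {
  stopifnot(n_units >= 1)
  countries <- sprintf("U%04d", seq_len(n_units))
  data_csv <- .with_seed(seed, {
    rows <- unlist(lapply(countries, function(cc) {
      cities <- sprintf("%s_city%d", cc, 1:3)
      pops <- sample(10000:5000000, 3)
      sprintf("%s,%s,%d", cc, cities, pops)
    }))
    paste(c("country,city,population", rows), collapse = "\n")
  })
  doc <- list(
    rules = list(
      all = list(input = as.list(sprintf("plots/%s.pdf", countries))),
      get_data = list(
        input = "data/cities_raw.csv",
        output = "results/cities.csv",
        shell = "cp {input} {output}",
        cache = cacheable,
        env = "coreutils"),
      select_by_country = list(
        input = "results/cities.csv",
        output = "results/by-country/{country}.csv",
        temp = if (temps) list(1L) else NULL,
        shell = "grep '^{wildcards.country},' {input} > {output}",
        group = if (grouped) "viz" else NULL,
        cache = cacheable,
        env = "coreutils"),
      plot_histogram = list(
        input = "results/by-country/{country}.csv",
        output = "plots/{country}.hist.txt",
        shell = paste0("awk -F, '$1 != \"country\" ",
                       "{ n=int($3/250000)+1; b=\"\"; ",
                       "while (n-- > 0) b=b\"#\"; print $2\" \"b }' ",
                       "{input} > {output}"),
        group = if (grouped) "viz" else NULL,
        cache = cacheable,
        env = "awk"),
      convert_to_pdf = list(
        input = "plots/{country}.hist.txt",
        output = "plots/{country}.pdf",
        shell = "cp {input} {output}",
        cache = cacheable,
        env = "coreutils")
    ))
  doc$rules <- lapply(doc$rules, function(r) r[!vapply(r, is.null, NA)])
  yaml_doc <- yaml::as.yaml(doc)
  files <- c("data/cities_raw.csv" = data_csv)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "data"), recursive = TRUE,
               showWarnings = FALSE)
    writeLines(data_csv, file.path(dir, "data/cities_raw.csv"))
    writeLines(yaml_doc, file.path(dir, "workflow.yaml"))
  }
  list(workflow = parse_workflow(yaml_doc), doc = yaml_doc, files = files,
       countries = countries, targets = "all",
       n_jobs = 3L * n_units + 2L)
}

#' The worked scheduling example instance
#'
#' Two "green" and three "blue" pending one-core jobs of equal priority,
#' three free cores, and one present temporary file whose only open
#' consumers are the three blue jobs: the optimal schedule starts the
#' three blue jobs so the temporary file can be deleted afterwards, while
#' the tempting "two green plus one blue" selection keeps it alive.
#'
#' @param file_size size of the temporary file in MB units.
#' @return an `fk_sched_instance`.
#' @export
fig4_instance <- function(file_size = 100L) {
  jobs <- data.frame(
    id = c("blue1", "blue2", "blue3", "green1", "green2"),
    priority = 0L, cores = 1L, stringsAsFactors = FALSE)
  files <- data.frame(file = "tempfile", size = file_size,
                      open_consumers = 3L, stringsAsFactors = FALSE)
  z <- matrix(c(1L, 1L, 1L, 0L, 0L), ncol = 1)
  scheduling_instance(jobs, c(cores = 3L), files, z)
}

#' Random scheduling instance
#'
#' Priorities in 0..3, core usages in 1..4, up to three temporary files
#' with sizes in 1..100 and random consumer sets over the open jobs (a
#' superset of the pending jobs: some consumers are open but not pending).
#' The core capacity is drawn large enough that every job individually
#' fits.
#'
#' @param seed RNG seed.
#' @param n_jobs number of pending jobs (default random in 1..8).
#' @param n_files number of temporary files (default random in 0..3).
#' @return an `fk_sched_instance`.
#' @export
generate_scheduler_instance <- function(seed, n_jobs = NULL,
                                        n_files = NULL) {
  .with_seed(seed, {
    if (is.null(n_jobs)) n_jobs <- sample(1:8, 1)
    if (is.null(n_files)) n_files <- sample(0:3, 1)
    jobs <- data.frame(
      id = sprintf("j%02d", seq_len(n_jobs)),
      priority = sample(0:3, n_jobs, replace = TRUE),
      cores = sample(1:4, n_jobs, replace = TRUE),
      stringsAsFactors = FALSE)
    cap <- c(cores = sample(max(jobs$cores):(max(jobs$cores) + 6), 1))
    files <- NULL; z <- NULL
    if (n_files > 0) {
      files <- data.frame(
        file = sprintf("f%d", seq_len(n_files)),
        size = sample(1:100, n_files, replace = TRUE),
        open_consumers = 0L, stringsAsFactors = FALSE)
      z <- matrix(0L, n_jobs, n_files)
      for (k in seq_len(n_files)) {
        pending_consumers <- which(stats::runif(n_jobs) < 0.5)
        z[pending_consumers, k] <- 1L
        extra_open <- sample(0:3, 1)
        files$open_consumers[k] <- length(pending_consumers) + extra_open
        if (files$open_consumers[k] == 0L) {
          files$open_consumers[k] <- 1L  # an open, non-pending consumer
        }
      }
    }
    scheduling_instance(jobs, cap, files, z)
  })
}

#' Generate a quality-control table for checkpoint tests
#'
#' TSV with columns `sample` and `some-value`; exactly
#' `round(n_rows * pass_fraction)` rows carry a value greater than 90.
#'
#' @param n_rows number of samples.
#' @param pass_fraction fraction in \[0, 1\] of rows exceeding the QC
#'   threshold of 90.
#' @param seed RNG seed.
#' @param path if non-`NULL`, the table is written there.
#' @return data.frame with the table (invisibly the path when written).
#' @export
generate_checkpoint_table <- function(n_rows, pass_fraction, seed = 1L,
                                      path = NULL) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1)
  tab <- .with_seed(seed, {
    n_pass <- round(n_rows * pass_fraction)
    vals <- c(sample(91:100, n_pass, replace = TRUE),
              sample(10:90, n_rows - n_pass, replace = TRUE))
    data.frame(sample = sprintf("S%03d", seq_len(n_rows)),
               `some-value` = sample(vals),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  tab
}

#' A checkpoint workflow around a QC table
#'
#' The `qc` checkpoint rule publishes the raw QC table; the `process` rule
#' handles one sample; the `aggregate` rule's input is a deferred resolver
#' selecting the samples whose `some-value` exceeds 90.
#'
#' @param dir directory to write the raw table into (required for
#'   running; `NULL` builds the workflow only).
#' @param n_rows,pass_fraction,seed passed to
#'   [generate_checkpoint_table()].
#' @return list with `workflow`, `doc`, `n_pass`.
#' @export
generate_checkpoint_workflow <- function(dir = NULL, n_rows = 5,
                                         pass_fraction = 0.4, seed = 1L) {
  doc <- paste(
    "rules:",
    "  qc:",
    "    input: data/qc_raw.tsv",
    "    output: results/qc.tsv",
    "    checkpoint: true",
    "    shell: 'cp {input} {output}'",
    "  process:",
    "    output: 'results/processed/{sample}.txt'",
    "    shell: 'echo {wildcards.sample} > {output}'",
    "  aggregate:",
    "    input:",
    "      - resolver:",
    "          checkpoint: qc",
    "          table: results/qc.tsv",
    "          column: some-value",
    "          threshold: 90",
    "          emit: 'results/processed/{sample}.txt'",
    "          var: sample",
    "    output: results/summary.txt",
    "    shell: 'cat /dev/null {input} > {output}'",
    sep = "\n")
  if (!is.null(dir))
    generate_checkpoint_table(n_rows, pass_fraction, seed,
                              path = file.path(dir, "data/qc_raw.tsv"))
  list(workflow = parse_workflow(doc), doc = doc,
       n_pass = round(n_rows * pass_fraction))
}

#' Random job DAG for simulations and property tests
#'
#' Builds an `fk_dag` directly (no YAML round trip): layered random
#' parents, one output file per job, temporary flags drawn with the given
#' density, random priorities, core usages and runtimes, and optional
#' group labels.
#'
#' @param n_jobs number of jobs.
#' @param seed RNG seed.
#' @param temp_density probability that a non-sink output is temporary.
#' @param group_labels optional character vector: each job gets a label
#'   from it with probability `group_prob`.
#' @param group_prob see `group_labels`.
#' @param max_cores maximum per-job core usage.
#' @return an `fk_dag`.
#' @export
generate_random_dag <- function(n_jobs, seed = 1L, temp_density = 0.4,
                                group_labels = NULL, group_prob = 0.5,
                                max_cores = 2L) {
  .with_seed(seed, {
    jobs <- list()
    edges <- list()
    for (i in seq_len(n_jobs)) {
      id <- sprintf("j%03d", i)
      out <- sprintf("out/%s.txt", id)
      parents <- if (i == 1L) integer(0) else {
        k <- sample(0:min(2, i - 1L), 1)
        if (k > 0) sample(seq_len(i - 1L), k) else integer(0)
      }
      inputs <- sprintf("out/j%03d.txt", parents)
      jobs[[id]] <- structure(list(
        id = id, rule_name = id, binding = character(0),
        inputs = inputs, resolvers = list(),
        outputs = out, temp = FALSE, stream = FALSE,
        cacheable = FALSE,
        params = list(alpha = sample(1:100, 1)),
        priority = sample(0:2, 1),
        resources = c(cores = sample(seq_len(max_cores), 1),
                      runtime = sample(1:20, 1)),
        group = if (!is.null(group_labels) &&
                    stats::runif(1) < group_prob)
          sample(group_labels, 1) else NULL,
        action = sprintf("make %s", out),
        environment = sprintf("env%d", sample(1:3, 1)),
        is_checkpoint = FALSE, log = NULL, status = "open"
      ), class = "fk_job")
      for (p in parents)
        edges[[length(edges) + 1L]] <- c(sprintf("j%03d", p), id,
                                         sprintf("out/j%03d.txt", p))
    }
    edges <- if (length(edges)) {
      e <- do.call(rbind, edges)
      data.frame(parent = e[, 1], child = e[, 2], file = e[, 3],
                 stringsAsFactors = FALSE)
    } else data.frame(parent = character(0), child = character(0),
                      file = character(0), stringsAsFactors = FALSE)
    # mark non-sink outputs temporary with the given density
    has_consumer <- unique(edges$file)
    for (id in names(jobs)) {
      f <- jobs[[id]]$outputs
      if (f %in% has_consumer && stats::runif(1) < temp_density)
        jobs[[id]]$temp <- TRUE
    }
    sinks <- setdiff(names(jobs), unique(edges$parent))
    structure(list(jobs = jobs, edges = edges,
                   targets = unlist(lapply(jobs[sinks], `[[`, "outputs")),
                   existing_files = character(0), deferred = list(),
                   workflow = NULL, workdir = "."),
              class = "fk_dag")
  })
}

#' Provenance records for a job DAG with synthetic raw inputs
#'
#' Associates every root job with a synthetic raw-input file content and
#' computes the recursive digest of every job bottom-up. Used to study
#' digest propagation: perturb any field of any job and recompute.
#'
#' @param dag an `fk_dag` (e.g. from [generate_random_dag()]).
#' @param overrides named list job id -> list of replaced fields (`code`,
#'   `params`, `environment`, `raw_content`).
#' @return named character vector job id -> digest.
#' @export
dag_digests_synthetic <- function(dag, overrides = list()) {
  parents <- dag_parents(dag)
  digests <- character(0)
  for (jid in topological_order(dag)) {
    job <- dag$jobs[[jid]]
    ov <- overrides[[jid]]
    raw_content <- if (!is.null(ov$raw_content)) ov$raw_content else
      if (!length(parents[[jid]])) paste0("rawdata-", jid) else NULL
    raw_dg <- if (is.null(raw_content)) character(0) else
      digest::digest(charToRaw(raw_content), algo = "sha256",
                     serialize = FALSE)
    rec <- provenance_record(
      code = if (!is.null(ov$code)) ov$code else job$action,
      params = if (!is.null(ov$params)) ov$params else job$params,
      raw_input_digests = raw_dg,
      environment = if (!is.null(ov$environment)) ov$environment else
        job$environment,
      dep_digests = unname(digests[parents[[jid]]]))
    digests[[jid]] <- provenance_hash(rec)
  }
  digests
}

#' Dispatch on a fixture family
#'
#' @param family one of `"fig3_like"`, `"random_dag"`,
#'   `"scheduler_instance"`, `"checkpoint_table"`.
#' @param replication size parameter (countries, jobs, rows, ...).
#' @param seed RNG seed.
#' @param ... forwarded to the family generator.
#' @return the family generator's value.
#' @export
generate_fixture <- function(family = c("fig3_like", "random_dag",
                                        "scheduler_instance",
                                        "checkpoint_table"),
                             replication = 5L, seed = 1L, ...) {
  family <- match.arg(family)
  switch(family,
         fig3_like = generate_fig3_like(replication, seed, ...),
         random_dag = generate_random_dag(replication, seed, ...),
         scheduler_instance = generate_scheduler_instance(
           seed, n_jobs = replication, ...),
         checkpoint_table = generate_checkpoint_table(
           replication, pass_fraction = 0.4, seed = seed, ...))
}
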