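# hand-built jobs and DAGs for unit tests (no YAML round trip needed)

mk_job <- function(id, inputs = character(0), outputs = character(0),
                   cores = 1L, runtime = 10L, priority = 0L, temp = FALSE,
                   group = NULL, action = paste("make", id),
                   environment = "env", params = list()) {
  structure(list(
    id = id, rule_name = id, binding = character(0),
    inputs = inputs, resolvers = list(),
    outputs = outputs, temp = rep(temp, length(outputs)),
    stream = rep(FALSE, length(outputs)),
    cacheable = FALSE, params = params, priority = priority,
    resources = c(cores = cores, runtime = runtime), group = group,
    action = action, environment = environment,
    is_checkpoint = FALSE, log = NULL, status = "open"
  ), class = "fk_job")
}

mk_dag <- function(jobs, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0),
                        file = character(0), stringsAsFactors = FALSE)
  names(jobs) <- vapply(jobs, `[[`, "", "id")
  sinks <- setdiff(names(jobs), unique(edges$parent))
  structure(list(jobs = jobs, edges = edges,
                 targets = unlist(lapply(jobs[sinks], `[[`, "outputs")),
                 existing_files = character(0), deferred = list(),
                 workflow = NULL, workdir = "."),
            class = "fk_dag")
}

# diamond: a -> {b, c} -> d
mk_diamond <- function(group = "g") {
  jobs <- list(
    mk_job("a", outputs = "x", runtime = 5L, group = group),
    mk_job("b", inputs = "x", outputs = "y", runtime = 10L, group = group),
    mk_job("c", inputs = "x", outputs = "z", runtime = 20L, group = group),
    mk_job("d", inputs = c("y", "z"), outputs = "w", runtime = 5L,
           group = group))
  edges <- data.frame(parent = c("a", "a", "b", "c"),
                      child = c("b", "c", "d", "d"),
                      file = c("x", "x", "y", "z"), stringsAsFactors = FALSE)
  mk_dag(jobs, edges)
}

# a fresh private working directory for engine tests
local_workdir <- function(env = parent.frame()) {
  wd <- tempfile("fk-wd-")
  dir.create(wd, recursive = TRUE)
  withr::defer(unlink(wd, recursive = TRUE), envir = env)
  wd
}

# descendants (inclusive) of a job in a dag
descendants_of <- function(dag, id) {
  desc <- id
  repeat {
    nxt <- unique(dag$edges$child[dag$edges$parent %in% desc])
    if (all(nxt %in% desc)) break
    desc <- union(desc, nxt)
  }
  desc
}
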