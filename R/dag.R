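#' Job-DAG inference
#'
#' The DAG of jobs is inferred recursively from the requested target files:
#' for every required file a producing rule is determined by matching the
#' file against rule output patterns, the matched rule is instantiated into
#' a job, and inference recurses into that job's inputs until every input is
#' either produced by another job or already present. Identical
#' (rule, binding) pairs merge into a single job, so construction is linear
#' in the number of jobs plus edges.
#'
#' @name dag-inference
NULL

#' Resolve the producer of a path
#'
#' Among rules with an output pattern matching `path`, ambiguity is resolved
#' by the cascade: (1) `ruleorder` precedence, (2) higher rule priority,
#' (3) fewer wildcards, (4) first declaration order. If no rule matches and
#' the file is pre-existing, the file is taken as given.
#'
#' @param path concrete path.
#' @param workflow an `fk_workflow`.
#' @param existing_files character set of pre-existing paths.
#' @return list with `kind` one of `"rule"` (plus `rule`, `binding`),
#'   `"existing"`, or `"unresolvable"`.
#' @export
resolve_producer <- function(path, workflow, existing_files = character(0)) {
  path <- normalize_relpath(path)
  cand <- list()
  for (i in seq_along(workflow$rules)) {
    r <- workflow$rules[[i]]
    if (is_target_rule(r)) next
    for (o in r$outputs) {
      b <- match_pattern(o, path, r$wildcard_constraints)
      if (!is.null(b)) {
        cand[[length(cand) + 1L]] <- list(rule = r, binding = b, decl = i,
                                          n_wc = length(wildcard_names(o)))
        break  # first declared output pattern of a rule wins
      }
    }
  }
  if (!length(cand)) {
    if (path %in% existing_files)
      return(list(kind = "existing", path = path))
    return(list(kind = "unresolvable", path = path))
  }
  if (length(cand) > 1L) cand <- .apply_ruleorder(cand, workflow$ruleorder)
  if (length(cand) > 1L) {
    pr <- vapply(cand, function(x) x$rule$priority, 0L)
    cand <- cand[pr == max(pr)]
  }
  if (length(cand) > 1L) {
    nw <- vapply(cand, `[[`, 0L, "n_wc")
    cand <- cand[nw == min(nw)]
  }
  if (length(cand) > 1L) {
    decl <- vapply(cand, `[[`, 0L, "decl")
    cand <- cand[order(decl)][1]
  }
  list(kind = "rule", rule = cand[[1]]$rule, binding = cand[[1]]$binding)
}

# Drop candidates dominated by another candidate under some ruleorder chain.
.apply_ruleorder <- function(cand, ruleorder) {
  if (!length(ruleorder)) return(cand)
  nms <- vapply(cand, function(x) x$rule$name, "")
  dominated <- rep(FALSE, length(cand))
  for (chain in ruleorder) {
    pos <- match(nms, chain)
    if (sum(!is.na(pos)) >= 2L) {
      best <- min(pos, na.rm = TRUE)
      dominated <- dominated | (!is.na(pos) & pos > best)
    }
  }
  if (all(dominated)) cand else cand[!dominated]
}

#' Build the job DAG for a set of targets
#'
#' @param workflow an `fk_workflow`.
#' @param targets character vector of requested paths; a target may also be
#'   the name of an output-less target rule, whose inputs are then
#'   requested.
#' @param existing_files character set of pre-existing file paths (in
#'   addition to files found on disk under `workdir`). File presence is
#'   evaluated once, here; mid-run filesystem changes are ignored except
#'   through checkpoints.
#' @param workdir directory against which on-disk presence is checked.
#' @param max_jobs guard against unbounded recursion through
#'   self-feeding patterns.
#' @return object of class `fk_dag`.
#' @export
build_dag <- function(workflow, targets, existing_files = character(0),
                      workdir = ".", max_jobs = 1e6) {
  stopifnot(length(targets) >= 1L)
  existing_files <- vapply(existing_files, normalize_relpath, "",
                           USE.NAMES = FALSE)
  g <- new.env(parent = emptyenv())
  g$jobs <- list()
  g$edges <- list()       # list of c(parent, child, file)
  g$producer <- list()    # file -> job id
  g$deferred <- list()    # per consumer job: resolvers awaiting checkpoints
  g$existing <- existing_files
  g$workdir <- workdir
  g$workflow <- workflow

  queue <- list()
  push_job <- function(job) {
    if (!is.null(g$jobs[[job$id]])) return(FALSE)
    if (length(g$jobs) >= max_jobs)
      stop("job limit exceeded while building DAG (self-feeding pattern?)",
           call. = FALSE)
    for (o in job$outputs) {
      prev <- g$producer[[o]]
      if (!is.null(prev) && prev != job$id)
        stop("output '", o, "' is produced by two jobs: ", prev, " and ",
             job$id, call. = FALSE)
      g$producer[[o]] <- job$id
    }
    g$jobs[[job$id]] <- job
    queue[[length(queue) + 1L]] <<- job$id
    TRUE
  }

  for (t in targets) {
    t <- normalize_relpath(t)
    r <- workflow$rules[[t]]
    if (!is.null(r) && is_target_rule(r)) {
      push_job(instantiate(r, character(0)))
    } else {
      .require_path(g, t, requester = "<target>", push_job)
    }
  }
  while (length(queue)) {
    jid <- queue[[1]]
    queue <- queue[-1]
    job <- g$jobs[[jid]]
    for (inp in job$inputs) .require_path(g, inp, jid, push_job)
    for (rs in job$resolvers) {
      # the consumer depends on the checkpoint producing the resolver table
      .require_path(g, rs$table, jid, push_job)
      prod <- g$producer[[rs$table]]
      if (is.null(prod))
        stop("resolver table '", rs$table, "' of job ", jid,
             " has no producing job", call. = FALSE)
      pj <- g$jobs[[prod]]
      if (pj$rule_name != rs$checkpoint)
        stop("resolver of job ", jid, " declares checkpoint '",
             rs$checkpoint, "' but table '", rs$table,
             "' is produced by rule '", pj$rule_name, "'", call. = FALSE)
      if (!pj$is_checkpoint)
        stop("rule '", pj$rule_name, "' is referenced by a resolver but is ",
             "not a checkpoint", call. = FALSE)
      g$deferred[[length(g$deferred) + 1L]] <-
        list(consumer = jid, resolver = rs)
    }
  }
  dag <- .finalize_dag(g, targets)
  dag
}

.require_path <- function(g, path, requester, push_job) {
  path <- normalize_relpath(path)
  if (!is.null(g$producer[[path]])) {
    if (requester != "<target>")
      g$edges[[length(g$edges) + 1L]] <- c(g$producer[[path]], requester, path)
    return(invisible())
  }
  res <- resolve_producer(path, g$workflow, g$existing)
  if (res$kind == "rule") {
    job <- instantiate(res$rule, res$binding)
    push_job(job)
    if (requester != "<target>")
      g$edges[[length(g$edges) + 1L]] <- c(job$id, requester, path)
  } else if (res$kind == "existing" ||
             file.exists(file.path(g$workdir, path))) {
    g$existing <- unique(c(g$existing, path))
  } else {
    stop("no rule produces '", path, "' and the file does not exist ",
         "(required by ", requester, ")", call. = FALSE)
  }
  invisible()
}

.finalize_dag <- function(g, targets) {
  edges <- if (length(g$edges)) {
    e <- do.call(rbind, g$edges)
    e <- unique(data.frame(parent = e[, 1], child = e[, 2], file = e[, 3],
                           stringsAsFactors = FALSE))
    # edges pushed in discovery order; fix child->parent duplicates order
    e[order(e$child, e$parent, e$file), , drop = FALSE]
  } else data.frame(parent = character(0), child = character(0),
                    file = character(0), stringsAsFactors = FALSE)
  dag <- structure(list(
    jobs = g$jobs, edges = edges, targets = targets,
    existing_files = g$existing, deferred = g$deferred,
    workflow = g$workflow, workdir = g$workdir
  ), class = "fk_dag")
  topological_order(dag)  # errors on cycles, naming one
  dag
}

#' Topological order of a job DAG
#'
#' Kahn's algorithm with deterministic (job-id) tie-breaking. Errors if the
#' graph contains a cycle, naming the jobs on it.
#'
#' @param dag an `fk_dag`, or a list with `jobs` and `edges`.
#' @return character vector of job ids in topological order.
#' @export
topological_order <- function(dag) {
  ids <- sort(names(dag$jobs))
  indeg <- stats::setNames(integer(length(ids)), ids)
  kids <- stats::setNames(vector("list", length(ids)), ids)
  ekey <- unique(dag$edges[, c("parent", "child")])
  for (i in seq_len(nrow(ekey))) {
    p <- ekey$parent[i]; c_ <- ekey$child[i]
    indeg[[c_]] <- indeg[[c_]] + 1L
    kids[[p]] <- c(kids[[p]], c_)
  }
  ready <- sort(ids[indeg == 0L])
  out <- character(0)
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (w in kids[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(out) != length(ids)) {
    cyc <- setdiff(ids, out)
    stop("cycle detected among jobs: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  out
}

#' Parents of each job
#'
#' @param dag an `fk_dag`.
#' @return named list: job id -> character vector of parent job ids.
#' @export
dag_parents <- function(dag) {
  out <- stats::setNames(vector("list", length(dag$jobs)), names(dag$jobs))
  ekey <- unique(dag$edges[, c("parent", "child")])
  for (i in seq_len(nrow(ekey)))
    out[[ekey$child[i]]] <- c(out[[ekey$child[i]]], ekey$parent[i])
  out
}

#' Re-evaluate deferred inputs after a checkpoint finishes
#'
#' Evaluates every table-driven resolver that depends on the finished
#' checkpoint job against the table it produced (which must now exist),
#' appends the emitted concrete paths to the consuming jobs' inputs, infers
#' producers for the new paths recursively, and re-verifies acyclicity.
#'
#' @param dag an `fk_dag`.
#' @param finished_job_id id of the finished checkpoint job.
#' @return updated `fk_dag` (jobs may have been added; statuses of existing
#'   jobs are preserved).
#' @export
update_after_checkpoint <- function(dag, finished_job_id) {
  job <- dag$jobs[[finished_job_id]]
  if (is.null(job)) stop("unknown job: ", finished_job_id, call. = FALSE)
  if (!job$is_checkpoint)
    stop("job ", finished_job_id, " is not a checkpoint", call. = FALSE)
  hit <- vapply(dag$deferred, function(d) {
    d$resolver$table %in% job$outputs
  }, NA)
  if (!any(hit)) return(dag)

  g <- new.env(parent = emptyenv())
  g$jobs <- dag$jobs
  g$edges <- lapply(seq_len(nrow(dag$edges)), function(i)
    c(dag$edges$parent[i], dag$edges$child[i], dag$edges$file[i]))
  g$producer <- list()
  for (j in dag$jobs) for (o in j$outputs) g$producer[[o]] <- j$id
  g$existing <- dag$existing_files
  g$workdir <- dag$workdir
  g$workflow <- dag$workflow
  queue <- list()
  push_job <- function(job) {
    if (!is.null(g$jobs[[job$id]])) return(FALSE)
    for (o in job$outputs) g$producer[[o]] <- job$id
    g$jobs[[job$id]] <- job
    queue[[length(queue) + 1L]] <<- job$id
    TRUE
  }
  for (k in which(hit)) {
    d <- dag$deferred[[k]]
    paths <- evaluate_resolver(d$resolver, dag$workdir)
    cons <- g$jobs[[d$consumer]]
    for (p in paths) {
      .require_path(g, p, d$consumer, push_job)
      cons$inputs <- unique(c(cons$inputs, p))
    }
    cons$resolvers <- Filter(function(rs)
      !identical(rs, d$resolver), cons$resolvers)
    # re-render the action: {input} now includes the resolved paths
    if (!is.null(dag$workflow)) {
      rl <- dag$workflow$rules[[cons$rule_name]]
      if (!is.null(rl))
        cons$action <- render_action(rl$action, cons$inputs, cons$outputs,
                                     cons$params, cons$binding, cons$log)
    }
    g$jobs[[d$consumer]] <- cons
  }
  while (length(queue)) {
    jid <- queue[[1]]; queue <- queue[-1]
    for (inp in g$jobs[[jid]]$inputs) .require_path(g, inp, jid, push_job)
    for (rs in g$jobs[[jid]]$resolvers)
      g$deferred[[length(g$deferred) + 1L]] <- list(consumer = jid,
                                                    resolver = rs)
  }
  dag$jobs <- g$jobs
  e <- do.call(rbind, g$edges)
  dag$edges <- unique(data.frame(parent = e[, 1], child = e[, 2],
                                 file = e[, 3], stringsAsFactors = FALSE))
  dag$existing_files <- g$existing
  dag$deferred <- dag$deferred[!hit]
  topological_order(dag)  # acyclicity re-verified
  dag
}

#' Evaluate a table-driven deferred-input resolver
#'
#' Reads the delimited table (TSV by default, CSV for `.csv`), filters rows
#' by the threshold comparison, and emits one path per surviving row.
#'
#' @param resolver an `fk_resolver` with a concrete `table` path.
#' @param workdir directory the table path is relative to.
#' @return character vector of emitted concrete paths (possibly empty).
#' @export
evaluate_resolver <- function(resolver, workdir = ".") {
  path <- file.path(workdir, resolver$table)
  if (!file.exists(path))
    stop("resolver table not found: ", resolver$table, call. = FALSE)
  sep <- if (grepl("\\.csv$", resolver$table)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(resolver$column, resolver$var))
    if (!col %in% names(tab))
      stop("resolver table '", resolver$table, "' lacks column '", col, "'",
           call. = FALSE)
  v <- tab[[resolver$column]]
  keep <- switch(resolver$op,
                 gt = v >  resolver$threshold,
                 ge = v >= resolver$threshold,
                 lt = v <  resolver$threshold,
                 le = v <= resolver$threshold,
                 eq = v == resolver$threshold)
  vals <- as.character(tab[[resolver$var]][keep & !is.na(keep)])
  vapply(vals, function(x)
    substitute_pattern(resolver$emit,
                       stats::setNames(x, resolver$var)), "",
    USE.NAMES = FALSE)
}

#' Export a job DAG as DOT text
#'
#' Node labels are rule name plus binding, mirroring the usual rendering of
#' workflow DAGs.
#'
#' @param dag an `fk_dag`.
#' @return character scalar of DOT source.
#' @export
dag_to_dot <- function(dag) {
  ids <- topological_order(dag)
  idx <- stats::setNames(seq_along(ids), ids)
  lab <- vapply(ids, function(i) {
    j <- dag$jobs[[i]]
    if (length(j$binding))
      sprintf("%s\\n%s", j$rule_name,
              paste0(names(j$binding), "=", j$binding, collapse = ", "))
    else j$rule_name
  }, "")
  nodes <- sprintf("  n%d [label=\"%s\"];", idx, lab)
  ekey <- unique(dag$edges[, c("parent", "child")])
  edges <- sprintf("  n%d -> n%d;", idx[ekey$parent], idx[ekey$child])
  paste(c("digraph jobs {", nodes, edges, "}"), collapse = "\n")
}

#' @export
print.fk_dag <- function(x, ...) {
  cat("<flowkern job DAG>", length(x$jobs), "job(s),",
      nrow(unique(x$edges[, c("parent", "child")])), "edge(s)\n")
  if (length(x$deferred))
    cat("  ", length(x$deferred), "deferred input(s) awaiting checkpoints\n")
  invisible(x)
}
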