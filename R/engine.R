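#' Workflow execution engine
#'
#' The engine repeatedly: determines the pending group-job units, builds a
#' scheduling instance, solves it exactly, launches the selected units,
#' and after each completion deletes eligible temporary files, re-evaluates
#' checkpoints, and reschedules. Cacheable jobs whose provenance digest
#' hits the cache are satisfied without execution. Outputs become visible
#' only after a job's action exits 0 (write to staging, then move).
#'
#' @name engine
NULL

# ---- run state ------------------------------------------------------------

.new_state <- function(dag, capacities) {
  st <- new.env(parent = emptyenv())
  st$status <- stats::setNames(rep("open", length(dag$jobs)),
                               names(dag$jobs))
  st$capacities <- .as_resources(capacities)
  st$running <- list()          # unit id -> named usage vector
  st$events <- list()
  st$seq <- 0L
  st$temp <- .temp_registry(dag)
  st$prov <- list()
  st$benchmarks <- list()
  st$deleted <- character(0)
  st$schedule_dumps <- list()
  st
}

.emit <- function(st, type, ...) {
  st$seq <- st$seq + 1L
  st$events[[st$seq]] <- c(list(seq = st$seq, type = type), list(...))
  invisible(st$seq)
}

# registry of temporary (and streamed) files: producer, consumers, flags
.temp_registry <- function(dag) {
  reg <- list()
  for (j in dag$jobs) {
    flags <- j$temp | j$stream
    for (i in which(flags)) {
      f <- j$outputs[i]
      reg[[f]] <- list(file = f, producer = j$id,
                       consumers = unique(dag$edges$child[dag$edges$file == f]),
                       stream = j$stream[i],
                       present = FALSE, deleted = FALSE)
    }
  }
  reg
}

# refresh consumers after the DAG grew through a checkpoint
.refresh_registry <- function(st, dag) {
  old <- st$temp
  st$temp <- .temp_registry(dag)
  for (f in names(st$temp)) {
    if (!is.null(old[[f]])) {
      st$temp[[f]]$present <- old[[f]]$present
      st$temp[[f]]$deleted <- old[[f]]$deleted
    }
  }
  invisible(st)
}

.done_status <- c("finished", "cached", "skipped")

# ---- scheduling instance from the engine state ----------------------------

#' Build a scheduling instance from a job DAG and run state
#'
#' Units are group jobs whose members are all unscheduled and whose
#' group-external parents are all done; the free capacity is the configured
#' capacity minus the aggregated usage of running units; the tracked
#' temporary files are those currently present with at least one open
#' consumer.
#'
#' @param dag an `fk_dag`.
#' @param capacities named configured capacities.
#' @param groups partition from [partition_groups()].
#' @param status named status vector (default: everything `"open"`).
#' @param running named list unit id -> usage vector of currently running
#'   units.
#' @param temp_registry temp-file registry (internal shape); `NULL` for
#'   none.
#' @return an `fk_sched_instance` whose unit ids are group-job ids, plus a
#'   `units` attribute mapping unit id -> member job ids.
#' @export
build_instance <- function(dag, capacities, groups = NULL, status = NULL,
                           running = list(), temp_registry = NULL) {
  capacities <- .as_resources(capacities)
  if (is.null(groups)) groups <- partition_groups(dag)
  if (is.null(status))
    status <- stats::setNames(rep("open", length(dag$jobs)),
                              names(dag$jobs))
  parents <- dag_parents(dag)
  unit_of <- character(0)
  for (g in groups) unit_of[g$members] <- g$id

  pending <- Filter(function(g) {
    if (!all(status[g$members] == "open")) return(FALSE)
    ext <- setdiff(unique(unlist(parents[g$members])), g$members)
    all(status[ext] %in% .done_status)
  }, groups)

  used <- Reduce(`+`, lapply(running, function(u) {
    v <- stats::setNames(numeric(length(capacities)), names(capacities))
    v[names(u)] <- u[names(u)[names(u) %in% names(v)]]
    v
  }), init = stats::setNames(numeric(length(capacities)), names(capacities)))
  free <- pmax(capacities - used, 0)

  res_names <- names(capacities)
  rows <- lapply(pending, function(g) {
    ag <- aggregate_resources(g, dag)
    u <- stats::setNames(integer(length(res_names)), res_names)
    common <- intersect(names(ag$resources), res_names)
    u[common] <- ag$resources[common]
    pr <- max(vapply(g$members, function(m) dag$jobs[[m]]$priority, 0L))
    c(list(id = g$id, priority = pr), as.list(u))
  })
  jobs <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    df <- data.frame(id = character(0), priority = integer(0))
    for (r in res_names) df[[r]] <- integer(0)
    df
  }

  open_ids <- names(status)[status == "open"]
  files <- NULL; z <- NULL
  if (!is.null(temp_registry) && length(temp_registry)) {
    fl <- Filter(function(tf) {
      tf$present && !tf$deleted &&
        any(status[tf$consumers] == "open")
    }, temp_registry)
    if (length(fl)) {
      files <- data.frame(
        file = vapply(fl, `[[`, "", "file"),
        size = vapply(fl, function(tf) .temp_file_size(dag, tf), 0),
        open_consumers = vapply(fl, function(tf)
          sum(status[tf$consumers] == "open"), 0L),
        stringsAsFactors = FALSE)
      z <- matrix(0L, nrow(jobs), nrow(files))
      for (k in seq_along(fl)) {
        cons_open <- fl[[k]]$consumers[status[fl[[k]]$consumers] == "open"]
        for (gi in seq_len(nrow(jobs))) {
          g <- Filter(function(x) x$id == jobs$id[gi], pending)[[1]]
          z[gi, k] <- length(intersect(g$members, cons_open))
        }
      }
    }
  }
  # a unit whose usage exceeds the configured capacity would never fit
  for (r in res_names) {
    over <- jobs[[r]] > capacities[[r]]
    if (any(over))
      stop("unit(s) ", paste(jobs$id[over], collapse = ", "),
           " require more '", r, "' than the configured capacity ",
           capacities[[r]], " and can never be scheduled", call. = FALSE)
  }
  inst <- scheduling_instance(jobs, free, files, z)
  attr(inst, "units") <- stats::setNames(
    lapply(pending, `[[`, "members"),
    vapply(pending, `[[`, "", "id"))
  inst
}

# temp file sizes in MB, rounded up, floored at 1 unit
.temp_file_size <- function(dag, tf) {
  p <- file.path(dag$workdir, tf$file)
  if (file.exists(p)) max(1, ceiling(file.size(p) / 2^20)) else 1
}

# ---- temporary-file deletion ---------------------------------------------

#' Delete temporary files whose consumers have all finished
#'
#' Deletes exactly the present temporary files whose remaining-consumer
#' count is zero; a file any unfinished job still needs is never touched.
#' I/O failures are logged and retried at the next completion, never fatal.
#'
#' @param st run state (internal).
#' @param dag an `fk_dag`.
#' @param physical also remove the file from disk.
#' @return character vector of deleted paths.
#' @export
#' @keywords internal
delete_eligible_temporaries <- function(st, dag, physical = TRUE) {
  deleted <- character(0)
  for (f in names(st$temp)) {
    tf <- st$temp[[f]]
    if (!tf$present || tf$deleted) next
    remaining <- sum(!(st$status[tf$consumers] %in% .done_status))
    if (remaining > 0L) next
    if (physical) {
      p <- file.path(dag$workdir, f)
      if (file.exists(p) && !isTRUE(file.remove(p))) {
        .emit(st, "delete_failed", file = f)
        next
      }
    }
    st$temp[[f]]$deleted <- TRUE
    st$deleted <- c(st$deleted, f)
    .emit(st, "delete", file = f)
    deleted <- c(deleted, f)
  }
  deleted
}

# ---- execution ------------------------------------------------------------

# Execute one job's action: staged outputs, optional log, benchmark.
# Returns list(ok, seconds, max_rss, log_tail).
.execute_job <- function(job, dag, st, verbose = FALSE) {
  if (!nzchar(job$action) && !length(job$outputs)) {
    # pure aggregation job (target rule): nothing to execute
    return(list(ok = TRUE, seconds = 0, max_rss = NA_real_))
  }
  wd <- dag$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  wd_abs <- normalizePath(wd)
  staging <- file.path(wd_abs, ".flowkern", "staging",
                       gsub("[^A-Za-z0-9_=.-]", "_", job$id))
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  out_map <- stats::setNames(file.path(staging, job$outputs), job$outputs)
  for (o in out_map) dir.create(dirname(o), recursive = TRUE,
                                showWarnings = FALSE)
  # re-render the action with staged output paths; inputs stay in place
  cmd <- job$action
  for (o in job$outputs)
    cmd <- gsub(o, out_map[[o]], cmd, fixed = TRUE)
  log_path <- NULL
  if (!is.null(job$log)) {
    log_path <- file.path(wd_abs, job$log)
    dir.create(dirname(log_path), recursive = TRUE, showWarnings = FALSE)
  }
  t0 <- Sys.time()
  px <- processx::process$new("sh", c("-c", cmd), wd = wd,
                              stdout = if (is.null(log_path)) "|" else log_path,
                              stderr = if (is.null(log_path)) "|" else
                                "2>&1")
  max_rss <- NA_real_
  status_file <- sprintf("/proc/%d/status", px$get_pid())
  while (px$is_alive()) {
    if (file.exists(status_file)) {
      ln <- tryCatch(suppressWarnings(readLines(status_file, warn = FALSE)),
                     error = function(e) character(0))
      hw <- grep("^VmHWM:", ln, value = TRUE)
      if (length(hw)) {
        kb <- suppressWarnings(as.numeric(gsub("[^0-9]", "", hw[1])))
        if (!is.na(kb)) max_rss <- max(max_rss, kb * 1024, na.rm = TRUE)
      }
    }
    px$poll_io(25)
  }
  px$wait()
  ok <- identical(px$get_exit_status(), 0L)
  seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (ok) {
    for (o in job$outputs) {
      src <- out_map[[o]]
      if (!file.exists(src)) {
        ok <- FALSE
        break
      }
      dst <- file.path(wd, o)
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      if (file.exists(dst)) unlink(dst)
      if (!file.rename(src, dst)) {
        file.copy(src, dst)
        unlink(src)
      }
    }
  }
  unlink(staging, recursive = TRUE)
  if (verbose) message(sprintf("[%s] %s (%.2fs)", job$id,
                               if (ok) "ok" else "FAILED", seconds))
  list(ok = ok, seconds = seconds, max_rss = max_rss)
}

# provenance record for a finished job
.record_job <- function(st, dag, job, digest = NA_character_,
                        cache_hit = FALSE, bench = NULL) {
  st$prov[[job$id]] <- list(
    job = job$id, rule = job$rule_name,
    binding = as.list(job$binding),
    inputs = job$inputs, outputs = job$outputs,
    params = job$params, action = job$action,
    environment = job$environment,
    start = if (is.null(bench)) NA else bench$start,
    end = if (is.null(bench)) NA else bench$end,
    seconds = if (is.null(bench)) NA_real_ else bench$seconds,
    max_rss = if (is.null(bench)) NA_real_ else bench$max_rss,
    cache_digest = digest, cache_hit = cache_hit)
  invisible(st)
}

# mark every transitive dependent of job_id as cancelled
.cancel_dependents <- function(st, dag, job_id) {
  kids <- dag$edges[, c("parent", "child")]
  frontier <- job_id
  while (length(frontier)) {
    nxt <- unique(kids$child[kids$parent %in% frontier])
    nxt <- nxt[st$status[nxt] %in% c("open", "pending")]
    st$status[nxt] <- "cancelled"
    frontier <- nxt
  }
  invisible(st)
}

# satisfy cacheable jobs from the cache; prune jobs nobody needs any more
.cache_pass <- function(st, dag, cache_root) {
  if (is.null(cache_root)) return(invisible(st))
  digests <- job_digests(dag)
  for (jid in topological_order(dag)) {
    if (st$status[[jid]] != "open") next
    job <- dag$jobs[[jid]]
    if (!job$cacheable || !jid %in% names(digests)) next
    hit <- cache_lookup(digests[[jid]], cache_root)
    if (is.null(hit)) next
    dest <- stats::setNames(file.path(dag$workdir, job$outputs),
                            basename(job$outputs))
    names(dest) <- job$outputs  # entry names are the relative output paths
    ok <- tryCatch({
      cache_restore(hit, dest)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    st$status[[jid]] <- "cached"
    for (o in job$outputs)
      if (!is.null(st$temp[[o]])) st$temp[[o]]$present <- TRUE
    .record_job(st, dag, job, digest = digests[[jid]], cache_hit = TRUE)
    .emit(st, "cached", job = jid)
  }
  # prune jobs whose every output consumer is satisfied and that produce no
  # still-missing target
  targets <- vapply(dag$targets, normalize_relpath, "")
  kids <- dag$edges
  for (jid in rev(topological_order(dag))) {
    if (st$status[[jid]] != "open") next
    job <- dag$jobs[[jid]]
    out_edges <- kids[kids$parent == jid, , drop = FALSE]
    consumers_ok <- all(st$status[unique(out_edges$child)] %in%
                          c("cached", "skipped"))
    is_target_producer <- any(job$outputs %in% targets) ||
      job$rule_name %in% targets
    if (nrow(out_edges) > 0 && consumers_ok && !is_target_producer) {
      st$status[[jid]] <- "skipped"
      .emit(st, "skipped", job = jid)
    }
  }
  invisible(st)
}

# store a finished cacheable job
.cache_put <- function(st, dag, job, cache_root) {
  if (is.null(cache_root) || !job$cacheable) return(NA_character_)
  digests <- job_digests(dag)
  if (!job$id %in% names(digests)) return(NA_character_)
  produced <- unlist(lapply(dag$jobs, `[[`, "outputs"))
  raw <- setdiff(job$inputs, produced)
  parents <- dag_parents(dag)[[job$id]]
  rec <- provenance_record(
    code = job$action, params = job$params,
    raw_input_digests = vapply(raw, function(p)
      file_digest(file.path(dag$workdir, p)), ""),
    environment = job$environment,
    dep_digests = unname(digests[parents]))
  outs <- stats::setNames(file.path(dag$workdir, job$outputs), job$outputs)
  cache_store(digests[[job$id]], outs, rec, cache_root,
              cacheable = TRUE, rule_name = job$rule_name)
  digests[[job$id]]
}

#' Run a workflow
#'
#' @param workflow an `fk_workflow` (or YAML text / path, which is parsed).
#' @param targets requested target files (or names of target rules).
#' @param capacities named resource capacities, at least `cores`.
#' @param workdir working directory files live under.
#' @param existing_files additional pre-existing paths.
#' @param dry_run plan only: no file is touched.
#' @param cache_root directory of the between-workflow cache, or `NULL` to
#'   disable caching.
#' @param span_per_group,group_overrides see [partition_groups()].
#' @param keep_going on a job failure, keep executing independent jobs
#'   instead of stopping (default fail-fast).
#' @param dump_schedule if `TRUE`, keep the JSON serialization of every
#'   scheduling round in the report.
#' @param verbose print per-job progress.
#' @return object of class `fk_run_report`: job statuses, event log,
#'   provenance records, benchmark records, deleted temporaries, the final
#'   DAG and partition, and `ok`.
#' @export
run_workflow <- function(workflow, targets, capacities = c(cores = 1L),
                         workdir = ".", existing_files = character(0),
                         dry_run = FALSE, cache_root = NULL,
                         span_per_group = integer(0),
                         group_overrides = character(0),
                         keep_going = FALSE, dump_schedule = FALSE,
                         verbose = FALSE) {
  if (!inherits(workflow, "fk_workflow")) workflow <- parse_workflow(workflow)
  dag <- build_dag(workflow, targets, existing_files, workdir)
  st <- .new_state(dag, capacities)
  groups <- partition_groups(dag, span_per_group, group_overrides)

  if (dry_run) {
    plan <- lapply(groups, function(g) list(unit = g$id, jobs = g$members))
    return(structure(list(ok = TRUE, dry_run = TRUE, plan = plan,
                          dag = dag, groups = groups,
                          status = st$status),
                     class = "fk_run_report"))
  }

  failed <- FALSE
  repeat {
    .cache_pass(st, dag, cache_root)
    inst <- build_instance(dag, st$capacities, groups, st$status,
                           running = list(), temp_registry = st$temp)
    if (nrow(inst$jobs) == 0L) break
    dec <- solve_milp(inst)
    if (isTRUE(dump_schedule))
      st$schedule_dumps[[length(st$schedule_dumps) + 1L]] <-
        schedule_to_json(inst, dec)
    if (!length(dec$selected)) break
    units <- attr(inst, "units")
    regroup <- FALSE
    for (uid in dec$selected) {
      members <- units[[uid]]
      .emit(st, "start", unit = uid, jobs = members)
      ekey <- unique(dag$edges[, c("parent", "child")])
      ekey <- ekey[ekey$parent %in% members & ekey$child %in% members, ,
                   drop = FALSE]
      unit_failed <- FALSE
      for (jid in .member_topo(sort(members), ekey)) {
        job <- dag$jobs[[jid]]
        st$status[[jid]] <- "running"
        t_start <- Sys.time()
        res <- .execute_job(job, dag, st, verbose)
        bench <- list(start = format(t_start, "%Y-%m-%dT%H:%M:%OS3"),
                      end = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                      seconds = res$seconds, max_rss = res$max_rss)
        if (!res$ok) {
          st$status[[jid]] <- "failed"
          .emit(st, "failed", job = jid)
          .cancel_dependents(st, dag, jid)
          unit_failed <- TRUE
          failed <- TRUE
          break
        }
        st$status[[jid]] <- "finished"
        st$benchmarks[[jid]] <- list(job = jid, seconds = res$seconds,
                                     max_rss = res$max_rss)
        for (o in job$outputs)
          if (!is.null(st$temp[[o]])) st$temp[[o]]$present <- TRUE
        dg <- tryCatch(.cache_put(st, dag, job, cache_root),
                       error = function(e) NA_character_)
        .record_job(st, dag, job, digest = dg, bench = bench)
        .emit(st, "finish", job = jid)
        delete_eligible_temporaries(st, dag)
        if (job$is_checkpoint) {
          dag <- update_after_checkpoint(dag, jid)
          new_ids <- setdiff(names(dag$jobs), names(st$status))
          if (length(new_ids))
            st$status[new_ids] <- "open"
          .refresh_registry(st, dag)
          regroup <- TRUE
        }
      }
      if (unit_failed) {
        # cancel remaining members of the group
        rest <- members[st$status[members] %in% c("open", "pending",
                                                  "running")]
        st$status[rest] <- "cancelled"
        if (!keep_going) break
      }
    }
    if (regroup)
      groups <- partition_groups(dag, span_per_group, group_overrides)
    if (failed && !keep_going) break
  }

  targets_resolved <- vapply(dag$targets, function(t) {
    r <- dag$workflow$rules[[t]]
    if (!is.null(r) && is_target_rule(r)) {
      all(st$status[job_id(t)] %in% .done_status)
    } else file.exists(file.path(dag$workdir, t)) ||
      normalize_relpath(t) %in% st$deleted
  }, NA)
  ok <- !failed && all(targets_resolved) &&
    !any(st$status %in% c("open", "pending", "running"))
  report <- structure(list(
    ok = ok, dry_run = FALSE, status = st$status, events = st$events,
    provenance = st$prov, benchmarks = st$benchmarks,
    deleted_temporaries = st$deleted, dag = dag, groups = groups,
    schedule_dumps = st$schedule_dumps
  ), class = "fk_run_report")
  if (failed && !keep_going)
    stop("workflow run failed: job(s) ",
         paste(names(st$status)[st$status == "failed"], collapse = ", "),
         " exited with a non-zero status", call. = FALSE)
  report
}

#' @export
print.fk_run_report <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("<flowkern dry run>", length(x$plan), "unit(s) planned:\n")
    for (p in x$plan)
      cat("  ", p$unit, ":", paste(p$jobs, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat("<flowkern run>", if (x$ok) "ok" else "NOT ok", "\n")
  tab <- table(x$status)
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (length(x$deleted_temporaries))
    cat("  deleted temporaries:",
        paste(x$deleted_temporaries, collapse = ", "), "\n")
  invisible(x)
}

#' Write the provenance document of a run
#'
#' One JSON record per executed (or cache-satisfied) job: rule, binding,
#' inputs, outputs, parameters, action text, environment text, start/end
#' times, benchmark record, and the cache digest where applicable. The
#' document shape is versioned in `inst/schema/provenance.schema.json`.
#'
#' @param report an `fk_run_report`.
#' @param path output path; `NULL` returns the JSON text.
#' @return the JSON text, invisibly when written to a file.
#' @export
write_provenance <- function(report, path = NULL) {
  jobs <- lapply(unname(report$provenance), function(rec) {
    rec$inputs <- I(as.character(rec$inputs))
    rec$outputs <- I(as.character(rec$outputs))
    rec
  })
  doc <- list(version = 1L, jobs = jobs)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---- simulation -----------------------------------------------------------

#' Simulate a concurrent execution of a job DAG
#'
#' No action is executed and no file is touched: job durations are drawn at
#' random, selected units run concurrently on a simulated clock, and every
#' completion triggers temporary-file bookkeeping and a new scheduling
#' round — the semantics of an executor with true parallelism. The
#' resulting event log is what the safety replay oracle checks.
#'
#' @param dag an `fk_dag` without unresolved deferred inputs.
#' @param capacities named capacities.
#' @param seed RNG seed for durations and (by shuffling ids) completion
#'   order.
#' @param span_per_group,group_overrides see [partition_groups()].
#' @return list with `events` (ordered list), `status`, `deleted`.
#' @export
simulate_run <- function(dag, capacities = c(cores = 2L), seed = 1L,
                         span_per_group = integer(0),
                         group_overrides = character(0)) {
  if (length(dag$deferred))
    stop("simulate_run does not support deferred inputs", call. = FALSE)
  set.seed(seed)
  st <- .new_state(dag, capacities)
  groups <- partition_groups(dag, span_per_group, group_overrides)
  running <- list()   # unit id -> list(end, members, usage)
  now <- 0
  repeat {
    inst <- build_instance(dag, st$capacities, groups, st$status,
                           running = lapply(running, `[[`, "usage"),
                           temp_registry = st$temp)
    dec <- solve_milp(inst)
    units <- attr(inst, "units")
    for (uid in dec$selected) {
      members <- units[[uid]]
      st$status[members] <- "running"
      u <- inst$jobs[inst$jobs$id == uid, inst$resources, drop = FALSE]
      running[[uid]] <- list(end = now + stats::runif(1, 1, 10),
                             members = members,
                             usage = stats::setNames(as.numeric(u),
                                                     inst$resources))
      .emit(st, "start", unit = uid, jobs = members, time = now,
            usage = running[[uid]]$usage)
    }
    if (!length(running)) break
    # next completion
    ends <- vapply(running, `[[`, 0, "end")
    uid <- names(running)[which.min(ends)]
    now <- running[[uid]]$end
    for (jid in running[[uid]]$members) {
      st$status[[jid]] <- "finished"
      job <- dag$jobs[[jid]]
      for (o in job$outputs)
        if (!is.null(st$temp[[o]])) st$temp[[o]]$present <- TRUE
      .emit(st, "finish", job = jid, time = now)
      delete_eligible_temporaries(st, dag, physical = FALSE)
    }
    running[[uid]] <- NULL
  }
  list(events = st$events, status = st$status, deleted = st$deleted,
       temp = st$temp)
}

#' Replay an event log and check executor safety invariants
#'
#' Verifies that (1) at no instant the summed usage of running units
#' exceeds any capacity, (2) no temporary file is deleted while a consumer
#' is unfinished, and (3) every present temporary file is deleted by run
#' end.
#'
#' @param events event list from [simulate_run()] (or a real run).
#' @param dag the `fk_dag` the events refer to.
#' @param capacities named capacities the run was given.
#' @return list with `ok` and a character vector `violations`.
#' @export
replay_events <- function(events, dag, capacities) {
  capacities <- .as_resources(capacities)
  reg <- .temp_registry(dag)
  finished <- character(0)
  usage <- stats::setNames(numeric(length(capacities)), names(capacities))
  running_usage <- list()
  member_unit <- character(0)
  violations <- character(0)
  for (ev in events) {
    if (ev$type == "start") {
      u <- if (!is.null(ev$usage)) ev$usage else c(cores = 1)
      running_usage[[ev$unit]] <- u
      for (m in ev$jobs) member_unit[[m]] <- ev$unit
      usage[names(u)] <- usage[names(u)] + u
      over <- names(capacities)[usage[names(capacities)] >
                                  capacities + 1e-9]
      if (length(over))
        violations <- c(violations, paste0(
          "capacity of ", paste(over, collapse = ","),
          " exceeded at event ", ev$seq))
    } else if (ev$type == "finish") {
      finished <- c(finished, ev$job)
      uid <- member_unit[[ev$job]]
      if (!is.null(running_usage[[uid]])) {
        members_left <- setdiff(names(member_unit)[member_unit == uid],
                                finished)
        if (!length(members_left)) {
          u <- running_usage[[uid]]
          usage[names(u)] <- usage[names(u)] - u
          running_usage[[uid]] <- NULL
        }
      }
    } else if (ev$type == "delete") {
      tf <- reg[[ev$file]]
      if (is.null(tf)) {
        violations <- c(violations,
                        paste0("deleted untracked file ", ev$file))
      } else if (length(setdiff(tf$consumers, finished))) {
        violations <- c(violations, paste0(
          "premature deletion of ", ev$file, " (unfinished consumer)"))
      }
    }
  }
  deleted <- vapply(Filter(function(e) e$type == "delete", events),
                    `[[`, "", "file")
  produced <- names(reg)[vapply(reg, function(tf)
    tf$producer %in% finished, NA)]
  never <- setdiff(produced, deleted)
  if (length(never))
    violations <- c(violations, paste0(
      "temporary file never deleted: ", paste(never, collapse = ", ")))
  list(ok = !length(violations), violations = violations)
}
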