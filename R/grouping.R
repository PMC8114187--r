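#' Group jobs: graph partitioning and resource aggregation
#'
#' Jobs sharing a group label are partitioned into connected subgraphs of
#' the DAG (connectivity through DAG edges between same-label jobs) and each
#' subgraph — or a pack of up to `span` subgraphs — is submitted and
#' executed as a single unit, a *group job*. Streamed files additionally
#' force their producer and single consumer into one group job regardless
#' of labels. Ungrouped jobs become singleton group jobs. The quotient
#' graph over group jobs must remain acyclic.
#'
#' @name grouping
NULL

#' Partition a job DAG into group jobs
#'
#' Connected components are computed on the subgraph induced by jobs with
#' the same label; components are sorted by their smallest member job id
#' and packed into group jobs of at most `span` components each (ceiling
#' packing, deterministic). Stream-connected producer/consumer pairs are
#' merged first, regardless of labels.
#'
#' @param dag an `fk_dag`.
#' @param span_per_group named integer vector: label -> maximum number of
#'   connected components per submitted group job (default 1 for every
#'   label).
#' @param group_overrides named character vector rule_name -> label,
#'   overriding the rules' own `group` keys.
#' @return list of `fk_group_job` objects, each with `id`, `label`,
#'   `members`; together they cover every job exactly once.
#' @export
partition_groups <- function(dag, span_per_group = integer(0),
                             group_overrides = character(0)) {
  ids <- sort(names(dag$jobs))
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  label <- vapply(ids, function(i) {
    j <- dag$jobs[[i]]
    if (j$rule_name %in% names(group_overrides))
      group_overrides[[j$rule_name]]
    else if (is.null(j$group)) NA_character_ else j$group
  }, "")

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  # streamed files force producer + unique consumer together
  streams <- .stream_pairs(dag)
  for (sp in streams) union_(idx[[sp$producer]], idx[[sp$consumer]])

  ekey <- unique(dag$edges[, c("parent", "child")])
  for (i in seq_len(nrow(ekey))) {
    a <- ekey$parent[i]; b <- ekey$child[i]
    if (!is.na(label[[a]]) && identical(label[[a]], label[[b]]))
      union_(idx[[a]], idx[[b]])
  }

  comp_of <- vapply(seq_len(n), find, 0L)
  comps <- split(ids, comp_of)
  # deterministic order: by smallest member id
  comps <- comps[order(vapply(comps, min, ""))]

  comp_label <- vapply(comps, function(members) {
    labs <- unique(label[members])
    labs <- labs[!is.na(labs)]
    if (length(labs)) labs[1] else NA_character_
  }, "")

  groups <- list()
  for (lab in unique(comp_label[!is.na(comp_label)])) {
    these <- comps[!is.na(comp_label) & comp_label == lab]
    k <- if (lab %in% names(span_per_group))
      max(1L, as.integer(span_per_group[[lab]])) else 1L
    packs <- split(these, ceiling(seq_along(these) / k))
    for (p in packs) {
      members <- sort(unlist(p, use.names = FALSE))
      groups[[length(groups) + 1L]] <- structure(
        list(id = paste0("group:", lab, ":", members[1]),
             label = lab, members = members),
        class = "fk_group_job")
    }
  }
  for (i in which(is.na(comp_label))) {
    members <- sort(comps[[i]])
    groups[[length(groups) + 1L]] <- structure(
      list(id = members[1], label = NA_character_, members = members),
      class = "fk_group_job")
  }
  groups <- groups[order(vapply(groups, function(g) g$members[1], ""))]
  .check_quotient_acyclic(dag, groups)
  groups
}

# streamed output -> (producer, consumer); a stream has exactly one reader
.stream_pairs <- function(dag) {
  out <- list()
  for (j in dag$jobs) {
    streamed <- j$outputs[j$stream]
    for (f in streamed) {
      consumers <- unique(dag$edges$child[dag$edges$file == f])
      if (length(consumers) != 1L)
        stop("streamed file '", f, "' must have exactly one consumer (has ",
             length(consumers), ")", call. = FALSE)
      out[[length(out) + 1L]] <- list(producer = j$id,
                                      consumer = consumers,
                                      file = f)
    }
  }
  out
}

.check_quotient_acyclic <- function(dag, groups) {
  gid <- character(0)
  for (g in groups) gid[g$members] <- g$id
  ekey <- unique(dag$edges[, c("parent", "child")])
  qe <- unique(data.frame(parent = gid[ekey$parent], child = gid[ekey$child],
                          stringsAsFactors = FALSE))
  qe <- qe[qe$parent != qe$child, , drop = FALSE]
  qn <- vapply(groups, `[[`, "", "id")
  indeg <- stats::setNames(integer(length(qn)), qn)
  for (i in seq_len(nrow(qe))) indeg[[qe$child[i]]] <- indeg[[qe$child[i]]] + 1L
  ready <- qn[indeg == 0L]
  seen <- 0L
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    seen <- seen + 1L
    kids <- qe$child[qe$parent == v]
    for (w in kids) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) ready <- c(ready, w)
    }
  }
  if (seen != length(qn)) {
    bad <- names(indeg)[indeg > 0L]
    labs <- unique(vapply(groups[match(bad, qn)], `[[`, "", "label"))
    stop("group partition yields a cyclic quotient graph (labels involved: ",
         paste(stats::na.omit(labs), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate the resources of a group job
#'
#' Members are layered by longest-path depth within the member-induced
#' subgraph. For every resource except runtime the aggregate is the maximum
#' over levels of the within-level sum (jobs on one level may run in
#' parallel); for runtime it is, vice versa, the sum over levels of the
#' within-level maximum (levels run in series).
#'
#' @param group an `fk_group_job` (or any list with a `members` field).
#' @param dag the `fk_dag` the members belong to.
#' @param runtime_resource name of the runtime entry in each job's
#'   resources mapping (default `"runtime"`; jobs lacking it count 1 time
#'   unit).
#' @return list with `resources` (named integer vector, aggregated) and
#'   `runtime` (integer).
#' @export
aggregate_resources <- function(group, dag, runtime_resource = "runtime") {
  members <- group$members
  stopifnot(length(members) >= 1L)
  ekey <- unique(dag$edges[, c("parent", "child")])
  ekey <- ekey[ekey$parent %in% members & ekey$child %in% members, ,
               drop = FALSE]
  level <- stats::setNames(rep(0L, length(members)), members)
  for (m in .member_topo(members, ekey)) {
    ps <- ekey$parent[ekey$child == m]
    if (length(ps)) level[[m]] <- max(level[ps]) + 1L
  }
  res_names <- unique(unlist(lapply(members, function(m)
    names(dag$jobs[[m]]$resources))))
  res_names <- setdiff(res_names, runtime_resource)
  usage <- function(m, r) {
    u <- dag$jobs[[m]]$resources
    if (r %in% names(u)) u[[r]] else 0L
  }
  runtime_of <- function(m) {
    u <- dag$jobs[[m]]$resources
    if (runtime_resource %in% names(u)) u[[runtime_resource]] else 1L
  }
  levels <- sort(unique(level))
  agg <- stats::setNames(integer(length(res_names)), res_names)
  runtime <- 0L
  for (lv in levels) {
    on_lv <- members[level[members] == lv]
    for (r in res_names)
      agg[[r]] <- max(agg[[r]], sum(vapply(on_lv, usage, 0L, r = r)))
    runtime <- runtime + max(vapply(on_lv, runtime_of, 0L))
  }
  list(resources = agg, runtime = runtime)
}

.member_topo <- function(members, ekey) {
  indeg <- stats::setNames(integer(length(members)), members)
  for (i in seq_len(nrow(ekey)))
    indeg[[ekey$child[i]]] <- indeg[[ekey$child[i]]] + 1L
  ready <- sort(members[indeg == 0L])
  out <- character(0)
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (w in ekey$child[ekey$parent == v]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) ready <- sort(c(ready, w))
    }
  }
  out
}

#' Force a streamed producer/consumer pair into one group job
#'
#' The streamed intermediate is written to an in-memory buffer (a named
#' pipe) where the platform supports it; the engine otherwise downgrades it
#' to a short-lived temporary file removed as soon as the consumer
#' finishes, with a logged note. Jobs already grouped together are left
#' unchanged (idempotent).
#'
#' @param dag an `fk_dag` in which an output of `producer_id` flagged as
#'   streamed is an input of `consumer_id` and of no other job.
#' @param producer_id,consumer_id member job ids.
#' @param span_per_group,group_overrides passed through to
#'   [partition_groups()].
#' @return the `fk_group_job` containing both jobs.
#' @export
co_schedule_stream <- function(dag, producer_id, consumer_id,
                               span_per_group = integer(0),
                               group_overrides = character(0)) {
  pj <- dag$jobs[[producer_id]]
  if (is.null(pj)) stop("unknown job: ", producer_id, call. = FALSE)
  streamed <- pj$outputs[pj$stream]
  feeding <- dag$edges$file[dag$edges$parent == producer_id &
                              dag$edges$child == consumer_id]
  if (!length(intersect(streamed, feeding)))
    stop("no streamed output of ", producer_id, " feeds ", consumer_id,
         call. = FALSE)
  groups <- partition_groups(dag, span_per_group, group_overrides)
  for (g in groups)
    if (producer_id %in% g$members) {
      if (!consumer_id %in% g$members)
        stop("internal error: stream pair split across group jobs",
             call. = FALSE)
      return(g)
    }
  stop("internal error: producer not covered by partition", call. = FALSE)
}

#' @export
print.fk_group_job <- function(x, ...) {
  cat("<flowkern group job>", x$id,
      if (!is.na(x$label)) paste0("[", x$label, "]") else "",
      "\n  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}
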