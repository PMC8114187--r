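#' Workflow and rule objects
#'
#' A workflow is an ordered list of rules. Each rule is a generic
#' transformation template: wildcard patterns for inputs and outputs, a shell
#' action, optional parameters, a priority, resource usages, an optional
#' group label, and flags (temporary outputs, cacheability, checkpoint).
#' Substituting concrete wildcard values turns a rule into a job.
#'
#' @name workflow-objects
NULL

#' Construct a rule
#'
#' @param name rule name (identifier).
#' @param inputs list of input entries: character patterns, or deferred-input
#'   resolvers created by [input_resolver()].
#' @param outputs character vector of output patterns.
#' @param temp logical vector parallel to `outputs`: delete after last
#'   consumer finishes.
#' @param cacheable logical flag: outputs may be stored in / restored from
#'   the provenance cache (opt-in; default `FALSE` because only
#'   deterministic actions should be cached).
#' @param params named list of parameter values (serializable to JSON).
#' @param priority non-negative integer scheduling priority.
#' @param resources named non-negative integer usages; always includes
#'   `cores` (default 1).
#' @param group optional group label for graph partitioning.
#' @param action shell command template; `{input}`, `{output}`, `{log}`,
#'   `{input[i]}`, `{output[i]}`, `{params.key}` and `{wildcards.name}` are
#'   substituted, all other braces are left verbatim.
#' @param environment free-text software environment descriptor.
#' @param is_checkpoint logical: downstream deferred inputs are re-evaluated
#'   after this rule's jobs finish.
#' @param log optional log-file pattern.
#' @param stream logical vector parallel to `outputs`: streamed to a single
#'   consumer, never stored persistently.
#' @param wildcard_constraints named character vector of per-wildcard
#'   regexes (one constraint per name per rule).
#' @return object of class `fk_rule`.
#' @export
rule <- function(name, inputs = list(), outputs = character(0),
                 temp = NULL, cacheable = FALSE, params = list(),
                 priority = 0L, resources = c(cores = 1L), group = NULL,
                 action = "", environment = "", is_checkpoint = FALSE,
                 log = NULL, stream = NULL, wildcard_constraints = NULL) {
  if (!grepl(.wc_name_re, name))
    stop("invalid rule name: ", name, call. = FALSE)
  if (is.character(inputs)) inputs <- as.list(inputs)
  outputs <- vapply(outputs, normalize_relpath, "", USE.NAMES = FALSE)
  if (is.null(temp)) temp <- rep(FALSE, length(outputs))
  if (is.null(stream)) stream <- rep(FALSE, length(outputs))
  stopifnot(length(temp) == length(outputs),
            length(stream) == length(outputs))
  resources <- .as_resources(resources)
  priority <- .as_count(priority, "priority")
  r <- structure(list(
    name = name, inputs = inputs, outputs = outputs,
    temp = as.logical(temp), stream = as.logical(stream),
    cacheable = isTRUE(cacheable), params = params,
    priority = priority, resources = resources,
    group = if (is.null(group) || !nzchar(group)) NULL else group,
    action = action, environment = environment,
    is_checkpoint = isTRUE(is_checkpoint),
    log = if (is.null(log)) NULL else normalize_relpath(log),
    wildcard_constraints = wildcard_constraints
  ), class = "fk_rule")
  validate_rule(r)
  r
}

#' Deferred-input resolver
#'
#' A declarative stand-in for arbitrary input functions: once the named
#' checkpoint rule has finished, the resolver reads a delimited table it
#' produced, keeps the rows whose `column` passes the threshold comparison,
#' and requests one concrete path per surviving row by substituting the
#' row's `var` column into the `emit` pattern.
#'
#' @param checkpoint name of the checkpoint rule this resolver depends on.
#' @param table path (pattern) of the delimited table, an output of the
#'   checkpoint.
#' @param column column examined by the filter.
#' @param threshold numeric threshold.
#' @param emit path pattern requested per surviving row; may use `{var}`.
#' @param var column providing the per-row wildcard value (default
#'   `"sample"`).
#' @param op comparison: one of `"gt"`, `"ge"`, `"lt"`, `"le"`, `"eq"`.
#' @return object of class `fk_resolver`.
#' @export
input_resolver <- function(checkpoint, table, column, threshold, emit,
                           var = "sample", op = "gt") {
  op <- match.arg(op, c("gt", "ge", "lt", "le", "eq"))
  structure(list(checkpoint = checkpoint, table = normalize_relpath(table),
                 column = column, threshold = threshold,
                 emit = normalize_relpath(emit), var = var, op = op),
            class = "fk_resolver")
}

is_resolver <- function(x) inherits(x, "fk_resolver")

.as_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
    stop(what, " must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}

.as_resources <- function(resources) {
  if (is.null(resources)) resources <- c(cores = 1L)
  resources <- unlist(resources)
  if (is.null(names(resources)) || any(!nzchar(names(resources))))
    stop("resources must be named", call. = FALSE)
  if (!"cores" %in% names(resources))
    resources <- c(cores = 1L, resources)
  if (any(is.na(resources)) || any(resources < 0) ||
      any(resources != as.integer(resources)))
    stop("resource usages must be non-negative integers", call. = FALSE)
  storage.mode(resources) <- "integer"
  resources
}

# Wildcard names referenced anywhere outside the outputs of a rule.
rule_used_wildcards <- function(r) {
  used <- character(0)
  for (inp in r$inputs) {
    if (is_resolver(inp)) {
      used <- c(used, wildcard_names(inp$table))
    } else used <- c(used, wildcard_names(inp))
  }
  if (!is.null(r$log)) used <- c(used, wildcard_names(r$log))
  used <- c(used, .action_wildcards(r$action))
  for (v in r$params)
    if (is.character(v) && length(v) == 1L)
      used <- c(used, .action_wildcards(v))
  unique(used)
}

.action_wildcards <- function(action) {
  m <- gregexpr("\\{wildcards\\.([A-Za-z_][A-Za-z0-9_]*)\\}", action)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(action, gregexpr(
    "\\{wildcards\\.([A-Za-z_][A-Za-z0-9_]*)\\}", action))[[1]]
  unique(sub("^\\{wildcards\\.", "", sub("\\}$", "", toks)))
}

validate_rule <- function(r) {
  out_wc <- unique(unlist(lapply(r$outputs, wildcard_names)))
  for (o in r$outputs) wc_tokens(o)  # brace validation
  used <- rule_used_wildcards(r)
  extra <- setdiff(used, out_wc)
  if (length(extra))
    stop("rule '", r$name, "': wildcard(s) ", paste(extra, collapse = ", "),
         " used in inputs/params/action/log but absent from every output ",
         "pattern", call. = FALSE)
  if (!is.null(r$wildcard_constraints)) {
    cn <- names(r$wildcard_constraints)
    if (anyDuplicated(cn))
      stop("rule '", r$name, "': conflicting wildcard constraints for ",
           paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  }
  invisible(r)
}

#' Construct a workflow
#'
#' @param rules list of [rule()] objects (order is significant: declaration
#'   order is the final producer-ambiguity tie-break).
#' @param ruleorder list of character vectors; each vector ranks rule names
#'   from highest to lowest precedence for producer resolution.
#' @param config free-form named list.
#' @return object of class `fk_workflow`.
#' @export
workflow <- function(rules, ruleorder = list(), config = list()) {
  nms <- vapply(rules, `[[`, "", "name")
  dup <- nms[duplicated(nms)]
  if (length(dup))
    stop("duplicate rule name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (chain in ruleorder) {
    unknown <- setdiff(chain, nms)
    if (length(unknown))
      stop("ruleorder mentions unknown rule(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  names(rules) <- nms
  structure(list(rules = rules, ruleorder = ruleorder, config = config),
            class = "fk_workflow")
}

#' Parse a workflow document
#'
#' Reads the YAML workflow dialect: a top-level `rules:` mapping (plus
#' optional `config:` and `ruleorder:`), with per-rule keys `input`,
#' `output`, `params`, `priority`, `resources`, `group`, `temp` (1-based
#' output indices or output pattern texts), `stream`, `cache`, `checkpoint`,
#' `shell`, `env`, `log`, and `wildcard_constraints`. A deferred input is a
#' mapping with a single `resolver:` key. The machine-readable schema ships
#' in `inst/schema/workflow.schema.json`.
#'
#' @param document YAML text, or the path of a YAML file.
#' @return validated [workflow()] object.
#' @export
#' @examples
#' wf <- parse_workflow("
#' rules:
#'   all:
#'     input: [results/x.txt]
#'   make:
#'     output: 'results/{name}.txt'
#'     shell: 'echo {wildcards.name} > {output}'
#' ")
parse_workflow <- function(document) {
  doc <- if (length(document) == 1L && !grepl("\n", document) &&
             file.exists(document)) {
    yaml::read_yaml(document)
  } else yaml::yaml.load(paste(document, collapse = "\n"))
  if (!is.list(doc) || is.null(doc$rules) || !length(doc$rules))
    stop("workflow parse error: top-level 'rules' mapping is required",
         call. = FALSE)
  if (is.null(names(doc$rules)) || any(!nzchar(names(doc$rules))))
    stop("workflow parse error: every rule needs a name", call. = FALSE)
  if (anyDuplicated(names(doc$rules)))
    stop("duplicate rule name(s): ",
         paste(unique(names(doc$rules)[duplicated(names(doc$rules))]),
               collapse = ", "), call. = FALSE)
  allowed <- c("input", "output", "params", "priority", "resources", "group",
               "temp", "stream", "cache", "checkpoint", "shell", "env",
               "log", "wildcard_constraints")
  rules <- vector("list", length(doc$rules))
  for (i in seq_along(doc$rules)) {
    nm <- names(doc$rules)[i]
    rd <- doc$rules[[i]]
    if (is.null(rd)) rd <- list()
    bad <- setdiff(names(rd), allowed)
    if (length(bad))
      stop("workflow parse error: rule '", nm, "' has unknown field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    inputs <- .parse_inputs(rd$input, nm)
    outputs <- as.character(unlist(rd$output))
    temp <- .parse_flag_list(rd$temp, outputs, nm, "temp")
    stream <- .parse_flag_list(rd$stream, outputs, nm, "stream")
    rules[[i]] <- tryCatch(
      rule(name = nm, inputs = inputs, outputs = outputs, temp = temp,
           stream = stream, cacheable = isTRUE(rd$cache),
           params = if (is.null(rd$params)) list() else rd$params,
           priority = if (is.null(rd$priority)) 0L else rd$priority,
           resources = if (is.null(rd$resources)) c(cores = 1L)
                       else rd$resources,
           group = rd$group,
           action = if (is.null(rd$shell)) "" else rd$shell,
           environment = if (is.null(rd$env)) "" else rd$env,
           is_checkpoint = isTRUE(rd$checkpoint),
           log = rd$log,
           wildcard_constraints = rd$wildcard_constraints),
      error = function(e) stop("workflow parse error in rule '", nm, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  workflow(rules,
           ruleorder = .parse_ruleorder(doc$ruleorder),
           config = if (is.null(doc$config)) list() else doc$config)
}

.parse_inputs <- function(input, rule_name) {
  if (is.null(input)) return(list())
  if (is.character(input)) return(as.list(input))
  if (!is.list(input)) input <- list(input)
  lapply(input, function(x) {
    if (is.character(x)) return(x)
    if (is.list(x) && identical(names(x), "resolver")) {
      rs <- x$resolver
      need <- c("checkpoint", "table", "column", "threshold", "emit")
      missing <- setdiff(need, names(rs))
      if (length(missing))
        stop("rule '", rule_name, "': resolver is missing field(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      return(input_resolver(rs$checkpoint, rs$table, rs$column,
                            rs$threshold, rs$emit,
                            var = if (is.null(rs$var)) "sample" else rs$var,
                            op = if (is.null(rs$op)) "gt" else rs$op))
    }
    stop("rule '", rule_name, "': invalid input entry", call. = FALSE)
  })
}

# temp/stream: YAML gives 1-based output indices or output pattern texts.
.parse_flag_list <- function(spec, outputs, rule_name, what) {
  flags <- rep(FALSE, length(outputs))
  if (is.null(spec)) return(flags)
  for (x in unlist(spec)) {
    if (is.numeric(x)) {
      if (x < 1 || x > length(outputs))
        stop("rule '", rule_name, "': ", what, " index ", x,
             " out of range", call. = FALSE)
      flags[as.integer(x)] <- TRUE
    } else {
      hit <- which(outputs == normalize_relpath(as.character(x)))
      if (!length(hit))
        stop("rule '", rule_name, "': ", what, " entry '", x,
             "' names no output", call. = FALSE)
      flags[hit] <- TRUE
    }
  }
  flags
}

.parse_ruleorder <- function(ro) {
  if (is.null(ro)) return(list())
  if (is.character(ro)) ro <- list(ro)
  lapply(ro, function(x) {
    if (is.character(x) && length(x) == 1L && grepl(">", x))
      trimws(strsplit(x, ">", fixed = TRUE)[[1]])
    else as.character(unlist(x))
  })
}

#' @export
print.fk_workflow <- function(x, ...) {
  cat("<flowkern workflow>", length(x$rules), "rule(s):\n")
  for (r in x$rules) {
    cat(sprintf("  %s%s: %d input(s) -> %d output(s)%s\n", r$name,
                if (r$is_checkpoint) " [checkpoint]" else "",
                length(r$inputs), length(r$outputs),
                if (!length(r$outputs)) " [target rule]" else ""))
  }
  invisible(x)
}

#' @export
print.fk_rule <- function(x, ...) {
  cat("<flowkern rule>", x$name, "\n")
  invisible(x)
}

#' Is a rule target-only?
#'
#' A rule with no outputs only aggregates requested files; it is never
#' matched as a producer.
#'
#' @param r an `fk_rule`.
#' @return logical.
#' @export
is_target_rule <- function(r) length(r$outputs) == 0L
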