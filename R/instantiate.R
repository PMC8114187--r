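#' Turn a rule into a concrete job
#'
#' Substitutes a wildcard binding into every pattern of the rule (inputs,
#' outputs, log) and renders the shell action. The job inherits priority,
#' resources, group label, flags and parameters from the rule; string
#' parameters may themselves contain `{wildcard}` placeholders, which are
#' substituted as well.
#'
#' @param rule an [rule()] object.
#' @param binding named character vector of wildcard values covering every
#'   wildcard the rule uses.
#' @param defer_resolvers if `TRUE` (default), deferred inputs remain
#'   unresolved markers on the job; if `FALSE`, the presence of a resolver
#'   is an error.
#' @return object of class `fk_job`.
#' @export
#' @examples
#' r <- rule("sel", inputs = "data.csv",
#'           outputs = "results/by-country/{country}.csv",
#'           action = "grep {wildcards.country} {input} > {output}")
#' instantiate(r, c(country = "X"))
instantiate <- function(rule, binding = character(0),
                        defer_resolvers = TRUE) {
  stopifnot(inherits(rule, "fk_rule"))
  binding <- .check_binding(binding)
  need <- unique(c(unlist(lapply(rule$outputs, wildcard_names)),
                   rule_used_wildcards(rule)))
  missing <- setdiff(need, names(binding))
  if (length(missing))
    stop("cannot instantiate rule '", rule$name, "': binding is missing ",
         "wildcard(s): ", paste(missing, collapse = ", "), call. = FALSE)
  inputs <- character(0)
  resolvers <- list()
  for (inp in rule$inputs) {
    if (is_resolver(inp)) {
      if (!defer_resolvers)
        stop("rule '", rule$name, "' has a deferred input that is not yet ",
             "resolvable", call. = FALSE)
      rs <- inp
      rs$table <- substitute_pattern(rs$table, binding)
      resolvers[[length(resolvers) + 1L]] <- rs
    } else {
      inputs <- c(inputs, substitute_pattern(inp, binding))
    }
  }
  outputs <- vapply(rule$outputs, substitute_pattern, "", binding = binding,
                    USE.NAMES = FALSE)
  if (anyDuplicated(outputs))
    stop("rule '", rule$name, "': outputs are not pairwise disjoint after ",
         "substitution", call. = FALSE)
  log <- if (is.null(rule$log)) NULL else
    substitute_pattern(rule$log, binding)
  params <- lapply(rule$params, function(v) {
    if (is.character(v) && length(v) == 1L && length(wildcard_names(v)))
      substitute_pattern(v, binding) else v
  })
  action <- render_action(rule$action, inputs, outputs, params, binding, log)
  structure(list(
    id = job_id(rule$name, binding),
    rule_name = rule$name, binding = binding,
    inputs = inputs, resolvers = resolvers,
    outputs = outputs, temp = rule$temp, stream = rule$stream,
    cacheable = rule$cacheable, params = params,
    priority = rule$priority, resources = rule$resources,
    group = rule$group, action = action, environment = rule$environment,
    is_checkpoint = rule$is_checkpoint, log = log,
    status = "open"
  ), class = "fk_job")
}

.check_binding <- function(binding) {
  if (!length(binding)) return(stats::setNames(character(0), character(0)))
  binding <- unlist(binding)
  if (is.null(names(binding)) || any(!grepl(.wc_name_re, names(binding))))
    stop("binding keys must be valid wildcard names", call. = FALSE)
  if (any(is.na(binding)) || any(!nzchar(binding)))
    stop("binding values must be non-empty", call. = FALSE)
  binding[order(names(binding))]
}

#' Stable job identifier
#'
#' Deterministic function of rule name and binding (keys sorted), so that
#' identical (rule, binding) pairs merge to one job and job ids are stable
#' across rebuilds.
#'
#' @param rule_name rule name.
#' @param binding named character vector.
#' @return character id.
#' @export
job_id <- function(rule_name, binding = character(0)) {
  if (!length(binding)) return(rule_name)
  b <- binding[order(names(binding))]
  paste0(rule_name, "|", paste0(names(b), "=", b, collapse = ","))
}

#' Render a shell action template
#'
#' Substitutes the recognized `{...}` references (`input`, `output`, `log`,
#' `input[i]`/`output[i]` with 1-based indices, `params.key`,
#' `wildcards.name`). Any other braced text (e.g. awk blocks) is left
#' verbatim.
#'
#' @param template action template text.
#' @param inputs,outputs concrete path vectors.
#' @param params concrete parameter list.
#' @param binding wildcard binding.
#' @param log concrete log path or `NULL`.
#' @return concrete command text.
#' @keywords internal
render_action <- function(template, inputs, outputs, params = list(),
                          binding = character(0), log = NULL) {
  subst <- function(text, token, value) {
    gsub(paste0("{", token, "}"), value, text, fixed = TRUE)
  }
  out <- template
  # indexed references first, so {input} does not shadow {input[2]}
  for (ref in c("input", "output")) {
    v <- if (ref == "input") inputs else outputs
    m <- gregexpr(sprintf("\\{%s\\[([0-9]+)\\]\\}", ref), out)[[1]]
    if (m[1] != -1L) {
      toks <- unique(regmatches(out, gregexpr(
        sprintf("\\{%s\\[([0-9]+)\\]\\}", ref), out))[[1]])
      for (tok in toks) {
        i <- as.integer(sub(".*\\[([0-9]+)\\].*", "\\1", tok))
        if (i < 1L || i > length(v))
          stop("action references ", tok, " but there are only ",
               length(v), " ", ref, "(s)", call. = FALSE)
        out <- gsub(tok, v[i], out, fixed = TRUE)
      }
    }
  }
  out <- subst(out, "input", paste(inputs, collapse = " "))
  out <- subst(out, "output", paste(outputs, collapse = " "))
  if (grepl("{log}", out, fixed = TRUE)) {
    if (is.null(log))
      stop("action references {log} but the rule declares no log",
           call. = FALSE)
    out <- subst(out, "log", log)
  }
  for (k in names(params)) {
    v <- params[[k]]
    vtxt <- if (is.character(v) && length(v) == 1L) v else
      as.character(jsonlite::toJSON(v, auto_unbox = TRUE))
    out <- subst(out, paste0("params.", k), vtxt)
  }
  for (k in names(binding))
    out <- subst(out, paste0("wildcards.", k), binding[[k]])
  leftover <- .action_wildcards(out)
  if (length(leftover))
    stop("action references unknown wildcard(s): ",
         paste(leftover, collapse = ", "), call. = FALSE)
  out
}

#' @export
print.fk_job <- function(x, ...) {
  cat("<flowkern job>", x$id, sprintf("[%s]", x$status), "\n")
  if (length(x$inputs)) cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$outputs)) cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}
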