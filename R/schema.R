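#' Structural JSON-schema validation
#'
#' A small validator for the subset of JSON Schema the shipped schemas use
#' (`type`, `properties`, `required`, `items`, `enum`,
#' `additionalProperties` as a boolean or subschema, `patternProperties`).
#' Used to check workflow documents and provenance documents against the
#' versioned schemas in `inst/schema/`.
#'
#' @param instance parsed JSON value (e.g. from [jsonlite::read_json()] or
#'   [yaml::read_yaml()]).
#' @param schema parsed schema, or the path of a schema file.
#' @return character vector of violation messages; empty when valid.
#' @export
schema_violations <- function(instance, schema) {
  if (is.character(schema) && length(schema) == 1L && file.exists(schema))
    schema <- jsonlite::read_json(schema)
  .sv(instance, schema, "$")
}

.sv <- function(x, sch, path) {
  out <- character(0)
  if (!is.null(sch$type)) {
    ok <- switch(sch$type,
      object = is.list(x) && (!length(x) || !is.null(names(x))),
      # YAML/JSON readers collapse one-element sequences to scalars, so a
      # length-1 atomic counts as an array
      array = (is.list(x) && (is.null(names(x)) || !length(x))) ||
        is.atomic(x),
      string = is.character(x) && length(x) == 1L,
      number = is.numeric(x) && length(x) == 1L,
      integer = is.numeric(x) && length(x) == 1L && x == as.integer(x),
      boolean = is.logical(x) && length(x) == 1L,
      null = is.null(x),
      TRUE)
    if (!isTRUE(ok))
      return(paste0(path, ": expected ", sch$type))
  }
  if (!is.null(sch$enum)) {
    if (!any(vapply(sch$enum, identical, NA, y = x)))
      out <- c(out, paste0(path, ": value not in enum"))
  }
  if (identical(sch$type, "object")) {
    for (req in unlist(sch$required))
      if (!req %in% names(x))
        out <- c(out, paste0(path, ": missing required property '", req, "'"))
    for (nm in names(x)) {
      sub <- sch$properties[[nm]]
      matched <- !is.null(sub)
      if (is.null(sub) && !is.null(sch$patternProperties)) {
        for (pat in names(sch$patternProperties)) {
          if (grepl(pat, nm)) {
            sub <- sch$patternProperties[[pat]]
            matched <- TRUE
            break
          }
        }
      }
      if (!is.null(sub)) {
        out <- c(out, .sv(x[[nm]], sub, paste0(path, ".", nm)))
      } else if (isFALSE(sch$additionalProperties) && !matched) {
        out <- c(out, paste0(path, ": unexpected property '", nm, "'"))
      } else if (is.list(sch$additionalProperties)) {
        out <- c(out, .sv(x[[nm]], sch$additionalProperties,
                          paste0(path, ".", nm)))
      }
    }
  }
  if (identical(sch$type, "array") && !is.null(sch$items)) {
    items <- if (is.list(x) && is.null(names(x))) x else as.list(x)
    for (i in seq_along(items))
      out <- c(out, .sv(items[[i]], sch$items,
                        paste0(path, "[", i, "]")))
  }
  out
}
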