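#' Provenance hashing and the between-workflow result cache
#'
#' Every job's outputs can be addressed by a recursive SHA-256 digest over
#' everything that determines their content: the concrete action text, the
#' parameters (key/value pairs as canonical JSON), the content digests of
#' raw input files (inputs not produced by any job), the software
#' environment descriptor, and — blockchain style — the digests of all
#' dependency jobs. Any change in an ancestor therefore propagates to every
#' descendant digest.
#'
#' Plain concatenation of fields is ambiguity-prone (`k="ab", v="c"` versus
#' `k="a", v="bc"`), so every field is length-prefixed (decimal byte length,
#' `:`, then the UTF-8 bytes) before concatenation. This framing is part of
#' the documented byte-level encoding and makes digests stable across
#' platforms; it intentionally differs from any encoding that concatenates
#' fields bare.
#'
#' @name provenance-cache
NULL

# length-prefix a field: "<decimal byte length>:<utf8 bytes>"
.lp <- function(x) {
  x <- enc2utf8(as.character(x))
  paste0(nchar(x, type = "bytes"), ":", x)
}

#' Canonical JSON text for a parameter value
#'
#' Objects are serialized with keys sorted recursively, scalars unboxed,
#' full numeric precision; the result is byte-stable.
#'
#' @param value any JSON-serializable R value.
#' @return character scalar.
#' @export
canonical_json <- function(value) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x))
      x <- lapply(x[order(names(x))], sort_keys)
    else if (is.list(x)) x <- lapply(x, sort_keys)
    x
  }
  as.character(jsonlite::toJSON(sort_keys(value), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

#' Build a provenance record
#'
#' @param code concrete action text of the job.
#' @param params named list of parameter values (canonicalized to JSON).
#' @param raw_input_digests named character vector: raw input path ->
#'   SHA-256 content digest (use [file_digest()]).
#' @param environment software environment descriptor text.
#' @param dep_digests character vector of dependency job digests
#'   (order-free; concatenated in lexicographic order).
#' @return object of class `fk_provenance`.
#' @export
provenance_record <- function(code, params = list(),
                              raw_input_digests = character(0),
                              environment = "",
                              dep_digests = character(0)) {
  if (length(params) && (is.null(names(params)) ||
                         any(!nzchar(names(params)))))
    stop("params must be named", call. = FALSE)
  structure(list(
    code = code,
    params = if (length(params)) params[order(names(params))] else list(),
    raw_input_digests = raw_input_digests,
    environment = environment,
    dep_digests = as.character(dep_digests)
  ), class = "fk_provenance")
}

#' SHA-256 content digest of a file
#'
#' @param path file path.
#' @return 64-character lowercase hex digest.
#' @export
file_digest <- function(path) {
  if (!file.exists(path))
    stop("cannot digest unreadable raw input: ", path, call. = FALSE)
  digest::digest(file = path, algo = "sha256")
}

#' Recursive provenance digest of a job
#'
#' SHA-256 over the length-prefixed concatenation of: the parameter pairs
#' in sorted-key order (key then canonical-JSON value), the action text,
#' the raw-input content digests in lexicographic order, the environment
#' descriptor, and the dependency digests in lexicographic order. Each
#' variable-length section (parameters, raw inputs, dependencies) is
#' preceded by its element count as a length-prefixed decimal, so the byte
#' string parses back into fields uniquely.
#'
#' @param record an `fk_provenance`.
#' @return 64-character lowercase hex digest.
#' @export
provenance_hash <- function(record) {
  stopifnot(inherits(record, "fk_provenance"))
  ptxt <- vapply(record$params, function(v)
    tryCatch(canonical_json(v), error = function(e)
      stop("unserializable param value", call. = FALSE)), "")
  .hash_pieces(names(record$params), unname(ptxt), record$code,
               unname(record$raw_input_digests), record$environment,
               record$dep_digests)
}

# Assemble the framed byte string and digest it. `param_values` are
# already canonical JSON texts.
.hash_pieces <- function(param_keys, param_values, code, raw_digests,
                         environment, dep_digests) {
  pieces <- .lp(length(param_keys))
  for (i in seq_along(param_keys))
    pieces <- c(pieces, .lp(param_keys[i]), .lp(param_values[i]))
  pieces <- c(pieces, .lp(code),
              .lp(length(raw_digests)), .lp(sort(raw_digests)),
              .lp(environment),
              .lp(length(dep_digests)), .lp(sort(dep_digests)))
  digest::digest(charToRaw(paste(pieces, collapse = "")),
                 algo = "sha256", serialize = FALSE)
}

#' Compute provenance digests for all (resolvable) jobs of a DAG
#'
#' Walks the DAG bottom-up; raw inputs (inputs no job produces) are
#' digested from disk under the DAG's working directory. Jobs with still
#' deferred inputs are skipped, as are their descendants.
#'
#' @param dag an `fk_dag`.
#' @return named character vector job id -> digest (jobs that could not be
#'   hashed are absent).
#' @export
job_digests <- function(dag) {
  produced <- unlist(lapply(dag$jobs, `[[`, "outputs"))
  parents <- dag_parents(dag)
  deferred_ids <- vapply(dag$deferred, `[[`, "", "consumer")
  digests <- character(0)
  for (jid in topological_order(dag)) {
    job <- dag$jobs[[jid]]
    if (jid %in% deferred_ids || length(job$resolvers)) next
    deps <- parents[[jid]]
    if (length(setdiff(deps, names(digests)))) next  # an ancestor skipped
    raw <- setdiff(job$inputs, produced)
    raw_dg <- tryCatch(
      vapply(raw, function(p) file_digest(file.path(dag$workdir, p)), ""),
      error = function(e) NULL)
    if (is.null(raw_dg)) next
    rec <- provenance_record(code = job$action, params = job$params,
                             raw_input_digests = raw_dg,
                             environment = job$environment,
                             dep_digests = unname(digests[deps]))
    digests[[jid]] <- provenance_hash(rec)
  }
  digests
}

# sidecar filename inside a cache entry
.sidecar <- "provenance.json"

#' Store a job's outputs in the content-addressed cache
#'
#' Writes to a staging directory first and renames it into place, so that
#' no partial entry ever becomes visible and concurrent stores of the same
#' digest resolve to one entry. Refuses jobs whose rule is not flagged
#' cacheable.
#'
#' @param digest the job's provenance digest (cache address).
#' @param outputs named character vector: relative output name -> path of
#'   the file to store.
#' @param record the `fk_provenance` the digest was computed from.
#' @param cache_root cache directory (created if absent).
#' @param cacheable is the rule flagged cacheable? (guard; default `TRUE`).
#' @param rule_name stored as metadata.
#' @return invisibly, the entry directory path.
#' @export
cache_store <- function(digest, outputs, record, cache_root,
                        cacheable = TRUE, rule_name = NA_character_) {
  if (!isTRUE(cacheable))
    stop("rule is not flagged cacheable; refusing to store", call. = FALSE)
  if (is.null(names(outputs)) || any(!nzchar(names(outputs))))
    stop("outputs must be named by their relative entry name", call. = FALSE)
  dir.create(cache_root, recursive = TRUE, showWarnings = FALSE)
  entry <- file.path(cache_root, digest)
  if (dir.exists(entry)) return(invisible(entry))  # concurrent store won
  staging <- tempfile(paste0(".staging-", digest, "-"), tmpdir = cache_root)
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)
  out_dg <- character(0)
  for (nm in names(outputs)) {
    src <- outputs[[nm]]
    if (!file.exists(src))
      stop("output to cache does not exist: ", src, call. = FALSE)
    dst <- file.path(staging, nm)
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    if (!file.copy(src, dst, copy.date = TRUE))
      stop("staging copy failed for ", src, call. = FALSE)
    out_dg[[nm]] <- file_digest(dst)
  }
  meta <- list(
    version = 1L, digest = digest, rule = rule_name,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(out_dg),
    provenance = list(
      code = record$code,
      params = lapply(record$params, canonical_json),
      raw_input_digests = as.list(record$raw_input_digests),
      environment = record$environment,
      dep_digests = as.list(record$dep_digests)
    ))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(staging, .sidecar))
  ok <- file.rename(staging, entry)
  if (!ok && dir.exists(entry)) {
    unlink(staging, recursive = TRUE)
    ok <- TRUE
  }
  if (!ok) stop("could not move staged cache entry into place", call. = FALSE)
  invisible(entry)
}

#' Look up a digest in the cache
#'
#' The entry passes the integrity check iff the sidecar's recorded digest
#' can be recomputed from the stored provenance fields and every stored
#' output matches its recorded content digest. A corrupted entry is
#' quarantined (moved aside) and reported as a miss.
#'
#' @param digest cache address.
#' @param cache_root cache directory.
#' @return `NULL` (miss) or a list with `digest`, `dir`, `outputs` (named
#'   paths inside the entry), `meta`.
#' @export
cache_lookup <- function(digest, cache_root) {
  entry <- file.path(cache_root, digest)
  if (!dir.exists(entry)) return(NULL)
  meta_path <- file.path(entry, .sidecar)
  quarantine <- function(reason) {
    qdir <- file.path(cache_root, "quarantine")
    dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
    file.rename(entry, file.path(qdir, paste0(digest, "-",
                                              format(Sys.time(), "%Y%m%d%H%M%OS3"))))
    warning("cache entry ", digest, " quarantined: ", reason, call. = FALSE)
    NULL
  }
  if (!file.exists(meta_path)) return(quarantine("missing sidecar"))
  meta <- tryCatch(jsonlite::read_json(meta_path), error = function(e) NULL)
  if (is.null(meta)) return(quarantine("unreadable sidecar"))
  pv <- meta$provenance
  recomputed <- .hash_pieces(
    names(pv$params), unname(unlist(c(pv$params, list()))),
    pv$code,
    as.character(unlist(c(pv$raw_input_digests, list()))),
    pv$environment,
    as.character(unlist(c(pv$dep_digests, list()))))
  if (!identical(recomputed, meta$digest) || !identical(digest, meta$digest))
    return(quarantine("sidecar digest mismatch"))
  outs <- character(0)
  for (nm in names(meta$outputs)) {
    p <- file.path(entry, nm)
    if (!file.exists(p) || !identical(file_digest(p), meta$outputs[[nm]]))
      return(quarantine(paste0("output '", nm, "' fails integrity check")))
    outs[[nm]] <- p
  }
  list(digest = digest, dir = entry, outputs = outs, meta = meta)
}

#' Restore cached outputs into a working directory
#'
#' Hard-links when the filesystem allows it, otherwise copies.
#'
#' @param entry a hit returned by [cache_lookup()].
#' @param destinations named character vector: relative entry name ->
#'   destination path.
#' @return invisibly, the destination paths.
#' @export
cache_restore <- function(entry, destinations) {
  for (nm in names(destinations)) {
    src <- entry$outputs[[nm]]
    if (is.null(src))
      stop("cache entry has no output named '", nm, "'", call. = FALSE)
    dst <- destinations[[nm]]
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    if (file.exists(dst)) unlink(dst)
    linked <- suppressWarnings(file.link(src, dst))
    if (!linked && !file.copy(src, dst))
      stop("could not restore '", nm, "' from cache", call. = FALSE)
  }
  invisible(unname(destinations))
}

#' Verify all cache entries
#'
#' @param cache_root cache directory.
#' @return data.frame with columns `digest` and `ok` (corrupt entries are
#'   quarantined as a side effect of the lookup).
#' @export
cache_verify <- function(cache_root) {
  entries <- list.dirs(cache_root, recursive = FALSE, full.names = FALSE)
  entries <- entries[grepl("^[0-9a-f]{64}$", entries)]
  ok <- vapply(entries, function(d)
    !is.null(suppressWarnings(cache_lookup(d, cache_root))), NA)
  data.frame(digest = entries, ok = unname(ok), stringsAsFactors = FALSE)
}

#' Drop cache entries
#'
#' @param cache_root cache directory.
#' @param keep character vector of digests to keep (default: drop nothing,
#'   only quarantined material).
#' @return character vector of removed entry names.
#' @export
cache_gc <- function(cache_root, keep = NULL) {
  removed <- character(0)
  q <- file.path(cache_root, "quarantine")
  if (dir.exists(q)) {
    unlink(q, recursive = TRUE)
    removed <- c(removed, "quarantine")
  }
  if (!is.null(keep)) {
    entries <- list.dirs(cache_root, recursive = FALSE, full.names = FALSE)
    entries <- entries[grepl("^[0-9a-f]{64}$", entries)]
    for (d in setdiff(entries, keep)) {
      unlink(file.path(cache_root, d), recursive = TRUE)
      removed <- c(removed, d)
    }
  }
  invisible(removed)
}
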