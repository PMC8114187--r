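#' Wildcard file patterns
#'
#' A wildcard pattern is a relative file path containing zero or more
#' placeholders written `{name}`. Substituting concrete, non-empty values for
#' every placeholder yields a concrete path; conversely, a concrete path can
#' be matched back against the pattern to recover the values. The default
#' placeholder regex is greedy and permissive (one or more of any character,
#' including the path separator); per-name constraints may narrow it.
#'
#' @name wildcard-patterns
#' @keywords internal
NULL

# Valid placeholder name: identifier not starting with a digit.
.wc_name_re <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Split a pattern into literal and placeholder tokens
#'
#' Checks that braces are balanced and non-nested and that placeholder names
#' are valid identifiers.
#'
#' @param template pattern text.
#' @return data.frame with columns `text` and `is_wc`.
#' @keywords internal
wc_tokens <- function(template) {
  stopifnot(is.character(template), length(template) == 1L, !is.na(template))
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  toks <- list()
  buf <- character(0)
  in_wc <- FALSE
  flush <- function(is_wc) {
    if (length(buf) || is_wc) {
      toks[[length(toks) + 1L]] <<- list(text = paste(buf, collapse = ""),
                                         is_wc = is_wc)
    }
    buf <<- character(0)
  }
  for (ch in chars) {
    if (ch == "{") {
      if (in_wc)
        stop("nested '{' in pattern: ", template, call. = FALSE)
      flush(FALSE)
      in_wc <- TRUE
    } else if (ch == "}") {
      if (!in_wc)
        stop("unbalanced '}' in pattern: ", template, call. = FALSE)
      name <- paste(buf, collapse = "")
      if (!grepl(.wc_name_re, name))
        stop("invalid wildcard name '", name, "' in pattern: ", template,
             call. = FALSE)
      flush(TRUE)
      in_wc <- FALSE
    } else {
      buf <- c(buf, ch)
    }
  }
  if (in_wc)
    stop("unbalanced '{' in pattern: ", template, call. = FALSE)
  flush(FALSE)
  if (!length(toks))
    return(data.frame(text = character(0), is_wc = logical(0),
                      stringsAsFactors = FALSE))
  data.frame(text = vapply(toks, `[[`, "", "text"),
             is_wc = vapply(toks, `[[`, NA, "is_wc"),
             stringsAsFactors = FALSE)
}

#' Names of the wildcards occurring in a pattern
#'
#' @param template pattern text.
#' @return character vector of unique placeholder names, in order of first
#'   occurrence.
#' @export
#' @examples
#' wildcard_names("results/by-country/{country}.csv")
wildcard_names <- function(template) {
  tk <- wc_tokens(template)
  unique(tk$text[tk$is_wc])
}

# Escape regex metacharacters in a literal chunk.
.re_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Compile a wildcard pattern to an anchored PCRE regex
#'
#' The first occurrence of each placeholder becomes a named capture group;
#' repeated occurrences become backreferences, so repeated placeholders must
#' bind identical values. The default per-placeholder regex is `.+` (greedy,
#' crosses `/`); `constraints` overrides it per name.
#'
#' @param template pattern text.
#' @param constraints named character vector of regex texts, or `NULL`.
#' @return single character regex, anchored with `^...$`.
#' @keywords internal
wc_regex <- function(template, constraints = NULL) {
  tk <- wc_tokens(template)
  if (!is.null(constraints)) {
    if (is.list(constraints)) constraints <- unlist(constraints)
    if (length(constraints) && (is.null(names(constraints)) ||
        anyDuplicated(names(constraints))))
      stop("constraints must be uniquely named", call. = FALSE)
  }
  seen <- character(0)
  parts <- character(nrow(tk))
  for (i in seq_len(nrow(tk))) {
    if (!tk$is_wc[i]) {
      parts[i] <- .re_escape(tk$text[i])
    } else {
      nm <- tk$text[i]
      if (nm %in% seen) {
        parts[i] <- sprintf("(?P=%s)", nm)
      } else {
        re <- if (!is.null(constraints) && nm %in% names(constraints))
          constraints[[nm]] else ".+"
        parts[i] <- sprintf("(?P<%s>%s)", nm, re)
        seen <- c(seen, nm)
      }
    }
  }
  paste0("^", paste(parts, collapse = ""), "$")
}

#' Match a concrete path against a wildcard pattern
#'
#' Matching is greedy and leftmost: when several parses of the path exist,
#' the leftmost-longest one wins, deterministically. A placeholder never
#' binds an empty string.
#'
#' @param pattern pattern text.
#' @param path concrete relative path.
#' @param constraints optional named character vector of per-wildcard regexes.
#' @return named character vector (the binding; possibly empty for a
#'   literal pattern) or `NULL` if the path cannot be produced from the
#'   pattern.
#' @export
#' @examples
#' match_pattern("results/by-country/{country}.csv",
#'               "results/by-country/X.csv")
match_pattern <- function(pattern, path, constraints = NULL) {
  stopifnot(is.character(path), length(path) == 1L, !is.na(path))
  path <- normalize_relpath(path)
  nms <- wildcard_names(pattern)
  re <- wc_regex(normalize_relpath(pattern), constraints)
  m <- regexpr(re, path, perl = TRUE)
  if (m == -1L) return(NULL)
  if (!length(nms)) return(stats::setNames(character(0), character(0)))
  st <- attr(m, "capture.start")[1, nms, drop = TRUE]
  len <- attr(m, "capture.length")[1, nms, drop = TRUE]
  vals <- substring(path, st, st + len - 1L)
  names(vals) <- nms
  if (any(!nzchar(vals))) return(NULL)
  vals
}

#' Substitute a binding into a wildcard pattern
#'
#' @param pattern pattern text.
#' @param binding named character vector of wildcard values (all non-empty).
#' @return concrete path.
#' @export
#' @examples
#' substitute_pattern("results/by-country/{country}.csv", c(country = "X"))
substitute_pattern <- function(pattern, binding) {
  tk <- wc_tokens(pattern)
  need <- unique(tk$text[tk$is_wc])
  missing <- setdiff(need, names(binding))
  if (length(missing))
    stop("binding is missing wildcard(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(binding) && any(!nzchar(binding)))
    stop("wildcard values must be non-empty", call. = FALSE)
  out <- tk$text
  out[tk$is_wc] <- unname(binding[tk$text[tk$is_wc]])
  normalize_relpath(paste(out, collapse = ""))
}

#' Normalize a relative path
#'
#' Paths are opaque slash-separated relative strings; the only normalization
#' applied is collapsing `./` components, so that matching is bit-stable.
#'
#' @param path character path.
#' @return normalized path.
#' @keywords internal
normalize_relpath <- function(path) {
  p <- sub("^\\./", "", path)
  while (grepl("/\\./", p)) p <- gsub("/\\./", "/", p)
  p
}
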