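# Hierarchical Event Descriptor (HED 2.0) vocabulary: tag tree, string parsing,
# validation against the tree, and prefix-based tag matching/search.

#' Construct a HED tag
#'
#' A HED tag is a path down the hierarchical event-descriptor vocabulary,
#' written with slash separators, e.g. `"Sensory Presentation/Auditory/Buzz"`.
#'
#' @param path Either a single slash-delimited string or a character vector of
#'   node names (no element may contain a slash).
#' @return An object of class `hed_tag`: a character vector of node names.
#' @export
#' @examples
#' hed_tag("Participant/Effect/Cognitive/Oddball/Target")
hed_tag <- function(path) {
  if (length(path) == 1L && grepl("/", path, fixed = TRUE)) {
    path <- strsplit(path, "/", fixed = TRUE)[[1]]
  }
  path <- trimws(as.character(path))
  if (length(path) == 0L || any(!nzchar(path))) {
    stop("HED tag path must be non-empty with non-empty components")
  }
  if (any(grepl("/", path, fixed = TRUE))) {
    stop("HED tag path components must not contain '/'")
  }
  structure(path, class = "hed_tag")
}

#' @export
format.hed_tag <- function(x, ...) paste(unclass(x), collapse = "/")

#' @export
print.hed_tag <- function(x, ...) {
  cat("<hed_tag> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Test whether a HED tag matches a query tag
#'
#' Matching is hierarchical: a query matches a tag when the query's path is a
#' case-insensitive prefix of the tag's path, so querying an interior node of
#' the vocabulary retrieves every more specific annotation beneath it.
#'
#' @param tag,query `hed_tag` objects (or strings coerced via [hed_tag()]).
#' @return Logical scalar.
#' @export
#' @examples
#' tag_matches(hed_tag("Participant/Effect/Cognitive/Oddball/Target"),
#'             hed_tag("Participant/Effect"))
tag_matches <- function(tag, query) {
  if (!inherits(tag, "hed_tag")) tag <- hed_tag(tag)
  if (!inherits(query, "hed_tag")) query <- hed_tag(query)
  nq <- length(query)
  if (nq > length(tag)) return(FALSE)
  all(tolower(unclass(tag)[seq_len(nq)]) == tolower(unclass(query)))
}

# ---- HED strings -----------------------------------------------------------

#' Parse a HED annotation string
#'
#' A HED string is a comma-separated list of items; each item is either a tag
#' or a parenthesized group (itself a HED string). Whitespace around delimiters
#' is ignored. The tilde role syntax of full HED 2.0 is not supported and is
#' rejected with a parse error.
#'
#' @param text A single non-empty character string.
#' @return An object of class `hed_string`: a list with element `items`, each
#'   item a `hed_tag` or a nested `hed_string`.
#' @export
#' @examples
#' parse_hed_string("Sensory Presentation/Auditory/Ding, Participant/Effect/Auditory")
parse_hed_string <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("HED string must be a single non-empty character string")
  }
  if (grepl("~", text, fixed = TRUE)) {
    stop("HED tilde (role) syntax is not supported (position ",
         regexpr("~", text, fixed = TRUE)[1], ")")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(' in HED string: ", depth,
                        " group(s) left open")
  .parse_hed_items(text)
}

# Recursive descent over one nesting level: split on depth-0 commas.
.parse_hed_items <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") depth <- depth + 1L
    else if (c == ")") depth <- depth - 1L
    else if (c == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  items <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    piece <- trimws(substr(text, starts[k], ends[k]))
    if (!nzchar(piece)) {
      stop("empty item in HED string (consecutive or trailing commas)")
    }
    if (startsWith(piece, "(")) {
      if (!endsWith(piece, ")")) stop("malformed group: ", piece)
      items[[k]] <- .parse_hed_items(substr(piece, 2L, nchar(piece) - 1L))
    } else {
      if (grepl("[()]", piece)) stop("misplaced parenthesis in item: ", piece)
      items[[k]] <- hed_tag(piece)
    }
  }
  structure(list(items = items), class = "hed_string")
}

#' @export
format.hed_string <- function(x, ...) {
  paste(vapply(x$items, function(it) {
    if (inherits(it, "hed_tag")) format(it)
    else paste0("(", format(it), ")")
  }, character(1)), collapse = ", ")
}

#' @export
print.hed_string <- function(x, ...) {
  cat("<hed_string> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.hed_string <- function(x, ...) format(x)

# All tags in a HED string, descending into groups, in reading order.
hed_string_tags <- function(s) {
  out <- list()
  for (it in s$items) {
    if (inherits(it, "hed_tag")) out[[length(out) + 1L]] <- it
    else out <- c(out, hed_string_tags(it))
  }
  out
}

# ---- Vocabulary hierarchy --------------------------------------------------

hed_node <- function(name, children = list(), extensionAllowed = FALSE,
                     takesValue = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            !grepl("/", name, fixed = TRUE))
  structure(list(name = name, children = children,
                 extensionAllowed = isTRUE(extensionAllowed),
                 takesValue = isTRUE(takesValue)),
            class = "hed_node")
}

#' Load a HED vocabulary hierarchy
#'
#' Reads the indentation-structured plain-text vocabulary format: one node per
#' line, leading tab count giving depth, with optional `[extensionAllowed]` and
#' `[takesValue]` attribute flags. Lines starting with `#` and a leading
#' `version:` directive are metadata. The package ships a trimmed HED 2.0
#' snapshot used by default throughout.
#'
#' @param path Path to a vocabulary file; `NULL` loads the shipped snapshot.
#' @return An object of class `hed_hierarchy` with fields `version` and
#'   `roots` (a list of node trees).
#' @export
load_hed_hierarchy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hed_vocabulary.txt", package = "esskit",
                        mustWork = TRUE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  version <- "unknown"
  vl <- grepl("^version:", lines)
  if (any(vl)) {
    version <- trimws(sub("^version:", "", lines[which(vl)[1]]))
    lines <- lines[!vl]
  }
  lines <- lines[nzchar(trimws(lines))]
  depth <- nchar(sub("[^\t].*$", "", paste0(lines, "x")))
  parsed <- lapply(lines, .parse_hed_vocab_line)
  build <- function(idx, d, parentPath) {
    # children of current parent: maximal runs at depth d
    kids <- list()
    i <- 1L
    while (i <= length(idx)) {
      if (depth[idx[i]] != d) {
        stop("vocabulary structural error: unexpected indentation at line '",
             lines[idx[i]], "'")
      }
      j <- i + 1L
      while (j <= length(idx) && depth[idx[j]] > d) j <- j + 1L
      p <- parsed[[idx[i]]]
      sub <- if (j > i + 1L) build(idx[(i + 1L):(j - 1L)], d + 1L,
                                   c(parentPath, p$name)) else list()
      kids[[length(kids) + 1L]] <- hed_node(p$name, sub,
                                            p$extensionAllowed, p$takesValue)
      i <- j
    }
    nm <- tolower(vapply(kids, `[[`, character(1), "name"))
    if (anyDuplicated(nm)) {
      dup <- vapply(kids, `[[`, character(1), "name")[duplicated(nm)][1]
      stop("vocabulary structural error: duplicate sibling '",
           paste(c(parentPath, dup), collapse = "/"),
           "' (names are case-insensitively unique)")
    }
    kids
  }
  roots <- build(seq_along(lines), 0L, character(0))
  structure(list(version = version, roots = roots), class = "hed_hierarchy")
}

.parse_hed_vocab_line <- function(line) {
  txt <- sub("^\t+", "", line)
  ext <- grepl("\\[extensionAllowed\\]", txt)
  tv <- grepl("\\[takesValue\\]", txt)
  name <- trimws(gsub("\\[(extensionAllowed|takesValue)\\]", "", txt))
  list(name = name, extensionAllowed = ext, takesValue = tv)
}

#' @export
print.hed_hierarchy <- function(x, ...) {
  n <- function(node) 1L + sum(vapply(node$children, n, integer(1)))
  cat("<hed_hierarchy> version ", x$version, ", ",
      sum(vapply(x$roots, n, integer(1))), " nodes under ",
      length(x$roots), " roots\n", sep = "")
  invisible(x)
}

# Walk a tag path down the hierarchy; returns the number of matched components
# and attributes of the deepest matched node.
.hed_walk <- function(h, path) {
  nodes <- h$roots
  matched <- 0L
  ext <- FALSE
  tv <- FALSE
  for (comp in path) {
    hit <- NULL
    for (nd in nodes) {
      if (tolower(nd$name) == tolower(comp)) { hit <- nd; break }
    }
    if (is.null(hit)) break
    matched <- matched + 1L
    ext <- ext || hit$extensionAllowed  # extension permission is inherited
    tv <- hit$takesValue
    nodes <- hit$children
  }
  list(matched = matched, extensionAllowed = ext, takesValue = tv)
}

#' Validate a HED string against a vocabulary hierarchy
#'
#' Every tag must either name an existing vocabulary path, extend below a node
#' carrying `extensionAllowed` (permission is inherited by descendants), or
#' supply a single value below a `takesValue` node. Issues are returned as
#' data, not raised.
#'
#' @param s A `hed_string` (or string, parsed on the fly).
#' @param h A `hed_hierarchy`; `NULL` loads the shipped snapshot.
#' @return Character vector of issue messages; empty when valid.
#' @export
validate_hed_string <- function(s, h = NULL) {
  if (is.character(s)) s <- parse_hed_string(s)
  if (is.null(h)) h <- ess_default_hierarchy()
  issues <- character(0)
  for (tag in hed_string_tags(s)) {
    path <- unclass(tag)
    w <- .hed_walk(h, path)
    if (w$matched == length(path)) next
    if (w$matched > 0L && w$takesValue && length(path) - w$matched == 1L) next
    if (w$matched > 0L && w$extensionAllowed) next
    issues <- c(issues, paste0(
      "unknown node '", path[w$matched + 1L], "' in tag '", format(tag),
      "' (matched ", w$matched, " of ", length(path), " levels)"))
  }
  issues
}

# Shared default hierarchy, loaded lazily once per session.
.esskit_env <- new.env(parent = emptyenv())

#' @rdname load_hed_hierarchy
#' @export
ess_default_hierarchy <- function() {
  if (is.null(.esskit_env$hierarchy)) {
    .esskit_env$hierarchy <- load_hed_hierarchy()
  }
  .esskit_env$hierarchy
}

#' Search event instances by HED query tag
#'
#' Returns, in input order, the events whose HED annotation contains at least
#' one tag (at any group depth) matched by the query under the hierarchical
#' prefix rule of [tag_matches()]. This is the operation that makes annotated
#' event streams self-describing: selection needs no external code table.
#'
#' @param events A list of [event_instance()] objects carrying parsed HED
#'   strings.
#' @param query A `hed_tag` (or slash-delimited string).
#' @return The matching subset of `events` (possibly empty), order preserved.
#' @export
search_event_instances <- function(events, query) {
  if (!inherits(query, "hed_tag")) query <- hed_tag(query)
  keep <- vapply(events, function(ev) {
    s <- ev$hedString
    if (is.character(s)) s <- parse_hed_string(s)
    if (is.null(s)) return(FALSE)
    any(vapply(hed_string_tags(s), tag_matches, logical(1), query = query))
  }, logical(1))
  events[keep]
}
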