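# Term encoding -------------------------------------------------------------
#
# Every term is carried as a single character scalar in a canonical encoding:
#   * IRIs          : the fully expanded IRI text, e.g. "http://.../mcf#Knee"
#   * literals      : the text wrapped in double quotes, e.g. "\"yellow\""
#   * variables     : a leading question mark, e.g. "?a"  (patterns only)
# The encoding is unambiguous because an IRI can start neither with '?' nor
# with '"'. Literals are plain text; embedded double quotes are not allowed.

#' Default namespace prefix table
#'
#' Five fixed prefixes cover the whole vocabulary: `mcf` (the anatomy
#' knowledge-base namespace), `fma` (the Foundational Model of Anatomy),
#' and the standard `rdf`, `rdfs` and `owl` namespaces.
#'
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
default_prefixes <- function() {
  c(
    mcf  = "http://anatkb.example.org/mcf#",
    fma  = "http://purl.org/sig/ont/fma/",
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl  = "http://www.w3.org/2002/07/owl#"
  )
}

#' Construct a literal term
#'
#' @param x Character vector of plain-text literal values. Embedded double
#'   quotes are not supported (plain-text literals only).
#' @return The canonical encoded form (quoted text).
#' @export
lit <- function(x) {
  if (any(grepl('"', x, fixed = TRUE))) {
    stop("literals may not contain double quotes", call. = FALSE)
  }
  paste0('"', x, '"')
}

#' Test / inspect encoded terms
#'
#' `is_literal_term()`, `is_variable_term()` and `is_iri_term()` classify an
#' encoded term; `term_value()` strips the encoding marker (quotes for
#' literals, the `?` for variables; IRIs are returned unchanged).
#'
#' @param x Character vector of encoded terms.
#' @return Logical vector, or character vector for `term_value()`.
#' @export
is_literal_term <- function(x) startsWith(x, '"')

#' @rdname is_literal_term
#' @export
is_variable_term <- function(x) startsWith(x, "?")

#' @rdname is_literal_term
#' @export
is_iri_term <- function(x) !is_literal_term(x) & !is_variable_term(x)

#' @rdname is_literal_term
#' @export
term_value <- function(x) {
  out <- x
  l <- is_literal_term(x)
  out[l] <- substr(x[l], 2L, nchar(x[l]) - 1L)
  v <- is_variable_term(x)
  out[v] <- substring(x[v], 2L)
  out
}

#' Expand prefixed names to full IRIs
#'
#' `expand_iri()` turns `"mcf:Knee"` into the full IRI using the prefix
#' table; names already in full form (or literals/variables) pass through.
#' `compact_iri()` is the inverse, preferring the longest matching
#' namespace. The two are exact inverses for IRIs under the fixed table.
#'
#' @param x Character vector of prefixed names or encoded terms.
#' @param prefixes Named character vector of prefix -> namespace.
#' @return Character vector of encoded terms / prefixed names.
#' @export
expand_iri <- function(x, prefixes = default_prefixes()) {
  out <- x
  cand <- is_iri_term(x) & grepl("^[A-Za-z][A-Za-z0-9]*:", x) &
    !grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x)
  if (any(cand)) {
    pfx <- sub(":.*$", "", x[cand])
    local <- sub("^[^:]*:", "", x[cand])
    ns <- prefixes[pfx]
    if (anyNA(ns)) {
      bad <- unique(pfx[is.na(ns)])
      stop("unknown prefix: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out[cand] <- paste0(ns, local)
  }
  out
}

#' @rdname expand_iri
#' @export
compact_iri <- function(x, prefixes = default_prefixes()) {
  out <- x
  iri <- is_iri_term(x)
  if (!any(iri)) return(out)
  ord <- order(nchar(prefixes), decreasing = TRUE)
  for (i in ord) {
    ns <- prefixes[[i]]
    hit <- iri & startsWith(out, ns) & !grepl("[/#]", sub(ns, "", out, fixed = TRUE))
    out[hit] <- paste0(names(prefixes)[i], ":", substring(out[hit], nchar(ns) + 1L))
  }
  out
}
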