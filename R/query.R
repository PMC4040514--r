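# Conjunctive queries (SELECT / WHERE basic graph patterns) ------------------
#
# The supported query language is the SELECT subset:
#   PREFIX p: <ns>          (any number, extending the default table)
#   SELECT [DISTINCT] ?v ?w ...
#   WHERE { pattern . pattern . ... }
# Patterns are triple patterns with variables allowed in any position,
# including the predicate. Because the store is saturated before querying,
# plain conjunctive patterns reach everything a property-path query would.

#' Construct a query
#'
#' @param select Non-empty character vector of projected variables
#'   (`"?name"`); each must occur in some pattern.
#' @param patterns List of pattern atoms `c(s, p, o)`.
#' @param distinct Drop duplicate rows? Defaults to `TRUE`, matching the set
#'   semantics of the store.
#' @param prefixes Prefix table used for expansion.
#' @return Object of class `kb_query`.
#' @export
kb_query <- function(select, patterns, distinct = TRUE,
                     prefixes = default_prefixes()) {
  stopifnot(length(select) >= 1L, length(patterns) >= 1L)
  select <- as.character(select)
  if (!all(is_variable_term(select))) {
    stop("projected terms must be variables ('?name')", call. = FALSE)
  }
  patterns <- lapply(patterns, function(a) expand_iri(as.character(a), prefixes))
  stopifnot(all(lengths(patterns) == 3L))
  pvars <- unique(unlist(lapply(patterns, atom_vars)))
  missing <- setdiff(select, pvars)
  if (length(missing) > 0L) {
    stop("projected variable(s) not used in any pattern: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(select = select, patterns = patterns, distinct = distinct),
            class = "kb_query")
}

#' @export
print.kb_query <- function(x, prefixes = default_prefixes(), ...) {
  cat("SELECT", if (x$distinct) "DISTINCT" else "",
      paste(x$select, collapse = " "), "WHERE {\n")
  for (p in x$patterns) {
    cat("  ", paste(compact_iri(p, prefixes), collapse = " "), " .\n", sep = "")
  }
  cat("}\n")
  invisible(x)
}

#' Parse a SELECT query
#'
#' @param text Query text (string or lines): optional `PREFIX` headers, then
#'   `SELECT [DISTINCT] ?v ... WHERE { p . p . ... }`.
#' @param prefixes Base prefix table; `PREFIX` headers extend/override it.
#' @return A [kb_query()]. Patterns are kept in document order.
#' @export
parse_query <- function(text, prefixes = default_prefixes()) {
  txt <- paste(paste(text, collapse = "\n"), collapse = "\n")
  # PREFIX headers
  rx_pfx <- "(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9]*):\\s*<([^<>\\s]+)>"
  m <- gregexpr(rx_pfx, txt, perl = TRUE)
  for (decl in regmatches(txt, m)[[1]]) {
    prefixes[sub(rx_pfx, "\\1", decl, perl = TRUE)] <-
      sub(rx_pfx, "\\2", decl, perl = TRUE)
  }
  txt <- gsub(rx_pfx, "", txt, perl = TRUE)
  rx <- "(?is)^\\s*SELECT\\s+(DISTINCT\\s+)?((?:\\?[A-Za-z0-9_']+\\s*)+)WHERE\\s*\\{(.*)\\}\\s*$"
  if (!grepl(rx, txt, perl = TRUE)) {
    parse_error("malformed query (expected SELECT [DISTINCT] ?v ... WHERE { ... })")
  }
  distinct <- grepl("(?i)DISTINCT", sub(rx, "\\1", txt, perl = TRUE), perl = TRUE)
  select <- strsplit(trimws(sub(rx, "\\2", txt, perl = TRUE)), "\\s+")[[1]]
  body <- sub(rx, "\\3", txt, perl = TRUE)
  # split on '.' statement terminators, ignoring dots inside "..." and <...>
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  stmts <- character(0); cur <- character(0)
  in_quote <- FALSE; in_angle <- FALSE
  for (ch in chars) {
    if (ch == '"') in_quote <- !in_quote
    if (!in_quote && ch == "<") in_angle <- TRUE
    if (!in_quote && ch == ">") in_angle <- FALSE
    if (ch == "." && !in_quote && !in_angle) {
      stmts <- c(stmts, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
  }
  stmts <- c(stmts, paste(cur, collapse = ""))
  stmts <- trimws(gsub("\\s+", " ", stmts))
  stmts <- stmts[stmts != ""]
  if (length(stmts) == 0L) parse_error("query has no patterns")
  patterns <- lapply(stmts, parse_rule_atom, prefixes = prefixes,
                     line = NA_integer_)
  # DISTINCT is the default (set semantics); the keyword is accepted but
  # does not change behaviour in this subset
  kb_query(select, patterns, distinct = TRUE, prefixes = prefixes)
}

#' Read a query file
#' @param path File path.
#' @param prefixes Prefix table.
#' @return A [kb_query()].
#' @export
read_query <- function(path, prefixes = default_prefixes()) {
  parse_query(readLines(path, encoding = "UTF-8", warn = FALSE), prefixes)
}

#' Evaluate a query against a store
#'
#' Natural-join semantics: the answers are the projections of all binding
#' maps that satisfy every pattern simultaneously. Patterns are joined
#' smallest-match-first as an optimisation; the answer set is independent of
#' pattern order. Rows are returned in deterministic lexicographic order.
#'
#' @param query A [kb_query()].
#' @param store A [triple_store()], normally saturated (evaluating an
#'   unsaturated store is allowed but warns, since entailed answers would be
#'   missed).
#' @return data.frame (the answer table) with one column per projected
#'   variable, named without the `?` marker.
#' @export
evaluate_query <- function(query, store) {
  if (is.null(store$report)) {
    warning("store has no saturation report; entailed answers may be missing",
            call. = FALSE)
  }
  sizes <- vapply(query$patterns, function(a)
    nrow(match_triples(store, a[[1]], a[[2]], a[[3]])), numeric(1))
  ord <- order(sizes)
  tabs <- lapply(query$patterns[ord], atom_bindings, store = store)
  b <- Reduce(join_bindings, tabs)
  if (is.null(b)) b <- data.frame()
  if (nrow(b) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character()), length(query$select)),
      substring(query$select, 2L)), stringsAsFactors = FALSE,
      optional = TRUE)
    return(out)
  }
  out <- b[, query$select, drop = FALSE]
  names(out) <- substring(query$select, 2L)
  if (query$distinct) out <- unique(out)
  out <- out[do.call(order, c(as.list(out), list(method = "radix"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an answer table as TSV
#'
#' @param answers data.frame from [evaluate_query()].
#' @param path Output file.
#' @param prefixes When given, IRIs are compacted to prefixed names first.
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers, path, prefixes = NULL) {
  if (!is.null(prefixes)) {
    answers[] <- lapply(answers, compact_iri, prefixes = prefixes)
  }
  utils::write.table(answers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
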