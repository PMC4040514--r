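# RDF readers / writers ------------------------------------------------------
#
# Two dialects:
#  * "ntriples"      : one statement per line, "<s> <p> <o> ." with full IRIs
#                      in angle brackets and plain-quoted literals.
#  * "turtle-subset" : @prefix declarations followed by simple
#                      subject-predicate-object statements using prefixed
#                      names; no blank nodes, collections or ';'/',' sugar.
# UTF-8 throughout. Literals are plain text (no language tags or datatypes).

parse_error <- function(msg, line = NA_integer_) {
  stop(structure(
    class = c("anatkb_parse_error", "error", "condition"),
    list(message = if (is.na(line)) msg else sprintf("line %d: %s", line, msg),
         call = NULL, line = line)
  ))
}

prefix_error <- function(prefix, line = NA_integer_) {
  stop(structure(
    class = c("anatkb_prefix_error", "anatkb_parse_error", "error", "condition"),
    list(message = sprintf("line %d: unknown prefix '%s'", line, prefix),
         call = NULL, line = line, prefix = prefix)
  ))
}

# one term token in either dialect -> encoded term, or NA if unparseable
.rx_iri_ref  <- "^<([^<>\"\\s]+)>$"
.rx_literal  <- '^"([^"]*)"$'
.rx_prefixed <- "^([A-Za-z][A-Za-z0-9]*):([A-Za-z0-9_][A-Za-z0-9_.-]*)$"

parse_term_token <- function(tok, prefixes, line) {
  if (grepl(.rx_iri_ref, tok, perl = TRUE)) {
    return(sub(.rx_iri_ref, "\\1", tok, perl = TRUE))
  }
  if (grepl(.rx_literal, tok)) return(tok)
  if (grepl(.rx_prefixed, tok)) {
    pfx <- sub(.rx_prefixed, "\\1", tok)
    if (!pfx %in% names(prefixes)) prefix_error(pfx, line)
    return(paste0(prefixes[[pfx]], sub(.rx_prefixed, "\\2", tok)))
  }
  parse_error(sprintf("cannot parse term '%s'", tok), line)
}

# split a statement body into exactly three term tokens (quote-aware)
split_statement <- function(body, line) {
  toks <- regmatches(body, gregexpr('"[^"]*"|<[^>\\s]+>|[^\\s]+', body,
                                    perl = TRUE))[[1]]
  if (length(toks) != 3L) {
    parse_error(sprintf("expected 3 terms, found %d", length(toks)), line)
  }
  toks
}

#' Parse an RDF document
#'
#' @param text Document text (single string or character vector of lines).
#' @param dialect `"ntriples"` or `"turtle-subset"`.
#' @param prefixes Prefix table; for the Turtle subset, `@prefix`
#'   declarations in the document extend/override it.
#' @return data.frame of triples (columns `s`, `p`, `o`, encoded terms) in
#'   document order. Malformed lines raise a parse error carrying the line
#'   number; an undeclared prefix raises a distinct prefix error.
#' @export
parse_rdf <- function(text, dialect = c("ntriples", "turtle-subset"),
                      prefixes = default_prefixes()) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- vector("list", length(lines))
  rx_prefix_decl <- "^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s*<([^<>\\s]+)>\\s*\\.$"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      if (dialect != "turtle-subset") {
        parse_error("@prefix is not allowed in N-Triples", i)
      }
      if (!grepl(rx_prefix_decl, ln, perl = TRUE)) {
        parse_error("malformed @prefix declaration", i)
      }
      pfx <- sub(rx_prefix_decl, "\\1", ln, perl = TRUE)
      ns <- sub(rx_prefix_decl, "\\2", ln, perl = TRUE)
      prefixes[pfx] <- ns
      next
    }
    if (!grepl("\\.$", ln)) parse_error("statement must end with '.'", i)
    body <- trimws(sub("\\s*\\.$", "", ln))
    toks <- split_statement(body, i)
    if (dialect == "ntriples" && any(grepl(.rx_prefixed, toks))) {
      parse_error("prefixed names are not allowed in N-Triples", i)
    }
    term <- vapply(toks, parse_term_token, character(1),
                   prefixes = prefixes, line = i, USE.NAMES = FALSE)
    if (is_literal_term(term[[1]]) || is_literal_term(term[[2]])) {
      parse_error("subject and predicate must be IRIs", i)
    }
    out[[i]] <- term
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_facts())
  m <- do.call(rbind, out)
  data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE)
}

#' Serialise a store
#'
#' Output is deterministic: statements are sorted by subject, predicate and
#' object text, so equal stores serialise identically and distinct stores
#' differ. `parse_rdf(serialize_rdf(store, d), d)` recovers the fact set.
#'
#' @param store A [triple_store()].
#' @param dialect `"ntriples"` or `"turtle-subset"`.
#' @return A single string (the document).
#' @export
serialize_rdf <- function(store, dialect = c("ntriples", "turtle-subset")) {
  dialect <- match.arg(dialect)
  f <- store$facts
  f <- f[order(f$s, f$p, f$o, method = "radix"), , drop = FALSE]
  fmt <- function(x, compacted) {
    ok <- compacted != x & grepl(.rx_prefixed, compacted)
    ifelse(is_literal_term(x), x, ifelse(ok, compacted, paste0("<", x, ">")))
  }
  if (dialect == "ntriples") {
    stmts <- sprintf("<%s> <%s> %s .", f$s, f$p,
                     ifelse(is_literal_term(f$o), f$o, paste0("<", f$o, ">")))
    return(paste0(paste(stmts, collapse = "\n"),
                  if (nrow(f) > 0L) "\n" else ""))
  }
  pfx <- store$prefixes[order(names(store$prefixes), method = "radix")]
  header <- sprintf("@prefix %s: <%s> .", names(pfx), unname(pfx))
  if (nrow(f) == 0L) return(paste0(paste(header, collapse = "\n"), "\n"))
  cs <- compact_iri(f$s, store$prefixes)
  cp <- compact_iri(f$p, store$prefixes)
  co <- compact_iri(f$o, store$prefixes)
  stmts <- sprintf("%s %s %s .", fmt(f$s, cs), fmt(f$p, cp), fmt(f$o, co))
  paste0(paste(c(header, "", stmts), collapse = "\n"), "\n")
}

#' Read / write RDF files
#'
#' Thin file wrappers over [parse_rdf()] and [serialize_rdf()].
#'
#' @param path File path.
#' @param dialect RDF dialect (see [parse_rdf()]).
#' @param prefixes Prefix table for the resulting store.
#' @param store A [triple_store()].
#' @return `read_rdf()` returns a [triple_store()]; `write_rdf()` returns
#'   `path` invisibly.
#' @export
read_rdf <- function(path, dialect = c("ntriples", "turtle-subset"),
                     prefixes = default_prefixes()) {
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  triple_store(parse_rdf(txt, dialect, prefixes), prefixes = prefixes)
}

#' @rdname read_rdf
#' @export
write_rdf <- function(store, path, dialect = c("ntriples", "turtle-subset")) {
  writeLines(serialize_rdf(store, dialect), path, useBytes = TRUE, sep = "")
  invisible(path)
}
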