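# Triple store ---------------------------------------------------------------
#
# A store is a list with class "triple_store":
#   $facts    : data.frame(s, p, o) of encoded terms, unique rows, no variables
#   $prefixes : named character vector (prefix -> namespace)
#   $index    : list(s=, p=, o=) of environments mapping term -> integer row ids
#   $log      : optional derivation log (see saturate)
#   $report   : optional saturation run report
# Set semantics throughout: adding an existing triple is a no-op.

new_index <- function(facts) {
  idx <- list(s = new.env(parent = emptyenv(), hash = TRUE),
              p = new.env(parent = emptyenv(), hash = TRUE),
              o = new.env(parent = emptyenv(), hash = TRUE))
  for (col in c("s", "p", "o")) {
    sp <- split(seq_len(nrow(facts)), facts[[col]])
    list2env(sp, idx[[col]])
  }
  idx
}

fact_key <- function(s, p, o) paste(s, p, o, sep = "\r")

empty_facts <- function() {
  data.frame(s = character(), p = character(), o = character(),
             stringsAsFactors = FALSE)
}

#' Create a triple store
#'
#' An indexed set of ground triples with set semantics. Subjects and
#' predicates are IRIs; objects are IRIs or plain-text literals. Terms are
#' given either as full IRIs, prefixed names (expanded against `prefixes`),
#' or quoted literals (see [lit()]). Variables are rejected: they belong in
#' patterns, never in stored facts.
#'
#' @param triples Optional data.frame (or matrix) with columns `s`, `p`, `o`.
#' @param prefixes Prefix table used for expansion and serialisation.
#' @return An object of class `triple_store`.
#' @export
triple_store <- function(triples = NULL, prefixes = default_prefixes()) {
  store <- structure(
    list(facts = empty_facts(), prefixes = prefixes, index = NULL,
         log = NULL, report = NULL),
    class = "triple_store"
  )
  store$index <- new_index(store$facts)
  if (!is.null(triples)) {
    triples <- as.data.frame(triples, stringsAsFactors = FALSE)
    store <- add_triples(store, triples$s, triples$p, triples$o)
  }
  store
}

check_ground <- function(x, role) {
  if (any(is_variable_term(x))) {
    stop("stored triples may not contain variables (found in ", role, ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Add or remove triples
#'
#' Vectorised over `s`, `p`, `o`. Prefixed names are expanded. Adding a
#' triple already present, or removing one that is absent, is a no-op;
#' indexes are kept consistent with the fact set.
#'
#' @param store A [triple_store()].
#' @param s,p,o Character vectors of terms (recycled to common length).
#' @return The updated store.
#' @export
add_triples <- function(store, s, p, o) {
  n <- max(length(s), length(p), length(o))
  if (n == 0L) return(store)
  s <- expand_iri(rep_len(as.character(s), n), store$prefixes)
  p <- expand_iri(rep_len(as.character(p), n), store$prefixes)
  o <- expand_iri(rep_len(as.character(o), n), store$prefixes)
  check_ground(s, "subject"); check_ground(p, "predicate"); check_ground(o, "object")
  if (any(is_literal_term(s)) || any(is_literal_term(p))) {
    stop("subjects and predicates must be IRIs", call. = FALSE)
  }
  cand <- data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
  cand <- cand[!duplicated(fact_key(cand$s, cand$p, cand$o)), , drop = FALSE]
  new <- !(fact_key(cand$s, cand$p, cand$o) %in%
             fact_key(store$facts$s, store$facts$p, store$facts$o))
  if (!any(new)) return(store)
  store$facts <- rbind(store$facts, cand[new, , drop = FALSE])
  rownames(store$facts) <- NULL
  store$index <- new_index(store$facts)
  store
}

#' @rdname add_triples
#' @export
remove_triples <- function(store, s, p, o) {
  n <- max(length(s), length(p), length(o))
  if (n == 0L || nrow(store$facts) == 0L) return(store)
  s <- expand_iri(rep_len(as.character(s), n), store$prefixes)
  p <- expand_iri(rep_len(as.character(p), n), store$prefixes)
  o <- expand_iri(rep_len(as.character(o), n), store$prefixes)
  keep <- !(fact_key(store$facts$s, store$facts$p, store$facts$o) %in%
              fact_key(s, p, o))
  if (all(keep)) return(store)
  store$facts <- store$facts[keep, , drop = FALSE]
  rownames(store$facts) <- NULL
  store$index <- new_index(store$facts)
  store
}

#' Number of facts in a store
#' @param store A [triple_store()].
#' @return Integer count.
#' @export
n_triples <- function(store) nrow(store$facts)

#' Facts of a store as a data.frame
#'
#' @param store A [triple_store()].
#' @param compact Compact IRIs back to prefixed names for display?
#' @return data.frame with columns `s`, `p`, `o`.
#' @export
store_triples <- function(store, compact = FALSE) {
  f <- store$facts
  if (compact) {
    f$s <- compact_iri(f$s, store$prefixes)
    f$p <- compact_iri(f$p, store$prefixes)
    f$o <- compact_iri(f$o, store$prefixes)
  }
  f
}

#' Test whether a ground triple is present
#' @param store A [triple_store()].
#' @param s,p,o Terms (prefixed names allowed).
#' @return Logical vector.
#' @export
has_triple <- function(store, s, p, o) {
  s <- expand_iri(s, store$prefixes)
  p <- expand_iri(p, store$prefixes)
  o <- expand_iri(o, store$prefixes)
  fact_key(s, p, o) %in% fact_key(store$facts$s, store$facts$p, store$facts$o)
}

#' @export
print.triple_store <- function(x, ...) {
  cat("<triple_store> ", nrow(x$facts), " facts, ",
      length(x$prefixes), " prefixes", sep = "")
  if (!is.null(x$report)) {
    cat(" (saturated: ", x$report$rounds, " rounds, ",
        x$report$inferred, " inferred)", sep = "")
  }
  cat("\n")
  if (nrow(x$facts) > 0L) {
    show <- utils::head(store_triples(x, compact = TRUE), 10L)
    print(show)
    if (nrow(x$facts) > 10L) cat("... and", nrow(x$facts) - 10L, "more\n")
  }
  invisible(x)
}

# Candidate row ids for a pattern, via the indexes. NULL means "all rows".
index_candidates <- function(store, s, p, o) {
  ids <- NULL
  pick <- function(env, key) {
    v <- get0(key, envir = env, ifnotfound = integer(0))
    v
  }
  if (!is_variable_term(s)) ids <- pick(store$index$s, s)
  if (!is_variable_term(p)) {
    v <- pick(store$index$p, p)
    ids <- if (is.null(ids)) v else intersect(ids, v)
  }
  if (!is_variable_term(o)) {
    v <- pick(store$index$o, o)
    ids <- if (is.null(ids)) v else intersect(ids, v)
  }
  if (is.null(ids)) seq_len(nrow(store$facts)) else ids
}

#' Match a triple pattern against a store
#'
#' Constants must match exactly; variables (terms starting `?`) match any
#' term, and a variable repeated within the pattern must bind to the same
#' value in every position where it occurs.
#'
#' @param store A [triple_store()].
#' @param s,p,o Pattern terms: constants (IRIs, prefixed names, literals) or
#'   variables written `"?name"`.
#' @return data.frame of the matching facts (columns `s`, `p`, `o`), in
#'   store order.
#' @export
match_triples <- function(store, s = "?s", p = "?p", o = "?o") {
  s <- expand_iri(s, store$prefixes)
  p <- expand_iri(p, store$prefixes)
  o <- expand_iri(o, store$prefixes)
  ids <- index_candidates(store, s, p, o)
  hit <- store$facts[ids, , drop = FALSE]
  # consistency of repeated variables
  if (is_variable_term(s) && identical(s, p)) hit <- hit[hit$s == hit$p, , drop = FALSE]
  if (is_variable_term(s) && identical(s, o)) hit <- hit[hit$s == hit$o, , drop = FALSE]
  if (is_variable_term(p) && identical(p, o)) hit <- hit[hit$p == hit$o, , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

# Bindings for one pattern atom: a data.frame with one column per distinct
# variable in the atom (deduplicated rows). Atom is c(s, p, o), expanded.
atom_bindings <- function(store, atom) {
  hit <- match_triples(store, atom[[1L]], atom[[2L]], atom[[3L]])
  vars <- character(0)
  cols <- list()
  for (i in 1:3) {
    t <- atom[[i]]
    if (is_variable_term(t) && !(t %in% vars)) {
      vars <- c(vars, t)
      cols[[t]] <- hit[[c("s", "p", "o")[i]]]
    }
  }
  if (length(vars) == 0L) {
    # no variables: zero-column frame with one row iff the atom is present
    return(structure(data.frame(row.names = seq_len(min(nrow(hit), 1L))),
                     names = character(0)))
  }
  b <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(b) <- vars
  unique(b)
}

# Natural join of two binding frames (shared columns equal; none -> cross).
join_bindings <- function(x, y) {
  if (ncol(x) == 0L) return(if (nrow(x) > 0L) y else y[0, , drop = FALSE])
  if (ncol(y) == 0L) return(if (nrow(y) > 0L) x else x[0, , drop = FALSE])
  if (nrow(x) == 0L || nrow(y) == 0L) {
    out <- merge(x[0, , drop = FALSE], y[0, , drop = FALSE],
                 by = intersect(names(x), names(y)), all = FALSE)
    return(out)
  }
  common <- intersect(names(x), names(y))
  if (length(common) == 0L) {
    xi <- rep(seq_len(nrow(x)), each = nrow(y))
    yi <- rep(seq_len(nrow(y)), times = nrow(x))
    return(cbind(x[xi, , drop = FALSE], y[yi, , drop = FALSE],
                 row.names = NULL))
  }
  merge(x, y, by = common, sort = FALSE)
}
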