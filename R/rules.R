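# Safe-rule (Datalog) engine -------------------------------------------------
#
# A rule has a non-empty body of triple patterns and a single-pattern head.
# Safety (every head variable occurs in the body) guarantees that forward
# chaining terminates: every derivable fact is built from constants already
# in the store, so the closure lives inside the finite Herbrand base.
#
# Saturation is semi-naive: after the first round, a rule only fires on
# bindings in which at least one body atom matches a fact derived in the
# previous round. The result is the same least fixpoint as naive
# re-evaluation (tested against a naive oracle), at much lower cost.

atom_vars <- function(atom) unique(atom[is_variable_term(atom)])

#' Construct a rule
#'
#' @param id Rule identifier (e.g. `"R1"`).
#' @param body List of pattern atoms, each a character vector
#'   `c(s, p, o)` of constants or `"?var"` terms (prefixed names allowed).
#' @param head A single pattern atom for the conclusion.
#' @param prefixes Prefix table for name expansion.
#' @param check Reject unsafe rules? (default `TRUE`).
#' @return An object of class `rule`.
#' @export
rule <- function(id, body, head, prefixes = default_prefixes(), check = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, length(body) >= 1L)
  body <- lapply(body, function(a) expand_iri(as.character(a), prefixes))
  head <- expand_iri(as.character(head), prefixes)
  stopifnot(all(lengths(body) == 3L), length(head) == 3L)
  r <- structure(list(id = id, body = body, head = head), class = "rule")
  if (check) {
    bad <- check_safety(r)
    if (length(bad) > 0L) {
      stop("unsafe rule '", id, "': head variable(s) ",
           paste(bad, collapse = ", "), " not bound in body", call. = FALSE)
    }
  }
  r
}

#' Check rule safety
#'
#' A rule is safe when every variable of its conclusion occurs in at least
#' one condition atom; only safe rules guarantee a finite closure.
#'
#' @param r A [rule()].
#' @return Character vector of violating head variables (empty when safe).
#' @export
check_safety <- function(r) {
  hv <- atom_vars(r$head)
  bv <- unique(unlist(lapply(r$body, atom_vars)))
  setdiff(hv, bv)
}

#' Construct a rule set
#' @param rules List of [rule()] objects with unique ids.
#' @return Object of class `rule_set`.
#' @export
rule_set <- function(rules) {
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(unname(rules), names = unname(ids), class = "rule_set")
}

#' @export
format.rule <- function(x, prefixes = default_prefixes(), ...) {
  fmt_atom <- function(a) {
    a <- compact_iri(a, prefixes)
    paste0("(", paste(a, collapse = " "), ")")
  }
  paste0(x$id, ": IF ", paste(vapply(x$body, fmt_atom, character(1)),
                              collapse = " AND "),
         " THEN ", fmt_atom(x$head))
}

#' @export
print.rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> ", length(x), " rules\n", sep = "")
  for (r in x) cat("  ", format(r), "\n", sep = "")
  invisible(x)
}

#' @export
format.rule_set <- function(x, ...) {
  vapply(unclass(x), format, character(1), ...)
}

rule_rx_atom <- "\\(([^()]*)\\)"

parse_rule_atom <- function(txt, prefixes, line) {
  toks <- regmatches(txt, gregexpr('"[^"]*"|<[^>\\s]+>|[^\\s]+', txt,
                                   perl = TRUE))[[1]]
  if (length(toks) != 3L) {
    parse_error(sprintf("rule atom must have 3 terms: (%s)", txt), line)
  }
  vapply(toks, function(tok) {
    if (grepl("^\\?[A-Za-z][A-Za-z0-9_']*$", tok)) return(tok)
    parse_term_token(tok, prefixes, line)
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a rule document
#'
#' One rule per line, in the form
#' `Rid: IF (s p o) AND (s p o) THEN (s p o)`, with terms written as
#' prefixed names, `<full-iri>`, `"literal"`, or `?variables`; `#` starts a
#' comment. Safety is checked at parse time; an unsafe rule is rejected
#' naming the offending head variable.
#'
#' @param text Document text (string or lines).
#' @param prefixes Prefix table.
#' @return A [rule_set()] in document order.
#' @export
parse_rules <- function(text, prefixes = default_prefixes()) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  rx <- "^([A-Za-z0-9_.-]+)\\s*:\\s*IF\\s+(.*)\\s+THEN\\s+(.*)$"
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[[i]]))
    if (ln == "") next
    if (!grepl(rx, ln)) parse_error("malformed rule (expected 'id: IF ... THEN ...')", i)
    id <- sub(rx, "\\1", ln)
    body_txt <- sub(rx, "\\2", ln)
    head_txt <- sub(rx, "\\3", ln)
    body_atoms <- regmatches(body_txt, gregexpr(rule_rx_atom, body_txt))[[1]]
    head_atoms <- regmatches(head_txt, gregexpr(rule_rx_atom, head_txt))[[1]]
    if (length(body_atoms) == 0L || length(head_atoms) != 1L) {
      parse_error("rule needs >=1 body atom and exactly 1 head atom", i)
    }
    body <- lapply(sub(rule_rx_atom, "\\1", body_atoms),
                   parse_rule_atom, prefixes = prefixes, line = i)
    head <- parse_rule_atom(sub(rule_rx_atom, "\\1", head_atoms), prefixes, i)
    rules[[length(rules) + 1L]] <-
      rule(id, body, head, prefixes = prefixes, check = TRUE)
  }
  rule_set(rules)
}

#' Read a rule file
#' @param path File path.
#' @param prefixes Prefix table.
#' @return A [rule_set()].
#' @export
read_rules <- function(path, prefixes = default_prefixes()) {
  parse_rules(readLines(path, encoding = "UTF-8", warn = FALSE), prefixes)
}

# All satisfying bindings of a rule body as a data.frame (one column per
# variable, deterministic row order). With `delta`, restricts to bindings in
# which at least one body atom matches a delta fact (semi-naive firing).
rule_bindings <- function(store, r, delta = NULL) {
  eval_with <- function(stores_per_atom) {
    tabs <- Map(function(atom, st) atom_bindings(st, atom),
                r$body, stores_per_atom)
    Reduce(join_bindings, tabs)
  }
  if (is.null(delta)) {
    b <- eval_with(rep(list(store), length(r$body)))
  } else {
    parts <- lapply(seq_along(r$body), function(i) {
      sts <- rep(list(store), length(r$body))
      sts[[i]] <- delta
      eval_with(sts)
    })
    b <- do.call(rbind, parts)
    if (!is.null(b) && ncol(b) > 0L) b <- unique(b)
  }
  if (is.null(b)) b <- data.frame()
  if (nrow(b) > 1L && ncol(b) > 0L) {
    b <- b[do.call(order, c(as.list(b), list(method = "radix"))), ,
           drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

instantiate_atom <- function(atom, bindings) {
  out <- vector("list", 3L)
  for (i in 1:3) {
    t <- atom[[i]]
    out[[i]] <- if (is_variable_term(t)) bindings[[t]] else
      rep_len(t, nrow(bindings))
  }
  data.frame(s = out[[1]], p = out[[2]], o = out[[3]],
             stringsAsFactors = FALSE)
}

#' Apply one rule to a store
#'
#' Computes every ground instance of the rule head whose body atoms are all
#' satisfied by the store, and returns those not already present.
#'
#' @param store A [triple_store()].
#' @param r A safe [rule()].
#' @param delta Optional delta store for semi-naive firing (internal use).
#' @return data.frame of new triples (columns `s`, `p`, `o`); zero rows when
#'   the rule fires nothing new.
#' @export
apply_rule <- function(store, r, delta = NULL) {
  b <- rule_bindings(store, r, delta)
  if (nrow(b) == 0L) return(empty_facts())
  heads <- instantiate_atom(r$head, b)
  keep <- !duplicated(fact_key(heads$s, heads$p, heads$o))
  heads <- heads[keep, , drop = FALSE]
  present <- fact_key(heads$s, heads$p, heads$o) %in%
    fact_key(store$facts$s, store$facts$p, store$facts$o)
  new <- heads[!present, , drop = FALSE]
  if (nrow(new) > 0L) {
    attr(new, "bindings") <- b[keep, , drop = FALSE][!present, , drop = FALSE]
  }
  rownames(new) <- NULL
  new
}

#' Saturate a store under a rule set
#'
#' Forward-chains the rules to the least fixpoint: the result contains the
#' input store, is closed under every rule, and contains nothing that is not
#' derivable. Evaluation is semi-naive; the fixpoint is independent of rule
#' order. A run report (rounds, per-rule inferred-fact counts) is stored in
#' the result's `$report` and retrievable with [saturation_report()].
#'
#' @param store A [triple_store()].
#' @param rules A [rule_set()] of safe rules.
#' @param max_rounds Round budget; `Inf` (the default) always reaches the
#'   fixpoint on safe rules. If exhausted earlier, an incomplete-closure
#'   error is raised.
#' @param log_derivations Record, for each inferred fact, the rule and the
#'   instantiated premises of its first derivation (enables [explain()]).
#'   First is tie-broken by rule order in `rules`, then by the sorted
#'   binding order.
#' @return The saturated [triple_store()].
#' @export
saturate <- function(store, rules, max_rounds = Inf, log_derivations = FALSE) {
  stopifnot(inherits(rules, "rule_set") || is.list(rules))
  per_rule <- stats::setNames(integer(length(rules)),
                              vapply(rules, `[[`, character(1), "id"))
  log <- if (log_derivations) new.env(parent = emptyenv(), hash = TRUE)
  delta <- store
  rounds <- 0L
  # internal safeguard, far above any reachable closure size
  n_const <- length(unique(c(store$facts$s, store$facts$o)))
  n_pred <- length(unique(store$facts$p)) +
    length(unique(vapply(rules, function(r) r$head[[2]], character(1))))
  hard_cap <- max(1, n_const)^3 * max(1, n_pred) + 1
  repeat {
    if (n_triples(delta) == 0L) break
    if (rounds >= max_rounds) {
      stop(structure(
        class = c("anatkb_incomplete_closure", "error", "condition"),
        list(message = sprintf(
          "fixpoint not reached within %s rounds", format(max_rounds)),
          call = NULL)
      ))
    }
    if (rounds > hard_cap) {
      stop("internal round cap exceeded; rule set appears non-terminating",
           call. = FALSE)
    }
    round_new <- empty_facts()
    round_bind <- list()
    working <- store
    for (r in rules) {
      # evaluate against store + facts already produced this round, so the
      # per-round result is insensitive to rule order at the fixpoint
      nf <- apply_rule(working, r, delta = if (rounds == 0L) NULL else delta)
      if (nrow(nf) > 0L) {
        per_rule[[r$id]] <- per_rule[[r$id]] + nrow(nf)
        if (log_derivations) {
          b <- attr(nf, "bindings")
          prem <- lapply(r$body, instantiate_atom, bindings = b)
          for (k in seq_len(nrow(nf))) {
            key <- fact_key(nf$s[k], nf$p[k], nf$o[k])
            if (is.null(get0(key, envir = log, ifnotfound = NULL))) {
              assign(key, list(
                rule = r$id,
                premises = do.call(rbind, lapply(prem, function(pa)
                  pa[k, , drop = FALSE]))
              ), envir = log)
            }
          }
        }
        working <- add_triples(working, nf$s, nf$p, nf$o)
        round_new <- rbind(round_new, nf)
      }
    }
    rounds <- rounds + 1L
    if (nrow(round_new) == 0L) break
    round_new <- round_new[!duplicated(
      fact_key(round_new$s, round_new$p, round_new$o)), , drop = FALSE]
    store <- add_triples(store, round_new$s, round_new$p, round_new$o)
    delta <- triple_store(round_new, prefixes = store$prefixes)
  }
  store$report <- list(rounds = rounds, inferred = sum(per_rule),
                       per_rule = per_rule)
  store$log <- log
  store
}

#' Retrieve the saturation run report
#' @param store A store returned by [saturate()].
#' @return List with `rounds`, `inferred` and `per_rule` counts, or `NULL`.
#' @export
saturation_report <- function(store) store$report

#' Explain an entailed fact
#'
#' Reconstructs a derivation tree for a fact in a saturated store: leaves
#' are asserted facts, internal nodes record the rule applied and the
#' instantiated premises. Requires `saturate(..., log_derivations = TRUE)`.
#'
#' @param store A saturated [triple_store()] with a derivation log.
#' @param s,p,o The fact to explain (prefixed names allowed).
#' @return A nested list of class `derivation` with elements `conclusion`
#'   (character 3-vector), `rule` (`"asserted"` for leaves) and `premises`
#'   (list of derivations).
#' @export
explain <- function(store, s, p, o) {
  if (is.null(store$log)) {
    stop("store has no derivation log; run saturate(..., log_derivations = TRUE)",
         call. = FALSE)
  }
  s <- expand_iri(s, store$prefixes)
  p <- expand_iri(p, store$prefixes)
  o <- expand_iri(o, store$prefixes)
  if (!has_triple(store, s, p, o)) {
    stop(structure(
      class = c("anatkb_not_entailed", "error", "condition"),
      list(message = sprintf("fact (%s %s %s) is not entailed",
                             compact_iri(s, store$prefixes),
                             compact_iri(p, store$prefixes),
                             compact_iri(o, store$prefixes)),
           call = NULL)
    ))
  }
  build <- function(s, p, o) {
    entry <- get0(fact_key(s, p, o), envir = store$log, ifnotfound = NULL)
    if (is.null(entry)) {
      return(structure(list(conclusion = c(s, p, o), rule = "asserted",
                            premises = list()), class = "derivation"))
    }
    prem <- lapply(seq_len(nrow(entry$premises)), function(i)
      build(entry$premises$s[i], entry$premises$p[i], entry$premises$o[i]))
    structure(list(conclusion = c(s, p, o), rule = entry$rule,
                   premises = prem), class = "derivation")
  }
  build(s, p, o)
}

#' @export
print.derivation <- function(x, ..., indent = 0) {
  pad <- strrep("  ", indent)
  cat(pad, paste(compact_iri(x$conclusion), collapse = " "),
      "   [", x$rule, "]\n", sep = "")
  for (pr in x$premises) print(pr, indent = indent + 1)
  invisible(x)
}
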