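# Anatomy vocabulary, core rule set, laterality expansion, constraints ------

#' The anatomy knowledge-base vocabulary
#'
#' IRI constants for the relations and top classes linking the three
#' taxonomies: anatomical entities (subclass taxonomy, partonomy, attachment
#' sites), anatomical functions, and 3D scenes/objects.
#'
#' @param expanded Return full IRIs (default) or prefixed names?
#' @return List with named character vectors `$relations` and `$classes`.
#' @export
mcf_vocabulary <- function(expanded = TRUE) {
  rel <- c(
    type           = "rdf:type",
    subClassOf     = "rdfs:subClassOf",
    sameAs         = "owl:sameAs",
    leftSubClassOf = "mcf:leftSubClassOf",
    rightSubClassOf = "mcf:rightSubClassOf",
    PartOf         = "mcf:PartOf",
    InsertOn       = "mcf:InsertOn",
    IsInvolvedIn   = "mcf:IsInvolvedIn",
    hasFunction    = "mcf:hasFunction",
    contributesTo  = "mcf:contributesTo",
    Contains       = "mcf:Contains",
    Describes      = "mcf:Describes",
    Displays       = "mcf:Displays",
    Position       = "mcf:Position",
    hasMesh        = "mcf:hasMesh",
    hasTexture     = "mcf:hasTexture",
    hasColour      = "mcf:hasColour"
  )
  cls <- c(
    anatomical_entity = "mcf:Anatomical_entity",
    functional_entity = "mcf:Functional_entity",
    entity_3d         = "mcf:3D-entity",
    scene_3d          = "mcf:3D-scene",
    object_3d         = "mcf:3D-object"
  )
  if (expanded) {
    rel <- stats::setNames(expand_iri(rel), names(rel))
    cls <- stats::setNames(expand_iri(cls), names(cls))
  }
  list(relations = rel, classes = cls)
}

#' The default rule set
#'
#' Loads the packaged core rules: three transitivity rules (subclass,
#' part-of, involved-in), three specialisation rules (left/right laterality
#' links are subclass links; whole-organ functions are contributions), and
#' five cross-relation composition rules (subclass with insertion,
#' involvement and contribution with subclass, contribution with
#' involvement, insertion with part-of). With `include_colour_rule` the
#' bone-colouring visualisation rule is appended.
#'
#' @param include_colour_rule Append the bone-colour rule?
#' @return A [rule_set()] (11 rules; 12 with the colour rule).
#' @export
default_ruleset <- function(include_colour_rule = FALSE) {
  core <- read_rules(system.file("extdata", "mcf_core.rules",
                                 package = "anatkb", mustWork = TRUE))
  if (!include_colour_rule) return(core)
  colour <- read_rules(system.file("extdata", "mcf_colour.rules",
                                   package = "anatkb", mustWork = TRUE))
  rule_set(c(unclass(core), unclass(colour)))
}

#' Laterality expansion policy
#'
#' Controls how a taxonomy subtree is replicated into left and right
#' specialisations: the name prefixes for the two copies and the predicates
#' whose within-subtree links are replicated.
#'
#' @param left_prefix,right_prefix Name prefixes for the copies.
#' @param replicate Predicates (prefixed names ok) replicated inside the
#'   subtree.
#' @return Object of class `laterality_policy`.
#' @export
laterality_policy <- function(left_prefix = "Left_", right_prefix = "Right_",
                              replicate = c("rdfs:subClassOf", "mcf:PartOf",
                                            "mcf:InsertOn", "mcf:hasFunction",
                                            "mcf:contributesTo")) {
  stopifnot(nzchar(left_prefix), nzchar(right_prefix),
            left_prefix != right_prefix, length(replicate) >= 1L)
  structure(list(left_prefix = left_prefix, right_prefix = right_prefix,
                 replicate = expand_iri(replicate)),
            class = "laterality_policy")
}

iri_local <- function(x) sub("^.*[#/]", "", x)
iri_ns <- function(x) sub("[^#/]*$", "", x)

# class members of the subClassOf-subtree rooted at `root` (asserted edges)
subclass_subtree <- function(store, root) {
  edges <- match_triples(store, "?a", "rdfs:subClassOf", "?b")
  members <- root
  frontier <- root
  while (length(frontier) > 0L) {
    kids <- unique(edges$s[edges$o %in% frontier])
    frontier <- setdiff(kids, members)
    members <- c(members, frontier)
  }
  members
}

#' Expand a taxonomy subtree into left and right specialisations
#'
#' For the root and every class in its subclass subtree, adds
#' `Left_X leftSubClassOf X` and `Right_X rightSubClassOf X`, and replicates
#' every stored link `(a p b)` whose predicate is in the policy's replicate
#' set and whose endpoints both lie inside the subtree as
#' `(Left_a p Left_b)` and `(Right_a p Right_b)`. The original subtree is
#' left untouched. Links crossing the subtree boundary are not replicated.
#'
#' Re-running the expansion on its own output raises a name-collision error
#' rather than silently duplicating.
#'
#' @param store A [triple_store()].
#' @param root IRI (or prefixed name) of the subtree root; must occur in the
#'   store.
#' @param policy A [laterality_policy()].
#' @return The store with the lateralised copies added.
#' @export
expand_laterality <- function(store, root, policy = laterality_policy()) {
  root <- expand_iri(root, store$prefixes)
  present <- root %in% store$facts$s | root %in% store$facts$o
  if (!present) stop("root '", compact_iri(root, store$prefixes),
                     "' not present in store", call. = FALSE)
  members <- subclass_subtree(store, root)
  lateral <- function(pfx, x) paste0(iri_ns(x), pfx, iri_local(x))
  left <- lateral(policy$left_prefix, members)
  right <- lateral(policy$right_prefix, members)
  existing <- unique(c(store$facts$s, store$facts$o))
  clash <- intersect(c(left, right), existing)
  if (length(clash) > 0L) {
    stop(structure(
      class = c("anatkb_name_collision", "error", "condition"),
      list(message = paste0("laterality expansion would collide with existing names: ",
                            paste(compact_iri(utils::head(clash, 5),
                                              store$prefixes), collapse = ", ")),
           call = NULL)
    ))
  }
  v <- mcf_vocabulary()$relations
  store <- add_triples(store, left, v[["leftSubClassOf"]], members)
  store <- add_triples(store, right, v[["rightSubClassOf"]], members)
  rep_edges <- store$facts[store$facts$p %in% policy$replicate &
                             store$facts$s %in% members &
                             store$facts$o %in% members, , drop = FALSE]
  if (nrow(rep_edges) > 0L) {
    li <- match(rep_edges$s, members); lo <- match(rep_edges$o, members)
    store <- add_triples(store, left[li], rep_edges$p, left[lo])
    store <- add_triples(store, right[li], rep_edges$p, right[lo])
  }
  store
}

# Constraints ----------------------------------------------------------------

#' Construct a model-checking constraint
#'
#' An existential constraint: for every binding of the body patterns, some
#' instance of the requirement pattern (with the body's bindings
#' substituted; remaining variables are existentially quantified) must be
#' present in the store. Example: every synovial joint must have an
#' articular capsule as a part.
#'
#' @param id Constraint identifier.
#' @param body List of pattern atoms (the "if" context).
#' @param require One pattern atom, or a list of atoms read as a
#'   conjunction, that must be jointly satisfiable (variables not bound by
#'   the body are existentially quantified across the conjunction).
#' @param prefixes Prefix table.
#' @return Object of class `constraint_rule`.
#' @export
constraint_rule <- function(id, body, require, prefixes = default_prefixes()) {
  stopifnot(length(body) >= 1L)
  body <- lapply(body, function(a) expand_iri(as.character(a), prefixes))
  if (!is.list(require)) require <- list(require)
  require <- lapply(require, function(a) expand_iri(as.character(a), prefixes))
  stopifnot(length(require) >= 1L, all(lengths(require) == 3L))
  structure(list(id = id, body = body, require = require),
            class = "constraint_rule")
}

#' Parse a constraint document
#'
#' Same atom syntax as rule files, with `REQUIRE` in place of `THEN`:
#' `Cid: IF (s p o) AND (s p o) REQUIRE (s p o) AND (s p o)`. The REQUIRE
#' side may be a conjunction of atoms sharing existential variables.
#'
#' @param text Document text.
#' @param prefixes Prefix table.
#' @return List of [constraint_rule()] objects.
#' @export
parse_constraints <- function(text, prefixes = default_prefixes()) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- list()
  rx <- "^([A-Za-z0-9_.-]+)\\s*:\\s*IF\\s+(.*)\\s+REQUIRE\\s+(.*)$"
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[[i]]))
    if (ln == "") next
    if (!grepl(rx, ln)) parse_error("malformed constraint (expected 'id: IF ... REQUIRE ...')", i)
    id <- sub(rx, "\\1", ln)
    body_atoms <- regmatches(sub(rx, "\\2", ln), gregexpr(rule_rx_atom, sub(rx, "\\2", ln)))[[1]]
    req_atoms <- regmatches(sub(rx, "\\3", ln), gregexpr(rule_rx_atom, sub(rx, "\\3", ln)))[[1]]
    if (length(body_atoms) == 0L || length(req_atoms) == 0L) {
      parse_error("constraint needs >=1 body atom and >=1 REQUIRE atom", i)
    }
    body <- lapply(sub(rule_rx_atom, "\\1", body_atoms),
                   parse_rule_atom, prefixes = prefixes, line = i)
    req <- lapply(sub(rule_rx_atom, "\\1", req_atoms),
                  parse_rule_atom, prefixes = prefixes, line = i)
    out[[length(out) + 1L]] <- constraint_rule(id, body, req, prefixes)
  }
  out
}

#' Read a constraint file
#' @param path File path.
#' @param prefixes Prefix table.
#' @return List of [constraint_rule()] objects.
#' @export
read_constraints <- function(path, prefixes = default_prefixes()) {
  parse_constraints(readLines(path, encoding = "UTF-8", warn = FALSE), prefixes)
}

validation_report <- function(violations) {
  if (is.null(violations) || nrow(violations) == 0L) {
    violations <- data.frame(check = character(), subject = character(),
                             detail = character(), stringsAsFactors = FALSE)
  }
  structure(list(violations = violations, valid = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("<validation_report> valid (no violations)\n")
  } else {
    cat("<validation_report>", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

#' Check a saturated store against constraints
#'
#' Evaluates each constraint against the entailed facts: for every binding
#' of the constraint's body, the requirement pattern (with body bindings
#' substituted) must have at least one satisfying instance in the store.
#' Constraints should be checked after [saturate()], since requirements are
#' meant to hold over entailed, not merely asserted, knowledge.
#'
#' @param store A (saturated) [triple_store()].
#' @param constraints List of [constraint_rule()] objects.
#' @return A `validation_report`; `$valid` is `TRUE` iff no body binding
#'   lacks a satisfying requirement instance.
#' @export
validate_model <- function(store, constraints) {
  if (inherits(constraints, "constraint_rule")) constraints <- list(constraints)
  rows <- list()
  for (con in constraints) {
    pseudo <- structure(list(id = con$id, body = con$body,
                             head = c("?s", "?p", "?o")), class = "rule")
    b <- rule_bindings(store, pseudo)
    if (nrow(b) == 0L) next
    for (k in seq_len(nrow(b))) {
      atoms <- lapply(con$require, function(a) vapply(a, function(t) {
        if (is_variable_term(t) && t %in% names(b)) b[[t]][k] else t
      }, character(1), USE.NAMES = FALSE))
      req_rule <- structure(list(id = con$id, body = atoms,
                                 head = c("?s", "?p", "?o")), class = "rule")
      sat <- rule_bindings(store, req_rule)
      if (nrow(sat) == 0L) {
        subj <- paste(sprintf("%s=%s", names(b),
                              compact_iri(unlist(b[k, , drop = FALSE]),
                                          store$prefixes)),
                      collapse = " ")
        shown <- paste(vapply(atoms, function(a)
          paste0("(", paste(compact_iri(a, store$prefixes), collapse = " "),
                 ")"), character(1)), collapse = " AND ")
        rows[[length(rows) + 1L]] <- data.frame(
          check = con$id, subject = subj,
          detail = paste("no instance of requirement", shown),
          stringsAsFactors = FALSE)
      }
    }
  }
  validation_report(do.call(rbind, rows))
}
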