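# Independent oracles used to cross-check the engine. These deliberately
# avoid the package's join machinery: matching is a plain linear scan with
# unification, rule application enumerates bindings atom by atom, and the
# fixpoint is naive full re-evaluation.

oracle_unify <- function(atom, fact, env) {
  for (i in 1:3) {
    t <- atom[[i]]
    v <- fact[[i]]
    if (startsWith(t, "?")) {
      if (!is.null(env[[t]])) {
        if (env[[t]] != v) return(NULL)
      } else {
        env[[t]] <- v
      }
    } else if (t != v) {
      return(NULL)
    }
  }
  env
}

# all facts unifying with a single pattern (linear scan)
oracle_match <- function(facts, s, p, o) {
  atom <- c(s, p, o)
  keep <- logical(nrow(facts))
  for (r in seq_len(nrow(facts))) {
    keep[r] <- !is.null(oracle_unify(atom, c(facts$s[r], facts$p[r], facts$o[r]),
                                     list()))
  }
  facts[keep, , drop = FALSE]
}

# all binding environments satisfying every atom of a rule body
oracle_body_bindings <- function(facts, body) {
  envs <- list(list())
  for (atom in body) {
    nxt <- list()
    for (env in envs) {
      ground <- vapply(atom, function(t)
        if (startsWith(t, "?") && !is.null(env[[t]])) env[[t]] else t,
        character(1), USE.NAMES = FALSE)
      for (r in seq_len(nrow(facts))) {
        e2 <- oracle_unify(ground, c(facts$s[r], facts$p[r], facts$o[r]), env)
        if (!is.null(e2)) nxt[[length(nxt) + 1L]] <- e2
      }
    }
    envs <- nxt
    if (length(envs) == 0L) break
  }
  envs
}

oracle_apply_rule <- function(facts, r) {
  envs <- oracle_body_bindings(facts, r$body)
  if (length(envs) == 0L) {
    return(data.frame(s = character(), p = character(), o = character(),
                      stringsAsFactors = FALSE))
  }
  heads <- lapply(envs, function(env) vapply(r$head, function(t)
    if (startsWith(t, "?")) env[[t]] else t, character(1),
    USE.NAMES = FALSE))
  m <- unique(do.call(rbind, heads))
  data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE)
}

key3 <- function(df) paste(df$s, df$p, df$o, sep = "\r")

# naive fixpoint: re-evaluate every rule over the full fact set each round
oracle_naive_fixpoint <- function(facts, rules) {
  repeat {
    new <- do.call(rbind, lapply(rules, function(r) oracle_apply_rule(facts, r)))
    new <- new[!(key3(new) %in% key3(facts)), , drop = FALSE]
    if (nrow(new) == 0L) return(facts)
    facts <- rbind(facts, new)
    facts <- facts[!duplicated(key3(facts)), , drop = FALSE]
  }
}

# reachability closure of an edge list (BFS per source node)
oracle_transitive_closure <- function(from, to) {
  nodes <- unique(c(from, to))
  out_from <- character(0); out_to <- character(0)
  adj <- split(to, factor(from, levels = nodes))
  for (src in nodes) {
    seen <- character(0)
    frontier <- adj[[src]]
    while (length(frontier) > 0L) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      frontier <- unlist(adj[frontier], use.names = FALSE)
    }
    out_from <- c(out_from, rep(src, length(seen)))
    out_to <- c(out_to, seen)
  }
  data.frame(from = out_from, to = out_to, stringsAsFactors = FALSE)
}

same_fact_set <- function(a, b) {
  setequal(key3(a), key3(b))
}

# random ground stores over small constant pools (for round-trip / match
# oracles); plain random triples, not anatomy-shaped
random_store <- function(n, n_const = 12, n_pred = 4, literals = TRUE,
                         prefixes = default_prefixes()) {
  consts <- sprintf("mcf:C%02d", seq_len(n_const))
  preds <- sprintf("mcf:p%d", seq_len(n_pred))
  o <- sample(consts, n, replace = TRUE)
  if (literals && n > 0) {
    is_lit <- runif(n) < 0.2
    o[is_lit] <- lit(sprintf("value %d", sample(99, sum(is_lit), replace = TRUE)))
  }
  triple_store(data.frame(s = sample(consts, n, replace = TRUE),
                          p = sample(preds, n, replace = TRUE),
                          o = o, stringsAsFactors = FALSE),
               prefixes = prefixes)
}

random_pattern <- function(store) {
  pool <- unique(c(store$facts$s, store$facts$p, store$facts$o))
  vars <- c("?x", "?y", "?z", "?x")   # repeated ?x makes shared-var patterns
  term <- function() {
    if (runif(1) < 0.5) sample(vars, 1) else sample(pool, 1)
  }
  c(term(), term(), term())
}

# random anatomy-shaped stores for saturation oracles
random_ontology <- function(seed, max_triples = 150) {
  params <- synth_params(
    depth = sample(2:4, 1), branching = sample(1:3, 1),
    n_functions = sample(3:10, 1),
    p_part_of = runif(1, 0.1, 0.5), p_insert_on = runif(1, 0, 0.3),
    p_has_function = runif(1, 0, 0.4), p_contributes_to = runif(1, 0, 0.3),
    p_is_involved_in = runif(1, 0.2, 0.8),
    laterality_fraction = sample(c(0, 0.5, 1), 1),
    seed = seed)
  store <- generate_synthetic_ontology(params)
  if (n_triples(store) > max_triples) {
    keep <- store$facts[seq_len(max_triples), , drop = FALSE]
    store <- triple_store(keep, prefixes = store$prefixes)
  }
  store
}

fixture_closed <- local({
  cache <- NULL
  function(colour = FALSE) {
    if (is.null(cache)) {
      fx <- lower_limb_fixture()
      cache <<- list(
        fx = fx,
        core = saturate(fx$store, default_ruleset(), log_derivations = TRUE),
        colour = saturate(fx$store, default_ruleset(TRUE))
      )
    }
    if (colour) cache$colour else cache$core
  }
})

fixture_cached <- function() {
  invisible(fixture_closed())
  environment(fixture_closed)$cache$fx
}
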