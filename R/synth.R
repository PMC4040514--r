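# Seeded synthetic ontology generator ----------------------------------------
#
# Emulates the structure of an anatomy knowledge base for property-based
# testing: a subclass taxonomy tree over anatomical classes, a forest of
# function classes linked by involvement edges, cross edges (part-of,
# insertion, function assignment) sampled at stated per-node densities, and
# optional laterality expansion of a fraction of the depth-2 subtrees.
# Fully reproducible from the seed; class names use a deterministic counter
# scheme (Ent_0001, Fun_0001, ...) to keep diffs stable.

#' Parameters for the synthetic ontology generator
#'
#' @param depth Taxonomy depth (levels, root included); >= 1.
#' @param branching Children per taxonomy node; 0 gives a single class.
#' @param n_functions Number of function classes.
#' @param p_part_of,p_insert_on,p_has_function,p_contributes_to Per-node
#'   probabilities of the corresponding cross edge, each in \[0, 1\].
#' @param p_is_involved_in Per-function probability of an involvement edge
#'   to an earlier function (keeps the involvement graph a forest).
#' @param laterality_fraction Fraction of the root's child subtrees to
#'   expand into left/right specialisations.
#' @param seed Random seed; the same seed always yields the same store.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(depth = 4, branching = 2, n_functions = 10,
                         p_part_of = 0.3, p_insert_on = 0.1,
                         p_has_function = 0.2, p_contributes_to = 0.1,
                         p_is_involved_in = 0.5,
                         laterality_fraction = 0, seed = 1L) {
  p <- list(depth = as.integer(depth), branching = as.integer(branching),
            n_functions = as.integer(n_functions),
            p_part_of = p_part_of, p_insert_on = p_insert_on,
            p_has_function = p_has_function,
            p_contributes_to = p_contributes_to,
            p_is_involved_in = p_is_involved_in,
            laterality_fraction = laterality_fraction,
            seed = as.integer(seed))
  probs <- unlist(p[grep("^p_", names(p))])
  if (p$depth < 1L || p$branching < 0L || p$n_functions < 0L ||
      any(probs < 0 | probs > 1) ||
      p$laterality_fraction < 0 || p$laterality_fraction > 1) {
    stop("invalid synthetic-ontology parameters", call. = FALSE)
  }
  structure(p, class = "synth_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic anatomy ontology
#'
#' @param params A [synth_params()].
#' @param prefixes Prefix table.
#' @return A [triple_store()]. Subclass and part-of graphs are acyclic by
#'   construction (part-of edges always point to a lower-numbered class).
#' @export
generate_synthetic_ontology <- function(params = synth_params(),
                                        prefixes = default_prefixes()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    ent <- function(i) sprintf("mcf:Ent_%04d", i)
    fun <- function(i) sprintf("mcf:Fun_%04d", i)
    s <- character(0); p <- character(0); o <- character(0)
    add <- function(ss, pp, oo) {
      s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
    }
    # root anchors the taxonomy under the anatomical top class, so even a
    # depth-1 store contains its single class
    add("mcf:Ent_0001", "rdfs:subClassOf", "mcf:Anatomical_entity")
    # taxonomy tree, breadth-first, counter-based names
    parent <- integer(0)          # parent index per node; 0 for the root
    level <- integer(0)
    nodes <- 1L; parent[1] <- 0L; level[1] <- 1L
    frontier <- 1L
    d <- 1L
    while (d < params$depth && params$branching > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        kids <- nodes + seq_len(params$branching)
        for (k in kids) {
          parent[k] <- u; level[k] <- d + 1L
          add(ent(k), "rdfs:subClassOf", ent(u))
        }
        nodes <- nodes + params$branching
        nxt <- c(nxt, kids)
      }
      frontier <- nxt
      d <- d + 1L
    }
    # part-of: each non-root node may be part of a lower-numbered node
    if (nodes > 1L) {
      for (i in 2:nodes) {
        if (stats::runif(1) < params$p_part_of) {
          add(ent(i), "mcf:PartOf", ent(sample.int(i - 1L, 1L)))
        }
      }
    }
    # insertion sites between arbitrary distinct classes
    if (nodes > 1L) {
      for (i in seq_len(nodes)) {
        if (stats::runif(1) < params$p_insert_on) {
          j <- sample.int(nodes - 1L, 1L)
          if (j >= i) j <- j + 1L
          add(ent(i), "mcf:InsertOn", ent(j))
        }
      }
    }
    # function forest: each later function may be involved in an earlier one
    if (params$n_functions > 1L) {
      for (i in 2:params$n_functions) {
        if (stats::runif(1) < params$p_is_involved_in) {
          add(fun(i), "mcf:IsInvolvedIn", fun(sample.int(i - 1L, 1L)))
        }
      }
    }
    # cross edges from anatomy to functions
    if (params$n_functions > 0L) {
      for (i in seq_len(nodes)) {
        if (stats::runif(1) < params$p_has_function) {
          add(ent(i), "mcf:hasFunction", fun(sample.int(params$n_functions, 1L)))
        }
        if (stats::runif(1) < params$p_contributes_to) {
          add(ent(i), "mcf:contributesTo",
              fun(sample.int(params$n_functions, 1L)))
        }
      }
    }
    store <- triple_store(data.frame(s = s, p = p, o = o,
                                     stringsAsFactors = FALSE),
                          prefixes = prefixes)
    if (params$laterality_fraction > 0 && params$branching > 0L &&
        params$depth > 1L) {
      roots <- which(level == 2L)
      k <- ceiling(params$laterality_fraction * length(roots))
      pick <- sort(sample(roots, k))
      for (r in pick) store <- expand_laterality(store, ent(r))
    }
    store
  })
}
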