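part_of_transitivity <- function() {
  rule("R2",
       body = list(c("?a", "mcf:PartOf", "?c"), c("?c", "mcf:PartOf", "?b")),
       head = c("?a", "mcf:PartOf", "?b"))
}

test_that("rule parsing round-trips and rejects unsafe rules", {
  txt <- "R2: IF (?a mcf:PartOf ?c) AND (?c mcf:PartOf ?b) THEN (?a mcf:PartOf ?b)"
  rs <- parse_rules(txt)
  expect_length(rs, 1L)
  expect_length(rs[[1]]$body, 2L)
  expect_equal(compact_iri(rs[[1]]$head),
               c("?a", "mcf:PartOf", "?b"))

  # print -> parse is the identity on the default rule set
  rs <- default_ruleset(include_colour_rule = TRUE)
  back <- parse_rules(format(rs))
  expect_equal(lapply(back, unclass), lapply(rs, unclass))

  err <- tryCatch(parse_rules("X: IF (?a mcf:p ?b) THEN (?a mcf:q ?c)"),
                  error = identity)
  expect_match(conditionMessage(err), "\\?c")
  expect_match(conditionMessage(err), "unsafe")

  expect_error(parse_rules("not a rule"), "malformed")
})

test_that("safety checking agrees with explicit variable-set difference", {
  rs <- default_ruleset(include_colour_rule = TRUE)
  for (r in rs) expect_length(check_safety(r), 0L)

  r <- structure(list(id = "bad", body = list(c("?a", "mcf:p", "?b")),
                      head = c("?a", "mcf:q", "?z")), class = "rule")
  expect_equal(check_safety(r), "?z")

  set.seed(3)
  vars <- paste0("?", letters[1:6])
  consts <- expand_iri(sprintf("mcf:k%d", 1:4))
  rand_atom <- function() {
    sapply(1:3, function(i)
      if (runif(1) < 0.6) sample(vars, 1) else sample(consts, 1))
  }
  for (i in 1:200) {
    r <- structure(list(id = "r", head = rand_atom(),
                        body = lapply(seq_len(sample(1:3, 1)),
                                      function(j) rand_atom())),
                   class = "rule")
    head_vars <- unique(r$head[startsWith(r$head, "?")])
    body_vars <- unique(unlist(r$body))
    body_vars <- body_vars[startsWith(body_vars, "?")]
    expect_setequal(check_safety(r), setdiff(head_vars, body_vars))
  }
})

test_that("apply_rule derives exactly the satisfied head instances", {
  r1 <- parse_rules(
    "R1: IF (?a rdfs:subClassOf ?c) AND (?c rdfs:subClassOf ?b) THEN (?a rdfs:subClassOf ?b)")[[1]]
  st <- triple_store(data.frame(
    s = c("mcf:a", "mcf:c"), p = "rdfs:subClassOf", o = c("mcf:c", "mcf:b")))
  nf <- apply_rule(st, r1)
  expect_equal(unname(compact_iri(unlist(nf))),
               c("mcf:a", "rdfs:subClassOf", "mcf:b"))

  # rule whose body matches nothing fires nothing
  expect_equal(nrow(apply_rule(st, part_of_transitivity())), 0L)
})

test_that("apply_rule equals an exhaustive-binding oracle on random stores", {
  rs <- default_ruleset(include_colour_rule = TRUE)
  set.seed(19)
  for (i in 1:60) {
    st <- random_ontology(seed = 1000 + i, max_triples = 60)
    r <- rs[[sample(length(rs), 1)]]
    got <- apply_rule(st, r)
    want <- oracle_apply_rule(st$facts, r)
    want <- want[!(key3(want) %in% key3(st$facts)), , drop = FALSE]
    expect_true(same_fact_set(got, want), info = paste("case", i, r$id))
  }
})

test_that("saturation reaches the worked muscle-function inferences", {
  st <- triple_store(data.frame(
    s = c("mcf:Sartorius", "mcf:Biceps_femoris", "mcf:Knee_flexion"),
    p = c("mcf:contributesTo", "mcf:contributesTo", "mcf:IsInvolvedIn"),
    o = c("mcf:Knee_flexion", "mcf:Knee_flexion", "mcf:Movement_of_knee")))
  closed <- saturate(st, default_ruleset())
  expect_true(has_triple(closed, "mcf:Sartorius", "mcf:contributesTo",
                         "mcf:Movement_of_knee"))
  expect_true(has_triple(closed, "mcf:Biceps_femoris", "mcf:contributesTo",
                         "mcf:Movement_of_knee"))
})

test_that("saturating the empty store is a no-op with zero rounds", {
  closed <- saturate(triple_store(), default_ruleset())
  expect_equal(n_triples(closed), 0L)
  expect_equal(saturation_report(closed)$rounds, 0L)
})

test_that("semi-naive saturation equals the naive fixpoint on random stores", {
  rs <- default_ruleset()
  for (i in 1:25) {
    st <- random_ontology(seed = 2000 + i, max_triples = 100)
    got <- saturate(st, rs)
    want <- oracle_naive_fixpoint(st$facts, rs)
    expect_true(same_fact_set(got$facts, want), info = paste("seed", 2000 + i))
  }
})

test_that("saturation is idempotent, monotone, and rule-order independent", {
  rs <- default_ruleset()
  fx <- fixture_cached()
  closed <- fixture_closed()
  again <- saturate(closed, rs)
  expect_true(same_fact_set(again$facts, closed$facts))

  set.seed(5)
  for (i in 1:10) {
    st <- random_ontology(seed = 3000 + i, max_triples = 80)
    closed <- saturate(st, rs)
    # idempotence
    expect_true(same_fact_set(saturate(closed, rs)$facts, closed$facts))
    # monotonicity on a nested sub-store
    sub <- triple_store(st$facts[sample(nrow(st$facts),
                                        floor(nrow(st$facts) / 2)), ],
                        prefixes = st$prefixes)
    expect_true(all(key3(saturate(sub, rs)$facts) %in% key3(closed$facts)))
    # order independence
    perm <- rule_set(unclass(rs)[sample(length(rs))])
    expect_true(same_fact_set(saturate(st, perm)$facts, closed$facts))
  }
})

test_that("round counts stay within the derivation bound", {
  for (i in 1:5) {
    st <- random_ontology(seed = 4000 + i, max_triples = 80)
    closed <- saturate(st, default_ruleset())
    derived <- n_triples(closed) - n_triples(st)
    expect_lte(saturation_report(closed)$rounds, derived + 1L)
  }
})

test_that("an exhausted round budget raises an incomplete-closure error", {
  st <- triple_store(data.frame(
    s = sprintf("mcf:n%d", 1:9), p = "mcf:PartOf", o = sprintf("mcf:n%d", 2:10)))
  err <- tryCatch(saturate(st, rule_set(list(part_of_transitivity())),
                           max_rounds = 1),
                  error = identity)
  expect_s3_class(err, "anatkb_incomplete_closure")
  # unlimited rounds reach the fixpoint: the full chain closure
  closed <- saturate(st, rule_set(list(part_of_transitivity())))
  expect_equal(n_triples(closed), 9L * 10L / 2L)
})

test_that("explanations are well-formed and replay to their conclusions", {
  closed <- fixture_closed()

  d <- explain(closed, "mcf:Knee", "mcf:hasFunction", "mcf:Knee_Movement")
  expect_equal(d$rule, "asserted")
  expect_length(d$premises, 0L)

  d <- explain(closed, "mcf:Sartorius", "mcf:contributesTo",
               "mcf:Movement_of_knee")
  expect_equal(d$rule, "R10")
  expect_length(d$premises, 2L)

  # replay every internal node bottom-up with the rule's oracle application
  rs <- default_ruleset()
  replay <- function(node) {
    if (node$rule == "asserted") {
      expect_true(has_triple(fixture_cached()$store, node$conclusion[1],
                             node$conclusion[2], node$conclusion[3]))
      return(invisible())
    }
    for (pr in node$premises) replay(pr)
    prem <- do.call(rbind, lapply(node$premises, function(pr)
      data.frame(s = pr$conclusion[1], p = pr$conclusion[2],
                 o = pr$conclusion[3], stringsAsFactors = FALSE)))
    got <- oracle_apply_rule(prem, rs[[node$rule]])
    expect_true(key3(data.frame(s = node$conclusion[1], p = node$conclusion[2],
                                o = node$conclusion[3])) %in% key3(got))
  }
  replay(d)
  replay(explain(closed, "mcf:Vastus_medialis", "mcf:contributesTo",
                 "mcf:Movement_of_knee"))

  err <- tryCatch(explain(closed, "mcf:Knee", "mcf:PartOf", "mcf:Toe"),
                  error = identity)
  expect_s3_class(err, "anatkb_not_entailed")
})
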