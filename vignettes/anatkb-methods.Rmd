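---
title: "Methods: a deductive triple store for anatomical knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deductive triple store for anatomical knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatkb)
```

## The model

`anatkb` represents anatomical knowledge as RDF-style triples
`(subject, predicate, object)` over three linked taxonomies:

1. **Anatomical entities** — a subclass hierarchy (`rdfs:subClassOf`) and a
   partonomy (`mcf:PartOf`), plus attachment sites (`mcf:InsertOn`) between
   entities (a tendon inserts on a bone).
2. **Anatomical functions** — a hierarchy of functions linked by
   `mcf:IsInvolvedIn` (knee flexion is involved in movement of the knee),
   connected to entities by `mcf:hasFunction` (the characteristic function
   of a whole organ) and `mcf:contributesTo` (a weaker contribution link).
3. **3D scenes** — scenes `Display` an entity and `Contain` objects; each
   object `Describes` one entity and carries mesh/texture paths, a colour
   and a 4x4 placement matrix as attribute literals.

Terms are encoded as single strings: IRIs are stored expanded, literals are
wrapped in `"`, and variables start with `?`. The three forms are
syntactically disjoint (an IRI can start with neither `?` nor `"`), so no
separate type tag is needed. A fixed prefix table (`mcf`, `fma`, `rdf`,
`rdfs`, `owl`) drives expansion and compaction; serialisation is sorted and
deterministic, so equal stores produce byte-identical documents.

### Assumptions

- **Canonical anatomy**: classes describe idealized anatomy; instance data
  (e.g. a patient scan `mcf:u rdf:type mcf:Patella`) may be present but no
  instance-level reasoning beyond the rules below is performed.
- `rdfs:subClassOf` is used non-reflexively: the closure contains
  `X subClassOf Y` only when a chain of asserted subclass (or laterality)
  edges leads from `X` to `Y`, never `X subClassOf X`.
- Literals may appear only in the object position; variables may appear in
  any position of a pattern or rule atom, but not in asserted facts.

## The rule set

The core rule set (`default_ruleset()`) has 11 safe Datalog rules:

| id | reading |
|----|---------|
| R1 | `subClassOf` is transitive |
| R2 | `PartOf` is transitive |
| R3 | `IsInvolvedIn` is transitive |
| R4 | `leftSubClassOf` implies `subClassOf` |
| R5 | `rightSubClassOf` implies `subClassOf` |
| R6 | `hasFunction` implies `contributesTo` |
| R7 | a subclass inherits its superclass's insertion sites |
| R8 | involvement lifts along function subclassing |
| R9 | contribution lifts along function subclassing |
| R10 | contribution composes with involvement |
| R11 | insertion on a part is insertion on the whole (`InsertOn ∘ PartOf`) |

An optional 12th rule (`default_ruleset(include_colour_rule = TRUE)`, also
exposed as `apply_colour_rules()`) implements a rendering convention: any
3D object describing an entailed subclass of bone receives
`hasColour "yellow"`.

**Safety** means every variable in a rule's conclusion occurs in its
conditions (`check_safety()`), so saturation can only produce facts over
the finite set of constants already present — the closure is finite and
saturation terminates.

**Semi-naive evaluation**: round 0 evaluates every rule against the full
store; each later round requires at least one condition atom to match the
facts newly derived in the previous round. This avoids re-deriving the
entire closure each round while provably reaching the same least fixpoint
as naive re-evaluation — the test suite checks this equality against an
independent naive oracle on hundreds of seeded random ontologies. With
`log_derivations = TRUE` each first derivation of a fact is recorded
(ties broken by rule order, then sorted bindings), and `explain()`
reconstructs the full derivation tree down to asserted leaves.

## Laterality

Anatomy is largely bilateral. `expand_laterality(store, root)` takes the
subtree of asserted subclass descendants of `root` and creates `Left_X` /
`Right_X` copies of each member, linked by `leftSubClassOf` /
`rightSubClassOf` to the original. Edges of the replicate relations
(`subClassOf`, `PartOf`, `InsertOn`, `hasFunction`, `contributesTo`,
configurable via `laterality_policy()`) are copied to each side **only
when both endpoints lie inside the subtree**: a boundary edge such as
`knee_joint subClassOf Joint` is deliberately not replicated, because the
generic fact is recovered through `Left_knee_joint leftSubClassOf
knee_joint` plus rules R4/R1 at saturation time. If a generated name
already exists in the store the expansion aborts with a name-collision
error rather than silently merging distinct classes.

Interpretation: `Left_X leftSubClassOf X` says the left instance class is a
specialisation of the side-neutral class; it is *not* a parthood claim.

## Queries, constraints and scenes

Queries are a SELECT/WHERE basic graph pattern subset with variables
allowed in any triple position, including the predicate. Evaluation orders
patterns by smallest match set, joins binding tables naturally, projects
the selected variables, and always deduplicates and sorts — answers are a
deterministic function of the store. Queries are usually evaluated against
a saturated store (a warning is issued otherwise), so entailed facts count
as answers.

Existential constraints (`C1: IF (?j rdf:type mcf:Sinovial_joint) REQUIRE
(?c rdf:type mcf:Articular_capsule) AND (?c mcf:PartOf ?j)`) are checked
per body binding; the REQUIRE part is a conjunction that must be satisfiable
by some assignment of its own variables. `validate_model()` returns a
report with one row per violating binding.

Scene validity (`check_scene_validity()`) flags each contained object whose
described entity is unrelated to the displayed entity in the closure.
"Related" means: equal; an entailed part or subclass (in either direction
of specialisation, so a knee scene admits the patella and a left/right
specialisation of a knee part); or, for scenes displaying a function, an
entailed contributor/realiser. This is deliberately a heuristic whole-scene
sanity check, not a logical entailment check.

## Fixture and synthetic data

The packaged lower-limb fixture (`lower_limb_fixture()`) contains 76
asserted triples around the knee: the worked flexor/extensor inference
premises, the tendon-insertion example with its tibia partonomy, the
knee-joint subtree with its laterality expansion, and a four-object 3D leg
scene. Every triple carries a provenance tag (`core` for the canonical
example statements, `connective` for documented glue with a justification
note, `laterality` for generated triples), so tests can distinguish curated
content from scaffolding.

`generate_synthetic_ontology()` emulates the *shape* of such a knowledge
base for property-based testing: a subclass tree of configurable depth and
branching, a function forest, and cross edges (`PartOf`, `InsertOn`,
`hasFunction`, `contributesTo`) sampled at stated per-node probabilities,
with `PartOf` always pointing to lower-numbered classes so the partonomy is
acyclic by construction. It is fully reproducible from its seed and does
**not** attempt statistical fidelity to any real ontology's size or degree
distribution; production-scale ontologies (tens of thousands of classes)
are out of scope for this in-memory engine.

## Numerical and design notes

- All joins and closures are exact set operations on strings; the only
  numerics are scene placement matrices, serialised with 15 significant
  digits so manifest round trips preserve values.
- Relation names are canonicalised to `leftSubClassOf`, `rightSubClassOf`
  and `contributesTo` (lower camel case for relations, class-style case for
  classes).
- Problem sizes exercised by the test suite: fixtures of ~80–120 triples,
  synthetic stores up to 150 asserted triples saturating to a few hundred,
  with oracle cross-checks over ~250 random stores per run. Saturating the
  fixture takes well under a second; the full suite runs in a few minutes
  on one CPU.
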