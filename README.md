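# anatkb

A deductive RDF-style triple store for anatomical knowledge bases, written
in R. It links three taxonomies — anatomical entities (a subclass hierarchy
and a partonomy with attachment sites), anatomical functions, and 3D scene
objects backed by mesh files — and closes them under a small set of safe
Datalog rules so that queries see entailed facts, not just asserted ones.

The scientific problem it addresses: anatomical knowledge is naturally
stated as a few thousand atomic facts ("the sartorius contributes to knee
flexion", "knee flexion is involved in movement of the knee", "the distal
tendon of the right sartorius inserts on the medial part of the proximal
epiphysis of the right tibia"), but the questions people ask of it — *which
muscles contribute to movement of the knee? on which bones do the tendons
of the sartorius insert?* — require composing those facts along
transitivity, specialisation and cross-relation rules. `anatkb` implements
that composition as forward-chaining saturation to the least fixpoint, with
every derived fact explainable back to asserted premises, and wires the
result into query-driven selection and validity checking of 3D scenes.

## What the package provides

- **Triple store** (`triple_store`, `add_triples`, `match_triples`):
  an indexed in-memory store with set semantics; pattern matching allows
  variables (`?x`) in any position, including the predicate.
- **RDF I/O** (`read_rdf`, `write_rdf`, `parse_rdf`, `serialize_rdf`):
  N-Triples and a Turtle subset (prefixed names, `@prefix`, comments),
  with deterministic sorted serialisation — equal stores give
  byte-identical documents.
- **Rule engine** (`rule`, `parse_rules`, `check_safety`, `saturate`,
  `explain`): safe Datalog rules written as
  `R2: IF (?a mcf:PartOf ?c) AND (?c mcf:PartOf ?b) THEN (?a mcf:PartOf ?b)`,
  applied by semi-naive evaluation until no new fact is derivable.
  Safety (every conclusion variable bound in the conditions) guarantees
  termination. With `log_derivations = TRUE`, `explain()` returns the full
  derivation tree of any entailed fact.
- **Anatomy vocabulary and core rules** (`mcf_vocabulary`,
  `default_ruleset`): 17 relations, 5 classes, and the 11 core rules
  (transitivity of subclass/part-of/involvement, laterality and
  whole-organ-function specialisation, and cross-relation composition such
  as InsertOn∘PartOf). An optional 12th rule colours bone-describing scene
  objects yellow.
- **Laterality expansion** (`expand_laterality`): generates `Left_X` /
  `Right_X` specialisations of a taxonomy subtree, linked by
  `leftSubClassOf` / `rightSubClassOf` and replicating the subtree-internal
  edges on each side.
- **Queries** (`parse_query`, `evaluate_query`): a SELECT/WHERE basic graph
  pattern subset, evaluated by natural join with deterministic, sorted,
  duplicate-free answers.
- **Constraints** (`parse_constraints`, `validate_model`): existential
  requirements such as "every synovial joint has an articular capsule as a
  part", reported per offending subject.
- **3D scene linkage** (`scene_manifest`, `ingest_scene`, `select_objects`,
  `check_scene_validity`): JSON scene manifests, query-driven object
  selection with highlight colours, and anatomical validity checking of a
  scene's contents against what it displays.
- **Fixtures** (`lower_limb_fixture`, `generate_synthetic_ontology`): a
  curated, provenance-tagged lower-limb knowledge base with a 3D leg scene,
  and a seeded synthetic ontology generator for property-based testing.
- **CLI** (`run_cli`, installed script `scripts/anatkb`): subcommands
  `fixture`, `synth`, `saturate`, `laterality`, `query`, `validate`,
  `scene-select`; exit status 0 on success, 1 on validation violations,
  2 on usage errors.

## Worked example

```r
library(anatkb)

fx <- lower_limb_fixture()          # 76 asserted triples + a 3D leg scene
closed <- saturate(fx$store, default_ruleset(), log_derivations = TRUE)
saturation_report(closed)
#> $rounds
#> [1] 3
#> $inferred
#> [1] 43
#> $per_rule
#>  R1  R2  R3  R4  R5  R6  R7  R8  R9 R10 R11
#>  18   2   0   6   5   3   0   0   0   7   2

# on which bones do the tendons of the sartorius insert?
ans <- evaluate_query(tendon_insertion_query(), closed)
compact_iri(ans$bone)
#> [1] "mcf:Medial_part_of_proximal_epiphysis_of_right_tibia"
#> [2] "mcf:Proximal_epiphysis_of_right_tibia"
#> [3] "mcf:Right_tibia"

# highlight the matching objects of the 3D leg scene
select_objects(closed, "mcf:id", tendon_insertion_query())
#> <selection_set> scene mcf:id - 1 object(s) selected
#>   mcf:id4 [yellow]

# why does the sartorius contribute to movement of the knee?
explain(closed, "mcf:Sartorius", "mcf:contributesTo", "mcf:Movement_of_knee")
#> mcf:Sartorius mcf:contributesTo mcf:Movement_of_knee   [R10]
#>   mcf:Sartorius mcf:contributesTo mcf:Knee_flexion   [asserted]
#>   mcf:Knee_flexion mcf:IsInvolvedIn mcf:Movement_of_knee   [asserted]
```

The same workflow from the command line:

```sh
anatkb fixture --out fixture.nt --out-scene scene.json
anatkb saturate --triples fixture.nt --out closed.nt
# tendon_insertion.rq ships in the package's extdata directory
anatkb query --triples fixture.nt --query tendon_insertion.rq --out answers.tsv
```

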