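Package: anatkb
Title: Deductive Triple Store and Query Engine for Anatomical Knowledge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deductive RDF-style triple store for anatomical knowledge
    bases that link three taxonomies: anatomical entities (a partonomy and
    subclass hierarchy with attachment sites), anatomical functions, and 3D
    scene objects backed by mesh files. Provides N-Triples and Turtle-subset
    readers and writers, a safe-rule (Datalog) forward-chaining engine with
    semi-naive saturation to the least fixpoint, the core anatomy rule set
    (transitivity of subclass/part-of/involved-in, laterality and function
    specialisations, and cross-relation composition rules), left/right
    laterality expansion of taxonomy subtrees, conjunctive SELECT queries
    with variables in any triple position, existential constraint checking,
    and query-driven selection, colouring and validity checking of 3D scene
    objects. Ships a curated lower-limb fixture and a seeded synthetic
    ontology generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
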