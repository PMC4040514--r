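leg_scene_store <- function() {
  fixture_closed()
}

test_that("scene ingestion emits the canonical leg-scene triples", {
  fx <- fixture_cached()
  tr <- suppressWarnings(ingest_scene(fx$scene))
  st <- triple_store(tr)
  expect_true(has_triple(st, "mcf:id", "rdf:type", "mcf:3D-scene"))
  expect_true(has_triple(st, "mcf:id", "mcf:Displays", "mcf:Leg"))
  expect_true(has_triple(st, "mcf:id", "mcf:Contains", "mcf:id1"))
  expect_true(has_triple(st, "mcf:id1", "rdf:type", "mcf:3D-object"))
  expect_true(has_triple(st, "mcf:id1", "mcf:Describes", "mcf:Left_sartorius"))
  expect_true(has_triple(st, "mcf:id1", "mcf:hasMesh",
                         lit("..\\geometries\\l_sartorius.obj")))
})

test_that("manifest invariants are enforced; empty scenes warn", {
  expect_error(scene_manifest("mcf:s", "mcf:Leg", objects = list(
    list(id = "mcf:o1", describes = "mcf:A", mesh = "a.obj"),
    list(id = "mcf:o1", describes = "mcf:B", mesh = "b.obj"))),
    "duplicate")
  expect_error(scene_manifest("mcf:s", "mcf:Leg", objects = list(
    list(id = "mcf:o1", mesh = "a.obj"))), "describes")
  expect_error(scene_manifest("mcf:s", "mcf:Leg", objects = list(
    list(id = "mcf:o1", describes = "mcf:A", mesh = ""))), "mesh")

  empty <- scene_manifest("mcf:s", "mcf:Knee")
  expect_warning(tr <- ingest_scene(empty), "no objects")
  expect_equal(nrow(tr), 2L)
  expect_setequal(compact_iri(tr$p), c("rdf:type", "mcf:Displays"))
})

test_that("ingest and extract round-trip random scenes", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(0:5, 1)
    objects <- lapply(seq_len(n), function(k) {
      ob <- list(id = sprintf("mcf:obj%d", k),
                 describes = sprintf("mcf:Entity_%d", sample(20, 1)),
                 mesh = sprintf("meshes/m%d.obj", k))
      if (runif(1) < 0.5) ob$texture <- sprintf("tex/t%d.jpg", k)
      if (runif(1) < 0.5) ob$colour <- sample(c("yellow", "red", "bone"), 1)
      if (runif(1) < 0.5) ob$position <- round(runif(16, -10, 10), 3)
      ob
    })
    mf <- scene_manifest(sprintf("mcf:scene%d", i), "mcf:Leg", objects)
    st <- triple_store(suppressWarnings(ingest_scene(mf)))
    back <- extract_scene(st, mf$scene_id)
    expect_equal(back$scene_id, mf$scene_id)
    expect_equal(back$displays, mf$displays)
    got <- back$objects[order(vapply(back$objects, `[[`, character(1), "id"))]
    want <- mf$objects[order(vapply(mf$objects, `[[`, character(1), "id"))]
    expect_equal(got, want, info = paste("scene", i))
  }
})

test_that("scene manifests read and write as JSON", {
  fx <- fixture_cached()
  path <- withr::local_tempfile(fileext = ".json")
  write_scene(fx$scene, path)
  back <- read_scene(path)
  expect_equal(back, fx$scene)
})

test_that("selecting the left sartorius picks exactly its object", {
  closed <- leg_scene_store()
  sel <- select_objects(closed, "mcf:id", "mcf:Left_sartorius")
  expect_equal(compact_iri(sel$selected), "mcf:id1")
  expect_equal(unname(sel$colour), "yellow")

  # a target described by no object selects nothing
  sel <- select_objects(closed, "mcf:id", "mcf:Patella")
  expect_length(sel$selected, 0L)

  expect_error(select_objects(closed, "mcf:nosuch", "mcf:Patella"),
               "unknown scene")
})

test_that("selecting a generic class follows the entailed subclass closure", {
  closed <- leg_scene_store()
  # Muscle selects all three muscle objects via leftSubClassOf -> subClassOf
  sel <- select_objects(closed, "mcf:id", "mcf:Muscle")
  expect_setequal(compact_iri(sel$selected), c("mcf:id1", "mcf:id2", "mcf:id3"))
  # Bone selects the tibia object
  sel <- select_objects(closed, "mcf:id", "mcf:Bone")
  expect_equal(compact_iri(sel$selected), "mcf:id4")

  # equals brute force: reachability over asserted subclass-ish edges
  fx <- fixture_cached()
  v <- mcf_vocabulary()$relations
  edges <- fx$store$facts[fx$store$facts$p %in%
                            v[c("subClassOf", "leftSubClassOf",
                                "rightSubClassOf")], , drop = FALSE]
  tc <- oracle_transitive_closure(edges$s, edges$o)
  for (target in expand_iri(c("mcf:Muscle", "mcf:Bone", "mcf:Left_sartorius"))) {
    desc <- match_triples(closed, "?o", v[["Describes"]], "?e")
    want <- desc$s[desc$o == target |
                     paste(desc$o, target) %in% paste(tc$from, tc$to)]
    sel <- select_objects(closed, "mcf:id", target)
    expect_setequal(sel$selected, unique(want))
  }
})

test_that("query-driven selection highlights the answer bones", {
  closed <- leg_scene_store()
  sel <- select_objects(closed, "mcf:id", tendon_insertion_query())
  expect_equal(compact_iri(sel$selected), "mcf:id4")
  expect_equal(sel$colour[[expand_iri("mcf:id4")]], "yellow")
  sel2 <- select_objects(closed, "mcf:id", tendon_insertion_query(),
                         colour = "red")
  expect_equal(unname(sel2$colour), "red")
})

test_that("selections are monotone and stay within the scene", {
  closed <- leg_scene_store()
  ids <- anatkb:::scene_object_ids(closed, expand_iri("mcf:id"))
  for (target in c("mcf:Muscle", "mcf:Bone", "mcf:Leg")) {
    sel <- select_objects(closed, "mcf:id", target)
    expect_true(all(sel$selected %in% ids))
    # enlarging the closure never shrinks the selection
    bigger <- add_triples(closed, "mcf:Extra", "rdfs:subClassOf", target)
    bigger <- add_triples(bigger, "mcf:id1", "mcf:Describes", "mcf:Extra")
    sel2 <- select_objects(bigger, "mcf:id", target)
    expect_true(all(sel$selected %in% sel2$selected))
  }
})

test_that("the bone-colour convention touches only bone objects", {
  closed <- leg_scene_store()
  coloured <- apply_colour_rules(closed)
  expect_true(has_triple(coloured, "mcf:id4", "mcf:hasColour", lit("yellow")))
  for (muscle_obj in c("mcf:id1", "mcf:id2", "mcf:id3")) {
    expect_false(has_triple(coloured, muscle_obj, "mcf:hasColour",
                            lit("yellow")))
  }
  # idempotent: a second application adds nothing
  again <- apply_colour_rules(coloured)
  expect_equal(n_triples(again), n_triples(coloured))
  # matches saturation with the colour rule included
  expect_true(same_fact_set(coloured$facts, fixture_closed(colour = TRUE)$facts))
})

test_that("scene validity accepts the leg scene and flags intruders", {
  closed <- leg_scene_store()
  expect_true(check_scene_validity(closed, "mcf:id")$valid)

  # a knee scene containing an ear object is invalid
  st <- fixture_cached()$store
  st <- add_triples(st,
                    c("mcf:kneescene", "mcf:kneescene", "mcf:kneescene",
                      "mcf:earobj", "mcf:earobj", "mcf:patobj", "mcf:patobj"),
                    c("rdf:type", "mcf:Displays", "mcf:Contains",
                      "rdf:type", "mcf:Describes", "rdf:type", "mcf:Describes"),
                    c("mcf:3D-scene", "mcf:Knee", "mcf:earobj",
                      "mcf:3D-object", "mcf:Ear_canal",
                      "mcf:3D-object", "mcf:Patella"))
  st <- add_triples(st, "mcf:kneescene", "mcf:Contains", "mcf:patobj")
  closed2 <- saturate(st, default_ruleset())
  rep <- check_scene_validity(closed2, "mcf:kneescene")
  expect_false(rep$valid)
  expect_equal(nrow(rep$violations), 1L)
  expect_match(rep$violations$subject, "earobj")
  expect_error(check_scene_validity(closed2, "mcf:ghost"), "unknown scene")
})

test_that("scene validity equals a brute-force relatedness check", {
  closed <- leg_scene_store()
  v <- mcf_vocabulary()$relations
  ids <- anatkb:::scene_object_ids(closed, expand_iri("mcf:id"))
  d <- match_triples(closed, expand_iri("mcf:id"), v[["Displays"]], "?d")$o
  fk <- key3(closed$facts)
  related <- function(e) {
    if (e == d) return(TRUE)
    pairs <- c(paste(e, v[["PartOf"]], d, sep = "\r"),
               paste(e, v[["subClassOf"]], d, sep = "\r"),
               paste(d, v[["subClassOf"]], e, sep = "\r"),
               paste(e, v[["contributesTo"]], d, sep = "\r"),
               paste(e, v[["hasFunction"]], d, sep = "\r"))
    if (any(pairs %in% fk)) return(TRUE)
    sup <- closed$facts$o[closed$facts$s == e &
                            closed$facts$p == v[["subClassOf"]]]
    any(paste(sup, v[["PartOf"]], d, sep = "\r") %in% fk)
  }
  rep <- check_scene_validity(closed, "mcf:id")
  flagged <- rep$violations$subject
  for (oid in ids) {
    e <- match_triples(closed, oid, v[["Describes"]], "?e")$o
    expect_equal(compact_iri(oid, closed$prefixes) %in% flagged, !related(e),
                 info = oid)
  }
})

test_that("missing mesh files are reported by path", {
  dir <- withr::local_tempdir()
  real <- file.path(dir, "femur.obj")
  writeLines("v 0 0 0", real)
  mf <- scene_manifest("mcf:s", "mcf:Leg", list(
    list(id = "mcf:o1", describes = "mcf:Femur", mesh = real),
    list(id = "mcf:o2", describes = "mcf:Tibia",
         mesh = file.path(dir, "absent.obj"))))
  expect_equal(missing_meshes(mf), file.path(dir, "absent.obj"))
})
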