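# Curated lower-limb fixture --------------------------------------------------
#
# A small knowledge base around the knee and the proximal lower limb that
# exercises every relation of the vocabulary: the knee-joint subclass
# subtree with left/right laterality, a partonomy down to the epiphyses of
# the tibia, tendon insertion sites, the function taxonomy (knee flexion /
# extension feeding into movement of the knee), and a 3D leg scene whose
# objects describe the muscles and the right tibia.
#
# Every triple carries a provenance tag in the side table:
#   "core"       - the canonical example statements the fixture is built
#                  around (worked inference premises, the leg scene block,
#                  the patella block, ...)
#   "connective" - minimal glue added so that the worked inferences and the
#                  packaged tendon-insertion query are executable (each row
#                  carries a note saying why it is needed)
#   "laterality" - generated by expand_laterality() on the knee-joint
#                  subtree

fixture_mesh <- function(name) paste0("..\\geometries\\", name, ".obj")

fixture_rows <- function() {
  core <- function(s, p, o) data.frame(s = s, p = p, o = o, tag = "core",
                                       note = "", stringsAsFactors = FALSE)
  conn <- function(s, p, o, note) data.frame(s = s, p = p, o = o,
                                             tag = "connective", note = note,
                                             stringsAsFactors = FALSE)
  rbind(
    # cross-ontology correspondence and partonomy / insertion examples
    core("mcf:Femur", "owl:sameAs", "fma:Femur"),
    core("mcf:Joint", "mcf:PartOf", "mcf:Articular_System"),
    core("mcf:Distal_Tendon_Of_Right_Sartorius", "mcf:InsertOn",
         "mcf:Medial_part_of_proximal_epiphysis_of_right_tibia"),
    # function taxonomy examples
    core("mcf:Extension_Of_The_Knee", "rdfs:subClassOf", "mcf:Simple_Movement"),
    core("mcf:Eversion_Of_The_Foot", "mcf:IsInvolvedIn",
         "mcf:Mobility_Of_Ankle_Joints"),
    core("mcf:Knee", "mcf:hasFunction", "mcf:Knee_Movement"),
    core("mcf:Joint_Cartilage", "mcf:hasFunction",
         "mcf:Ensure_Sliding_Motion_Of_Articular_Surface"),
    core("mcf:Joint_Cartilage", "mcf:hasFunction",
         "mcf:Ensure_Transmission_And_Amortization_Of_Charges"),
    core("mcf:Toe", "mcf:contributesTo", "mcf:Body_Stability"),
    # patella block (scan instance u plus domain knowledge about patella)
    core("mcf:u", "rdf:type", "mcf:Patella"),
    core("mcf:Patella", "rdfs:subClassOf", "mcf:CircularTriangularBone"),
    core("mcf:Patella", "mcf:PartOf", "mcf:Knee"),
    # worked-example premises: flexors and extensors of the knee
    core("mcf:Sartorius", "mcf:contributesTo", "mcf:Knee_flexion"),
    core("mcf:Biceps_femoris", "mcf:contributesTo", "mcf:Knee_flexion"),
    core("mcf:Knee_flexion", "mcf:IsInvolvedIn", "mcf:Movement_of_knee"),
    core("mcf:Tensor_fascia_lata", "mcf:contributesTo", "mcf:Knee_extension"),
    core("mcf:Rectus_femoris", "mcf:contributesTo", "mcf:Knee_extension"),
    core("mcf:Vastus_lateralis", "mcf:contributesTo", "mcf:Knee_extension"),
    core("mcf:Vastus_medialis", "mcf:contributesTo", "mcf:Knee_extension"),
    core("mcf:Vastus_intermedius", "mcf:contributesTo", "mcf:Knee_extension"),
    core("mcf:Knee_extension", "mcf:IsInvolvedIn", "mcf:Movement_of_knee"),
    # knee-joint subclass subtree (roots the laterality expansion)
    conn("mcf:Femoropatellar_joint", "rdfs:subClassOf", "mcf:knee_joint",
         "member of the knee-joint subtree used by the laterality expansion"),
    conn("mcf:Femorotibial_joint", "rdfs:subClassOf", "mcf:knee_joint",
         "member of the knee-joint subtree used by the laterality expansion"),
    conn("mcf:knee_joint", "rdfs:subClassOf", "mcf:Joint",
         "anchors the knee-joint subtree in the joint taxonomy"),
    # muscle taxonomy and left/right specialisations used by the leg scene
    conn("mcf:Sartorius", "rdfs:subClassOf", "mcf:Muscle",
         "muscle taxonomy for the leg scene"),
    conn("mcf:Biceps_femoris", "rdfs:subClassOf", "mcf:Muscle",
         "muscle taxonomy for the leg scene"),
    conn("mcf:Semimembranosus", "rdfs:subClassOf", "mcf:Muscle",
         "muscle taxonomy for the leg scene"),
    conn("mcf:Tensor_fascia_lata", "rdfs:subClassOf", "mcf:Muscle",
         "extensor muscle taxonomy"),
    conn("mcf:Rectus_femoris", "rdfs:subClassOf", "mcf:Muscle",
         "extensor muscle taxonomy"),
    conn("mcf:Vastus_lateralis", "rdfs:subClassOf", "mcf:Muscle",
         "extensor muscle taxonomy"),
    conn("mcf:Vastus_medialis", "rdfs:subClassOf", "mcf:Muscle",
         "extensor muscle taxonomy"),
    conn("mcf:Vastus_intermedius", "rdfs:subClassOf", "mcf:Muscle",
         "extensor muscle taxonomy"),
    conn("mcf:Left_sartorius", "mcf:leftSubClassOf", "mcf:Sartorius",
         "left specialisation described by scene object id1"),
    conn("mcf:Right_sartorius", "mcf:rightSubClassOf", "mcf:Sartorius",
         "right specialisation carrying the distal tendon"),
    conn("mcf:Left_bicepsfemoris", "mcf:leftSubClassOf", "mcf:Biceps_femoris",
         "left specialisation described by scene object id2"),
    conn("mcf:Left_semimembranosus", "mcf:leftSubClassOf",
         "mcf:Semimembranosus",
         "left specialisation described by scene object id3"),
    # bones
    conn("mcf:Tibia", "rdfs:subClassOf", "mcf:Bone",
         "bone taxonomy for the insertion query and the colour rule"),
    conn("mcf:Right_tibia", "mcf:rightSubClassOf", "mcf:Tibia",
         "right specialisation carrying the insertion partonomy"),
    conn("mcf:CircularTriangularBone", "rdfs:subClassOf", "mcf:Bone",
         "anchors the patella in the bone taxonomy"),
    # tendon taxonomy and partonomy
    conn("mcf:Distal_Tendon_Of_Right_Sartorius", "rdfs:subClassOf",
         "mcf:Tendon",
         "lets the tendon-insertion query restrict to tendons"),
    conn("mcf:Distal_Tendon_Of_Right_Sartorius", "mcf:PartOf",
         "mcf:Right_sartorius",
         "the distal tendon is a part of the right sartorius"),
    conn("mcf:Medial_part_of_proximal_epiphysis_of_right_tibia", "mcf:PartOf",
         "mcf:Proximal_epiphysis_of_right_tibia",
         "tibia partonomy: insertion site up to the whole bone"),
    conn("mcf:Proximal_epiphysis_of_right_tibia", "mcf:PartOf",
         "mcf:Right_tibia",
         "tibia partonomy: insertion site up to the whole bone"),
    # partonomy of the leg (scene validity)
    conn("mcf:Sartorius", "mcf:PartOf", "mcf:Leg",
         "leg partonomy: scene objects must relate to the displayed leg"),
    conn("mcf:Biceps_femoris", "mcf:PartOf", "mcf:Leg",
         "leg partonomy: scene objects must relate to the displayed leg"),
    conn("mcf:Semimembranosus", "mcf:PartOf", "mcf:Leg",
         "leg partonomy: scene objects must relate to the displayed leg"),
    conn("mcf:Tibia", "mcf:PartOf", "mcf:Leg",
         "leg partonomy: scene objects must relate to the displayed leg"),
    conn("mcf:Knee", "mcf:PartOf", "mcf:Leg",
         "places the knee inside the leg partonomy")
  )
}

fixture_scene <- function(prefixes = default_prefixes()) {
  scene_manifest(
    scene_id = "mcf:id",
    displays = "mcf:Leg",
    objects = list(
      list(id = "mcf:id1", describes = "mcf:Left_sartorius",
           mesh = fixture_mesh("l_sartorius")),
      list(id = "mcf:id2", describes = "mcf:Left_bicepsfemoris",
           mesh = fixture_mesh("l_bicepsfemoris")),
      list(id = "mcf:id3", describes = "mcf:Left_semimembranosus",
           mesh = fixture_mesh("l_semimembranosus")),
      list(id = "mcf:id4", describes = "mcf:Right_tibia",
           mesh = fixture_mesh("r_tibia"))
    ),
    prefixes = prefixes
  )
}

#' The packaged lower-limb fixture
#'
#' Builds a deterministic knowledge base around the knee and proximal lower
#' limb, together with a 3D leg scene manifest (three muscles and the right
#' tibia) and a provenance side table tagging each triple as `"core"` (the
#' canonical example statements), `"connective"` (documented glue making the
#' worked inferences and the packaged tendon-insertion query executable;
#' this includes the fourth, bone-describing scene object), or
#' `"laterality"` (generated by [expand_laterality()] on the knee-joint
#' subtree when `lateralise = TRUE`).
#'
#' Two consecutive builds are identical.
#'
#' @param lateralise Apply the laterality expansion to the knee-joint
#'   subtree? Use `FALSE` to obtain the pre-expansion store (for instance to
#'   run [expand_laterality()] yourself).
#' @param prefixes Prefix table.
#' @return List with `store` (a [triple_store()]), `scene` (a
#'   [scene_manifest()]) and `provenance` (data.frame with columns `s`, `p`,
#'   `o`, `tag`, `note`; terms fully expanded).
#' @export
lower_limb_fixture <- function(lateralise = TRUE,
                               prefixes = default_prefixes()) {
  rows <- fixture_rows()
  scene <- fixture_scene(prefixes)
  scene_triples <- ingest_scene(scene)
  # the id3 mesh assignment and the bone object id4 are connective; the rest
  # of the scene block is core
  scene_conn <- scene_triples$s == expand_iri("mcf:id4", prefixes) |
    scene_triples$o == expand_iri("mcf:id4", prefixes) |
    (scene_triples$s == expand_iri("mcf:id3", prefixes) &
       scene_triples$p == mcf_vocabulary()$relations[["hasMesh"]])
  scene_rows <- data.frame(
    s = scene_triples$s, p = scene_triples$p, o = scene_triples$o,
    tag = ifelse(scene_conn, "connective", "core"),
    note = ifelse(scene_conn,
                  "bone scene object / mesh assignment completing the scene",
                  ""),
    stringsAsFactors = FALSE)
  prov <- rbind(
    data.frame(s = expand_iri(rows$s, prefixes),
               p = expand_iri(rows$p, prefixes),
               o = expand_iri(rows$o, prefixes),
               tag = rows$tag, note = rows$note, stringsAsFactors = FALSE),
    scene_rows)
  store <- triple_store(prov[, c("s", "p", "o")], prefixes = prefixes)
  if (lateralise) {
    before <- fact_key(store$facts$s, store$facts$p, store$facts$o)
    store <- expand_laterality(store, "mcf:knee_joint")
    f <- store$facts
    new <- !(fact_key(f$s, f$p, f$o) %in% before)
    if (any(new)) {
      prov <- rbind(prov, data.frame(
        s = f$s[new], p = f$p[new], o = f$o[new], tag = "laterality",
        note = "generated by expand_laterality on the knee-joint subtree",
        stringsAsFactors = FALSE))
    }
  }
  list(store = store, scene = scene, provenance = prov)
}

#' The packaged tendon-insertion query
#'
#' A reconstruction of the worked query "on which bones do the tendons of
#' the sartorius insert?": find every tendon that is part of a sartorius
#' specialisation and return its (entailed) insertion sites. On the
#' saturated fixture the answers include the asserted medial part of the
#' proximal epiphysis of the right tibia and - through the
#' insertion/part-of composition rule - the whole right tibia.
#'
#' @param prefixes Prefix table.
#' @return A [kb_query()] with four patterns.
#' @export
tendon_insertion_query <- function(prefixes = default_prefixes()) {
  read_query(system.file("extdata", "tendon_insertion.rq",
                         package = "anatkb", mustWork = TRUE),
             prefixes = prefixes)
}
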