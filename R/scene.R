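# 3D scene linkage ------------------------------------------------------------
#
# A scene manifest is a lightweight JSON document describing one 3D scene:
#   { "scene_id": "...", "displays": "...",
#     "objects": [ {"id","describes","mesh","texture","colour","position"} ] }
# Mesh/texture files are referenced by path only; geometry is never parsed.
# Positions are row-major 4x4 matrices, stored in the knowledge base as a
# literal of 16 whitespace-separated numbers.

#' Construct a scene manifest
#'
#' @param scene_id Scene IRI (prefixed name allowed).
#' @param displays IRI of the anatomical entity (or function) the scene
#'   displays.
#' @param objects List of object descriptors; each a list with `id` and
#'   `describes` (IRIs), `mesh` (non-empty path), and optional `texture`,
#'   `colour` (plain text) and `position` (16 numbers, row-major 4x4).
#' @param prefixes Prefix table.
#' @return Object of class `scene_manifest`. Duplicate object ids and
#'   objects lacking a `describes` target or mesh path are rejected.
#' @export
scene_manifest <- function(scene_id, displays, objects = list(),
                           prefixes = default_prefixes()) {
  scene_id <- expand_iri(scene_id, prefixes)
  displays <- expand_iri(displays, prefixes)
  objects <- lapply(objects, function(ob) {
    if (is.null(ob$id) || !nzchar(ob$id)) {
      stop("scene object without id", call. = FALSE)
    }
    if (is.null(ob$describes) || !nzchar(ob$describes)) {
      stop("scene object '", ob$id, "' has no describes target", call. = FALSE)
    }
    if (is.null(ob$mesh) || !nzchar(ob$mesh)) {
      stop("scene object '", ob$id, "' has an empty mesh path", call. = FALSE)
    }
    if (!is.null(ob$position) && length(ob$position) != 16L) {
      stop("scene object '", ob$id, "' position must have 16 numbers",
           call. = FALSE)
    }
    ob$id <- expand_iri(ob$id, prefixes)
    ob$describes <- expand_iri(ob$describes, prefixes)
    fields <- c("id", "describes", "mesh", "texture", "colour", "position")
    ob <- ob[fields]
    names(ob) <- fields
    ob[!vapply(ob, is.null, logical(1))]
  })
  ids <- vapply(objects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate object id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(scene_id = scene_id, displays = displays, objects = objects,
                 prefixes = prefixes),
            class = "scene_manifest")
}

#' Read / write scene manifests (JSON)
#'
#' @param path File path.
#' @param prefixes Prefix table.
#' @param manifest A [scene_manifest()].
#' @return `read_scene()` returns a [scene_manifest()]; `write_scene()`
#'   returns `path` invisibly.
#' @export
read_scene <- function(path, prefixes = default_prefixes()) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  objects <- lapply(j$objects, function(ob) {
    if (!is.null(ob$position)) ob$position <- as.numeric(unlist(ob$position))
    ob
  })
  scene_manifest(j$scene_id, j$displays, objects, prefixes)
}

#' @rdname read_scene
#' @export
write_scene <- function(manifest, path) {
  j <- list(scene_id = compact_iri(manifest$scene_id, manifest$prefixes),
            displays = compact_iri(manifest$displays, manifest$prefixes),
            objects = lapply(manifest$objects, function(ob) {
              ob$id <- compact_iri(ob$id, manifest$prefixes)
              ob$describes <- compact_iri(ob$describes, manifest$prefixes)
              ob[!vapply(ob, is.null, logical(1))]
            }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Paths of mesh/texture files referenced by a manifest that do not exist
#'
#' File contents are never parsed; existence is the only check performed.
#'
#' @param manifest A [scene_manifest()].
#' @return Character vector of missing paths (empty when all exist).
#' @export
missing_meshes <- function(manifest) {
  paths <- unlist(lapply(manifest$objects, function(ob)
    c(ob$mesh, ob$texture)))
  paths <- paths[nzchar(paths)]
  paths[!file.exists(paths)]
}

position_literal <- function(position) {
  lit(paste(format(position, trim = TRUE, scientific = FALSE, digits = 15),
            collapse = " "))
}

#' Turn a scene manifest into triples
#'
#' Emits the scene's `rdf:type` and `Displays` triples, and per object the
#' `Contains`, `rdf:type`, `Describes`, `hasMesh` and (when present)
#' `hasTexture` / `hasColour` / `Position` triples.
#'
#' @param manifest A [scene_manifest()].
#' @return data.frame of triples (columns `s`, `p`, `o`), suitable for
#'   [add_triples()] / [triple_store()].
#' @export
ingest_scene <- function(manifest) {
  v <- mcf_vocabulary()$relations
  cls <- mcf_vocabulary()$classes
  rows <- list(data.frame(
    s = manifest$scene_id,
    p = c(v[["type"]], v[["Displays"]]),
    o = c(cls[["scene_3d"]], manifest$displays),
    stringsAsFactors = FALSE))
  if (length(manifest$objects) == 0L) {
    warning("scene '", manifest$scene_id, "' contains no objects",
            call. = FALSE)
  }
  for (ob in manifest$objects) {
    s <- c(manifest$scene_id, ob$id, ob$id, ob$id)
    p <- c(v[["Contains"]], v[["type"]], v[["Describes"]], v[["hasMesh"]])
    o <- c(ob$id, cls[["object_3d"]], ob$describes, lit(ob$mesh))
    if (!is.null(ob$texture)) {
      s <- c(s, ob$id); p <- c(p, v[["hasTexture"]]); o <- c(o, lit(ob$texture))
    }
    if (!is.null(ob$colour)) {
      s <- c(s, ob$id); p <- c(p, v[["hasColour"]]); o <- c(o, lit(ob$colour))
    }
    if (!is.null(ob$position)) {
      s <- c(s, ob$id); p <- c(p, v[["Position"]])
      o <- c(o, position_literal(ob$position))
    }
    rows[[length(rows) + 1L]] <- data.frame(s = s, p = p, o = o,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Reconstruct a scene manifest from a store
#'
#' Inverse of [ingest_scene()] for scenes previously ingested.
#'
#' @param store A [triple_store()].
#' @param scene_id Scene IRI.
#' @return A [scene_manifest()].
#' @export
extract_scene <- function(store, scene_id) {
  v <- mcf_vocabulary()$relations
  scene_id <- expand_iri(scene_id, store$prefixes)
  disp <- match_triples(store, scene_id, v[["Displays"]], "?d")
  if (nrow(disp) == 0L) {
    stop("unknown scene: ", compact_iri(scene_id, store$prefixes),
         call. = FALSE)
  }
  contained <- sort(match_triples(store, scene_id, v[["Contains"]], "?o")$o)
  objects <- lapply(contained, function(oid) {
    one <- function(pred) {
      hit <- match_triples(store, oid, v[[pred]], "?x")$o
      if (length(hit) == 0L) NULL else hit[[1L]]
    }
    pos <- one("Position")
    list(id = oid,
         describes = one("Describes"),
         mesh = term_value(one("hasMesh")),
         texture = if (!is.null(one("hasTexture"))) term_value(one("hasTexture")),
         colour = if (!is.null(one("hasColour"))) term_value(one("hasColour")),
         position = if (!is.null(pos))
           as.numeric(strsplit(term_value(pos), "\\s+")[[1]]))
  })
  scene_manifest(scene_id, disp$o[[1L]], objects, prefixes = store$prefixes)
}

scene_object_ids <- function(store, scene_id) {
  v <- mcf_vocabulary()$relations
  hits <- match_triples(store, scene_id, v[["Contains"]], "?o")
  if (nrow(hits) == 0L &&
      !has_triple(store, scene_id, v[["type"]],
                  mcf_vocabulary()$classes[["scene_3d"]])) {
    stop("unknown scene: ", compact_iri(scene_id, store$prefixes),
         call. = FALSE)
  }
  sort(hits$o)
}

#' Select scene objects by entity or by query
#'
#' Selects every object `o` of the scene whose described entity `e` matches
#' the target: when `target` is a [kb_query()], `e` must appear among the
#' query's answers (any projected column); when `target` is an entity IRI,
#' `e` must equal the target or be an entailed subclass of it, so selecting
#' a generic class (e.g. bones) selects all described subclasses, left/right
#' specialisations included once the store is saturated.
#'
#' @param store A saturated [triple_store()] with the scene ingested.
#' @param scene_id Scene IRI.
#' @param target A [kb_query()] or an entity IRI (prefixed name allowed).
#' @param colour Highlight colour for the selected objects.
#' @return Object of class `selection_set`: list with `scene_id`,
#'   `selected` (sorted object IRIs) and `colour` (named character vector
#'   per selected object).
#' @export
select_objects <- function(store, scene_id, target, colour = "yellow") {
  v <- mcf_vocabulary()$relations
  scene_id <- expand_iri(scene_id, store$prefixes)
  ids <- scene_object_ids(store, scene_id)
  desc <- match_triples(store, "?o", v[["Describes"]], "?e")
  desc <- desc[desc$s %in% ids, , drop = FALSE]
  if (inherits(target, "kb_query")) {
    ans <- evaluate_query(target, store)
    entities <- unique(unlist(ans, use.names = FALSE))
    hit <- desc$o %in% entities
  } else {
    target <- expand_iri(target, store$prefixes)
    hit <- desc$o == target |
      has_triple(store, desc$o, v[["subClassOf"]], target)
  }
  selected <- sort(unique(desc$s[hit]))
  structure(list(scene_id = scene_id, selected = selected,
                 colour = stats::setNames(rep(colour, length(selected)),
                                          selected)),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, prefixes = default_prefixes(), ...) {
  cat("<selection_set> scene", compact_iri(x$scene_id, prefixes), "-",
      length(x$selected), "object(s) selected\n")
  for (id in x$selected) {
    cat("  ", compact_iri(id, prefixes), " [", x$colour[[id]], "]\n", sep = "")
  }
  invisible(x)
}

#' Write a selection set (JSON)
#' @param selection A `selection_set` from [select_objects()].
#' @param path Output file.
#' @param prefixes Prefix table for compaction.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, prefixes = default_prefixes()) {
  j <- list(scene_id = compact_iri(selection$scene_id, prefixes),
            selected = lapply(selection$selected, function(id)
              list(id = compact_iri(id, prefixes),
                   colour = selection$colour[[id]])))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Apply the bone-colour convention to a saturated store
#'
#' Adds `hasColour "yellow"` to every 3D object whose described entity is an
#' entailed subclass of bone; other objects are untouched. Idempotent under
#' set semantics.
#'
#' @param store A saturated [triple_store()].
#' @return The store with colour triples added.
#' @export
apply_colour_rules <- function(store) {
  colour <- read_rules(system.file("extdata", "mcf_colour.rules",
                                   package = "anatkb", mustWork = TRUE))
  nf <- apply_rule(store, colour[[1L]])
  if (nrow(nf) > 0L) store <- add_triples(store, nf$s, nf$p, nf$o)
  store
}

# is entity e anatomically related to displayed entity d in the closure?
related_to_display <- function(store, e, d) {
  v <- mcf_vocabulary()$relations
  if (e == d) return(TRUE)
  if (has_triple(store, e, v[["PartOf"]], d)) return(TRUE)
  if (has_triple(store, e, v[["subClassOf"]], d)) return(TRUE)
  if (has_triple(store, d, v[["subClassOf"]], e)) return(TRUE)
  # left/right (or other) specialisation of a part: e subClassOf x, x PartOf d
  sup <- match_triples(store, e, v[["subClassOf"]], "?x")$o
  if (length(sup) > 0L && any(has_triple(store, sup, v[["PartOf"]], d))) {
    return(TRUE)
  }
  # scenes displaying a function: contribution/realisation counts as related
  if (has_triple(store, e, v[["contributesTo"]], d)) return(TRUE)
  if (has_triple(store, e, v[["hasFunction"]], d)) return(TRUE)
  FALSE
}

#' Check the anatomical validity of a scene
#'
#' Flags every contained object whose described entity is neither the
#' displayed entity nor related to it in the closure: by entailed part-of or
#' subclass links (in either direction of specialisation, so a scene
#' displaying the knee admits parts of the knee and their left/right
#' specialisations), or - for scenes displaying a function - by entailed
#' contribution/realisation links.
#'
#' @param store A saturated [triple_store()] with the scene ingested.
#' @param scene_id Scene IRI.
#' @return A `validation_report`; empty means the scene is valid.
#' @export
check_scene_validity <- function(store, scene_id) {
  v <- mcf_vocabulary()$relations
  scene_id <- expand_iri(scene_id, store$prefixes)
  ids <- scene_object_ids(store, scene_id)
  disp <- match_triples(store, scene_id, v[["Displays"]], "?d")$o
  rows <- list()
  for (oid in ids) {
    ent <- match_triples(store, oid, v[["Describes"]], "?e")$o
    for (e in ent) {
      if (!any(vapply(disp, function(d) related_to_display(store, e, d),
                      logical(1)))) {
        rows[[length(rows) + 1L]] <- data.frame(
          check = "scene-containment",
          subject = compact_iri(oid, store$prefixes),
          detail = paste0("described entity ",
                          compact_iri(e, store$prefixes),
                          " is unrelated to displayed ",
                          paste(compact_iri(disp, store$prefixes),
                                collapse = "/")),
          stringsAsFactors = FALSE)
      }
    }
  }
  validation_report(do.call(rbind, rows))
}
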