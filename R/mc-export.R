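#' Export configuration for MC input decks
#'
#' Bundles the run-level constants of a lattice transport deck: the two
#' bounding spheres enclosing the lattice (the outer one is the vacuum
#' calculation boundary), the outside universe ID, and batch settings.
#'
#' @param inner_radius_cm lattice-region sphere radius, default 750.
#' @param outer_radius_cm boundary sphere radius, default 800.
#' @param outside_id exterior universe ID, default 255.
#' @param batches number of batches, default 10.
#' @param particles particles per batch, default 8e7.
#' @return an object of class \code{export_config}.
#' @export
export_config <- function(inner_radius_cm = 750, outer_radius_cm = 800,
                          outside_id = 255L, batches = 10L,
                          particles = 8e7) {
  if (inner_radius_cm >= outer_radius_cm) {
    stop("the inner sphere must lie inside the outer boundary sphere")
  }
  structure(list(inner_radius_cm = inner_radius_cm,
                 outer_radius_cm = outer_radius_cm,
                 outside_id = as.integer(outside_id),
                 batches = as.integer(batches),
                 particles = particles), class = "export_config")
}

num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Export a materials card
#'
#' One material element per registry organ, numbered by organ ID, plus
#' air as the outside universe's material; densities in g/cm3 and
#' elemental mass fractions. Round-trips through
#' \code{\link{parse_materials}}.
#'
#' @param registry an \code{organ_registry}.
#' @param config an \code{export_config}.
#' @return an \code{xml2} document.
#' @export
export_materials <- function(registry, config = export_config()) {
  registry <- if (inherits(registry, "organ_registry") || nrow(registry) == 0) {
    registry
  } else organ_registry(registry)
  root <- xml2::xml_new_root("materials")
  add_material <- function(id, name, density, comp, weight_class = NULL) {
    if (abs(sum(comp) - 1) > 1e-6) {
      stop("mass fractions for material ", id, " do not sum to 1")
    }
    m <- xml2::xml_add_child(root, "material", id = as.character(id), name = name)
    if (!is.null(weight_class)) xml2::xml_set_attr(m, "weight_class", weight_class)
    xml2::xml_add_child(m, "density", value = num(density), units = "g/cm3")
    for (el in names(comp)) {
      xml2::xml_add_child(m, "element", name = el, fraction = num(comp[[el]]),
                          type = "wo")
    }
  }
  if (nrow(registry)) {
    for (i in seq_len(nrow(registry))) {
      add_material(registry$id[i], registry$name[i], registry$density[i],
                   organ_composition(registry, registry$id[i]),
                   registry$weight_class[i])
    }
  }
  air <- air_spec()
  add_material(config$outside_id, air$name, air$density, air$composition,
               "unscored")
  root
}

#' Parse a materials card back into a registry
#'
#' @param doc an \code{xml2} document from \code{\link{export_materials}}.
#' @return an \code{organ_registry} (the air material is dropped).
#' @export
parse_materials <- function(doc) {
  mats <- xml2::xml_find_all(doc, "//material")
  elems <- registry_elements()
  rows <- lapply(mats, function(m) {
    id <- as.integer(xml2::xml_attr(m, "id"))
    if (id == 255L) return(NULL)
    comp <- stats::setNames(rep(0, length(elems)), elems)
    for (e in xml2::xml_find_all(m, "element")) {
      comp[[xml2::xml_attr(e, "name")]] <- as.numeric(xml2::xml_attr(e, "fraction"))
    }
    cbind(data.frame(id = id, name = xml2::xml_attr(m, "name"),
                     density = as.numeric(xml2::xml_attr(
                       xml2::xml_find_first(m, "density"), "value")),
                     weight_class = xml2::xml_attr(m, "weight_class")),
          as.data.frame(as.list(comp)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no organ materials in document")
  organ_registry(do.call(rbind, rows))
}

#' Export a geometry card
#'
#' Writes the phantom as a rectangular lattice (dimensions, pitch,
#' lower-left corner from the centered physical extent, and the full
#' universe map in fill order), an outer universe for the exterior,
#' and the two bounding spheres, the outer one marked as a vacuum
#' boundary.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param config an \code{export_config}.
#' @return an \code{xml2} document.
#' @export
export_geometry <- function(phantom, config = export_config()) {
  ext <- phantom_extent(phantom)
  root <- xml2::xml_new_root("geometry")
  lat <- xml2::xml_add_child(root, "lattice", id = "1", name = "phantom",
                             type = "rectangular")
  xml2::xml_add_child(lat, "dimension", paste(phantom$dims, collapse = " "))
  xml2::xml_add_child(lat, "pitch", paste(rep(num(phantom$pitch), 3), collapse = " "))
  xml2::xml_add_child(lat, "lower_left", paste(num(ext$lower), collapse = " "))
  xml2::xml_add_child(lat, "outer", as.character(config$outside_id))
  xml2::xml_add_child(lat, "universes",
                      paste(flatten_phantom(phantom), collapse = " "))
  xml2::xml_add_child(root, "surface", id = "1", type = "sphere",
                      coeffs = paste("0 0 0", num(config$inner_radius_cm)))
  xml2::xml_add_child(root, "surface", id = "2", type = "sphere",
                      coeffs = paste("0 0 0", num(config$outer_radius_cm)),
                      boundary = "vacuum")
  xml2::xml_add_child(root, "cell", id = "1", fill = "1", region = "-1")
  xml2::xml_add_child(root, "cell", id = "2",
                      material = as.character(config$outside_id),
                      region = "1 -2")
  root
}

#' Parse a geometry card
#'
#' @param doc an \code{xml2} document from \code{\link{export_geometry}}.
#' @return list with \code{dims}, \code{pitch}, \code{lower_left},
#'   \code{universes} (integer array in lattice shape),
#'   \code{outer_universe} and the two sphere radii.
#' @export
parse_geometry <- function(doc) {
  lat <- xml2::xml_find_first(doc, "//lattice")
  dims <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(lat, "dimension"))), "\\s+")[[1]])
  pitch <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(lat, "pitch"))), "\\s+")[[1]])[1]
  ll <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(lat, "lower_left"))), "\\s+")[[1]])
  uni <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(lat, "universes"))), "\\s+")[[1]])
  radii <- vapply(xml2::xml_find_all(doc, "//surface"), function(s) {
    as.numeric(utils::tail(strsplit(xml2::xml_attr(s, "coeffs"), "\\s+")[[1]], 1))
  }, numeric(1))
  list(dims = dims, pitch = pitch, lower_left = ll,
       universes = array(uni, dim = dims),
       outer_universe = as.integer(xml2::xml_text(
         xml2::xml_find_first(lat, "outer"))),
       inner_radius_cm = min(radii), outer_radius_cm = max(radii))
}

#' Export a settings card
#'
#' Fixed-source run: monodirectional +x photon plane source with a
#' single energy line, and batch/particle counts.
#'
#' @param source a \code{plane_source}.
#' @param E photon energy, MeV.
#' @param config an \code{export_config}.
#' @return an \code{xml2} document.
#' @export
export_settings <- function(source, E, config = export_config()) {
  stopifnot(inherits(source, "plane_source"))
  root <- xml2::xml_new_root("settings")
  xml2::xml_add_child(root, "run_mode", "fixed source")
  xml2::xml_add_child(root, "batches", as.character(config$batches))
  xml2::xml_add_child(root, "particles", num(config$particles))
  src <- xml2::xml_add_child(root, "source", particle = "photon")
  sp <- xml2::xml_add_child(src, "space", type = "box")
  xml2::xml_add_child(sp, "parameters", paste(
    num(c(source$x, source$y[1], source$z[1],
          source$x, source$y[2], source$z[2])), collapse = " "))
  ang <- xml2::xml_add_child(src, "angle", type = "monodirectional")
  xml2::xml_add_child(ang, "reference_uvw", "1 0 0")
  en <- xml2::xml_add_child(src, "energy", type = "discrete")
  xml2::xml_add_child(en, "parameters", paste(num(E * 1e6), "1.0"))
  root
}

#' Parse a settings card
#'
#' @param doc an \code{xml2} document from \code{\link{export_settings}}.
#' @return list with the \code{plane_source}, \code{E_MeV},
#'   \code{batches} and \code{particles}.
#' @export
parse_settings <- function(doc) {
  par <- as.numeric(strsplit(trimws(xml2::xml_text(xml2::xml_find_first(
    doc, "//space/parameters"))), "\\s+")[[1]])
  epar <- as.numeric(strsplit(trimws(xml2::xml_text(xml2::xml_find_first(
    doc, "//energy/parameters"))), "\\s+")[[1]])
  list(source = plane_source(par[1], c(par[2], par[5]), c(par[3], par[6])),
       E_MeV = epar[1] / 1e6,
       batches = as.integer(xml2::xml_text(xml2::xml_find_first(doc, "//batches"))),
       particles = as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "//particles"))))
}

#' Export a tallies card
#'
#' Supported kinds: \code{"heating-by-universe"} (a heating tally with a
#' universe filter listing every registry organ) and \code{"mesh-flux"}
#' (a photon flux tally on a regular mesh).
#'
#' @param spec list with \code{kinds} (character vector), and depending
#'   on the kinds: \code{universes} (integer IDs) and \code{mesh} (a
#'   \code{mesh_spec}).
#' @return an \code{xml2} document.
#' @export
export_tallies <- function(spec) {
  if (is.null(spec$kinds) || !length(spec$kinds)) {
    stop("tally spec names no tally kind")
  }
  bad <- setdiff(spec$kinds, c("heating-by-universe", "mesh-flux"))
  if (length(bad)) stop("unknown tally kind(s): ", paste(bad, collapse = ", "))
  root <- xml2::xml_new_root("tallies")
  tid <- 0L
  if ("mesh-flux" %in% spec$kinds) {
    if (is.null(spec$mesh)) stop("mesh-flux tally requires a mesh_spec")
    m <- spec$mesh
    mesh <- xml2::xml_add_child(root, "mesh", id = "1")
    xml2::xml_add_child(mesh, "dimension", paste(m$dims, collapse = " "))
    xml2::xml_add_child(mesh, "lower_left", paste(num(m$lower), collapse = " "))
    xml2::xml_add_child(mesh, "upper_right", paste(num(m$upper), collapse = " "))
    tid <- tid + 1L
    t <- xml2::xml_add_child(root, "tally", id = as.character(tid))
    xml2::xml_add_child(t, "filter", type = "mesh", bins = "1")
    xml2::xml_add_child(t, "filter", type = "particle", bins = "photon")
    xml2::xml_add_child(t, "scores", "flux")
  }
  if ("heating-by-universe" %in% spec$kinds) {
    if (is.null(spec$universes) || !length(spec$universes)) {
      stop("heating-by-universe tally requires universe IDs")
    }
    tid <- tid + 1L
    t <- xml2::xml_add_child(root, "tally", id = as.character(tid))
    xml2::xml_add_child(t, "filter", type = "universe",
                        bins = paste(spec$universes, collapse = " "))
    xml2::xml_add_child(t, "scores", "heating")
  }
  root
}

#' Parse a tallies card
#'
#' @param doc an \code{xml2} document from \code{\link{export_tallies}}.
#' @return list with \code{kinds}, \code{universes}, \code{mesh}.
#' @export
parse_tallies <- function(doc) {
  kinds <- character()
  universes <- NULL
  mesh <- NULL
  uf <- xml2::xml_find_first(doc, "//filter[@type='universe']")
  if (!inherits(uf, "xml_missing")) {
    kinds <- c(kinds, "heating-by-universe")
    universes <- as.integer(strsplit(xml2::xml_attr(uf, "bins"), "\\s+")[[1]])
  }
  mn <- xml2::xml_find_first(doc, "//mesh")
  if (!inherits(mn, "xml_missing")) {
    kinds <- c(kinds, "mesh-flux")
    g <- function(tag) as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(mn, tag))), "\\s+")[[1]])
    mesh <- mesh_spec(as.integer(g("dimension")), g("lower_left"), g("upper_right"))
  }
  list(kinds = kinds, universes = universes, mesh = mesh)
}

#' Export a complete input deck
#'
#' Writes materials, geometry, settings and tallies XML files plus a
#' JSON manifest recording the configuration.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param source a \code{plane_source}.
#' @param E photon energy, MeV.
#' @param dir output directory.
#' @param config an \code{export_config}.
#' @param tally_spec tally spec for \code{\link{export_tallies}};
#'   default heating by every registry universe.
#' @return the directory, invisibly.
#' @export
export_deck <- function(phantom, source, E, dir, config = export_config(),
                        tally_spec = list(kinds = "heating-by-universe",
                                          universes = phantom$registry$id)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xml2::write_xml(export_materials(phantom$registry, config),
                  file.path(dir, "materials.xml"))
  xml2::write_xml(export_geometry(phantom, config),
                  file.path(dir, "geometry.xml"))
  xml2::write_xml(export_settings(source, E, config),
                  file.path(dir, "settings.xml"))
  xml2::write_xml(export_tallies(tally_spec),
                  file.path(dir, "tallies.xml"))
  manifest <- list(dims = phantom$dims, pitch = phantom$pitch,
                   energy_MeV = E, batches = config$batches,
                   particles = config$particles,
                   inner_radius_cm = config$inner_radius_cm,
                   outer_radius_cm = config$outer_radius_cm)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
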