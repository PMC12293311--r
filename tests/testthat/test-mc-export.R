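test_that("materials cards carry every organ plus air and round-trip", {
  reg <- default_registry()
  doc <- export_materials(reg)
  mats <- xml2::xml_find_all(doc, "//material")
  expect_length(mats, 31)  # 30 organs + air

  back <- parse_materials(doc)
  expect_equal(back$id, reg$id)
  expect_equal(back$name, reg$name)
  expect_equal(back$density, reg$density)
  expect_equal(back$weight_class, reg$weight_class)
  for (el in c("H", "O", "Ca", "I")) expect_equal(back[[el]], reg[[el]])

  # empty registry: air-only document
  empty <- reg[0, ]
  doc0 <- export_materials(empty)
  expect_length(xml2::xml_find_all(doc0, "//material"), 1)
  expect_equal(xml2::xml_attr(xml2::xml_find_first(doc0, "//material"), "id"),
               "255")
})

test_that("geometry cards encode the lattice and bounding spheres", {
  ph <- water_block(3, 4, 5, pitch = 0.2)
  doc <- export_geometry(ph)
  g <- parse_geometry(doc)
  expect_identical(g$dims, c(3L, 4L, 5L))
  expect_equal(g$pitch, 0.2)
  expect_equal(g$lower_left, -c(3, 4, 5) * 0.2 / 2)
  expect_identical(g$universes, ph$ids)
  expect_equal(g$outer_universe, 255L)
  expect_equal(g$inner_radius_cm, 750)
  expect_equal(g$outer_radius_cm, 800)

  one <- voxel_phantom(array(1L, c(1, 1, 1)), registry = water_registry())
  g1 <- parse_geometry(export_geometry(one))
  expect_identical(g1$dims, c(1L, 1L, 1L))

  # grid round-trips through the XML text for a random phantom
  set.seed(6)
  ids <- array(sample(c(1L, 255L), 24, replace = TRUE), c(2, 3, 4))
  ph2 <- voxel_phantom(ids, registry = water_registry())
  expect_identical(parse_geometry(export_geometry(ph2))$universes, ids)
})

test_that("settings cards describe the AP plane source run", {
  src <- plane_source(-45, c(-27, 27), c(-95, 95))
  doc <- export_settings(src, 0.1)
  s <- parse_settings(doc)
  expect_equal(s$source$x, -45)
  expect_equal(s$source$y, c(-27, 27))
  expect_equal(s$source$z, c(-95, 95))
  expect_equal(s$E_MeV, 0.1)
  expect_equal(s$batches, 10L)      # default batch count
  expect_equal(s$particles, 8e7)
})

test_that("tally cards cover mesh-flux and heating-by-universe kinds", {
  mesh <- mesh_spec(c(1, 1000, 1000), c(-11, -20, 0), c(-10, 20, 67))
  reg <- default_registry()
  doc <- export_tallies(list(kinds = c("mesh-flux", "heating-by-universe"),
                             mesh = mesh, universes = reg$id))
  t <- parse_tallies(doc)
  expect_setequal(t$kinds, c("mesh-flux", "heating-by-universe"))
  expect_identical(t$mesh$dims, c(1L, 1000L, 1000L))
  expect_equal(t$mesh$lower, c(-11, -20, 0))
  expect_equal(t$mesh$upper, c(-10, 20, 67))
  expect_length(t$universes, nrow(reg))  # one filter entry per organ

  expect_error(export_tallies(list()), "no tally kind")
  expect_error(export_tallies(list(kinds = "bogus")), "unknown tally kind")
})

test_that("a full deck export writes well-formed XML plus a manifest", {
  ph <- water_block(4, 4, 4)
  dir <- withr::local_tempdir()
  export_deck(ph, ap_source(ph), 0.07, dir)
  files <- c("materials.xml", "geometry.xml", "settings.xml", "tallies.xml",
             "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))
  # every file re-parses as XML / JSON
  for (f in files[1:4]) expect_s3_class(xml2::read_xml(file.path(dir, f)),
                                        "xml_document")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$energy_MeV, 0.07)
  expect_equal(unlist(man$dims), c(4L, 4L, 4L))

  # parse-back from disk reproduces the lattice
  g <- parse_geometry(xml2::read_xml(file.path(dir, "geometry.xml")))
  expect_identical(g$universes, ph$ids)
})
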