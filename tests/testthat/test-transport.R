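# analytic ray-box intersection length (slab method), independent of the
# traversal kernel
box_chord <- function(origin, direction, half) {
  d <- direction / sqrt(sum(direction^2))
  tmin <- -Inf
  tmax <- Inf
  for (i in 1:3) {
    if (abs(d[i]) < 1e-300) {
      if (origin[i] <= -half[i] || origin[i] >= half[i]) return(0)
    } else {
      t1 <- (-half[i] - origin[i]) / d[i]
      t2 <- (half[i] - origin[i]) / d[i]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - max(tmin, 0))
}

test_that("lattice traversal visits voxels with exact chords", {
  ph <- water_block(10, 4, 4, pitch = 0.5)
  tv <- siddon_traverse(ph, c(-10, 0.1, 0.1), c(1, 0, 0))
  expect_equal(nrow(tv), 10)
  expect_true(all(abs(tv$chord - 0.5) < 1e-12))
  expect_identical(tv$ix, 1:10)

  # body diagonal of a single voxel
  one <- voxel_phantom(array(1L, c(1, 1, 1)), pitch = 0.7,
                       registry = water_registry())
  tv1 <- siddon_traverse(one, c(-1, -1, -1), c(1, 1, 1))
  expect_equal(nrow(tv1), 1)
  expect_equal(tv1$chord, 0.7 * sqrt(3), tolerance = 1e-12)

  # miss
  expect_equal(nrow(siddon_traverse(ph, c(-10, 50, 0), c(1, 0, 0))), 0)
})

test_that("chord sums equal the analytic box intersection for random rays", {
  ph <- water_block(7, 9, 11, pitch = 0.4)
  half <- ph$dims * ph$pitch / 2
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    o <- runif(3, -8, 8)
    d <- rnorm(3)
    tv <- siddon_traverse(ph, o, d)
    got <- if (nrow(tv)) sum(tv$chord) else 0
    worst <- max(worst, abs(got - box_chord(o, d, half)))
  }
  expect_lt(worst, 1e-9)
})

test_that("primary transmission matches the Beer-Lambert closed form", {
  expect_equal(primary_transmission(air_block(), c(-10, 0, 0), c(1, 0, 0), 0.1),
               1.0)
  for (L in c(2, 10, 25)) {
    slab <- generate_slab_phantom(list(list(id = 1, thickness = L)),
                                  pitch = 0.5, registry = water_registry())
    tr <- primary_transmission(slab, c(-L, 0, 0), c(1, 0, 0), 0.08)
    expect_equal(tr, exp(-mu_water(0.08) * L), tolerance = 1e-12)
  }
  # monotone non-increasing in path length
  trans <- vapply(c(1, 5, 10, 20), function(L) {
    slab <- generate_slab_phantom(list(list(id = 1, thickness = L)),
                                  pitch = 0.5, registry = water_registry())
    primary_transmission(slab, c(-30, 0, 0), c(1, 0, 0), 0.1)
  }, numeric(1))
  expect_true(all(diff(trans) < 0))
})

radiograph_setup <- function(E, nx = 24, nyz = 24) {
  reg <- bone_water_registry()
  ids <- array(1L, c(nx, nyz, nyz))
  # bone cylinder along x in the middle
  yc <- axis_centers(nyz, 0.5)
  zc <- axis_centers(nyz, 0.5)
  for (iy in seq_len(nyz)) for (iz in seq_len(nyz)) {
    if (yc[iy]^2 + zc[iz]^2 <= 2^2) ids[, iy, iz] <- 2L
  }
  ph <- voxel_phantom(ids, pitch = 0.5, registry = reg)
  src <- ap_source(ph)
  ext <- phantom_extent(ph)
  mesh <- mesh_spec(c(1, nyz, nyz),
                    c(ext$upper[1], ext$lower[2], ext$lower[3]),
                    c(ext$upper[1] + 1, ext$upper[2], ext$upper[3]))
  list(rg = project_radiograph(ph, src, mesh, E), ph = ph, src = src,
       mesh = mesh)
}

test_that("radiographs attenuate dense inclusions and stay uniform in air", {
  # empty lattice: uniform unit image
  air <- air_block()
  ext <- phantom_extent(air)
  mesh <- mesh_spec(c(1, 8, 8), c(ext$upper[1], ext$lower[2], ext$lower[3]),
                    c(ext$upper[1] + 1, ext$upper[2], ext$upper[3]))
  rg0 <- project_radiograph(air, ap_source(air), mesh, 0.1)
  expect_true(all(rg0 == 1))

  s <- radiograph_setup(0.08)
  center <- s$rg[12, 12]
  edge <- s$rg[2, 2]
  expect_lt(center, edge)  # bone shadow is darker (lower flux)

  # geometry error: mesh upstream of the source
  bad <- mesh_spec(c(1, 8, 8), c(-100, -6, -6), c(-99, 6, 6))
  expect_error(project_radiograph(s$ph, s$src, bad, 0.1), "front of the source")
})

test_that("bone/soft contrast is non-increasing with energy", {
  a <- list(y = 11:14, z = 11:14)   # behind the bone cylinder
  b <- list(y = 1:3, z = 1:3)       # water background
  cons <- vapply(c(0.05, 0.07, 0.1, 0.12, 0.15), function(E) {
    michelson_contrast(radiograph_setup(E)$rg, a, b)
  }, numeric(1))
  expect_true(all(diff(cons) < 0))
})

test_that("kerma deposition matches the thin-target and closed-form limits", {
  reg <- water_registry()
  thin <- voxel_phantom(array(1L, c(1, 1, 1)), pitch = 0.01, registry = reg)
  src <- plane_source(-1, c(-0.005, 0.005), c(-0.005, 0.005))
  E <- 0.1
  tal <- deposit_kerma(thin, src, E)
  # thin limit: E * muen * dx per unit fluence; here fluence/particle = 1/area
  mu <- mu_water(E)
  muen <- muen_water(E)
  expected_exact <- E * 1e6 * (1 - exp(-mu * 0.01)) * (muen / mu) *
    (0.01^2 / src$area)
  expect_equal(unname(tal$heating_eV["1"]), expected_exact, tolerance = 1e-12)
  expect_equal(expected_exact, E * 1e6 * muen * 0.01 * 0.01^2 / src$area,
               tolerance = 1e-3)

  # vacuum: nothing deposits
  tal0 <- deposit_kerma(air_block(), plane_source(-10, c(-2, 2), c(-2, 2)), 0.1)
  expect_true(all(tal0$heating_eV == 0))
})

test_that("kerma bookkeeping conserves energy ray by ray", {
  ph <- small_body()
  tal <- deposit_kerma(ph, ap_source(ph), 0.08, detail = TRUE)
  bal <- tal$per_ray$deposited + tal$per_ray$transmitted +
    tal$per_ray$scattered_escape
  expect_lt(max(abs(bal - 0.08)), 1e-9)
})

test_that("Monte Carlo transport is reproducible and unbiased vs kerma", {
  slab <- generate_slab_phantom(list(list(id = 1, thickness = 10)),
                                pitch = 0.5, ny = 6, nz = 6,
                                registry = water_registry())
  src <- ap_source(slab)
  a <- mc_transport(slab, src, 0.1, n = 2e4, seed = 5, scatter = FALSE)
  b <- mc_transport(slab, src, 0.1, n = 2e4, seed = 5, scatter = FALSE)
  expect_identical(a$heating$heating_eV, b$heating$heating_eV)
  expect_identical(a$heating$sd_eV, b$heating$sd_eV)

  det <- deposit_kerma(slab, src, 0.1)
  z <- (a$heating$heating_eV["1"] - det$heating_eV["1"]) / a$heating$sd_eV["1"]
  expect_lt(abs(z), 3)

  expect_error(mc_transport(slab, src, 0.1, n = 0), "n must be")
})

test_that("Monte Carlo uncertainty scales as one over root n", {
  slab <- generate_slab_phantom(list(list(id = 1, thickness = 10)),
                                pitch = 0.5, ny = 6, nz = 6,
                                registry = water_registry())
  src <- ap_source(slab)
  s1 <- mc_transport(slab, src, 0.1, n = 4e4, seed = 1, scatter = FALSE,
                     batches = 400)$heating$sd_eV["1"]
  s4 <- mc_transport(slab, src, 0.1, n = 1.6e5, seed = 2, scatter = FALSE,
                     batches = 400)$heating$sd_eV["1"]
  expect_equal(unname(s4 / s1), 0.5, tolerance = 0.2)
})

test_that("scattered histories deposit more energy than primaries alone", {
  slab <- generate_slab_phantom(list(list(id = 1, thickness = 20)),
                                pitch = 0.5, ny = 8, nz = 8,
                                registry = water_registry())
  src <- ap_source(slab)
  on_ <- mc_transport(slab, src, 0.1, n = 1e4, seed = 9, scatter = TRUE)
  off <- mc_transport(slab, src, 0.1, n = 1e4, seed = 9, scatter = FALSE)
  expect_gt(sum(on_$heating$heating_eV), sum(off$heating$heating_eV))
})

test_that("radiograph export writes csv and pgm", {
  s <- radiograph_setup(0.07, nx = 8, nyz = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  pgm <- withr::local_tempfile(fileext = ".pgm")
  export_radiograph(s$rg, csv, "csv")
  export_radiograph(s$rg, pgm, "pgm")
  back <- as.matrix(read.csv(csv))
  expect_equal(as.vector(back), as.vector(unclass(s$rg)), tolerance = 1e-12)
  expect_identical(readLines(pgm, n = 1), "P2")
})
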