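#' Planar monodirectional photon source
#'
#' A rectangular plane source at fixed x, emitting monodirectional
#' photons along +x, uniform over its y-z extent. This is the standard
#' anterior-posterior (AP) broad-beam irradiation geometry when the
#' plane sits in front of the phantom.
#'
#' @param x plane position, cm.
#' @param y,z length-2 extents, cm.
#' @return an object of class \code{plane_source}.
#' @export
plane_source <- function(x, y, z) {
  stopifnot(length(y) == 2L, length(z) == 2L, y[2] > y[1], z[2] > z[1])
  structure(list(x = x, y = sort(y), z = sort(z),
                 area = diff(y) * diff(z), direction = c(1, 0, 0)),
            class = "plane_source")
}

#' AP source covering a phantom
#'
#' Convenience constructor: a plane source just upstream (-x) of the
#' phantom, spanning its full y-z cross-section.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param margin distance upstream of the lattice face, cm.
#' @return a \code{plane_source}.
#' @export
ap_source <- function(phantom, margin = 5) {
  ext <- phantom_extent(phantom)
  plane_source(x = ext$lower[1] - margin,
               y = c(ext$lower[2], ext$upper[2]),
               z = c(ext$lower[3], ext$upper[3]))
}

#' Mesh tally specification
#'
#' A regular mesh on which transmitted photon flux is scored to form a
#' radiographic projection: one slab along x and a 2D grid in the y-z
#' image plane.
#'
#' @param dims grid dimensions \code{c(nx, ny, nz)}; \code{nx} is
#'   typically 1.
#' @param lower,upper corner coordinates, cm.
#' @return an object of class \code{mesh_spec}.
#' @export
mesh_spec <- function(dims, lower, upper) {
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(lower) == 3L, length(upper) == 3L)
  if (any(upper <= lower)) stop("mesh corners must satisfy lower < upper")
  structure(list(dims = as.integer(dims), lower = as.numeric(lower),
                 upper = as.numeric(upper)), class = "mesh_spec")
}

# per-material linear coefficients (1/cm) at energy E (scalar)
mats_at_energy <- function(mats, E) {
  rng <- range(mats$grid)
  if (E < rng[1] - 1e-12 || E > rng[2] + 1e-12) {
    stop(sprintf("energy %g MeV outside table range %g-%g MeV", E, rng[1], rng[2]))
  }
  lx <- log(min(max(E, rng[1]), rng[2]))
  interp_row <- function(r) exp(stats::approx(log(mats$grid), log(r), xout = lx)$y)
  list(mu = apply(mats$mu, 1, interp_row),
       muen = apply(mats$muen, 1, interp_row))
}

# lookup tables over ID 0..255 -> mu, muen (1/cm); outside/vacuum = 0
id_lut <- function(phantom, E, mats = material_arrays(phantom$registry),
                   outside_vacuum = TRUE) {
  at <- mats_at_energy(mats, E)
  mu_lut <- numeric(256)
  muen_lut <- numeric(256)
  mu_lut[mats$ids + 1L] <- at$mu
  muen_lut[mats$ids + 1L] <- at$muen
  if (outside_vacuum) {
    mu_lut[phantom$outside_id + 1L] <- 0
    muen_lut[phantom$outside_id + 1L] <- 0
  }
  list(mu = mu_lut, muen = muen_lut)
}

#' Traverse the voxel lattice along a ray
#'
#' Computes the ordered list of voxels a ray crosses together with the
#' chord length in each (the radiological-path traversal of Siddon /
#' Amanatides-Woo). The chord lengths sum to the length of the ray's
#' intersection with the lattice box.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param origin ray origin, cm (centered frame).
#' @param direction ray direction (any non-zero vector).
#' @return data.frame with columns \code{ix}, \code{iy}, \code{iz}
#'   (1-based voxel indices) and \code{chord} (cm); zero rows if the
#'   ray misses the lattice.
#' @export
siddon_traverse <- function(phantom, origin, direction) {
  m <- .siddon_cpp(as.numeric(origin), as.numeric(direction),
                   phantom$dims, phantom$pitch)
  data.frame(ix = as.integer(m[, 1]), iy = as.integer(m[, 2]),
             iz = as.integer(m[, 3]), chord = m[, 4])
}

#' Primary beam transmission along a ray
#'
#' Beer-Lambert attenuation of the uncollided beam over the voxel
#' traversal: \code{exp(-sum(mu_voxel * chord))}.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param origin,direction the ray.
#' @param E photon energy, MeV.
#' @return transmitted fraction in (0, 1].
#' @export
primary_transmission <- function(phantom, origin, direction, E) {
  tv <- siddon_traverse(phantom, origin, direction)
  if (!nrow(tv)) return(1.0)
  lut <- id_lut(phantom, E)
  ids <- phantom$ids[cbind(tv$ix, tv$iy, tv$iz)]
  exp(-sum(lut$mu[ids + 1L] * tv$chord))
}

#' Project a radiograph through the phantom
#'
#' Casts one parallel primary ray along +x through the center of every
#' mesh cell and records the transmitted primary fluence per unit
#' incident fluence. This is the deterministic (noise-free) analog of a
#' flux mesh tally behind the phantom.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param source a \code{plane_source} upstream of the phantom.
#' @param mesh a \code{mesh_spec}; must lie downstream (+x) of the
#'   source plane.
#' @param E photon energy, MeV.
#' @return a \code{radiograph}: a \code{ny x nz} matrix of relative
#'   transmitted flux with the mesh and energy attached as attributes.
#' @export
project_radiograph <- function(phantom, source, mesh, E) {
  stopifnot(inherits(source, "plane_source"), inherits(mesh, "mesh_spec"))
  if (mesh$lower[1] < source$x) {
    stop("mesh lies in front of the source plane (geometry error)")
  }
  lut <- id_lut(phantom, E)
  d <- phantom$dims
  p <- phantom$pitch
  # path integral of mu along x for every phantom (y,z) voxel column
  mu_arr <- array(lut$mu[phantom$ids + 1L], dim = d)
  att <- apply(mu_arr, c(2, 3), sum) * p   # (ny, nz) optical depth

  ny <- mesh$dims[2]; nz <- mesh$dims[3]
  yc <- mesh$lower[2] + (seq_len(ny) - 0.5) * (mesh$upper[2] - mesh$lower[2]) / ny
  zc <- mesh$lower[3] + (seq_len(nz) - 0.5) * (mesh$upper[3] - mesh$lower[3]) / nz
  half <- d * p / 2
  iy <- floor((yc + half[2]) / p) + 1
  iz <- floor((zc + half[3]) / p) + 1
  od <- matrix(0, ny, nz)
  ok_y <- iy >= 1 & iy <= d[2]
  ok_z <- iz >= 1 & iz <= d[3]
  od[ok_y, ok_z] <- att[iy[ok_y], iz[ok_z]]
  img <- exp(-od)
  structure(img, class = c("radiograph", "matrix"),
            mesh = mesh, energy_MeV = E)
}

#' Michelson contrast between two radiograph regions
#'
#' @param rg a \code{radiograph}.
#' @param region_a,region_b lists with integer index vectors \code{y}
#'   and \code{z} selecting mesh cells.
#' @return \code{|I_a - I_b| / (I_a + I_b)} using region-mean fluxes.
#' @export
michelson_contrast <- function(rg, region_a, region_b) {
  ia <- mean(rg[region_a$y, region_a$z])
  ib <- mean(rg[region_b$y, region_b$z])
  abs(ia - ib) / (ia + ib)
}

#' Export a radiograph
#'
#' Writes the mesh-tally image as raw CSV, ASCII PGM, or PNG. Grayscale
#' exports apply logarithmic normalization so that several orders of
#' magnitude of flux remain visible.
#'
#' @param rg a \code{radiograph}.
#' @param path output file path.
#' @param format one of \code{"csv"}, \code{"pgm"}, \code{"png"}.
#' @param log_scale use log normalization for grayscale formats.
#' @return \code{path}, invisibly.
#' @export
export_radiograph <- function(rg, path, format = c("csv", "pgm", "png"),
                              log_scale = TRUE) {
  format <- match.arg(format)
  img <- unclass(rg)
  if (format == "csv") {
    utils::write.csv(img, path, row.names = FALSE)
    return(invisible(path))
  }
  v <- img
  if (log_scale) {
    floor_v <- max(min(v[v > 0]), 1e-12)
    v <- log10(pmax(v, floor_v))
  }
  rngv <- range(v)
  g <- if (diff(rngv) > 0) (v - rngv[1]) / diff(rngv) else v * 0
  if (format == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    gi <- round(t(g[, rev(seq_len(ncol(g))), drop = FALSE]) * 255)
    writeLines(c("P2", sprintf("%d %d", ncol(gi), nrow(gi)), "255"), con)
    utils::write.table(gi, con, row.names = FALSE, col.names = FALSE)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required for PNG export; use format='pgm'")
    }
    png::writePNG(t(g[, rev(seq_len(ncol(g))), drop = FALSE]), path)
  }
  invisible(path)
}

#' Deterministic kerma deposition (primary beam)
#'
#' Ray-casts the parallel AP beam column-by-column and deposits, in each
#' voxel, the collision-kerma energy of the uncollided beam:
#' \code{E * F_in * (1 - exp(-mu * pitch)) * (muen/mu)}, where
#' \code{F_in} is the primary fluence entering the voxel. Scattered
#' energy is accounted as escaping (primary-only engine). The result is
#' expressed per source particle, so it is directly comparable with the
#' Monte Carlo estimator.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param source a \code{plane_source} (monodirectional +x).
#' @param E photon energy, MeV.
#' @param detail if TRUE, attach per-ray (per-column) deposited,
#'   transmitted and scattered-escape energies for bookkeeping checks.
#' @return a \code{heating_tally} with per-organ deposited energy in eV
#'   per source particle and zero uncertainty.
#' @export
deposit_kerma <- function(phantom, source, E, detail = FALSE) {
  stopifnot(inherits(source, "plane_source"))
  lut <- id_lut(phantom, E)
  d <- phantom$dims
  p <- phantom$pitch
  yc <- axis_centers(d[2], p)
  zc <- axis_centers(d[3], p)
  cov_y <- which(yc > source$y[1] & yc < source$y[2])
  cov_z <- which(zc > source$z[1] & zc < source$z[2])

  ids_sub <- phantom$ids[, cov_y, cov_z, drop = FALSE]
  mu <- array(lut$mu[ids_sub + 1L], dim = dim(ids_sub))
  muen <- array(lut$muen[ids_sub + 1L], dim = dim(ids_sub))
  ncol_sub <- length(cov_y) * length(cov_z)
  mu_m <- matrix(mu, nrow = d[1])
  T_vox <- exp(-mu_m * p)
  # fluence entering each voxel: cumulative product of upstream transmissions
  F_in <- apply(rbind(1, T_vox[-d[1], , drop = FALSE]), 2, cumprod)
  F_in <- matrix(F_in, nrow = d[1])
  frac <- matrix(0, d[1], ncol_sub)
  pos <- mu_m > 0
  frac[pos] <- matrix(muen, nrow = d[1])[pos] / mu_m[pos]
  dep <- E * F_in * (1 - T_vox) * frac              # MeV per ray photon
  trans_ray <- E * F_in[d[1], ] * T_vox[d[1], ]
  dep_ray <- colSums(dep)
  scat_ray <- E - trans_ray - dep_ray

  # per-particle weighting: each covered column intercepts pitch^2 of the
  # source area; the remainder of the source never meets the lattice
  w <- p^2 / source$area
  ids_vec <- as.integer(ids_sub)
  organ_dep <- rowsum(as.numeric(dep) * w, group = ids_vec)
  heating <- stats::setNames(numeric(nrow(phantom$registry)),
                             phantom$registry$id)
  hit <- intersect(rownames(organ_dep), names(heating))
  heating[hit] <- organ_dep[hit, 1] * 1e6           # eV per source particle

  out <- structure(list(
    heating_eV = heating,
    sd_eV = heating * 0,
    E_MeV = E,
    mode = "kerma",
    n = NA_integer_,
    deposited_MeV = sum(dep_ray) * w,
    transmitted_MeV = sum(trans_ray) * w + E * max(0, 1 - ncol_sub * p^2 / source$area),
    scattered_escape_MeV = sum(scat_ray) * w,
    source = source), class = "heating_tally")
  if (detail) {
    out$per_ray <- data.frame(deposited = dep_ray, transmitted = trans_ray,
                              scattered_escape = scat_ray)
  }
  out
}

#' @export
print.heating_tally <- function(x, ...) {
  cat(sprintf("heating tally (%s mode) at %g MeV\n", x$mode, x$E_MeV))
  nz <- x$heating_eV[x$heating_eV > 0]
  cat(sprintf("  %d organs with deposition; total %.4g eV/particle\n",
              length(nz), sum(x$heating_eV)))
  if (!is.na(x$n)) cat(sprintf("  %d histories; max relative error %.3g\n",
                               x$n, max(x$sd_eV[nz > 0] / nz)))
  invisible(x)
}

#' Analog photon Monte Carlo transport
#'
#' Runs an analog history loop on the voxel lattice with delta
#' tracking: free paths are sampled from the total attenuation
#' coefficient; at a collision the photon either Compton-scatters
#' (free-electron Klein-Nishina sampling of the scattered energy and
#' angle; the transferred energy is deposited locally, i.e. the kerma
#' approximation) or is photoabsorbed. Rayleigh scattering is not
#' modeled. With \code{scatter = FALSE} the history terminates at its
#' first collision and deposits the expected collision kerma, making the
#' estimator unbiased against \code{\link{deposit_kerma}}.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param source a \code{plane_source}.
#' @param E photon energy, MeV.
#' @param n number of histories.
#' @param seed RNG seed (integer); fixed seed gives identical tallies.
#' @param scatter follow Compton-scattered photons (default TRUE).
#' @param batches number of batches for the uncertainty estimate.
#' @param e_cutoff terminate and deposit locally below this energy, MeV.
#' @return list with components \code{heating} (a \code{heating_tally},
#'   per-organ eV per source particle with standard deviation of the
#'   mean from batch statistics) and \code{fluence} (a
#'   \code{fluence_tally} on the source plane).
#' @export
mc_transport <- function(phantom, source, E, n, seed = 1L, scatter = TRUE,
                         batches = 10L, e_cutoff = 0.01) {
  if (n < 1) stop("n must be >= 1")
  batches <- max(1L, min(as.integer(batches), as.integer(n)))
  mats <- material_arrays(phantom$registry)
  midx <- material_index_grid(phantom, mats)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  res <- .mc_transport_cpp(as.integer(midx), phantom$dims, phantom$pitch,
                           mats$mu, mats$muen, mats$ne, mats$grid, E,
                           source$x, source$y[1], source$y[2],
                           source$z[1], source$z[2],
                           as.integer(n), batches, isTRUE(scatter), e_cutoff)
  dep <- res$dep_MeV                       # nmat x batches, MeV
  per_batch <- res$histories / batches
  batch_eV <- dep * 1e6 / per_batch        # eV per particle, per batch
  mean_eV <- rowMeans(batch_eV)
  sd_eV <- if (batches > 1) {
    apply(batch_eV, 1, stats::sd) / sqrt(batches)
  } else rep(NA_real_, length(mean_eV))

  reg_ids <- phantom$registry$id
  rowpos <- match(reg_ids, mats$ids)
  heating <- structure(list(
    heating_eV = stats::setNames(mean_eV[rowpos], reg_ids),
    sd_eV = stats::setNames(sd_eV[rowpos], reg_ids),
    E_MeV = E, mode = if (scatter) "mc" else "mc-primary",
    n = res$histories, batches = batches, seed = as.integer(seed),
    source = source), class = "heating_tally")
  list(heating = heating, fluence = fluence_tally(source))
}

#' Fluence tally on the normalization plane
#'
#' The monodirectional plane source delivers, per emitted particle, a
#' fluence of \code{1 / area} on its own plane; the source plane is the
#' default normalization plane for dose conversion coefficients. The
#' value is analytic, so its uncertainty is zero.
#'
#' @param source a \code{plane_source}.
#' @return a \code{fluence_tally}: list with \code{fluence_cm2}
#'   (cm^-2 per source particle) and \code{sd}.
#' @export
fluence_tally <- function(source) {
  stopifnot(inherits(source, "plane_source"))
  structure(list(fluence_cm2 = 1 / source$area, sd = 0, source = source),
            class = "fluence_tally")
}
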