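#' Phantom recipe
#'
#' A recipe describes a stylized voxel body as a prioritized list of
#' geometric primitives painted into the lattice. Later (higher
#' priority) primitives overwrite earlier ones, so internal organs are
#' listed after the body volume they sit in. Supported shapes:
#' \describe{
#'   \item{ellipsoid}{\code{center = c(x,y,z)}, \code{semi = c(a,b,c)} cm}
#'   \item{cylinder}{z-aligned elliptical cylinder: \code{center = c(x,y)},
#'     \code{semi = c(a,b)}, \code{zrange = c(zmin, zmax)}}
#'   \item{box}{\code{center = c(x,y,z)}, \code{half = c(hx,hy,hz)}}
#'   \item{shell}{ellipsoidal shell: \code{center}, \code{semi} (outer),
#'     \code{inner} (inner semi-axes)}
#' }
#' Coordinates are in the centered physical frame (cm). Organ centers
#' are jittered by a small seeded random offset unless a primitive sets
#' \code{jitter = FALSE}; geometry is otherwise deterministic.
#'
#' @param dims lattice dimensions \code{c(nx, ny, nz)}.
#' @param pitch voxel edge, cm.
#' @param primitives list of primitive lists with fields \code{id},
#'   \code{shape}, geometry fields as above, and optional
#'   \code{priority} (defaults to list order) and \code{jitter}.
#' @param seed integer seed for center jitter.
#' @param skin_id if non-NULL, the one-voxel outer shell of the body is
#'   painted with this ID after all primitives.
#' @param registry the organ registry the IDs refer to.
#' @param jitter_cm maximum center jitter per axis, cm.
#' @return an object of class \code{phantom_recipe}.
#' @export
phantom_recipe <- function(dims, pitch, primitives, seed = 1L,
                           skin_id = NULL, registry = default_registry(),
                           jitter_cm = 0.2) {
  stopifnot(length(dims) == 3L, pitch > 0, is.list(primitives))
  for (i in seq_along(primitives)) {
    p <- primitives[[i]]
    if (is.null(p$priority)) primitives[[i]]$priority <- i
    if (is.null(p$jitter)) primitives[[i]]$jitter <- TRUE
    if (!p$shape %in% c("ellipsoid", "cylinder", "box", "shell")) {
      stop("unknown primitive shape: ", p$shape)
    }
  }
  structure(list(dims = as.integer(dims), pitch = pitch,
                 primitives = primitives, seed = as.integer(seed),
                 skin_id = skin_id, registry = registry,
                 jitter_cm = jitter_cm),
            class = "phantom_recipe")
}

paint_primitive <- function(mask_env, p, cx, cy, cz) {
  X <- mask_env$X; Y <- mask_env$Y; Z <- mask_env$Z
  c0 <- p$center
  switch(p$shape,
    ellipsoid = {
      s <- p$semi
      ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 + ((Z - c0[3]) / s[3])^2 <= 1
    },
    cylinder = {
      s <- p$semi
      if (length(s) == 1L) s <- c(s, s)
      (((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 <= 1) &
        Z >= p$zrange[1] & Z <= p$zrange[2]
    },
    box = {
      h <- p$half
      abs(X - c0[1]) <= h[1] & abs(Y - c0[2]) <= h[2] & abs(Z - c0[3]) <= h[3]
    },
    shell = {
      s <- p$semi; si <- p$inner
      outer <- ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 + ((Z - c0[3]) / s[3])^2 <= 1
      inner <- ((X - c0[1]) / si[1])^2 + ((Y - c0[2]) / si[2])^2 + ((Z - c0[3]) / si[3])^2 <= 1
      outer & !inner
    })
}

#' Generate a voxel phantom from a recipe
#'
#' Deterministic for a fixed seed. Primitives are painted in priority
#' order; if \code{skin_id} is set, body voxels facing air are repainted
#' as a one-voxel skin shell, so the skin always encloses the body.
#' Organs that end up with zero voxels at the requested resolution
#' trigger a warning listing their IDs.
#'
#' @param recipe a \code{phantom_recipe}.
#' @return a \code{voxel_phantom}.
#' @export
generate_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  d <- recipe$dims
  xs <- axis_centers(d[1], recipe$pitch)
  ys <- axis_centers(d[2], recipe$pitch)
  zs <- axis_centers(d[3], recipe$pitch)
  env <- new.env(parent = emptyenv())
  env$X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  env$Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  env$Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  prims <- recipe$primitives[order(vapply(recipe$primitives, `[[`, numeric(1), "priority"))]
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(recipe$seed)
  jit <- lapply(prims, function(p) {
    if (isTRUE(p$jitter)) stats::runif(3, -recipe$jitter_cm, recipe$jitter_cm) else c(0, 0, 0)
  })

  ids <- array(AIR_ID, dim = d)
  for (i in seq_along(prims)) {
    p <- prims[[i]]
    p$center <- p$center + jit[[i]][seq_along(p$center)]
    ids[paint_primitive(env, p)] <- as.integer(p$id)
  }

  if (!is.null(recipe$skin_id)) {
    body <- ids != AIR_ID
    interior <- body
    interior[] <- FALSE
    nx <- d[1]; ny <- d[2]; nz <- d[3]
    core <- body[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] &
      body[1:(nx - 2), 2:(ny - 1), 2:(nz - 1)] & body[3:nx, 2:(ny - 1), 2:(nz - 1)] &
      body[2:(nx - 1), 1:(ny - 2), 2:(nz - 1)] & body[2:(nx - 1), 3:ny, 2:(nz - 1)] &
      body[2:(nx - 1), 2:(ny - 1), 1:(nz - 2)] & body[2:(nx - 1), 2:(ny - 1), 3:nz]
    interior[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] <- core
    skin <- body & !interior
    ids[skin] <- as.integer(recipe$skin_id)
  }

  wanted <- unique(vapply(prims, function(p) as.integer(p$id), integer(1)))
  if (!is.null(recipe$skin_id)) wanted <- unique(c(wanted, as.integer(recipe$skin_id)))
  present <- unique(as.vector(ids))
  missing <- setdiff(wanted, present)
  if (length(missing)) {
    warning("organs with zero voxels at this resolution: ",
            paste(missing, collapse = ", "))
  }
  voxel_phantom(ids, pitch = recipe$pitch, registry = recipe$registry)
}

#' Default stylized 30-organ body recipe
#'
#' A deterministic whole-body recipe exercising every organ in the
#' bundled synthetic registry: an adipose body volume with muscle bulk,
#' skeleton (spine, skull, ribcage, pelvis), red marrow and bone
#' surface, head with brain, eye lenses and salivary glands, thoracic
#' and abdominal organs, pelvic organs, and a one-voxel skin shell.
#' The default lattice is 64 x 64 x 160 voxels at 0.5 cm pitch (a
#' 32 x 32 x 80 cm frame); other dims/pitch values rescale the anatomy
#' linearly to the new extent.
#'
#' @param dims lattice dimensions, default \code{c(64, 64, 160)}.
#' @param pitch voxel edge in cm, default 0.5.
#' @param seed jitter seed.
#' @param registry organ registry, default the bundled synthetic one.
#' @return a \code{phantom_recipe}.
#' @export
default_body_recipe <- function(dims = c(64, 64, 160), pitch = 0.5,
                                seed = 1L, registry = default_registry()) {
  s <- dims * pitch / c(32, 32, 80)  # per-axis scale vs the reference frame
  E <- function(id, cx, cy, cz, a, b, c, jitter = TRUE) {
    list(id = id, shape = "ellipsoid",
         center = c(cx * s[1], cy * s[2], cz * s[3]),
         semi = c(a * s[1], b * s[2], c * s[3]), jitter = jitter)
  }
  Cyl <- function(id, cx, cy, a, b, z1, z2, jitter = TRUE) {
    list(id = id, shape = "cylinder",
         center = c(cx * s[1], cy * s[2]),
         semi = c(a * s[1], b * s[2]),
         zrange = c(z1 * s[3], z2 * s[3]), jitter = jitter)
  }
  B <- function(id, cx, cy, cz, hx, hy, hz, jitter = TRUE) {
    list(id = id, shape = "box",
         center = c(cx * s[1], cy * s[2], cz * s[3]),
         half = c(hx * s[1], hy * s[2], hz * s[3]), jitter = jitter)
  }
  Sh <- function(id, cx, cy, cz, a, b, c, ia, ib, ic, jitter = TRUE) {
    list(id = id, shape = "shell",
         center = c(cx * s[1], cy * s[2], cz * s[3]),
         semi = c(a * s[1], b * s[2], c * s[3]),
         inner = c(ia * s[1], ib * s[2], ic * s[3]), jitter = jitter)
  }
  prims <- list(
    # body volumes (no jitter so the frame is stable)
    Cyl(30, 0, 0, 14, 15, -40, 16, jitter = FALSE),        # torso, adipose
    Cyl(30, 0, 0, 5, 5.5, 14, 22, jitter = FALSE),         # neck
    E(30, 0, 0, 30, 8.5, 9, 10, jitter = FALSE),           # head
    Cyl(2, 0, 0, 12.5, 13.5, -40, 16, jitter = FALSE),     # muscle bulk
    Cyl(2, 0, 0, 4, 4.5, 14, 22, jitter = FALSE),          # neck muscle
    # skeleton
    Cyl(3, 4.5, 0, 2.4, 2.4, -35, 25, jitter = FALSE),     # spine
    Sh(3, 0, 0, 30, 8, 8.5, 9.5, 6.8, 7.3, 7.8, jitter = FALSE),  # skull
    Sh(3, 0, 0, 4, 11.5, 12.5, 30, 10.5, 11.5, 28, jitter = FALSE), # ribcage band
    B(3, 0, 0, -30, 9, 10, 2.5, jitter = FALSE),           # pelvis
    Sh(5, 4.5, 0, -5, 1.95, 1.95, 30.4, 1.6, 1.6, 30.1, jitter = FALSE), # bone surface lining (spine)
    Cyl(4, 4.5, 0, 1.6, 1.6, -34, 24, jitter = FALSE),     # red marrow (spine core)
    # head and neck organs
    E(6, 0, 0, 30.5, 6.4, 6.9, 7.4),                       # brain
    E(7, -6.2, -2.7, 31, 0.55, 0.55, 0.55),                # eye lens (L)
    E(7, -6.2, 2.7, 31, 0.55, 0.55, 0.55),                 # eye lens (R)
    E(8, -3.5, -5, 24.5, 1.6, 1.6, 1.4),                   # salivary glands
    E(8, -3.5, 5, 24.5, 1.6, 1.6, 1.4),
    E(9, -3, 0, 18.5, 1.8, 1.8, 1.4),                      # thyroid
    Cyl(10, 1.5, 0.5, 0.9, 0.9, 0, 19),                    # oesophagus
    Cyl(29, 4.5, 0, 0.7, 0.7, -30, 23, jitter = FALSE),    # spinal cord
    # thorax
    E(11, -1, -6.5, 4, 5.6, 4.4, 8.6),                     # lungs (L)
    E(11, -1, 6.5, 4, 5.6, 4.4, 8.6),                      # lungs (R)
    E(12, -4, -1.5, 2, 4, 4, 4),                           # heart
    E(25, -6, 0, 10, 2, 2, 2),                             # thymus
    E(24, -12.8, -6, 6, 2.2, 3.4, 3.4),                    # breast (L)
    E(24, -12.8, 6, 6, 2.2, 3.4, 3.4),                     # breast (R)
    # abdomen
    E(13, -2, -6, -6, 6.4, 5.8, 4.4),                      # liver
    E(14, -6, 4, -4, 3.4, 3, 4.4),                         # stomach
    E(15, 2, 9, -5, 2.5, 2, 3.4),                          # spleen
    E(16, 5, -5.5, -10, 2.4, 2, 3.9),                      # kidneys (L)
    E(16, 5, 5.5, -10, 2.4, 2, 3.9),                       # kidneys (R)
    E(18, 5, -5.5, -5.4, 1.2, 1.2, 1),                     # adrenals (L)
    E(18, 5, 5.5, -5.4, 1.2, 1.2, 1),                      # adrenals (R)
    E(17, 0, 1, -7, 4.9, 1.5, 1.5),                        # pancreas
    E(26, -6, -4, -8.5, 1.5, 1.2, 1.9),                    # gall bladder
    E(19, -2, 0, -16, 6.9, 7.9, 5.9),                      # small intestine
    E(27, 1, 0, -16, 1.1, 3.9, 1.1),                       # lymph nodes (mesenteric)
    B(20, -2, 0, -10.5, 3, 8.8, 1.4),                      # colon, transverse band
    Cyl(21, -1, -9, 1.7, 1.7, -22, -10),                   # colon, descending
    # pelvis
    E(22, -5, 0, -26, 2.9, 2.9, 2.4),                      # bladder
    E(28, 1, 0, -27.5, 1.3, 1.3, 1.3),                     # prostate
    E(23, -6, -2, -32, 1.4, 1.4, 1.4),                     # gonads (L)
    E(23, -6, 2, -32, 1.4, 1.4, 1.4)                       # gonads (R)
  )
  phantom_recipe(dims = dims, pitch = pitch, primitives = prims,
                 seed = seed, skin_id = 1L, registry = registry)
}

#' Generate a layered slab phantom
#'
#' Builds a 1D-layered lattice along x: each layer is one material
#' filling the full y-z cross-section. Used for closed-form transport
#' fixtures.
#'
#' @param layers list of \code{list(id, thickness)} pairs (cm); each
#'   thickness must be an integer multiple of \code{pitch}.
#' @param pitch voxel edge, cm.
#' @param ny,nz cross-section size in voxels.
#' @param registry organ registry for the layer IDs.
#' @return a \code{voxel_phantom}.
#' @export
generate_slab_phantom <- function(layers, pitch = 0.5, ny = 1L, nz = 1L,
                                  registry = default_registry()) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  nvox <- vapply(layers, function(l) {
    n <- l$thickness / pitch
    if (abs(n - round(n)) > 1e-9) {
      stop(sprintf("layer thickness %g cm is not a multiple of pitch %g cm",
                   l$thickness, pitch))
    }
    as.integer(round(n))
  }, integer(1))
  xids <- unlist(mapply(function(l, n) rep(as.integer(l$id), n),
                        layers, nvox, SIMPLIFY = FALSE))
  nx <- length(xids)
  ids <- array(rep(xids, times = ny * nz), dim = c(nx, ny, nz))
  voxel_phantom(ids, pitch = pitch, registry = registry)
}
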