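#' Organ registry
#'
#' An organ registry maps small integer organ IDs (1--254) to tissue
#' properties: name, mass density, elemental composition (mass fractions
#' over the bundled element set) and an effective-dose weighting class.
#' ID 255 is reserved for the air/outside universe and may not appear in
#' a registry.
#'
#' @param x a data.frame with columns \code{id}, \code{name},
#'   \code{density}, \code{weight_class} and one column per element
#'   symbol (H, C, N, O, Na, Mg, P, S, Cl, K, Ca, Fe, I) holding mass
#'   fractions, or a path to a CSV file with those columns.
#' @return a validated data.frame of class \code{organ_registry}.
#' @export
organ_registry <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- utils::read.csv(x, check.names = FALSE)
  }
  stopifnot(is.data.frame(x))
  need <- c("id", "name", "density", "weight_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("organ registry is missing columns: ", paste(miss, collapse = ", "))
  }
  elems <- intersect(registry_elements(), names(x))
  if (!length(elems)) stop("organ registry has no element mass-fraction columns")
  x$id <- as.integer(x$id)
  if (anyNA(x$id) || any(x$id < 1L) || any(x$id > 254L)) {
    stop("organ IDs must be integers in 1-254 (255 is reserved for air)")
  }
  if (anyDuplicated(x$id)) {
    stop("duplicate organ IDs in registry: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  if (any(x$density <= 0)) stop("organ densities must be positive")
  bad_class <- setdiff(unique(x$weight_class), c("weighted", "remainder", "unscored"))
  if (length(bad_class)) {
    stop("unknown weight_class value(s): ", paste(bad_class, collapse = ", "))
  }
  fr <- as.matrix(x[, elems, drop = FALSE])
  sums <- rowSums(fr)
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop("composition mass fractions must sum to 1 (off for ID ",
         paste(x$id[off], collapse = ", "), ")")
  }
  class(x) <- c("organ_registry", "data.frame")
  x
}

#' Bundled synthetic 30-organ registry
#'
#' Returns the package's default organ registry: a synthetic stand-in
#' for a segmented whole-body inventory, with 30 organs/tissues carrying
#' ICRU-44-style densities and elemental compositions. It is a stylized
#' registry constructed for this package, not measured data for any
#' real phantom.
#'
#' @return an \code{organ_registry}.
#' @export
default_registry <- function() {
  organ_registry(system.file("extdata", "organ_registry_synthetic.csv",
                             package = "voxdose", mustWork = TRUE))
}

registry_elements <- function() {
  c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca", "Fe", "I")
}

#' Composition of a registry organ
#'
#' @param registry an \code{organ_registry}.
#' @param id organ ID.
#' @return named numeric vector of mass fractions (non-zero entries only).
#' @export
organ_composition <- function(registry, id) {
  row <- match(as.integer(id), registry$id)
  if (is.na(row)) stop("unknown organ ID: ", id)
  elems <- intersect(registry_elements(), names(registry))
  comp <- unlist(registry[row, elems])
  comp[comp > 0]
}

AIR_ID <- 255L

# Composition and density used for the air/outside universe (ID 255).
air_spec <- function() {
  list(id = AIR_ID, name = "air", density = 0.001205,
       composition = c(N = 0.765, O = 0.235))
}

#' Construct a voxel phantom
#'
#' A voxel phantom is a 3D lattice of organ IDs with a physical voxel
#' pitch and an organ registry. The lattice is stored as an integer
#' array indexed \code{[x, y, z]} (x fastest in memory, i.e. the fill
#' order reads x, then y, then z, filling from the bottom slice up) and
#' its physical extent is centered on the origin: voxel \code{(i,j,k)}
#' has its center at \code{((i - nx/2 - 0.5) * pitch, ...)} cm.
#'
#' @param ids integer array of organ IDs with \code{dim = c(nx, ny, nz)},
#'   or a linear vector (then \code{dims} is required).
#' @param dims integer vector \code{c(nx, ny, nz)}; required when
#'   \code{ids} is linear.
#' @param pitch voxel edge length in cm.
#' @param registry an \code{organ_registry}; defaults to the bundled
#'   synthetic registry.
#' @param outside_id the ID used for the exterior (air), default 255.
#' @return an object of class \code{voxel_phantom}.
#' @export
voxel_phantom <- function(ids, dims = NULL, pitch = 0.2,
                          registry = default_registry(),
                          outside_id = AIR_ID) {
  if (is.null(dim(ids))) {
    if (is.null(dims)) stop("dims is required when ids is a linear array")
    dims <- as.integer(dims)
    if (length(dims) != 3L) stop("dims must be c(nx, ny, nz)")
    if (length(ids) != prod(dims)) {
      stop(sprintf("fill array has %d entries but dims imply %d voxels",
                   length(ids), prod(dims)))
    }
    ids <- array(as.integer(ids), dim = dims)
  } else {
    if (length(dim(ids)) != 3L) stop("ids must be a 3D array")
    storage.mode(ids) <- "integer"
  }
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0) {
    stop("pitch must be a single positive number (cm)")
  }
  registry <- if (inherits(registry, "organ_registry")) registry else organ_registry(registry)
  outside_id <- as.integer(outside_id)
  if (outside_id %in% registry$id) {
    stop("outside_id ", outside_id, " must not appear in the registry")
  }
  present <- sort(unique(as.vector(ids)))
  unknown <- setdiff(present, c(registry$id, outside_id))
  if (length(unknown)) {
    stop("grid contains IDs absent from the registry: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(ids = ids, dims = dim(ids), pitch = pitch,
                 registry = registry, outside_id = outside_id),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- x$dims
  cat(sprintf("voxel phantom: %d x %d x %d voxels (%s total), pitch %g cm\n",
              d[1], d[2], d[3], format(prod(d), big.mark = ","), x$pitch))
  cat(sprintf("  extent: %g x %g x %g cm, centered on the origin\n",
              d[1] * x$pitch, d[2] * x$pitch, d[3] * x$pitch))
  ids <- setdiff(sort(unique(as.vector(x$ids))), x$outside_id)
  cat(sprintf("  organs present: %d of %d registry entries; outside ID %d\n",
              length(ids), nrow(x$registry), x$outside_id))
  invisible(x)
}

#' Total voxel count
#'
#' @param x a \code{voxel_phantom}, or an integer vector of dims
#'   \code{c(nx, ny, nz)}.
#' @return the number of voxels, as a double to avoid integer overflow.
#' @export
voxel_count <- function(x) {
  d <- if (inherits(x, "voxel_phantom")) x$dims else as.integer(x)
  if (length(d) != 3L || any(d < 1L)) stop("dims must be three positive integers")
  prod(as.numeric(d))
}

#' Read a fill card
#'
#' Fill cards are plain-text files of whitespace-separated organ IDs in
#' fill order (x fastest, then y, then z), optionally using run-length
#' tokens \code{<value>r<count>} ("3r4" expands to four 3s). A header
#' comment \code{# dims nx ny nz pitch} is honored when present and
#' recorded as attributes on the result.
#'
#' @param path path to the fill-card file, or a character vector of
#'   lines (given as \code{textConnection} content via \code{text =}).
#' @param text optional character vector of card lines, used instead of
#'   \code{path}.
#' @return integer vector of IDs in file order, with attributes
#'   \code{dims} and \code{pitch} when a header was present.
#' @export
read_fill_card <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  dims <- NULL
  pitch <- NULL
  out <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^\\s*#", line)) {
      m <- regmatches(line, regexec(
        "^\\s*#\\s*dims\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)\\s+([0-9.eE+-]+)", line))[[1]]
      if (length(m) == 5L) {
        dims <- as.integer(m[2:4])
        pitch <- as.numeric(m[5])
      }
      next
    }
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    vals <- lapply(toks, function(tk) {
      if (grepl("^\\d+$", tk)) return(as.integer(tk))
      m <- regmatches(tk, regexec("^(\\d+)r(\\d+)$", tk))[[1]]
      if (length(m) == 3L) return(rep(as.integer(m[2]), as.integer(m[3])))
      stop(sprintf("fill card parse error on line %d: token '%s' is not an integer or <value>r<count>",
                   ln, tk))
    })
    vals <- unlist(vals)
    if (any(vals < 0L | vals > 255L)) {
      stop(sprintf("fill card line %d: ID outside 0-255", ln))
    }
    out[[ln]] <- vals
  }
  ids <- as.integer(unlist(out))
  if (!is.null(dims)) {
    attr(ids, "dims") <- dims
    attr(ids, "pitch") <- pitch
  }
  ids
}

#' Write a fill card
#'
#' Emits the canonical form: a \code{# dims nx ny nz pitch} header, then
#' IDs with runs of four or more identical values compressed to
#' \code{<value>r<count>} tokens, 12 tokens per line.
#'
#' @param ids integer vector of IDs, or a \code{voxel_phantom} (then its
#'   flattened grid, dims and pitch are used).
#' @param path output file path.
#' @param dims,pitch header values; taken from the phantom when one is
#'   given.
#' @return \code{path}, invisibly.
#' @export
write_fill_card <- function(ids, path, dims = NULL, pitch = NULL) {
  if (inherits(ids, "voxel_phantom")) {
    dims <- ids$dims
    pitch <- ids$pitch
    ids <- flatten_phantom(ids)
  }
  ids <- as.integer(ids)
  if (any(ids < 0L | ids > 255L)) stop("IDs must be in 0-255")
  r <- rle(ids)
  toks <- ifelse(r$lengths >= 4L,
                 sprintf("%dr%d", r$values, r$lengths),
                 NA_character_)
  pieces <- mapply(function(tok, val, len) {
    if (is.na(tok)) rep(as.character(val), len) else tok
  }, toks, r$values, r$lengths, SIMPLIFY = FALSE)
  toks <- unlist(pieces)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(dims)) {
    writeLines(sprintf("# dims %d %d %d %g", dims[1], dims[2], dims[3],
                       if (is.null(pitch)) 0.2 else pitch), con)
  }
  idx <- seq_along(toks)
  for (grp in split(toks, ceiling(idx / 12))) {
    writeLines(paste(grp, collapse = " "), con)
  }
  invisible(path)
}

#' Populate a lattice from a linear fill array
#'
#' The linear array is read in fill order: x fastest, then y, then z
#' (the lattice fills from the bottom slice upward). Round-trips with
#' \code{\link{flatten_phantom}}.
#'
#' @param linear integer vector of organ IDs, length \code{nx*ny*nz}.
#' @param dims integer vector \code{c(nx, ny, nz)}; defaults to the
#'   \code{dims} attribute read from a fill-card header.
#' @param pitch voxel pitch in cm.
#' @param registry an \code{organ_registry}.
#' @param outside_id exterior ID, default 255.
#' @return a \code{voxel_phantom}.
#' @export
populate_lattice <- function(linear, dims = attr(linear, "dims"),
                             pitch = if (is.null(attr(linear, "pitch"))) 0.2 else attr(linear, "pitch"),
                             registry = default_registry(),
                             outside_id = AIR_ID) {
  if (is.null(dims)) stop("dims must be given (or present as a fill-card header)")
  voxel_phantom(as.integer(linear), dims = dims, pitch = pitch,
                registry = registry, outside_id = outside_id)
}

#' Flatten a phantom grid to its linear fill array
#'
#' @param phantom a \code{voxel_phantom}.
#' @return integer vector in fill order (x fastest, then y, then z).
#' @export
flatten_phantom <- function(phantom) {
  as.integer(as.vector(phantom$ids))
}

#' Organ mass
#'
#' Mass of one organ, or of every registry organ, from its voxel count,
#' the voxel volume and the registry density.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param id organ ID; an organ absent from the grid has mass zero.
#' @return mass in grams.
#' @export
organ_mass <- function(phantom, id) {
  id <- as.integer(id)
  if (!id %in% phantom$registry$id) stop("unknown organ ID: ", id)
  n <- sum(phantom$ids == id)
  rho <- phantom$registry$density[match(id, phantom$registry$id)]
  n * phantom$pitch^3 * rho
}

#' @rdname organ_mass
#' @return \code{phantom_masses}: named numeric vector (names are organ
#'   IDs) of masses in grams for every registry organ.
#' @export
phantom_masses <- function(phantom) {
  counts <- tabulate(phantom$ids, nbins = 255L)
  ids <- phantom$registry$id
  m <- counts[ids] * phantom$pitch^3 * phantom$registry$density
  names(m) <- ids
  m
}

#' Extract a 2D slice of the phantom
#'
#' Axis conventions: x is the anterior-posterior (depth) axis, y is
#' left-right, z is vertical. A \code{coronal} slice fixes x (a y-z
#' plane), \code{sagittal} fixes y (an x-z plane), \code{transverse}
#' fixes z (an x-y plane).
#'
#' @param phantom a \code{voxel_phantom}.
#' @param axis one of \code{"coronal"}, \code{"sagittal"},
#'   \code{"transverse"}.
#' @param index 1-based voxel index along the fixed axis; defaults to
#'   the middle slice.
#' @return an integer matrix of organ IDs of class \code{phantom_slice},
#'   with the phantom registry attached for rendering.
#' @export
slice_view <- function(phantom, axis = c("coronal", "sagittal", "transverse"),
                       index = NULL) {
  axis <- match.arg(axis)
  ax <- switch(axis, coronal = 1L, sagittal = 2L, transverse = 3L)
  n <- phantom$dims[ax]
  if (is.null(index)) index <- (n + 1L) %/% 2L
  index <- as.integer(index)
  if (index < 1L || index > n) {
    stop(sprintf("slice index %d out of range 1-%d for %s axis", index, n, axis))
  }
  m <- switch(axis,
              coronal = phantom$ids[index, , , drop = TRUE],
              sagittal = phantom$ids[, index, , drop = TRUE],
              transverse = phantom$ids[, , index, drop = TRUE])
  m <- matrix(m, nrow = dim(phantom$ids)[setdiff(1:3, ax)][1])
  structure(m, class = c("phantom_slice", class(m)),
            axis = axis, index = index,
            registry = phantom$registry, outside_id = phantom$outside_id)
}

#' Render a phantom slice
#'
#' Plots the organ-ID map with one color per registry organ; the outside
#' (air) region and any organs listed in \code{hide} are rendered as
#' transparent/background.
#'
#' @param x a \code{phantom_slice}.
#' @param hide integer IDs to render as background.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.phantom_slice <- function(x, hide = integer(), ...) {
  reg <- attr(x, "registry")
  ids <- sort(unique(as.vector(unclass(x))))
  pal <- grDevices::hcl.colors(max(nrow(reg), 3L), "Spectral")
  cols <- stats::setNames(pal[seq_len(nrow(reg))], reg$id)
  cols[as.character(attr(x, "outside_id"))] <- "#FFFFFF"
  cols[as.character(hide)] <- "#FFFFFF"
  z <- matrix(match(as.vector(unclass(x)), ids), nrow = nrow(x))
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), z,
                  col = cols[as.character(ids)], useRaster = TRUE,
                  xlab = "", ylab = "", asp = 1, ...)
  invisible(x)
}

# Physical voxel-center coordinates along one axis (cm), centered frame.
axis_centers <- function(n, pitch) {
  (seq_len(n) - 0.5 - n / 2) * pitch
}

#' Physical extent of the phantom
#'
#' @param phantom a \code{voxel_phantom}.
#' @return list with \code{lower} and \code{upper} corners (cm).
#' @export
phantom_extent <- function(phantom) {
  half <- phantom$dims * phantom$pitch / 2
  list(lower = -half, upper = half)
}
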