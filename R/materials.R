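#' Bundled elemental photon coefficients
#'
#' Loads the package's elemental photon coefficient table: mass
#' attenuation \code{mu_rho} and mass energy-absorption \code{muen_rho}
#' (cm^2/g, coherent scattering excluded) for 13 biologically relevant
#' elements on an 18-point energy grid covering 0.01--1.25 MeV. The
#' table is generated from free-electron Klein-Nishina incoherent cross
#' sections plus a calibrated photoelectric power law (see the package
#' vignette); it is an approximate, self-contained table, adequate at
#' the few-percent level for low-Z tissues in the diagnostic range.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return data.frame with columns \code{element}, \code{energy_MeV},
#'   \code{mu_rho}, \code{muen_rho}.
#' @export
element_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("coef_table", envir = .voxdose_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "photon_coefficients.csv",
                        package = "voxdose", mustWork = TRUE)
    tab <- validate_coefficients(utils::read.csv(path))
    assign("coef_table", tab, envir = .voxdose_cache)
    return(tab)
  }
  validate_coefficients(utils::read.csv(path))
}

.voxdose_cache <- new.env(parent = emptyenv())

validate_coefficients <- function(tab) {
  stopifnot(all(c("element", "energy_MeV", "mu_rho", "muen_rho") %in% names(tab)))
  if (any(tab$mu_rho <= 0) || any(tab$muen_rho <= 0)) {
    stop("photon coefficients must be positive")
  }
  if (any(tab$muen_rho > tab$mu_rho * (1 + 1e-9))) {
    stop("muen/rho exceeds mu/rho in the coefficient table")
  }
  for (el in unique(tab$element)) {
    e <- tab$energy_MeV[tab$element == el]
    if (is.unsorted(e, strictly = TRUE)) {
      stop("energy grid for element ", el, " is not strictly increasing")
    }
  }
  tab
}

#' Energy range covered by the coefficient table
#'
#' @return numeric length-2 vector (MeV).
#' @export
coefficient_range <- function() {
  tab <- element_coefficients()
  range(tab$energy_MeV)
}

#' The default 20-point photon energy grid
#'
#' Diagnostic-to-gamma energies from 10 keV to 1 MeV, including the
#' 511 keV annihilation and 662 keV Cs-137 lines.
#'
#' @return numeric vector of 20 energies in MeV.
#' @export
default_energies <- function() {
  c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.1,
    0.15, 0.2, 0.3, 0.4, 0.5, 0.511, 0.6, 0.662, 0.8, 1.0)
}

# log-log linear interpolation of one element's coefficient at E (vectorized)
interp_coef <- function(element, E, column) {
  tab <- element_coefficients()
  rows <- tab$element == element
  if (!any(rows)) stop("unknown element: ", element)
  grid <- tab$energy_MeV[rows]
  val <- tab[[column]][rows]
  rng <- range(grid)
  if (any(E < rng[1] - 1e-12) || any(E > rng[2] + 1e-12)) {
    stop(sprintf("energy outside table range %g-%g MeV", rng[1], rng[2]))
  }
  E <- pmin(pmax(E, rng[1]), rng[2])
  exp(stats::approx(log(grid), log(val), xout = log(E))$y)
}

check_composition <- function(composition) {
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mass fractions")
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition mass fractions must sum to 1 (got ",
         format(sum(composition)), ")")
  }
  known <- unique(element_coefficients()$element)
  bad <- setdiff(names(composition), known)
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  composition
}

#' Mixture photon coefficients (Bragg additivity)
#'
#' Mass attenuation (\code{mixture_mu}) and mass energy-absorption
#' (\code{mixture_muen}) coefficients of a mixture, as the mass-fraction
#' weighted sum of elemental coefficients, each interpolated log-log on
#' the bundled grid.
#'
#' @param composition named numeric vector of elemental mass fractions
#'   summing to 1 (names are element symbols).
#' @param E photon energy in MeV (vectorized); must lie within the
#'   table range.
#' @return coefficient(s) in cm^2/g.
#' @export
mixture_mu <- function(composition, E) {
  composition <- check_composition(composition)
  vals <- vapply(names(composition),
                 function(el) interp_coef(el, E, "mu_rho"),
                 numeric(length(E)))
  as.numeric(matrix(vals, nrow = length(E)) %*% composition)
}

#' @rdname mixture_mu
#' @export
mixture_muen <- function(composition, E) {
  composition <- check_composition(composition)
  vals <- vapply(names(composition),
                 function(el) interp_coef(el, E, "muen_rho"),
                 numeric(length(E)))
  as.numeric(matrix(vals, nrow = length(E)) %*% composition)
}

# Z and A for the supported elements (for electron densities / KN split)
element_ZA <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca", "Fe", "I"),
    Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 19, 20, 26, 53),
    A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
          35.45, 39.098, 40.078, 55.845, 126.904)
  )
}

# electrons per gram of a mixture: N_A * sum w_e Z_e / A_e
electrons_per_gram <- function(composition) {
  za <- element_ZA()
  idx <- match(names(composition), za$element)
  if (anyNA(idx)) stop("unknown element(s) in composition")
  6.02214076e23 * sum(composition * za$Z[idx] / za$A[idx])
}

#' Total Klein-Nishina cross section per electron
#'
#' @param E photon energy in MeV (vectorized).
#' @return cross section in cm^2 per electron.
#' @export
klein_nishina_sigma <- function(E) {
  r_e <- 2.8179403262e-13
  k <- E / 0.51099895
  2 * pi * r_e^2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# Per-organ material arrays for the transport kernels, on the table's
# native energy grid: linear attenuation and energy-absorption
# coefficients (cm^-1) for every registry organ plus the air/outside
# universe, and electron densities (cm^-3) for the Compton split.
material_arrays <- function(registry) {
  tab <- element_coefficients()
  grid <- sort(unique(tab$energy_MeV))
  specs <- c(lapply(seq_len(nrow(registry)), function(i) {
    list(id = registry$id[i], density = registry$density[i],
         composition = organ_composition(registry, registry$id[i]))
  }), list(air_spec()))
  ids <- vapply(specs, `[[`, integer(1), "id")
  mu <- matrix(0, nrow = length(specs), ncol = length(grid))
  muen <- matrix(0, nrow = length(specs), ncol = length(grid))
  ne <- numeric(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    comp <- s$composition / sum(s$composition)
    mu[i, ] <- s$density * mixture_mu(comp, grid)
    muen[i, ] <- s$density * mixture_muen(comp, grid)
    ne[i] <- s$density * electrons_per_gram(comp)
  }
  list(ids = ids, grid = grid, mu = mu, muen = muen, ne = ne)
}

# map a grid of organ IDs to row indices of material_arrays (0-based for C++)
material_index_grid <- function(phantom, mats, outside_vacuum = TRUE) {
  lut <- integer(256)
  lut[] <- NA_integer_
  lut[mats$ids + 1L] <- seq_along(mats$ids)
  idx <- lut[phantom$ids + 1L]
  if (anyNA(idx)) stop("phantom contains IDs without material data")
  idx <- array(idx, dim = phantom$dims)
  if (outside_vacuum) idx[phantom$ids == phantom$outside_id] <- 0L
  idx - 1L  # 0-based; -1 marks vacuum
}
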