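#' ICRP-103 tissue weighting factors
#'
#' The default tissue weighting scheme: w_T = 0.12 for red marrow,
#' colon, lung, stomach, breast and the remainder; 0.08 for gonads;
#' 0.04 for bladder, oesophagus, liver and thyroid; 0.01 for bone
#' surface, brain, salivary glands and skin. The weights sum to exactly
#' 1. The remainder dose is the arithmetic mean of the equivalent doses
#' of the remainder organs. The radiation weighting factor w_R is 1 for
#' photons.
#'
#' @param weights named numeric vector of w_T for the explicitly
#'   weighted targets.
#' @param remainder_weight w_T of the remainder term.
#' @param w_R radiation weighting factor (photons: 1).
#' @param combine named character vector mapping registry organ names to
#'   weighting targets (several organs may map to one target; they are
#'   combined by mass-weighted mean dose). Default folds the upper and
#'   lower colon into one colon target.
#' @return an object of class \code{tissue_weights}.
#' @export
tissue_weights <- function(weights = c(red_marrow = 0.12, colon = 0.12,
                                       lungs = 0.12, stomach = 0.12,
                                       breast = 0.12, gonads = 0.08,
                                       bladder = 0.04, oesophagus = 0.04,
                                       liver = 0.04, thyroid = 0.04,
                                       bone_surface = 0.01, brain = 0.01,
                                       salivary_glands = 0.01, skin = 0.01),
                           remainder_weight = 0.12, w_R = 1,
                           combine = c(colon_upper = "colon",
                                       colon_lower = "colon")) {
  stopifnot(!is.null(names(weights)), all(weights > 0), remainder_weight >= 0)
  total <- sum(weights) + remainder_weight
  if (abs(total - 1) > 1e-12) {
    stop("tissue weights must sum to exactly 1 (got ", format(total), ")")
  }
  structure(list(weights = weights, remainder_weight = remainder_weight,
                 w_R = w_R, combine = combine), class = "tissue_weights")
}

EV_PER_JOULE_C1 <- 1.602176634e-19  # J per eV
PGY_PER_GY_C2 <- 1e12               # pGy per Gy

#' Convert a heating tally to organ absorbed doses
#'
#' D_T = heating[eV] * C1 / mass[kg] * C2, with C1 the
#' electron-volt-to-joule conversion (1.602176634e-19 J/eV) and C2 the
#' gray-to-picogray conversion (1e12). Uncertainties scale the same way.
#'
#' @param tally a \code{heating_tally} (eV per source particle).
#' @param masses named numeric vector of organ masses in kg (names are
#'   organ IDs); typically \code{phantom_masses(phantom) / 1000}.
#' @return data.frame with organ \code{id}, \code{dose_pGy} (per source
#'   particle) and \code{sd_pGy}.
#' @export
heating_to_dose <- function(tally, masses) {
  ids <- names(tally$heating_eV)
  m <- masses[ids]
  if (anyNA(m)) {
    stop("missing mass for organ ID(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  }
  scored <- tally$heating_eV > 0 | m > 0
  if (any(m[scored] <= 0 & tally$heating_eV[scored] > 0)) {
    stop("organ with deposited energy but non-positive mass: ",
         paste(ids[m <= 0 & tally$heating_eV > 0], collapse = ", "))
  }
  dose <- ifelse(m > 0, tally$heating_eV * EV_PER_JOULE_C1 / m * PGY_PER_GY_C2, 0)
  sd <- ifelse(m > 0, tally$sd_eV * EV_PER_JOULE_C1 / m * PGY_PER_GY_C2, 0)
  data.frame(id = as.integer(ids), dose_pGy = as.numeric(dose),
             sd_pGy = as.numeric(sd))
}

#' Normalize a per-particle dose to unit fluence
#'
#' Divides the per-source-particle dose by the per-particle fluence on
#' the normalization plane, yielding the fluence-to-dose conversion
#' coefficient DCC in pGy cm^2. Independent of the particle count, and
#' (for a beam fully covering the phantom) of the source area.
#'
#' @param dose dose(s) per source particle (pGy).
#' @param fluence a \code{fluence_tally}, or a positive number
#'   (cm^-2 per source particle).
#' @return DCC in pGy cm^2 (same shape as \code{dose}).
#' @export
normalize_to_fluence <- function(dose, fluence) {
  f <- if (inherits(fluence, "fluence_tally")) fluence$fluence_cm2 else fluence
  if (!is.numeric(f) || f <= 0) stop("fluence must be positive")
  dose / f
}

#' Organ dose conversion coefficients over an energy grid
#'
#' Runs the transport engine at each energy and assembles the organ x
#' energy table of fluence-normalized absorbed doses (DCC, pGy cm^2).
#'
#' @param phantom a \code{voxel_phantom}.
#' @param source a \code{plane_source}; default AP beam covering the
#'   phantom.
#' @param energies energy grid in MeV, default the 20-point grid.
#' @param method \code{"kerma"} (deterministic, primary-only) or
#'   \code{"mc"} (analog Monte Carlo).
#' @param n,seed,scatter,batches Monte Carlo parameters (see
#'   \code{\link{mc_transport}}).
#' @return an \code{organ_dose_table}: list with matrices \code{dcc} and
#'   \code{sd} (organs x energies, pGy cm^2), \code{energies}, and the
#'   organ metadata.
#' @export
organ_dose_table <- function(phantom, source = ap_source(phantom),
                             energies = default_energies(),
                             method = c("kerma", "mc"),
                             n = 1e5, seed = 1L, scatter = TRUE,
                             batches = 10L) {
  method <- match.arg(method)
  masses_kg <- phantom_masses(phantom) / 1000
  flu <- fluence_tally(source)
  reg <- phantom$registry
  dcc <- matrix(0, nrow(reg), length(energies),
                dimnames = list(reg$id, signif(energies, 6)))
  sd <- dcc
  for (j in seq_along(energies)) {
    E <- energies[j]
    tal <- if (method == "kerma") {
      deposit_kerma(phantom, source, E)
    } else {
      mc_transport(phantom, source, E, n = n, seed = seed + j,
                   scatter = scatter, batches = batches)$heating
    }
    d <- heating_to_dose(tal, masses_kg)
    dcc[, j] <- normalize_to_fluence(d$dose_pGy, flu)
    sd[, j] <- normalize_to_fluence(d$sd_pGy, flu)
  }
  structure(list(dcc = dcc, sd = sd, energies = energies,
                 organs = reg[, c("id", "name", "weight_class")],
                 masses_kg = masses_kg, method = method),
            class = "organ_dose_table")
}

#' @export
print.organ_dose_table <- function(x, ...) {
  cat(sprintf("organ dose table: %d organs x %d energies (%s engine), pGy cm^2\n",
              nrow(x$dcc), ncol(x$dcc), x$method))
  invisible(x)
}

#' Effective dose from an organ dose table
#'
#' Applies the tissue weighting scheme per energy: equivalent doses
#' H_T = w_R * D_T (numerically pSv = pGy for photons), the named
#' targets contribute w_T * H_T, and the remainder organs contribute
#' remainder_weight times the arithmetic mean of their equivalent
#' doses. Uncertainties propagate in quadrature with the same weights.
#' Organs mapped onto one target by \code{weights$combine} (the upper
#' and lower colon by default) are first combined by mass-weighted mean
#' dose.
#'
#' @param doses an \code{organ_dose_table}.
#' @param weights a \code{tissue_weights}; default ICRP-103.
#' @return an \code{effective_dose_table}: data.frame with
#'   \code{energy_MeV}, \code{ED} (pSv cm^2) and \code{sd}.
#' @export
effective_dose <- function(doses, weights = tissue_weights()) {
  stopifnot(inherits(doses, "organ_dose_table"),
            inherits(weights, "tissue_weights"))
  org <- doses$organs
  target <- org$name
  hit <- match(target, names(weights$combine))
  target[!is.na(hit)] <- weights$combine[hit[!is.na(hit)]]

  H <- weights$w_R * doses$dcc
  U <- weights$w_R * doses$sd
  mass <- doses$masses_kg[as.character(org$id)]

  # combine multi-organ targets by mass-weighted mean dose
  comb_dose <- function(rows, col) {
    if (length(rows) == 1L) return(H[rows, col])
    wts <- mass[rows]
    if (sum(wts) <= 0) wts <- rep(1, length(rows))
    sum(H[rows, col] * wts) / sum(wts)
  }
  comb_sd <- function(rows, col) {
    if (length(rows) == 1L) return(U[rows, col])
    wts <- mass[rows]
    if (sum(wts) <= 0) wts <- rep(1, length(rows))
    sqrt(sum((wts / sum(wts) * U[rows, col])^2))
  }

  named <- names(weights$weights)
  missing_named <- named[!named %in% target[org$weight_class == "weighted"]]
  if (length(missing_named)) {
    stop("weighted organ(s) missing from the dose table: ",
         paste(missing_named, collapse = ", "))
  }
  rem_rows <- which(org$weight_class == "remainder")
  if (weights$remainder_weight > 0 && !length(rem_rows)) {
    stop("remainder weight is positive but no remainder organs are present")
  }

  ne <- length(doses$energies)
  ED <- numeric(ne)
  SD <- numeric(ne)
  for (j in seq_len(ne)) {
    acc <- 0
    var_acc <- 0
    for (t in named) {
      rows <- which(target == t & org$weight_class == "weighted")
      w <- weights$weights[[t]]
      acc <- acc + w * comb_dose(rows, j)
      var_acc <- var_acc + (w * comb_sd(rows, j))^2
    }
    if (weights$remainder_weight > 0) {
      hrem <- H[rem_rows, j]
      acc <- acc + weights$remainder_weight * mean(hrem)
      var_acc <- var_acc +
        sum((weights$remainder_weight / length(rem_rows) * U[rem_rows, j])^2)
    }
    ED[j] <- acc
    SD[j] <- sqrt(var_acc)
  }
  structure(data.frame(energy_MeV = doses$energies, ED = ED, sd = SD),
            class = c("effective_dose_table", "data.frame"))
}

#' Write organ-dose and effective-dose tables as CSV
#'
#' Organ rows by energy columns, with the effective dose appended as the
#' final row, mirroring the usual published layout.
#'
#' @param doses an \code{organ_dose_table}.
#' @param ed an \code{effective_dose_table} for the same grid.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dose_csv <- function(doses, ed, path) {
  vals <- rbind(doses$dcc, effective_dose = ed$ED)
  out <- data.frame(organ = c(doses$organs$name, "effective_dose"),
                    id = c(doses$organs$id, NA),
                    vals, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
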