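#' Energy-binned effective-dose series
#'
#' A named series of effective-dose values on an energy grid, with
#' missing entries allowed (a model may not report every energy).
#' Missing entries are excluded from all statistics pairwise.
#'
#' @param name model name.
#' @param energy_MeV energy grid.
#' @param values ED values (pSv cm^2); \code{NA} marks missing bins.
#' @return an object of class \code{dose_series}.
#' @export
dose_series <- function(name, energy_MeV, values) {
  stopifnot(is.character(name), length(energy_MeV) == length(values))
  if (is.unsorted(energy_MeV, strictly = TRUE)) {
    stop("energy grid must be strictly increasing")
  }
  structure(list(name = name, energy_MeV = as.numeric(energy_MeV),
                 values = as.numeric(values)), class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("dose series '%s': %d energies, %d defined\n",
              x$name, length(x$values), sum(!is.na(x$values))))
  invisible(x)
}

#' Read a multi-model effective-dose table
#'
#' Reads a CSV with an \code{energy_MeV} column and one column per
#' model; \code{"-"} or empty cells mark missing values. The bundled
#' fixture \code{table1_effective_dose.csv} transcribes a published
#' AP effective-dose comparison (ICRP-116 reference, XGB-SA, MCNPX and
#' OpenMC columns over 20 energies).
#'
#' @param path CSV path; default the bundled fixture.
#' @param drop columns to ignore (default the uncertainty column).
#' @return named list of \code{dose_series}.
#' @export
read_dose_table <- function(path = NULL, drop = "OpenMC_uncertainty") {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_effective_dose.csv",
                        package = "voxdose", mustWork = TRUE)
  }
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("-", "", "NA"))
  stopifnot("energy_MeV" %in% names(df))
  models <- setdiff(names(df), c("energy_MeV", drop))
  out <- lapply(models, function(m) {
    dose_series(m, df$energy_MeV, as.numeric(df[[m]]))
  })
  stats::setNames(out, models)
}

#' Percent difference against a reference
#'
#' \code{(value - reference) / reference * 100}.
#'
#' @param value,reference numeric (vectorized); reference must be
#'   non-zero.
#' @return percent difference(s).
#' @export
percent_diff <- function(value, reference) {
  if (any(reference == 0, na.rm = TRUE)) {
    stop("reference value of zero in percent difference")
  }
  (value - reference) / reference * 100
}

#' Pairwise-complete root mean square error between two series
#'
#' RMSE over the energies where both series have a value; errors if the
#' series share no defined energy.
#'
#' @param a,b \code{dose_series} on the same energy grid.
#' @return list-free numeric RMSE; the number of energies used is
#'   attached as attribute \code{n}.
#' @export
rmse <- function(a, b) {
  stopifnot(inherits(a, "dose_series"), inherits(b, "dose_series"))
  if (!isTRUE(all.equal(a$energy_MeV, b$energy_MeV))) {
    stop("series are on different energy grids")
  }
  ok <- !is.na(a$values) & !is.na(b$values)
  if (!any(ok)) stop("series have no overlapping defined energies")
  structure(sqrt(mean((a$values[ok] - b$values[ok])^2)), n = sum(ok))
}

#' Per-energy average of several model series
#'
#' At each energy, the arithmetic mean over the models that define a
#' value there; an energy missing in every series stays missing.
#'
#' @param series list of \code{dose_series} on a common grid.
#' @param name name for the averaged series.
#' @return a \code{dose_series}.
#' @export
model_average <- function(series, name = "average") {
  stopifnot(length(series) >= 1L)
  grid <- series[[1]]$energy_MeV
  for (s in series) {
    if (!isTRUE(all.equal(s$energy_MeV, grid))) {
      stop("series are on different energy grids")
    }
  }
  vals <- sapply(series, `[[`, "values")
  vals <- matrix(vals, nrow = length(grid))
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  dose_series(name, grid, avg)
}

#' Build a full model-comparison report
#'
#' Computes, for a set of model series: the per-energy percent
#' differences of every model against the reference, the symmetric
#' pairwise-complete RMSE matrix with the number of shared energies per
#' pair, and the maximum absolute percent difference per pair with the
#' energy at which it occurs.
#'
#' @param series named list of \code{dose_series}.
#' @param reference name of the reference series.
#' @return an object of class \code{comparison_report} with components
#'   \code{percent_diff} (energy x model data.frame vs the reference),
#'   \code{rmse} (model x model matrix), \code{n_pair} (shared-energy
#'   counts), \code{max_diff} (per-pair max |%| with energy), and
#'   \code{reference}.
#' @export
build_report <- function(series, reference) {
  nm <- vapply(series, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate model names in report")
  names(series) <- nm
  if (!reference %in% nm) stop("reference series '", reference, "' not present")
  grid <- series[[1]]$energy_MeV
  ref <- series[[reference]]

  pd <- data.frame(energy_MeV = grid)
  for (m in setdiff(nm, reference)) {
    pd[[m]] <- percent_diff(series[[m]]$values, ref$values)
  }

  k <- length(nm)
  R <- matrix(0, k, k, dimnames = list(nm, nm))
  N <- matrix(NA_integer_, k, k, dimnames = list(nm, nm))
  md <- NULL
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        N[i, j] <- sum(!is.na(series[[i]]$values))
        next
      }
      r <- rmse(series[[i]], series[[j]])
      R[i, j] <- as.numeric(r)
      N[i, j] <- attr(r, "n")
      if (i < j) {
        # percent difference of the later model against the earlier one
        # as reference ("b vs a"), matching the usual table convention
        d <- percent_diff(series[[j]]$values, series[[i]]$values)
        at <- which.max(abs(d))
        md <- rbind(md, data.frame(
          a = nm[i], b = nm[j],
          max_abs_pct = d[at], at_energy_MeV = grid[at]))
      }
    }
  }
  structure(list(percent_diff = pd, rmse = R, n_pair = N, max_diff = md,
                 reference = reference, energy_MeV = grid),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("model comparison report (reference:", x$reference, ")\n\nRMSE matrix:\n")
  print(round(x$rmse, 6))
  cat("\nshared energies per pair:\n")
  print(x$n_pair)
  invisible(x)
}

#' Write a comparison report as CSV files
#'
#' @param report a \code{comparison_report}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$percent_diff,
                   file.path(dir, "percent_differences.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$rmse),
                   file.path(dir, "rmse_matrix.csv"))
  utils::write.csv(report$max_diff,
                   file.path(dir, "max_differences.csv"), row.names = FALSE)
  invisible(dir)
}

#' Plot effective-dose series
#'
#' Line plot of ED against energy for several models, log-log axes.
#'
#' @param series named list of \code{dose_series}.
#' @param ... passed to \code{graphics::matplot}.
#' @export
plot_dose_series <- function(series, ...) {
  grid <- series[[1]]$energy_MeV
  vals <- sapply(series, `[[`, "values")
  graphics::matplot(grid, vals, type = "b", log = "xy", pch = 1,
                    xlab = "energy (MeV)", ylab = "effective dose (pSv cm^2)", ...)
  graphics::legend("topleft", legend = names(series), col = seq_along(series),
                   lty = seq_along(series), bty = "n")
  invisible(NULL)
}
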