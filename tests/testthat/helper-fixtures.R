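# shared fixtures: tiny registries and phantoms built in code

zero_comp <- function() {
  stats::setNames(as.list(rep(0, 13)),
                  c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K",
                    "Ca", "Fe", "I"))
}

registry_row <- function(id, name, density, weight_class, ...) {
  comp <- zero_comp()
  dots <- list(...)
  comp[names(dots)] <- dots
  cbind(data.frame(id = id, name = name, density = density,
                   weight_class = weight_class),
        as.data.frame(comp))
}

water_registry <- function() {
  organ_registry(registry_row(1, "water", 1.0, "remainder",
                              H = 0.1119, O = 0.8881))
}

bone_water_registry <- function() {
  organ_registry(rbind(
    registry_row(1, "water", 1.0, "remainder", H = 0.1119, O = 0.8881),
    registry_row(2, "bone", 1.92, "unscored",
                 H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001,
                 Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225)))
}

# homogeneous water block phantom
water_block <- function(nx = 20, ny = 5, nz = 5, pitch = 0.5) {
  voxel_phantom(array(1L, dim = c(nx, ny, nz)), pitch = pitch,
                registry = water_registry())
}

# all-air phantom
air_block <- function(nx = 8, ny = 8, nz = 8, pitch = 0.5) {
  voxel_phantom(array(255L, dim = c(nx, ny, nz)), pitch = pitch,
                registry = water_registry())
}

mu_water <- function(E) mixture_mu(c(H = 0.1119, O = 0.8881), E)
muen_water <- function(E) mixture_muen(c(H = 0.1119, O = 0.8881), E)

# small body phantom shared across tests (built once per test run)
small_body <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(default_body_recipe())
    ph
  }
})

# hand-built organ dose table for effective-dose unit tests
toy_dose_table <- function(dcc, registry = default_registry(),
                           energies = 0.1, sd = dcc * 0) {
  masses <- stats::setNames(rep(1, nrow(registry)), registry$id)
  structure(list(dcc = dcc, sd = sd, energies = energies,
                 organs = registry[, c("id", "name", "weight_class")],
                 masses_kg = masses, method = "toy"),
            class = "organ_dose_table")
}
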