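test_that("heating converts to dose through the physical constants", {
  tal <- structure(list(heating_eV = c(`1` = 1), sd_eV = c(`1` = 0),
                        E_MeV = 1, mode = "toy", n = NA_integer_),
                   class = "heating_tally")
  d <- heating_to_dose(tal, c(`1` = 1))
  expect_equal(d$dose_pGy, 1.602176634e-7)

  tal$heating_eV <- c(`1` = 0)
  expect_equal(heating_to_dose(tal, c(`1` = 2))$dose_pGy, 0)

  tal$heating_eV <- c(`1` = 10)
  expect_equal(heating_to_dose(tal, c(`1` = 2))$dose_pGy,
               heating_to_dose(tal, c(`1` = 1))$dose_pGy / 2)

  expect_error(heating_to_dose(tal, c(`9` = 1)), "missing mass.*1")
})

test_that("fluence normalization yields particle-count-invariant DCCs", {
  expect_equal(normalize_to_fluence(2, 2), 1)
  expect_error(normalize_to_fluence(1, 0), "positive")

  slab <- generate_slab_phantom(list(list(id = 1, thickness = 6)),
                                pitch = 0.5, ny = 4, nz = 4,
                                registry = water_registry())
  src <- ap_source(slab)
  flu <- fluence_tally(src)
  masses <- phantom_masses(slab) / 1000
  run_dcc <- function(n, seed) {
    h <- mc_transport(slab, src, 0.1, n = n, seed = seed, scatter = FALSE)
    d <- heating_to_dose(h$heating, masses)
    list(dcc = normalize_to_fluence(d$dose_pGy, flu),
         sd = normalize_to_fluence(d$sd_pGy, flu))
  }
  a <- run_dcc(2e4, 1)
  b <- run_dcc(4e4, 2)
  z <- abs(a$dcc - b$dcc) / sqrt(a$sd^2 + b$sd^2)
  expect_lt(z, 4)

  # deterministic engine: DCC independent of source area when the beam
  # fully covers the phantom
  dcc_for <- function(src) {
    tal <- deposit_kerma(slab, src, 0.1)
    normalize_to_fluence(heating_to_dose(tal, masses)$dose_pGy,
                         fluence_tally(src))
  }
  s1 <- plane_source(-10, c(-2, 2), c(-2, 2))
  s2 <- plane_source(-10, c(-8, 8), c(-8, 8))
  expect_equal(dcc_for(s1), dcc_for(s2), tolerance = 1e-9)
})

test_that("tissue weights must sum to one and default to ICRP-103", {
  w <- tissue_weights()
  expect_equal(sum(w$weights) + w$remainder_weight, 1)
  expect_error(tissue_weights(c(red_marrow = 0.5), remainder_weight = 0.2),
               "sum to exactly 1")
})

test_that("uniform organ doses collapse to that dose as effective dose", {
  reg <- default_registry()
  d <- 3.7
  dcc <- matrix(d, nrow(reg), 1, dimnames = list(reg$id, "0.1"))
  ed <- effective_dose(toy_dose_table(dcc, reg))
  expect_equal(ed$ED, d, tolerance = 1e-12)
})

test_that("remainder-only doses contribute with weight 0.12", {
  reg <- default_registry()
  d <- 2.5
  dcc <- matrix(0, nrow(reg), 1, dimnames = list(reg$id, "0.1"))
  dcc[reg$weight_class == "remainder", 1] <- d
  ed <- effective_dose(toy_dose_table(dcc, reg))
  expect_equal(ed$ED, 0.12 * d, tolerance = 1e-12)
})

test_that("a three-organ toy table reproduces the hand-computed sum", {
  reg <- organ_registry(rbind(
    registry_row(1, "lungs", 1, "weighted", H = 1),
    registry_row(2, "thyroid", 1, "weighted", H = 1),
    registry_row(3, "heart", 1, "remainder", H = 1)))
  w <- tissue_weights(weights = c(lungs = 0.5, thyroid = 0.3),
                      remainder_weight = 0.2, combine = character())
  dcc <- matrix(c(2, 4, 10), 3, 1, dimnames = list(reg$id, "0.1"))
  ed <- effective_dose(toy_dose_table(dcc, reg), w)
  expect_equal(ed$ED, 0.5 * 2 + 0.3 * 4 + 0.2 * 10)
})

test_that("effective dose is linear, bounded and remainder-permutation-invariant", {
  reg <- default_registry()
  set.seed(3)
  for (i in 1:5) {
    v <- runif(nrow(reg), 0, 10)
    dcc <- matrix(v, nrow(reg), 1, dimnames = list(reg$id, "0.1"))
    ed <- effective_dose(toy_dose_table(dcc, reg))$ED
    expect_gte(ed, min(v) - 1e-12)
    expect_lte(ed, max(v) + 1e-12)
    # linearity
    ed2 <- effective_dose(toy_dose_table(2 * dcc, reg))$ED
    expect_equal(ed2, 2 * ed, tolerance = 1e-12)
    # permute doses within the remainder set
    rem <- which(reg$weight_class == "remainder")
    v2 <- v
    v2[rem] <- v[sample(rem)]
    dccp <- matrix(v2, nrow(reg), 1, dimnames = list(reg$id, "0.1"))
    expect_equal(effective_dose(toy_dose_table(dccp, reg))$ED, ed,
                 tolerance = 1e-12)
  }
})

test_that("missing weighted organs are reported by name", {
  reg <- organ_registry(rbind(
    registry_row(1, "lungs", 1, "weighted", H = 1),
    registry_row(3, "heart", 1, "remainder", H = 1)))
  dcc <- matrix(1, 2, 1, dimnames = list(reg$id, "0.1"))
  expect_error(effective_dose(toy_dose_table(dcc, reg)), "stomach")
})

test_that("colon halves combine by mass-weighted mean dose", {
  reg <- default_registry()
  dcc <- matrix(0, nrow(reg), 1, dimnames = list(reg$id, "0.1"))
  iu <- which(reg$name == "colon_upper")
  il <- which(reg$name == "colon_lower")
  dcc[iu, 1] <- 6
  dcc[il, 1] <- 2
  masses <- stats::setNames(rep(1, nrow(reg)), reg$id)
  masses[as.character(reg$id[iu])] <- 3  # upper colon three times heavier
  tab <- toy_dose_table(dcc, reg)
  tab$masses_kg <- masses
  ed <- effective_dose(tab)
  expect_equal(ed$ED, 0.12 * (3 * 6 + 1 * 2) / 4, tolerance = 1e-12)
})

test_that("the full pipeline produces dose tables on the synthetic body", {
  ph <- small_body()
  odt <- organ_dose_table(ph, energies = c(0.08, 0.3))
  expect_identical(dim(odt$dcc), c(30L, 2L))
  expect_true(all(odt$dcc >= 0))
  ed <- effective_dose(odt)
  expect_true(all(ed$ED > 0))
  expect_lt(ed$ED[1], ed$ED[2])
  # superficial organs see more dose than deep ones at low energy
  skin_row <- which(odt$organs$name == "skin")
  bladder_row <- which(odt$organs$name == "bladder")
  low <- organ_dose_table(ph, energies = 0.02)
  expect_gt(low$dcc[skin_row, 1], low$dcc[bladder_row, 1])
})
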