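# a degenerate couple whose mole fractions are both 1 at high pH: monoprotic
# thiolate monomer and a single very acidic dummy site on the dimer
standard_state_system <- function(c_red = 1, c_ox = 1, e0 = -0.3157) {
  monomer <- monoprotic_thiol_system(8)
  dimer <- generate_consistent_microconstants(c(D = -20))
  redox_pair_system(monomer, dimer,
                    list(list(reduced = character(0),
                              oxidized = character(0), e0 = e0)),
                    c_red_total = c_red, c_ox_total = c_ox)
}

test_that("pair potentials obey the Nernst stoichiometry", {
  # at unit concentrations and unit mole fractions the potential is E0
  sys <- standard_state_system()
  expect_equal(pair_potential(sys, 1, pH = 30), -0.3157)

  # one decade more oxidized total raises E by (RT/2F) ln 10
  up <- standard_state_system(c_ox = 10)
  expect_equal(pair_potential(up, 1, 30) - pair_potential(sys, 1, 30),
               NERNST_2E * log(10), tolerance = 1e-12)

  # doubling the reduced side lowers E by (RT/2F) ln 4 (squared stoichiometry)
  dbl <- standard_state_system(c_red = 2)
  expect_equal(pair_potential(dbl, 1, 30) - pair_potential(sys, 1, 30),
               -NERNST_2E * log(4), tolerance = 1e-12)

  # vanishing mole fractions stay finite through the log-space route
  expect_true(all(is.finite(pair_potential(sys, 1, c(-10, 0, 14, 30)))))
})

test_that("single-pair apparent profiles degenerate to the pair potential", {
  sys <- standard_state_system()
  pH <- seq(0, 14, by = 0.25)
  prof <- apparent_potential(sys, pH)
  expect_equal(prof$E_app, pair_potential(sys, 1, pH))
  expect_equal(prof$E_sd, rep(0, length(pH)))
  expect_equal(prof$w_1, rep(1, length(pH)))
})

test_that("equal-weight pairs average symmetrically", {
  monomer <- monoprotic_thiol_system(8)
  dimer <- generate_consistent_microconstants(c(D = -20))
  two <- redox_pair_system(monomer, dimer, list(
    list(reduced = character(0), oxidized = character(0), e0 = -0.30),
    list(reduced = character(0), oxidized = character(0), e0 = -0.40)))
  prof <- apparent_potential(two, pH = c(2, 7, 12))
  expect_equal(prof$E_app, (prof$E_1 + prof$E_2) / 2)
})

test_that("the four-pair aminothiol profile matches the longhand weighted mean", {
  monomer <- example_aminothiol_system()
  dimer <- example_disulfide_system()
  model <- basicity_redox_model()
  sys <- build_pairs_from_basicity(monomer, dimer, model, aminothiol_pairing())
  expect_length(sys$pairs, 4)

  set.seed(7)
  pH <- stats::runif(100, 2, 12)
  prof <- apparent_potential(sys, sort(pH))

  # longhand: chi from the naive linear-space oracle, Nernst and the
  # abundance-weighted mean written out term by term
  reduced <- list(character(0), "N", "O", c("N", "O"))
  oxidized <- list(character(0), c("N1", "N2"), c("O1", "O2"),
                   c("N1", "N2", "O1", "O2"))
  e0 <- vapply(reduced, function(r)
    predict_e0(model, oracle_logk(monomer, "S", r)), numeric(1))
  for (i in seq_along(prof$pH)) {
    p <- prof$pH[i]
    chi_r <- vapply(reduced, function(r)
      oracle_chi_state(monomer, p, r), numeric(1))
    chi_o <- vapply(oxidized, function(o)
      oracle_chi_state(dimer, p, o), numeric(1))
    E <- e0 - NERNST_2E * log(chi_r^2 / chi_o)
    w <- chi_r * chi_o
    expect_equal(prof$E_app[i], sum(w * E) / sum(w), tolerance = 1e-10)
  }

  # convex combination: E_app bounded by the per-pair potentials
  Emat <- as.matrix(prof[, paste0("E_", 1:4)])
  expect_true(all(prof$E_app >= apply(Emat, 1, min) - 1e-12))
  expect_true(all(prof$E_app <= apply(Emat, 1, max) + 1e-12))

  # band columns exist since pair standard errors were propagated
  expect_true(all(prof$band_low <= prof$E_app & prof$E_app <= prof$band_high))
})

test_that("profiles are invariant to the s / s^2 concentration scaling", {
  monomer <- example_aminothiol_system()
  dimer <- example_disulfide_system()
  model <- basicity_redox_model()
  base <- build_pairs_from_basicity(monomer, dimer, model,
                                    aminothiol_pairing())
  scaled <- build_pairs_from_basicity(monomer, dimer, model,
                                      aminothiol_pairing(),
                                      c_red_total = 3, c_ox_total = 9)
  pH <- seq(1, 13, by = 0.5)
  expect_equal(apparent_potential(base, pH)$E_app,
               apparent_potential(scaled, pH)$E_app, tolerance = 1e-12)
})

test_that("a monoprotic couple shows the two-proton Nernst slope below logk and flattens above", {
  sys <- standard_state_system()
  # below logk: dE/dpH -> -(RT/F) ln 10 (two protons per two electrons)
  pH_lo <- c(2, 3)
  E_lo <- pair_potential(sys, 1, pH_lo)
  expect_equal(diff(E_lo) / diff(pH_lo), -2 * NERNST_2E * log(10),
               tolerance = 1e-4)
  # above logk the profile flattens
  pH_hi <- c(12, 13)
  expect_lt(abs(diff(pair_potential(sys, 1, pH_hi))), 1e-3)
  # and is monotone non-increasing throughout
  prof <- apparent_potential(sys, seq(0, 14, by = 0.05))
  expect_true(all(diff(prof$E_app) <= 1e-12))
})

test_that("invalid pairings are rejected", {
  monomer <- example_aminothiol_system()
  dimer <- example_disulfide_system()
  expect_error(
    redox_pair_system(monomer, dimer,
                      list(list(reduced = "S", oxidized = character(0),
                                e0 = -0.3))),
    "protonated redox site")
  expect_error(
    build_pairs_from_basicity(monomer, dimer, basicity_redox_model(),
                              list(list(reduced = c("N", "S"),
                                        oxidized = c("N1", "N2")))),
    "protonated redox site")
  expect_error(
    redox_pair_system(monomer, dimer, list(), c_red_total = 1),
    "non-empty")
  expect_error(
    redox_pair_system(monomer, dimer,
                      list(list(reduced = "N", oxidized = "N1", e0 = 0)),
                      c_red_total = -1),
    "positive")
})
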