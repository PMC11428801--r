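test_that("microstate enumeration covers every protonation subset once, in canonical order", {
  sys3 <- example_aminothiol_system()
  ms <- enumerate_microstates(sys3)
  expect_equal(nrow(ms), 8)
  expect_equal(ms$h, c(0, 1, 1, 1, 2, 2, 2, 3))
  expect_equal(anyDuplicated(ms$protonated_sites), 0L)
  expect_equal(ms$letter, letters[1:8])
  # conventional lettering: b is N-protonated, f is the N,O species
  expect_equal(ms$protonated_sites[ms$letter == "b"], "N")
  expect_equal(ms$protonated_sites[ms$letter == "f"], "NO")

  sys1 <- monoprotic_thiol_system(8)
  expect_equal(nrow(enumerate_microstates(sys1)), 2)

  sys4 <- example_disulfide_system()
  ms4 <- enumerate_microstates(sys4)
  expect_equal(nrow(ms4), 16)
  expect_equal(ms4$letter, paste0(letters[1:16], "'"))
  # dimer pairing anchors: f' = both amines, k' = both carboxylates
  expect_equal(ms4$protonated_sites[ms4$letter == "f'"], "N1N2")
  expect_equal(ms4$protonated_sites[ms4$letter == "k'"], "O1O2")

  expect_error(generate_consistent_microconstants(numeric(0)),
               "at least one basic site")
})

test_that("macroscopic constants collapse correctly from the microscopic set", {
  # three equivalent independent sites: K_p1 is the sum of the microconstants
  sym <- generate_consistent_microconstants(c(A = 5, B = 5, C = 5))
  mac <- macro_from_micro(sym)
  expect_equal(mac$log_Kp[1], 5 + log10(3), tolerance = 1e-12)

  # single site: beta_1 = K_p1 = the lone microconstant
  one <- monoprotic_thiol_system(8)
  mac1 <- macro_from_micro(one)
  expect_equal(mac1$log_beta, 8)
  expect_equal(mac1$log_Kp, 8)

  # beta_2 longhand: k^N k^S_N + k^S k^O_S + k^N k^O_N, and the equivalent
  # alternative path products must agree
  sys <- example_aminothiol_system()
  b2_a <- log10(10^(oracle_logk(sys, "N", c()) + oracle_logk(sys, "S", "N")) +
                10^(oracle_logk(sys, "S", c()) + oracle_logk(sys, "O", "S")) +
                10^(oracle_logk(sys, "N", c()) + oracle_logk(sys, "O", "N")))
  b2_b <- log10(10^(oracle_logk(sys, "S", c()) + oracle_logk(sys, "N", "S")) +
                10^(oracle_logk(sys, "O", c()) + oracle_logk(sys, "S", "O")) +
                10^(oracle_logk(sys, "O", c()) + oracle_logk(sys, "N", "O")))
  expect_equal(b2_a, b2_b, tolerance = 1e-12)
  expect_equal(macro_from_micro(sys)$log_beta[2], b2_a, tolerance = 1e-10)

  # beta_n is the single full-protonation path product
  expect_equal(macro_from_micro(sys)$log_beta[3],
               oracle_path_logsum(sys, c(1, 2, 3)), tolerance = 1e-10)
})

test_that("mole fractions hit the protonation limits and the macroscopic closed form", {
  sys <- example_aminothiol_system()
  hi <- mole_fractions(sys, 30)$chi
  expect_equal(unname(hi[1, 1]), 1, tolerance = 1e-12)  # first column: empty state
  lo <- mole_fractions(sys, -10)$chi
  expect_equal(unname(lo[1, "NSO"]), 1, tolerance = 1e-9)

  # fully deprotonated chi equals 1/(1 + sum_i beta_i [H+]^i)
  mac <- macro_from_micro(sys)
  for (pH in c(2, 5, 7, 9.5, 12)) {
    closed <- 1 / (1 + sum(10^(mac$log_beta - seq_along(mac$log_beta) * pH)))
    expect_equal(unname(mole_fractions(sys, pH)$chi[1, 1]), closed,
                 tolerance = 1e-12)
  }
})

test_that("generator produces closure-consistent systems with additive energetics", {
  # zero interactions: every context shares the site's intrinsic constant
  ind <- generate_consistent_microconstants(c(N = 9, S = 7, O = 3))
  for (si in 1:3) {
    vals <- ind$logk[si, !is.na(ind$logk[si, ])]
    expect_equal(unname(vals), rep(c(9, 7, 3)[si], 4))
  }

  # uniform -0.5 interactions: all 6 full-protonation paths sum identically
  M <- matrix(-0.5, 3, 3); diag(M) <- 0
  sys <- generate_consistent_microconstants(c(10.5, 8.5, 2.5), interaction = M)
  paths <- oracle_all_path_logsums(sys, 7L)
  expect_length(paths, 6)
  expect_equal(paths, rep(10.5 + 8.5 + 2.5 - 3 * 0.5, 6), tolerance = 1e-12)

  # seeded draws are reproducible and leave the caller's RNG untouched
  set.seed(424242)
  before <- .Random.seed
  a <- random_microstate_system(3, seed = 11)
  expect_identical(.Random.seed, before)
  b <- random_microstate_system(3, seed = 11)
  expect_identical(a$logk, b$logk)

  expect_error(
    generate_consistent_microconstants(c(5, 6),
      interaction = matrix(c(0, -1, -2, 0), 2, 2)),
    "symmetric")
  expect_error(
    generate_consistent_microconstants(c(5, 6),
      interaction = matrix(c(1, -1, -1, 0), 2, 2)),
    "zero diagonal")
})

test_that("hand-built microconstant sets are validated for completeness and closure", {
  # a consistent 2-site set built entry by entry round-trips fine
  entries <- data.frame(site = c("N", "N", "S", "S"),
                        context = c("", "S", "", "N"),
                        logk = c(9, 8.5, 7, 6.5))
  sys <- microstate_system(c("N", "S"), entries)
  expect_equal(macro_from_micro(sys)$log_beta[2], 9 + 6.5, tolerance = 1e-12)

  # breaking one path by 0.1 log units must be rejected, not averaged
  bad <- entries
  bad$logk[4] <- 6.6   # N-then-S path no longer matches S-then-N
  bad$logk[2] <- 8.4
  expect_error(microstate_system(c("N", "S"), bad), "cycle closure")

  # a missing context is reported with its (site | {context}) identifier
  expect_error(microstate_system(c("N", "S"), entries[-4, ]),
               "(S | {N})", fixed = TRUE)
  expect_error(microstate_system(c("N", "S"), rbind(entries, entries[1, ])),
               "duplicate")
})

test_that("random cycle-closed systems keep unit chi sums, path independence and the macro closed form", {
  for (seed in 1:25) {
    n <- 1 + (seed %% 4)
    sys <- random_microstate_system(n, seed = seed)
    pH <- stats::runif(12, -2, 16)
    spec <- mole_fractions(sys, pH)
    expect_true(all(abs(rowSums(spec$chi) - 1) < 1e-12))

    # every protonation path to every microstate gives the same log product
    for (m in 0:(2^n - 1L)) {
      paths <- oracle_all_path_logsums(sys, m)
      expect_lt(max(paths) - min(paths), 1e-9)
    }

    # macroscopic closed form vs microstate-sum chi of the empty state
    mac <- macro_from_micro(sys)
    for (p in stats::runif(5, 0, 14)) {
      closed <- 1 / (1 + sum(10^(mac$log_beta - seq_len(n) * p)))
      micro <- unname(mole_fractions(sys, p)$chi[1, 1])
      expect_equal(micro, closed, tolerance = 1e-10)
    }
  }
})

test_that("each microstate's mole fraction is unimodal in pH", {
  sys <- example_aminothiol_system()
  pH <- seq(-2, 16, by = 0.01)
  chi <- mole_fractions(sys, pH)$chi
  for (j in seq_len(ncol(chi))) {
    d <- diff(chi[, j])
    s <- sign(d[abs(d) > 1e-15])
    # once decreasing, never increasing again: at most one +/- sign change
    flips <- sum(diff(s) != 0)
    expect_lte(flips, 1)
  }
})
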