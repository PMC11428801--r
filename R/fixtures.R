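#' Monoprotic thiol system
#'
#' The smallest useful speciation system: a single thiolate site with the
#' given log basicity, two microstates (thiolate and thiol). This is the
#' model behind the design surface and a convenient degenerate case for the
#' redox-profile machinery.
#'
#' @param logk thiolate log10 protonation constant.
#' @param chalcogen `"S"` or `"Se"`.
#' @return a [microstate_system()].
#' @examples
#' mole_fractions(monoprotic_thiol_system(8), pH = 8)$chi  # 0.5 / 0.5
#' @export
monoprotic_thiol_system <- function(logk = 8, chalcogen = "S") {
  generate_consistent_microconstants(stats::setNames(logk, "S"),
                                     redox_site = "S",
                                     chalcogen = chalcogen)
}

#' Synthetic cysteine-like aminothiol system (three basic sites)
#'
#' A synthetic three-site ligand with amino (N), thiolate (S) and
#' carboxylate (O) groups, built from plausible intrinsic basicities and
#' negative pairwise interaction terms. The values are illustrative, chosen
#' to resemble a generic aminothiol amino acid; they are NOT experimental
#' microconstants of cysteine or any other real compound. The system is
#' cycle-closed by construction and carries the conventional a..h species
#' lettering.
#'
#' @return a [microstate_system()] with 8 microstates and 12 microconstants.
#' @examples
#' enumerate_microstates(example_aminothiol_system())
#' @export
example_aminothiol_system <- function() {
  M <- matrix(c(0, -0.6, -0.4,
                -0.6, 0, -0.3,
                -0.4, -0.3, 0), 3, 3, byrow = TRUE)
  generate_consistent_microconstants(
    c(N = 10.5, S = 8.5, O = 2.2), interaction = M,
    redox_site = "S", chalcogen = "S")
}

#' Synthetic cystine-like disulfide system (four basic sites)
#'
#' The oxidized dimer partner of [example_aminothiol_system()]: two amino
#' (N1, N2) and two carboxylate (O1, O2) sites, the thiol protons being
#' consumed by the disulfide bond. Synthetic illustrative values, not
#' experimental cystine microconstants. Carries the a'..p' species
#' lettering.
#'
#' @return a [microstate_system()] with 16 microstates and 32 microconstants.
#' @export
example_disulfide_system <- function() {
  labels <- c("N1", "N2", "O1", "O2")
  M <- matrix(-0.2, 4, 4, dimnames = list(labels, labels))
  M["N1", "N2"] <- M["N2", "N1"] <- -0.4
  M["O1", "O2"] <- M["O2", "O1"] <- -0.1
  diag(M) <- 0
  generate_consistent_microconstants(
    c(N1 = 9.2, N2 = 9.2, O1 = 1.9, O2 = 1.9), interaction = M,
    labels = labels)
}

#' Canonical monomer/dimer pairing for the aminothiol fixture
#'
#' The four matched microspecies redox pairs of the synthetic
#' aminothiol/disulfide couple: each thiolate-bearing monomer microstate
#' (redox site deprotonated) is paired with the dimer microstate whose two
#' halves carry the same protonation pattern. In the conventional species
#' lettering these are the pairs a'/a, f'/b, k'/d and p'/f.
#'
#' @return list of four `list(reduced=, oxidized=)` entries, suitable for
#'   [build_pairs_from_basicity()].
#' @export
aminothiol_pairing <- function() {
  list(
    list(reduced = character(0), oxidized = character(0)),       # a'/a
    list(reduced = "N", oxidized = c("N1", "N2")),               # f'/b
    list(reduced = "O", oxidized = c("O1", "O2")),               # k'/d
    list(reduced = c("N", "O"),
         oxidized = c("N1", "N2", "O1", "O2"))                   # p'/f
  )
}
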