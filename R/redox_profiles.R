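#' Matched monomer/dimer microspecies redox pairs
#'
#' A thiol-disulfide couple (e.g. cysteine/cystine) is a family of
#' two-electron half-reactions between matched microspecies: a
#' thiolate-bearing monomer microstate (redox site deprotonated) and the
#' dimer microstate obtained by oxidatively joining two such monomers. Each
#' pair carries its own species-specific standard potential. This container
#' bundles the monomer and dimer speciation systems, the pair list and the
#' analytical total concentrations of both forms.
#'
#' @param monomer [microstate_system()] of the reduced (thiol) form, with
#'   exactly one site flagged as the redox site.
#' @param dimer [microstate_system()] of the oxidized (disulfide) form,
#'   with its own complete microconstant set.
#' @param pairs list of pairs; each element is a list with `reduced` and
#'   `oxidized` (character vectors of protonated site labels in the
#'   respective systems), `e0` (V) and optionally `se_e0` (V).
#' @param c_red_total,c_ox_total total concentrations of the reduced and
#'   oxidized forms in mol/L (> 0). The conventional choice 1 mol/L for both
#'   makes profiles concentration-standardized; different totals give
#'   different curves.
#' @return object of class `redox_pair_system`.
#' @seealso [build_pairs_from_basicity()] to derive the pair potentials from
#'   thiolate basicities, [pair_potential()], [apparent_potential()].
#' @export
redox_pair_system <- function(monomer, dimer, pairs,
                              c_red_total = 1, c_ox_total = 1) {
  stopifnot(inherits(monomer, "microstate_system"),
            inherits(dimer, "microstate_system"))
  if (!is.list(pairs) || length(pairs) == 0L) {
    stop("'pairs' must be a non-empty list")
  }
  if (!is.finite(c_red_total) || !is.finite(c_ox_total) ||
      c_red_total <= 0 || c_ox_total <= 0) {
    stop("total concentrations must be positive")
  }
  ri <- which(monomer$sites$is_redox_site)
  if (length(ri) != 1L) {
    stop("the monomer must have exactly one flagged redox site")
  }
  rbit <- bitwShiftL(1L, ri - 1L)

  parsed <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (!is.list(p) || is.null(p$e0)) {
      stop("pair ", i, " must be a list with 'reduced', 'oxidized', 'e0'")
    }
    red_mask <- state_mask(monomer, p$reduced)
    ox_mask <- state_mask(dimer, p$oxidized)
    if (bitwAnd(red_mask, rbit) > 0L) {
      stop("invalid pairing: reduced microstate '",
           monomer$state_labels[red_mask + 1L],
           "' has a protonated redox site")
    }
    list(red_mask = red_mask, ox_mask = ox_mask,
         e0 = as.numeric(p$e0),
         se_e0 = if (is.null(p$se_e0)) NA_real_ else as.numeric(p$se_e0),
         label = paste0(dimer$state_labels[ox_mask + 1L], "/",
                        monomer$state_labels[red_mask + 1L]))
  })

  structure(list(monomer = monomer, dimer = dimer, pairs = parsed,
                 c_red_total = c_red_total, c_ox_total = c_ox_total,
                 z = 2L, redox_site = monomer$sites$label[ri]),
            class = "redox_pair_system")
}

#' @export
print.redox_pair_system <- function(x, ...) {
  cat("Thiol-disulfide redox pair system:", length(x$pairs), "pair(s)\n")
  cat(sprintf("  totals: reduced %g mol/L, oxidized %g mol/L, z = %d\n",
              x$c_red_total, x$c_ox_total, x$z))
  for (p in x$pairs) {
    cat(sprintf("  %-12s E0 = %+.4f V\n",
                ifelse(nzchar(p$label), p$label, "/"), p$e0))
  }
  invisible(x)
}

#' Nernst potential of one microspecies redox pair at given pH
#'
#' Evaluates
#' `E = E0 - RT/(2F) * ln( (c_red_total * chi_red)^2 /
#' (c_ox_total * chi_ox) )` for one matched monomer/dimer pair. The mole
#' fractions enter through their log10 values, so vanishing abundances at
#' extreme pH produce large but finite potentials rather than division
#' errors.
#'
#' @param system a [redox_pair_system()].
#' @param pair index into `system$pairs` (or one such pair element).
#' @param pH numeric vector.
#' @param temperature kelvin.
#' @return numeric vector of potentials in V.
#' @export
pair_potential <- function(system, pair, pH, temperature = 298.15) {
  stopifnot(inherits(system, "redox_pair_system"))
  if (!is.list(pair)) pair <- system$pairs[[pair]]
  red_chi <- log10_chi_mask(system$monomer, pair$red_mask, pH)
  ox_chi <- log10_chi_mask(system$dimer, pair$ox_mask, pH)
  nf <- nernst_factor(temperature, system$z)
  # ln(arg) = ln10 * [ 2 log10(c_red chi_red) - log10(c_ox chi_ox) ]
  l10arg <- 2 * (log10(system$c_red_total) + red_chi) -
    (log10(system$c_ox_total) + ox_chi)
  pair$e0 - nf * .LN10 * l10arg
}

# log10 mole fraction of a single microstate (by mask) over a pH vector
log10_chi_mask <- function(system, mask, pH) {
  G <- system$G
  h <- system$h
  vapply(pH, function(p) {
    lw <- G - h * p
    lw[mask + 1L] - lse10(lw)
  }, numeric(1))
}

#' Abundance-weighted apparent redox potential profile
#'
#' At each pH the potentials of all microspecies redox pairs are combined
#' into the apparent (conditional) potential by weighting each pair with the
#' product of its reduced and oxidized mole fractions,
#' `w_i = chi_red,i * chi_ox,i`, which measures the relative abundance of
#' that pair: `E_app = sum(w_i E_i) / sum(w_i)`. The weighted standard
#' deviation across pairs is reported alongside. This weighted mean is the
#' conventional heuristic average, not a simultaneous common-potential
#' equilibrium solve. Weights are normalized in log space, so the profile
#' has no gaps even where every individual abundance product underflows.
#'
#' When the pairs carry standard errors on their `e0` (e.g. from
#' [build_pairs_from_basicity()]), an approximate confidence band is
#' propagated by the delta method treating the chi weights as exact.
#'
#' @param system a [redox_pair_system()].
#' @param pH numeric grid (default 0..14 step 0.01).
#' @param temperature kelvin.
#' @param level confidence level for the band.
#' @return data.frame of class `apparent_potential_profile` with columns
#'   `pH`, one `E_<i>` and `w_<i>` per pair (weights normalized to sum 1),
#'   `E_app`, `E_sd`, and `band_low`/`band_high` when pair standard errors
#'   are available. Pair labels are kept in `attr(, "pair_labels")`.
#' @export
apparent_potential <- function(system, pH = seq(0, 14, by = 0.01),
                               temperature = 298.15, level = 0.95) {
  stopifnot(inherits(system, "redox_pair_system"))
  np <- length(system$pairs)
  E <- matrix(NA_real_, nrow = length(pH), ncol = np)
  l10w <- matrix(NA_real_, nrow = length(pH), ncol = np)
  se <- vapply(system$pairs, function(p) p$se_e0, numeric(1))
  for (j in seq_len(np)) {
    p <- system$pairs[[j]]
    E[, j] <- pair_potential(system, p, pH, temperature)
    l10w[, j] <- log10_chi_mask(system$monomer, p$red_mask, pH) +
      log10_chi_mask(system$dimer, p$ox_mask, pH)
  }
  w <- t(apply(l10w, 1L, function(lw) 10^(lw - lse10(lw))))
  if (np == 1L) w <- matrix(1, nrow = length(pH), ncol = 1L)
  e_app <- rowSums(w * E)
  e_sd <- sqrt(pmax(rowSums(w * (E - e_app)^2), 0))

  out <- data.frame(pH = pH)
  for (j in seq_len(np)) out[[paste0("E_", j)]] <- E[, j]
  for (j in seq_len(np)) out[[paste0("w_", j)]] <- w[, j]
  out$E_app <- e_app
  out$E_sd <- e_sd
  if (all(is.finite(se))) {
    se_app <- sqrt(rowSums((w^2) %*% diag(se^2, np)))
    z <- stats::qnorm((1 + level) / 2)
    out$band_low <- e_app - z * se_app
    out$band_high <- e_app + z * se_app
  }
  attr(out, "pair_labels") <- vapply(system$pairs, `[[`, character(1), "label")
  class(out) <- c("apparent_potential_profile", "data.frame")
  out
}

#' Assemble a redox pair system from thiolate basicities
#'
#' Derives the species-specific standard potential of every matched
#' monomer/dimer pair from the monomer's thiolate basicity in that pair's
#' protonation context, via the calibrated basicity-to-potential model: the
#' relevant `logk` is the microscopic constant for protonating the redox
#' site given the reduced microstate's other-site protonation pattern. Pair
#' standard errors come from the model's delta-method prediction error.
#'
#' @param monomer,dimer [microstate_system()] objects (monomer must have
#'   exactly one redox site, deprotonated in every reduced pairing state).
#' @param model a [basicity_redox_model()].
#' @param pairing list of `list(reduced = <labels>, oxidized = <labels>)`
#'   entries naming the matched microstates.
#' @param c_red_total,c_ox_total totals in mol/L.
#' @return a [redox_pair_system()] with per-pair `e0` and `se_e0` filled in.
#' @examples
#' sys <- build_pairs_from_basicity(
#'   example_aminothiol_system(), example_disulfide_system(),
#'   basicity_redox_model(), aminothiol_pairing())
#' length(sys$pairs)  # 4
#' @export
build_pairs_from_basicity <- function(monomer, dimer, model, pairing,
                                      c_red_total = 1, c_ox_total = 1) {
  stopifnot(inherits(monomer, "microstate_system"),
            inherits(dimer, "microstate_system"),
            inherits(model, "basicity_redox_model"))
  ri <- which(monomer$sites$is_redox_site)
  if (length(ri) != 1L) {
    stop("the monomer must have exactly one flagged redox site")
  }
  rbit <- bitwShiftL(1L, ri - 1L)
  pairs <- lapply(pairing, function(p) {
    red_mask <- state_mask(monomer, p$reduced)
    if (bitwAnd(red_mask, rbit) > 0L) {
      stop("invalid pairing: reduced microstate '",
           monomer$state_labels[red_mask + 1L],
           "' has a protonated redox site")
    }
    logk <- unname(monomer$logk[ri, red_mask + 1L])
    list(reduced = p$reduced, oxidized = p$oxidized,
         e0 = predict_e0(model, logk),
         se_e0 = e0_standard_error(model, logk))
  })
  redox_pair_system(monomer, dimer, pairs,
                    c_red_total = c_red_total, c_ox_total = c_ox_total)
}
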