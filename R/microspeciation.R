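#' Protonation microstate system of a polyprotic ligand
#'
#' Builds the complete microspeciation scheme of a ligand with `n` basic
#' sites: all `2^n` protonation microstates and the `n * 2^(n-1)` microscopic
#' log10 protonation constants connecting them (one per site per protonation
#' context of the remaining sites). The constructor validates completeness of
#' the microconstant set and thermodynamic cycle closure: the summed log
#' microconstants along any protonation path between two microstates must be
#' path-invariant. Inputs violating closure beyond `tol` are rejected rather
#' than averaged, so data errors surface immediately.
#'
#' Microstates are kept in a canonical order: by proton count, then by the
#' site-order bitmask ascending. For 3-site and 4-site ligands the
#' customary one-letter species tags (`a`..`h`, and `a'`..`p'` for the
#' disulfide dimer) are attached as documentation metadata in that order;
#' for the amino/thiolate/carboxylate site order N, S, O this reproduces the
#' usual lettering in which, e.g., species `b` is the N-protonated monomer
#' and `f` the N,O-protonated one.
#'
#' @param sites either a character vector of unique site labels, or a
#'   data.frame with columns `label`, and optionally `is_redox_site`
#'   (logical, marks the thiolate/selenolate moiety) and `chalcogen`
#'   (`"S"` or `"Se"`, meaningful only for redox sites).
#' @param micro_logk data.frame with columns `site` (label of the site being
#'   protonated), `context` (the other sites already protonated: either a
#'   list-column of character vectors or comma-separated strings, `""` for
#'   the empty context) and `logk` (log10 microscopic protonation constant).
#'   Exactly one entry per (site, context) combination is required.
#' @param tol cycle-closure tolerance on the log10 scale.
#' @return An object of class `microstate_system`.
#' @seealso [generate_consistent_microconstants()] for building consistent
#'   systems from site basicities and pairwise interaction terms,
#'   [enumerate_microstates()], [macro_from_micro()], [mole_fractions()].
#' @examples
#' sys <- microstate_system(
#'   sites = "S",
#'   micro_logk = data.frame(site = "S", context = "", logk = 8))
#' mole_fractions(sys, pH = 8)$chi
#' @export
microstate_system <- function(sites, micro_logk, tol = 1e-9) {
  sites <- normalize_sites(sites)
  n <- nrow(sites)
  nstates <- 2L^n
  labels <- sites$label

  if (!is.data.frame(micro_logk) ||
      !all(c("site", "context", "logk") %in% names(micro_logk))) {
    stop("'micro_logk' must be a data.frame with columns site, context, logk")
  }

  logk <- matrix(NA_real_, nrow = n, ncol = nstates,
                 dimnames = list(labels, NULL))
  for (e in seq_len(nrow(micro_logk))) {
    site <- as.character(micro_logk$site[[e]])
    si <- match(site, labels)
    if (is.na(si)) stop("unknown site label in micro_logk: '", site, "'")
    ctx <- parse_context(micro_logk$context[[e]])
    ci <- match(ctx, labels)
    if (anyNA(ci)) {
      stop("unknown context label(s) in micro_logk entry for site '", site, "'")
    }
    if (si %in% ci) {
      stop("site '", site, "' cannot appear in its own protonation context")
    }
    cmask <- sum(bitwShiftL(1L, ci - 1L))
    if (!is.na(logk[si, cmask + 1L])) {
      stop("duplicate microconstant entry ", context_id(site, ctx))
    }
    logk[si, cmask + 1L] <- as.numeric(micro_logk$logk[[e]])
  }

  # completeness: each site needs one constant for every context mask that
  # excludes the site itself -> n * 2^(n-1) entries in total
  missing <- character(0)
  for (si in seq_len(n)) {
    for (cmask in 0:(nstates - 1L)) {
      if (bitwAnd(cmask, bitwShiftL(1L, si - 1L)) > 0L) next
      if (is.na(logk[si, cmask + 1L])) {
        missing <- c(missing,
                     context_id(labels[si], labels[mask_bits(cmask, n)]))
      }
    }
  }
  if (length(missing) > 0L) {
    stop("incomplete microconstant set; missing ", length(missing),
         " entries: ", paste(missing, collapse = ", "))
  }

  build_system(sites, logk, tol)
}

# shared finalization: free energies, closure check, canonical order
build_system <- function(sites, logk, tol = 1e-9) {
  n <- nrow(sites)
  nstates <- 2L^n
  labels <- sites$label
  h <- bit_counts(n)

  # cumulative log10 path product ("free energy") of each microstate,
  # accumulated along the lowest-set-bit path from the empty state
  G <- numeric(nstates)
  for (m in 1:(nstates - 1L)) {
    lowest <- bitwAnd(m, -m)
    si <- as.integer(round(log2(lowest))) + 1L
    prev <- m - lowest
    G[m + 1L] <- G[prev + 1L] + logk[si, prev + 1L]
  }

  # cycle closure: every edge must be consistent with the energies, which
  # makes every path log-product between any two microstates path-invariant
  worst <- 0
  for (m in 1:(nstates - 1L)) {
    for (si in mask_bits(m, n)) {
      prev <- m - bitwShiftL(1L, si - 1L)
      dev <- abs(G[prev + 1L] + logk[si, prev + 1L] - G[m + 1L])
      worst <- max(worst, dev)
    }
  }
  if (worst > tol) {
    stop("inconsistent microconstants: cycle closure violated by ",
         format(worst, digits = 3), " log units (tolerance ",
         format(tol), ")")
  }

  state_labels <- vapply(0:(nstates - 1L), function(m) {
    paste(labels[mask_bits(m, n)], collapse = "")
  }, character(1))
  ord <- order(h, 0:(nstates - 1L))

  letter <- rep(NA_character_, nstates)
  if (n == 3L) letter[ord] <- letters[1:8]
  if (n == 4L) letter[ord] <- paste0(letters[1:16], "'")

  structure(list(
    sites = sites, n = n, logk = logk, G = G, h = h,
    order = ord, state_labels = state_labels, letter = letter,
    tol = tol
  ), class = "microstate_system")
}

normalize_sites <- function(sites) {
  if (is.character(sites)) {
    sites <- data.frame(label = sites, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sites) || !"label" %in% names(sites)) {
    stop("'sites' must be a character vector or a data.frame with a 'label' column")
  }
  if (is.null(sites$is_redox_site)) sites$is_redox_site <- FALSE
  if (is.null(sites$chalcogen)) sites$chalcogen <- NA_character_
  sites$label <- as.character(sites$label)
  sites$is_redox_site <- as.logical(sites$is_redox_site)
  sites$chalcogen <- as.character(sites$chalcogen)
  sites$chalcogen[sites$is_redox_site & is.na(sites$chalcogen)] <- "S"
  bad <- sites$is_redox_site & !sites$chalcogen %in% c("S", "Se")
  if (any(bad)) stop("chalcogen of a redox site must be 'S' or 'Se'")
  n <- nrow(sites)
  if (n < 1L) stop("invalid ligand: at least one basic site is required")
  if (n > 12L) stop("ligands with more than 12 basic sites are not supported")
  if (anyDuplicated(sites$label)) stop("site labels must be unique")
  rownames(sites) <- NULL
  sites[, c("label", "is_redox_site", "chalcogen")]
}

parse_context <- function(ctx) {
  if (is.null(ctx) || length(ctx) == 0L) return(character(0))
  if (is.character(ctx) && length(ctx) == 1L) {
    if (!nzchar(trimws(ctx))) return(character(0))
    return(trimws(strsplit(ctx, ",", fixed = TRUE)[[1]]))
  }
  as.character(ctx)
}

# "(S | {N,O})" identifiers used in validation messages
context_id <- function(site, ctx) {
  paste0("(", site, " | {", paste(ctx, collapse = ","), "})")
}

#' @export
print.microstate_system <- function(x, ...) {
  redox <- x$sites$label[x$sites$is_redox_site]
  cat("Microstate system: ", x$n, " basic site(s) [",
      paste(x$sites$label, collapse = ", "), "], ",
      2^x$n, " microstates\n", sep = "")
  if (length(redox) > 0) {
    cat("Redox site(s): ",
        paste0(redox, " (", x$sites$chalcogen[x$sites$is_redox_site], ")",
               collapse = ", "), "\n", sep = "")
  }
  mac <- macro_from_micro(x)
  cat("log beta:", paste(format(mac$log_beta, digits = 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Enumerate the protonation microstates of a ligand
#'
#' Lists all `2^n` protonation microstates in canonical order (by proton
#' count, then by site-order bitmask ascending), together with the
#' conventional one-letter species tags for 3- and 4-site ligands.
#'
#' @param system a [microstate_system()].
#' @return data.frame with one row per microstate and columns `h` (proton
#'   count), `protonated_sites` (concatenated site labels, `""` for the fully
#'   deprotonated species) and `letter` (documentation tag, `NA` unless the
#'   ligand has 3 or 4 sites).
#' @examples
#' enumerate_microstates(example_aminothiol_system())
#' @export
enumerate_microstates <- function(system) {
  stopifnot(inherits(system, "microstate_system"))
  ord <- system$order
  data.frame(
    h = system$h[ord],
    protonated_sites = system$state_labels[ord],
    letter = system$letter[ord],
    stringsAsFactors = FALSE
  )
}

#' Macroscopic protonation constants from the microscopic set
#'
#' Collapses the microscopic constants into the cumulative macroscopic
#' constants `beta_i` (summing the path products of all microstates carrying
#' `i` protons; each path product is path-independent by cycle closure) and
#' the stepwise macroscopic constants `K_pi = beta_i / beta_(i-1)`. For a
#' three-site ligand this reproduces the familiar identities
#' `K_p1 = k^N + k^S + k^O` and `beta_n` equal to the single
#' full-protonation path product.
#'
#' @param system a [microstate_system()].
#' @return list with numeric vectors `log_beta` and `log_Kp`, each of
#'   length `n` (log10 scale).
#' @examples
#' sys <- generate_consistent_microconstants(c(A = 5, B = 5, C = 5))
#' macro_from_micro(sys)$log_Kp[1]  # 5 + log10(3)
#' @export
macro_from_micro <- function(system) {
  stopifnot(inherits(system, "microstate_system"))
  n <- system$n
  log_beta <- vapply(seq_len(n), function(i) {
    lse10(system$G[system$h == i])
  }, numeric(1))
  list(log_beta = log_beta, log_Kp = diff(c(0, log_beta)))
}

#' pH-dependent mole fractions of every microstate
#'
#' Evaluates the binding polynomial in log space (max-shifted, so cumulative
#' constants up to ~10^300 and pH values of +-30 are handled without
#' overflow) and returns the mole fraction of each protonation microstate at
#' each supplied pH. pH is treated as -log10 of the proton concentration;
#' activity corrections are not applied.
#'
#' @param system a [microstate_system()].
#' @param pH numeric vector of pH values (finite).
#' @return object of class `speciation_result`: a list with `pH`, `chi`
#'   (matrix, one row per pH, one column per microstate in canonical order,
#'   each row summing to 1) and `log10_chi` (same layout, always finite, for
#'   downstream log-space work with vanishing fractions).
#' @examples
#' sys <- example_aminothiol_system()
#' mole_fractions(sys, pH = c(3, 7, 11))$chi
#' @export
mole_fractions <- function(system, pH) {
  stopifnot(inherits(system, "microstate_system"))
  if (!is.numeric(pH) || length(pH) == 0L || !all(is.finite(pH))) {
    stop("'pH' must be a non-empty finite numeric vector")
  }
  ord <- system$order
  G <- system$G
  h <- system$h
  l10 <- matrix(NA_real_, nrow = length(pH), ncol = length(G))
  for (i in seq_along(pH)) {
    lw <- G - h * pH[i]           # log10( path_product * [H+]^h )
    l10[i, ] <- lw - lse10(lw)
  }
  l10 <- l10[, ord, drop = FALSE]
  colnames(l10) <- system$state_labels[ord]
  structure(list(pH = pH, chi = 10^l10, log10_chi = l10),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Microspecies mole fractions at", length(x$pH), "pH value(s)\n")
  show <- cbind(pH = x$pH, x$chi)
  print(utils::head(show, 10), digits = 4)
  if (length(x$pH) > 10) cat("...\n")
  invisible(x)
}

#' Build a thermodynamically consistent microconstant set
#'
#' Constructs the full microscopic constant set of a ligand from per-site
#' intrinsic log basicities and pairwise interaction terms:
#' `log k(site s | context C) = site_logk[s] + sum over t in C of
#' interaction[s, t]`. Because every microconstant derives from an additive
#' site-energy model, the resulting system satisfies cycle closure by
#' construction, making this the canonical way to produce consistent
#' synthetic systems for simulation and testing.
#'
#' @param site_logk numeric vector of intrinsic per-site log10 protonation
#'   constants; names are used as site labels when `labels` is `NULL`.
#' @param interaction symmetric numeric matrix of pairwise log-unit
#'   interaction terms with zero diagonal (typically negative: protonating
#'   one site lowers the basicity of its neighbours); `NULL` means no
#'   interactions.
#' @param labels character vector of site labels (defaults to
#'   `names(site_logk)`, or `site1`, `site2`, ... when unnamed).
#' @param redox_site label of the thiolate/selenolate site, if any.
#' @param chalcogen `"S"` or `"Se"` for the redox site.
#' @return a [microstate_system()].
#' @examples
#' M <- matrix(-0.5, 3, 3); diag(M) <- 0
#' sys <- generate_consistent_microconstants(
#'   c(N = 10.5, S = 8.5, O = 2.5), interaction = M, redox_site = "S")
#' macro_from_micro(sys)$log_beta[3]  # 10.5 + 8.5 + 2.5 - 3*0.5
#' @export
generate_consistent_microconstants <- function(site_logk, interaction = NULL,
                                               labels = NULL,
                                               redox_site = NULL,
                                               chalcogen = "S") {
  n <- length(site_logk)
  if (n < 1L) stop("invalid ligand: at least one basic site is required")
  if (is.null(labels)) {
    labels <- names(site_logk)
    if (is.null(labels)) labels <- paste0("site", seq_len(n))
  }
  if (length(labels) != n) stop("'labels' must match length(site_logk)")
  if (is.null(interaction)) interaction <- matrix(0, n, n)
  interaction <- as.matrix(interaction)
  if (!is.numeric(interaction) || any(dim(interaction) != c(n, n))) {
    stop("'interaction' must be an n x n numeric matrix")
  }
  if (any(abs(interaction - t(interaction)) > 1e-12)) {
    stop("'interaction' matrix must be symmetric")
  }
  if (any(abs(diag(interaction)) > 1e-12)) {
    stop("'interaction' matrix must have a zero diagonal")
  }

  sites <- data.frame(label = labels,
                      is_redox_site = labels %in% (redox_site %||% character(0)),
                      chalcogen = NA_character_,
                      stringsAsFactors = FALSE)
  sites$chalcogen[sites$is_redox_site] <- chalcogen
  if (!is.null(redox_site) && sum(sites$is_redox_site) != length(redox_site)) {
    stop("redox_site label(s) not found among site labels")
  }

  nstates <- 2L^n
  logk <- matrix(NA_real_, nrow = n, ncol = nstates,
                 dimnames = list(labels, NULL))
  for (si in seq_len(n)) {
    for (cmask in 0:(nstates - 1L)) {
      if (bitwAnd(cmask, bitwShiftL(1L, si - 1L)) > 0L) next
      ctx <- mask_bits(cmask, n)
      logk[si, cmask + 1L] <- site_logk[si] + sum(interaction[si, ctx])
    }
  }
  build_system(normalize_sites(sites), logk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a random thermodynamically consistent microstate system
#'
#' Samples intrinsic site basicities and pairwise interaction terms from
#' uniform ranges and assembles them with
#' [generate_consistent_microconstants()], so the result is cycle-closed by
#' construction. Intended for property-style testing and simulation.
#'
#' @param n_sites number of basic sites (1..12).
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @param site_logk_range,interaction_range uniform sampling ranges (log10
#'   units) for site basicities and pairwise interactions.
#' @param redox_site index or label of the site to flag as the thiolate;
#'   defaults to site 1.
#' @param chalcogen `"S"` or `"Se"`.
#' @return a [microstate_system()].
#' @export
random_microstate_system <- function(n_sites, seed = NULL,
                                     site_logk_range = c(2, 11),
                                     interaction_range = c(-1, 0),
                                     redox_site = 1L, chalcogen = "S") {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  n <- as.integer(n_sites)
  site_logk <- stats::runif(n, site_logk_range[1], site_logk_range[2])
  M <- matrix(0, n, n)
  if (n > 1L) {
    vals <- stats::runif(n * (n - 1) / 2,
                         interaction_range[1], interaction_range[2])
    M[upper.tri(M)] <- vals
    M <- M + t(M)
  }
  labels <- paste0("B", seq_len(n))
  if (is.numeric(redox_site)) redox_site <- labels[redox_site]
  generate_consistent_microconstants(site_logk, M, labels = labels,
                                     redox_site = redox_site,
                                     chalcogen = chalcogen)
}

# mask (0-based bitmask) of a microstate given its protonated site labels
state_mask <- function(system, protonated) {
  protonated <- parse_context(protonated)
  if (length(protonated) == 0L) return(0L)
  idx <- match(protonated, system$sites$label)
  if (anyNA(idx)) {
    stop("unknown site label(s): ",
         paste(protonated[is.na(idx)], collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("duplicated site labels in microstate")
  sum(bitwShiftL(1L, idx - 1L))
}
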