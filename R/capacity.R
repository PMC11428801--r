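#' pH-dependent antioxidant-capacity score Y
#'
#' The score Y of a thiol (or selenol) compound is the abundance-weighted
#' sum of its species-specific thiolate basicities:
#' `Y(pH) = sum over thiolate-bearing microstates i of
#' chi_i(pH) * logk_i`, where `logk_i` is the microscopic constant for
#' protonating the redox site given microstate i's other-site protonation
#' pattern and `chi_i` is that microstate's mole fraction. A weighted sum is
#' used rather than a weighted mean so that Y falls to zero at low pH, where
#' the reactive thiolate-bearing species vanish; at high pH Y saturates at
#' the basicity of the fully deprotonated context. For an n-site ligand the
#' sum runs over the `2^(n-1)` microstates with the redox site deprotonated.
#'
#' Y is concentration-independent, but thiolate and selenolate scores are
#' not mutually comparable (the basicity-to-potential maps of the two
#' classes are offset); the returned profile therefore carries the
#' compound's chalcogen as an attribute.
#'
#' When per-context standard errors of the thiolate microconstants are
#' supplied, the standard error of Y is propagated by the delta method,
#' treating the chi weights as exact and the errors as independent:
#' `se_Y^2 = sum( (chi_i * se_i)^2 )`.
#'
#' @param system a [microstate_system()] with exactly one redox site.
#' @param pH numeric grid.
#' @param logk_se optional standard errors of the redox-site microconstants:
#'   a scalar applied to every context, or a numeric vector named by the
#'   thiolate-bearing microstate labels (`""` for the empty context).
#' @return data.frame of class `capacity_profile` with columns `pH`, `Y`,
#'   one `term_<label>` column per thiolate-bearing microstate
#'   (`chi_i * logk_i` contributions) and `se_Y` when `logk_se` is given.
#'   The chalcogen tag is in `attr(, "chalcogen")`.
#' @examples
#' capacity_profile(monoprotic_thiol_system(8), pH = c(7, 8, 12))
#' @export
capacity_profile <- function(system, pH = seq(0, 14, by = 0.01),
                             logk_se = NULL) {
  stopifnot(inherits(system, "microstate_system"))
  ri <- which(system$sites$is_redox_site)
  if (length(ri) != 1L) {
    stop("unsupported configuration: exactly one redox site is required (found ",
         length(ri), ")")
  }
  rbit <- bitwShiftL(1L, ri - 1L)
  masks <- 0:(2^system$n - 1L)
  bearing <- masks[bitwAnd(masks, rbit) == 0L]     # redox site deprotonated
  labels <- system$state_labels[bearing + 1L]
  logk_s <- unname(system$logk[ri, bearing + 1L])  # k^S(context) per microstate

  spec <- mole_fractions(system, pH)
  pos <- match(bearing + 1L, system$order)   # canonical column positions
  chi <- spec$chi[, pos, drop = FALSE]
  terms <- sweep(chi, 2L, logk_s, `*`)
  out <- data.frame(pH = pH, Y = rowSums(terms))
  for (j in seq_along(labels)) out[[paste0("term_", labels[j])]] <- terms[, j]

  if (!is.null(logk_se)) {
    if (length(logk_se) == 1L && is.null(names(logk_se))) {
      se <- rep(as.numeric(logk_se), length(labels))
    } else {
      idx <- match(labels, names(logk_se))
      if (anyNA(idx)) {
        stop("'logk_se' must be named by the thiolate-bearing microstate ",
             "labels: ", paste(sQuote(labels), collapse = ", "))
      }
      se <- as.numeric(logk_se[idx])
    }
    if (any(se < 0)) stop("'logk_se' must be non-negative")
    out$se_Y <- sqrt(rowSums(sweep(chi^2, 2L, se^2, `*`)))
  }
  attr(out, "chalcogen") <- system$sites$chalcogen[ri]
  attr(out, "redox_site") <- system$sites$label[ri]
  class(out) <- c("capacity_profile", "data.frame")
  out
}

#' Capacity score of an idealized monoprotic thiol
#'
#' For a thiolate with no interacting neighbour sites the capacity score
#' reduces to the closed form `Y = logk / (1 + 10^(logk - pH))`: the
#' basicity times the thiolate mole fraction of a one-site ligand. This is
#' the model underlying the design surface.
#'
#' @param logk thiolate log10 basicity (vectorized).
#' @param pH pH (vectorized, recycled against `logk`).
#' @return numeric vector of Y values.
#' @examples
#' monoprotic_Y(8, 8)    # 4: half-deprotonation point
#' monoprotic_Y(6, 14)   # ~6: saturation at the basicity
#' @export
monoprotic_Y <- function(logk, pH) {
  logk / (1 + 10^(logk - pH))
}

#' Design surface: optimal thiolate basicity at each pH
#'
#' Evaluates the monoprotic capacity score on a (logk, pH) grid and locates,
#' for each pH, the basicity that maximizes Y. A more basic thiolate is a
#' stronger reductant but deprotonates (and hence acts) only at higher pH;
#' the optimum balances the two. The grid argmax is additionally refined by
#' solving the closed-form stationarity condition
#' `1 + u - logk * ln(10) * u = 0`, `u = 10^(logk - pH)`.
#'
#' @param logk numeric grid of basicities (strictly increasing; default
#'   0..14 step 0.01).
#' @param pH numeric grid (strictly increasing; default 0..14 step 0.1).
#' @return object of class `design_surface`: list with `logk`, `pH`, the
#'   `Y` matrix (logk in rows, pH in columns) and `argmax`, a data.frame
#'   with per-pH columns `logk_opt` (grid argmax), `logk_opt_refined`
#'   (stationary point) and `Y_opt`.
#' @examples
#' ds <- design_surface(pH = c(4, 7, 10))
#' ds$argmax
#' @export
design_surface <- function(logk = seq(0, 14, by = 0.01),
                           pH = seq(0, 14, by = 0.1)) {
  check_grid <- function(g, what) {
    if (length(g) == 0L || !is.numeric(g) || !all(is.finite(g))) {
      stop("'", what, "' grid must be non-empty finite numeric")
    }
    if (length(g) > 1L && any(diff(g) <= 0)) {
      stop("'", what, "' grid must be strictly increasing")
    }
  }
  check_grid(logk, "logk")
  check_grid(pH, "pH")

  Y <- outer(logk, pH, monoprotic_Y)
  idx <- apply(Y, 2L, which.max)
  argmax <- data.frame(
    pH = pH,
    logk_opt = logk[idx],
    logk_opt_refined = vapply(pH, stationary_logk, numeric(1)),
    Y_opt = Y[cbind(idx, seq_along(pH))]
  )
  structure(list(logk = logk, pH = pH, Y = Y, argmax = argmax),
            class = "design_surface")
}

# interior stationary point of the monoprotic Y at one pH
stationary_logk <- function(pH) {
  g <- function(L) {
    u <- 10^(L - pH)
    1 + u - L * .LN10 * u
  }
  upper <- max(pH + 20, 2)
  stats::uniroot(g, lower = 1e-9, upper = upper, tol = 1e-10)$root
}

#' @export
print.design_surface <- function(x, ...) {
  cat("Monoprotic capacity design surface:",
      length(x$logk), "x", length(x$pH), "(logk x pH) grid\n")
  print(utils::head(x$argmax, 8), digits = 4)
  if (nrow(x$argmax) > 8) cat("...\n")
  invisible(x)
}
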