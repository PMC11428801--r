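#' Calibrated linear map from thiolate basicity to standard redox potential
#'
#' Species-specific standard redox potentials of thiolate/disulfide couples
#' correlate tightly with the log basicity of the same-sulfur thiolate: both
#' are governed by the electron density on the sulfur atom. This constructor
#' holds the calibrated linear model `E0 = slope * logk + intercept` together
#' with the standard errors of its coefficients for delta-method uncertainty
#' propagation. Default coefficients are the published calibration over 31
#' species-specific (logk, E0) points (`model_version = "printed-v1"`).
#' Selenolates follow a parallel line displaced by roughly a quarter volt;
#' they are handled with a single additive offset applied to the intercept
#' when `chalcogen = "Se"`, flagged as approximate.
#'
#' The slope-intercept covariance of the published fit is not available;
#' the default `cov_slope_intercept = 0` therefore yields conservative
#' (wider) confidence intervals. See [calibrate_covariance()] to back-solve
#' a covariance from one known interval.
#'
#' @param slope V per log-unit (negative: more basic thiolates are more
#'   reducing).
#' @param intercept V.
#' @param se_slope,se_intercept standard errors of the coefficients.
#' @param cov_slope_intercept their covariance in V^2; must satisfy
#'   `|cov| <= se_slope * se_intercept`.
#' @param chalcogen `"S"` (thiolate) or `"Se"` (selenolate).
#' @param selenolate_offset_volts additive offset applied for `"Se"`;
#'   the default -0.25 V makes selenolates the stronger reductants.
#' @param temperature kelvin, used by exchange-equilibrium helpers.
#' @param model_version free-text tag recorded in tabular output.
#' @return object of class `basicity_redox_model`.
#' @examples
#' m <- basicity_redox_model()
#' predict_e0(m, 7.1)
#' @export
basicity_redox_model <- function(slope = -0.0605, intercept = 0.1683,
                                 se_slope = 0.0011, se_intercept = 0.0083,
                                 cov_slope_intercept = 0,
                                 chalcogen = c("S", "Se"),
                                 selenolate_offset_volts = -0.250,
                                 temperature = 298.15,
                                 model_version = "printed-v1") {
  chalcogen <- match.arg(chalcogen)
  if (se_slope < 0 || se_intercept < 0) {
    stop("invalid model: standard errors must be non-negative")
  }
  if (abs(cov_slope_intercept) > se_slope * se_intercept + 1e-15) {
    stop("invalid model: |cov_slope_intercept| exceeds se_slope * se_intercept")
  }
  structure(list(
    slope = slope, intercept = intercept,
    se_slope = se_slope, se_intercept = se_intercept,
    cov_slope_intercept = cov_slope_intercept,
    chalcogen = chalcogen,
    selenolate_offset_volts = selenolate_offset_volts,
    temperature = temperature,
    model_version = model_version
  ), class = "basicity_redox_model")
}

#' @export
print.basicity_redox_model <- function(x, ...) {
  cat("Basicity -> E0 linear model (", x$model_version, ")\n", sep = "")
  cat(sprintf("  E0 = %.4f * logk + %.4f  [V], chalcogen %s\n",
              x$slope, x$intercept, x$chalcogen))
  if (x$chalcogen == "Se") {
    cat(sprintf("  selenolate offset %.3f V (approximate)\n",
                x$selenolate_offset_volts))
  }
  cat(sprintf("  se(slope) = %.4f, se(intercept) = %.4f, cov = %g\n",
              x$se_slope, x$se_intercept, x$cov_slope_intercept))
  invisible(x)
}

#' Predict a species-specific standard redox potential from log basicity
#'
#' Point prediction `E0 = slope * logk + intercept`, with the selenolate
#' offset added when the model's chalcogen is `"Se"`. Values are returned at
#' full precision; use [round_half_away()] (3 decimals) for tabulation.
#'
#' @param model a [basicity_redox_model()].
#' @param logk numeric vector of species-specific log10 thiolate basicities.
#' @return numeric vector of predicted standard redox potentials in V.
#' @examples
#' round_half_away(predict_e0(basicity_redox_model(), 6.86), 3)  # -0.247
#' @export
predict_e0 <- function(model, logk) {
  stopifnot(inherits(model, "basicity_redox_model"))
  if (!is.numeric(logk) || !all(is.finite(logk))) {
    stop("'logk' must be finite numeric")
  }
  e0 <- model$slope * logk + model$intercept
  if (model$chalcogen == "Se") e0 <- e0 + model$selenolate_offset_volts
  e0
}

# delta-method standard error of the predicted potential
e0_standard_error <- function(model, logk) {
  v <- logk^2 * model$se_slope^2 + model$se_intercept^2 +
    2 * logk * model$cov_slope_intercept
  if (any(v < 0)) {
    stop("invalid model: negative prediction variance after covariance term")
  }
  sqrt(v)
}

#' Predicted potential with a delta-method confidence interval
#'
#' First-order (delta-method) propagation of the coefficient uncertainties
#' into the predicted potential:
#' `se(E0)^2 = logk^2 se_slope^2 + se_intercept^2 + 2 logk cov`, with a
#' symmetric normal-quantile interval about the point estimate.
#'
#' @inheritParams predict_e0
#' @param level confidence level in (0, 1).
#' @return data.frame with columns `logk`, `e0`, `se`, `ci_low`, `ci_high`,
#'   `level` (volts, full precision).
#' @examples
#' predict_interval(basicity_redox_model(), 6.86)
#' @export
predict_interval <- function(model, logk, level = 0.95) {
  stopifnot(inherits(model, "basicity_redox_model"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)")
  }
  e0 <- predict_e0(model, logk)
  se <- e0_standard_error(model, logk)
  z <- stats::qnorm((1 + level) / 2)
  data.frame(logk = logk, e0 = e0, se = se,
             ci_low = e0 - z * se, ci_high = e0 + z * se, level = level)
}

#' Back-solve the slope-intercept covariance from one known interval
#'
#' The published calibration reports coefficient standard errors but not
#' their covariance, which published prediction intervals clearly used
#' (printed intervals are much narrower than the covariance-free delta
#' method gives). Given one reference interval at a known `logk`, this
#' routine solves the delta-method variance equation for the covariance and
#' returns an updated model. Agreement on other rows is approximate, not
#' exact; inspect residual misfit with [predict_interval()].
#'
#' @param model a [basicity_redox_model()].
#' @param logk abscissa of the reference interval.
#' @param ci_low,ci_high the reference interval bounds in V.
#' @param level confidence level of the reference interval.
#' @return the model with `cov_slope_intercept` replaced.
#' @export
calibrate_covariance <- function(model, logk, ci_low, ci_high, level = 0.95) {
  stopifnot(inherits(model, "basicity_redox_model"))
  if (logk == 0) stop("cannot identify the covariance from logk = 0")
  z <- stats::qnorm((1 + level) / 2)
  half <- (ci_high - ci_low) / 2
  cov <- ((half / z)^2 - logk^2 * model$se_slope^2 - model$se_intercept^2) /
    (2 * logk)
  basicity_redox_model(
    slope = model$slope, intercept = model$intercept,
    se_slope = model$se_slope, se_intercept = model$se_intercept,
    cov_slope_intercept = cov, chalcogen = model$chalcogen,
    selenolate_offset_volts = model$selenolate_offset_volts,
    temperature = model$temperature,
    model_version = paste0(model$model_version, "+cov")
  )
}

#' Standard redox potential from an exchange equilibrium against a reference
#'
#' A species-specific standard potential can be measured by equilibrating
#' the thiol/disulfide couple of interest against a couple of known
#' potential (canonically glutathione, GSSG/GSH) and observing the apparent
#' exchange constant `K_C`. With mole fractions converting apparent to
#' species-specific concentrations, the target couple's standard potential
#' is
#' `E0 = E0_ref + RT/(zF) * ln( K_C * chi_red^2 * chi_ox_ref /
#' (chi_ox * chi_red_ref^2) )` with `z = 2` electrons and the squares
#' reflecting the 2 thiol : 1 disulfide stoichiometry.
#'
#' @param e0_ref standard potential of the reference couple, V.
#' @param k_c apparent exchange equilibrium constant (> 0).
#' @param chi_red,chi_ox mole fractions of the target reduced/oxidized
#'   microspecies in (0, 1].
#' @param chi_red_ref,chi_ox_ref mole fractions of the reference reduced/
#'   oxidized microspecies.
#' @param temperature kelvin.
#' @param z electrons transferred (2 for thiol-disulfide).
#' @return standard redox potential of the target couple, V.
#' @examples
#' e0_from_exchange(-0.262, k_c = 10)  # shifts by (RT/2F) ln 10
#' @export
e0_from_exchange <- function(e0_ref, k_c, chi_red = 1, chi_ox = 1,
                             chi_red_ref = 1, chi_ox_ref = 1,
                             temperature = 298.15, z = 2) {
  vals <- c(k_c = k_c, chi_red = chi_red, chi_ox = chi_ox,
            chi_red_ref = chi_red_ref, chi_ox_ref = chi_ox_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("k_c and all mole fractions must be positive")
  }
  chis <- vals[-1]
  if (any(chis > 1)) stop("mole fractions must lie in (0, 1]")
  e0_ref + nernst_factor(temperature, z) *
    log(k_c * chi_red^2 * chi_ox_ref / (chi_ox * chi_red_ref^2))
}

#' Annotate a table of thiolate basicities with predicted potentials
#'
#' Applies [predict_e0()] and [predict_interval()] row-wise to a table of
#' protein (or small-molecule) thiolate log basicities, appending the
#' predicted standard potential and its confidence bounds formatted to
#' 3 decimals (half away from zero). Rows with missing or non-numeric
#' `logk` produce `NA` results and a warning naming the row index;
#' processing continues.
#'
#' @param model a [basicity_redox_model()].
#' @param rows data.frame with a numeric `logk` column (e.g. from
#'   [protein_thiol_table()]).
#' @param level confidence level for the interval columns.
#' @return the input data.frame with columns `e0_volts`, `ci_low`,
#'   `ci_high` (V, 3 decimals) and `model_version` appended.
#' @examples
#' annotate_table(basicity_redox_model(), protein_thiol_table())
#' @export
annotate_table <- function(model, rows, level = 0.95) {
  stopifnot(inherits(model, "basicity_redox_model"))
  if (!is.data.frame(rows)) stop("'rows' must be a data.frame")
  if (nrow(rows) == 0L) {
    out <- rows
    out$e0_volts <- numeric(0)
    out$ci_low <- numeric(0)
    out$ci_high <- numeric(0)
    out$model_version <- character(0)
    return(out)
  }
  if (!"logk" %in% names(rows)) stop("'rows' must contain a 'logk' column")
  logk <- suppressWarnings(as.numeric(rows$logk))
  bad <- !is.finite(logk)
  if (any(bad)) {
    warning("non-numeric logk in row(s) ",
            paste(which(bad), collapse = ", "), "; returning NA for them")
  }
  e0 <- ci_lo <- ci_hi <- rep(NA_real_, length(logk))
  if (any(!bad)) {
    pr <- predict_interval(model, logk[!bad], level = level)
    e0[!bad] <- pr$e0
    ci_lo[!bad] <- pr$ci_low
    ci_hi[!bad] <- pr$ci_high
  }
  out <- rows
  out$e0_volts <- round_half_away(e0, 3)
  out$ci_low <- round_half_away(ci_lo, 3)
  out$ci_high <- round_half_away(ci_hi, 3)
  out$model_version <- model$model_version
  out
}

#' Embedded table of experimentally determined protein thiolate basicities
#'
#' Species-specific log10 basicities of reactive cysteine thiolates in
#' proteins, collected from the PKAD database of experimentally determined
#' ionizable-residue pKa values. Two proteins (thioredoxin 2TRX and
#' glutaredoxin 1EGO) contribute two residues each, for 19 records in total.
#' PDB identifiers are opaque labels here; no structural data is read.
#'
#' @return data.frame with columns `protein_name`, `pdb_id`, `res_id`
#'   (integer) and `logk` (numeric), 19 rows.
#' @examples
#' head(protein_thiol_table())
#' @export
protein_thiol_table <- function() {
  path <- system.file("extdata", "protein_thiol_basicities.tsv",
                      package = "redoxspec", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$res_id <- as.integer(tab$res_id)
  tab$logk <- as.numeric(tab$logk)
  tab
}
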