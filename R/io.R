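#' Read a compound parameter file
#'
#' Loads a JSON compound description with fields `name`, `sites` (array of
#' `{label, is_redox_site, chalcogen}`) and `micro_logk` (array of
#' `{site, context, logk}` with `context` an array of site labels). The
#' microconstant set is validated for completeness (`n * 2^(n-1)` entries,
#' errors name the missing `(site | {context})` combinations) and cycle
#' closure on load. Optional fields `c_red_total`, `c_ox_total` and
#' `provenance` are carried through.
#'
#' @param path path to a JSON file.
#' @return object of class `compound_record`: list with `name`, `system`
#'   (a [microstate_system()]), `provenance`, and any concentrations given.
#' @seealso [write_compound()]
#' @export
read_compound <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$sites) || is.null(doc$micro_logk)) {
    stop("compound file must contain 'sites' and 'micro_logk'")
  }
  sites <- data.frame(
    label = vapply(doc$sites, function(s) as.character(s$label), character(1)),
    is_redox_site = vapply(doc$sites, function(s)
      isTRUE(s$is_redox_site), logical(1)),
    chalcogen = vapply(doc$sites, function(s)
      if (is.null(s$chalcogen)) NA_character_ else as.character(s$chalcogen),
      character(1)),
    stringsAsFactors = FALSE
  )
  entries <- data.frame(
    site = vapply(doc$micro_logk, function(e) as.character(e$site),
                  character(1)),
    logk = vapply(doc$micro_logk, function(e) as.numeric(e$logk), numeric(1)),
    stringsAsFactors = FALSE
  )
  entries$context <- I(lapply(doc$micro_logk, function(e) {
    if (is.null(e$context)) character(0) else unlist(e$context)
  }))
  system <- microstate_system(sites, entries)
  structure(list(
    name = if (is.null(doc$name)) basename(path) else doc$name,
    system = system,
    provenance = if (is.null(doc$provenance)) "user" else doc$provenance,
    c_red_total = doc$c_red_total,
    c_ox_total = doc$c_ox_total
  ), class = "compound_record")
}

#' Write a compound parameter file
#'
#' Serializes a [microstate_system()] to the JSON schema read by
#' [read_compound()]. Microconstant entries are emitted in site order with
#' context masks ascending, contexts as arrays of site labels.
#'
#' @param system a [microstate_system()].
#' @param path output path.
#' @param name compound name recorded in the file.
#' @param provenance free-text provenance note (e.g. `"fixture"`).
#' @return `path`, invisibly.
#' @export
write_compound <- function(system, path, name = "compound",
                           provenance = "user") {
  stopifnot(inherits(system, "microstate_system"))
  n <- system$n
  labels <- system$sites$label
  entries <- list()
  for (si in seq_len(n)) {
    for (cmask in 0:(2^n - 1L)) {
      if (bitwAnd(cmask, bitwShiftL(1L, si - 1L)) > 0L) next
      entries[[length(entries) + 1L]] <- list(
        site = labels[si],
        context = as.list(labels[mask_bits(cmask, n)]),
        logk = system$logk[si, cmask + 1L]
      )
    }
  }
  doc <- list(
    name = name,
    provenance = provenance,
    sites = lapply(seq_len(n), function(i) {
      s <- list(label = labels[i],
                is_redox_site = system$sites$is_redox_site[i])
      if (!is.na(system$sites$chalcogen[i])) {
        s$chalcogen <- system$sites$chalcogen[i]
      }
      s
    }),
    micro_logk = entries
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.compound_record <- function(x, ...) {
  cat("Compound record '", x$name, "' (", x$provenance, ")\n", sep = "")
  print(x$system)
  invisible(x)
}

#' Write a speciation table as TSV
#'
#' One row per pH with one mole-fraction column per microstate
#' (`chi_<labels>` headers, `chi_` for the fully deprotonated species).
#' Decimal separator is `.`, encoding UTF-8, minus signs plain hyphens.
#'
#' @param spec a `speciation_result` from [mole_fractions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_speciation_tsv <- function(spec, path) {
  stopifnot(inherits(spec, "speciation_result"))
  out <- data.frame(pH = spec$pH, check.names = FALSE)
  for (j in seq_len(ncol(spec$chi))) {
    out[[paste0("chi_", colnames(spec$chi)[j])]] <- spec$chi[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table of protein thiolate basicities
#'
#' Reads a PKAD-style TSV with columns `protein_name`, `pdb_id`, `res_id`,
#' `logk` for use with [annotate_table()].
#'
#' @param path path to a TSV file.
#' @return data.frame with the four columns coerced to their types.
#' @export
read_thiol_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_name", "pdb_id", "res_id", "logk")
  if (!all(need %in% names(tab))) {
    stop("thiol table must have columns: ", paste(need, collapse = ", "))
  }
  tab$res_id <- as.integer(tab$res_id)
  tab$logk <- suppressWarnings(as.numeric(tab$logk))
  tab
}
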