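# Independent brute-force oracles used across the suite. These deliberately
# work in plain linear arithmetic (no log-sum-exp, no shared code path with
# the package internals beyond reading the stored microconstants).

# all permutations of a vector (n <= 4 in the tests)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# indices of bits set in a mask
oracle_bits <- function(mask, n) which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)

# summed log microconstants along one protonation path (ordered site indices)
oracle_path_logsum <- function(system, path) {
  cm <- 0L
  s <- 0
  for (si in path) {
    s <- s + unname(system$logk[si, cm + 1L])
    cm <- cm + bitwShiftL(1L, si - 1L)
  }
  s
}

# log path sums over ALL protonation orders reaching a microstate
oracle_all_path_logsums <- function(system, mask) {
  bits <- oracle_bits(mask, system$n)
  if (length(bits) == 0L) return(0)
  vapply(all_perms(bits), function(p) oracle_path_logsum(system, p),
         numeric(1))
}

# mole fractions by naive linear-space evaluation of the binding polynomial,
# returned in the package's canonical microstate order
oracle_chi <- function(system, pH) {
  n <- system$n
  masks <- 0:(2^n - 1L)
  w <- vapply(masks, function(m) {
    bits <- oracle_bits(m, n)
    p <- 1
    cm <- 0L
    for (si in bits) {
      p <- p * 10^system$logk[si, cm + 1L]
      cm <- cm + bitwShiftL(1L, si - 1L)
    }
    p * (10^-pH)^length(bits)
  }, numeric(1))
  (w / sum(w))[system$order]
}

# microconstant of `site` in the context of protonated `ctx` labels
oracle_logk <- function(system, site, ctx) {
  si <- match(site, system$sites$label)
  ci <- match(ctx, system$sites$label)
  unname(system$logk[si, sum(2^(ci - 1)) * (length(ci) > 0) + 1L])
}

# chi of one microstate named by its protonated site labels
oracle_chi_state <- function(system, pH, protonated) {
  chi <- oracle_chi(system, pH)
  lab <- paste(system$sites$label[sort(match(protonated, system$sites$label))],
               collapse = "")
  names(chi) <- system$state_labels[system$order]
  unname(chi[match(lab, names(chi))])
}

NERNST_2E <- 8.314 * 298.15 / (2 * 96485)   # RT/2F at 298.15 K, V per ln unit
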