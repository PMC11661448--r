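# Isotope-pattern machinery: natural-abundance envelopes by polynomial
# convolution over an extra-neutron grid, plus the binomial deuteration shift
# used by the synthetic forward model.

# CODATA/IUPAC 2021 isotope masses (Da) and representative abundances.
isotope_table <- function() {
  list(
    C = list(mass = c(12.0000000, 13.0033548), abundance = c(0.9893, 0.0107)),
    H = list(mass = c(1.0078250, 2.0141018),   abundance = c(0.999885, 0.000115)),
    N = list(mass = c(14.0030740, 15.0001089), abundance = c(0.99636, 0.00364)),
    O = list(mass = c(15.9949146, 16.9991317, 17.9991596),
             abundance = c(0.99757, 0.00038, 0.00205)),
    S = list(mass = c(31.9720707, 32.9714589, 33.9678668, 35.9670809),
             abundance = c(0.9499, 0.0075, 0.0425, 0.0001)))
}

# Mass of the 2H-1H substitution applied per incorporated deuteron.
DEUTERIUM_MASS_SHIFT <- 1.00628
PROTON_MASS <- 1.007276

# A "distribution" here is a list(delta, prob, mass): integer offsets from the
# lightest species, probabilities, and the conditional mean mass at each
# offset. Convolution tracks both the probability and the mass first moment.
dist_delta <- function(masses, probs) {
  delta <- seq_along(masses) - 1L
  list(delta = delta, prob = probs / sum(probs), mass = masses)
}

dist_convolve <- function(a, b, tol = 1e-12) {
  nd <- max(a$delta) + max(b$delta)
  prob <- numeric(nd + 1L)
  mom <- numeric(nd + 1L)
  for (i in seq_along(a$delta)) {
    d <- a$delta[i] + b$delta
    p <- a$prob[i] * b$prob
    m <- a$mass[i] + b$mass
    prob[d + 1L] <- prob[d + 1L] + p
    mom[d + 1L] <- mom[d + 1L] + p * m
  }
  keep <- prob > tol * max(prob)
  list(delta = which(keep) - 1L, prob = prob[keep] / sum(prob[keep]),
       mass = mom[keep] / prob[keep])
}

# single-atom isotope distribution raised to the n-th convolution power
dist_power <- function(single, n) {
  out <- NULL
  base <- single
  while (n > 0) {
    if (n %% 2 == 1) out <- if (is.null(out)) base else dist_convolve(out, base)
    n <- n %/% 2
    if (n > 0) base <- dist_convolve(base, base)
  }
  if (is.null(out)) list(delta = 0L, prob = 1, mass = 0)
  else out
}

# Natural isotope distribution of a peptide from its elemental composition.
natural_isotope_distribution <- function(sequence) {
  comp <- peptide_composition(sequence)
  iso <- isotope_table()
  out <- list(delta = 0L, prob = 1, mass = 0)
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    single <- dist_delta(iso[[el]]$mass, iso[[el]]$abundance)
    out <- dist_convolve(out, dist_power(single, comp[[el]]))
  }
  out
}

# Binomial distribution of incorporated deuterons over n_ex sites with mean
# `uptake` deuterons; each deuteron adds DEUTERIUM_MASS_SHIFT Da.
deuteration_distribution <- function(uptake, n_ex) {
  if (n_ex == 0 || uptake <= 0) return(list(delta = 0L, prob = 1, mass = 0))
  q <- min(uptake / n_ex, 1)
  k <- 0:n_ex
  list(delta = k, prob = stats::dbinom(k, n_ex, q),
       mass = k * DEUTERIUM_MASS_SHIFT)
}

#' Simulate the isotope envelope of a (partially deuterated) peptide
#'
#' Convolves the peptide's natural isotope distribution, computed from its
#' elemental composition, with a binomial deuteration distribution whose mean
#' equals `uptake` deuterons. The result is a stick spectrum on the m/z axis
#' for the peptide's charge state; with `resolution_points > 0` the sticks are
#' rendered as Gaussian peaks on a regular m/z grid instead.
#'
#' @param peptide One row of a [peptide_table()] (or a list with `sequence`,
#'   `charge`, and optionally `n_ex`).
#' @param uptake Mean number of incorporated deuterons (>= 0).
#' @param resolution_points If > 0, number of grid points of the rendered
#'   profile; 0 (default) returns the stick spectrum.
#' @param peak_fwhm Full width at half maximum (Th) of rendered peaks.
#'
#' @return An object of class `isotope_envelope`: a tibble with columns `mz`
#'   (ascending, Th) and `intensity` (sums to 1), with the charge state stored
#'   in attribute `charge`.
#' @export
#' @examples
#' p <- peptide_table("x", 1, 5, "GGGGG", charge = 1)[1, ]
#' env <- simulate_envelope(p, uptake = 1)
#' envelope_centroid(env)
simulate_envelope <- function(peptide, uptake, resolution_points = 0L,
                              peak_fwhm = 0.05) {
  stopifnot(uptake >= 0)
  sequence <- peptide$sequence
  charge <- as.integer(peptide$charge)
  n_ex <- if (!is.null(peptide$n_ex)) peptide$n_ex else exchangeable_amides(sequence)
  nat <- natural_isotope_distribution(sequence)
  deut <- deuteration_distribution(uptake, n_ex)
  full <- dist_convolve(nat, deut)
  mz <- (full$mass + charge * PROTON_MASS) / charge
  o <- order(mz)
  env <- tibble(mz = mz[o], intensity = full$prob[o] / sum(full$prob))
  if (resolution_points > 0) {
    sdw <- peak_fwhm / (2 * sqrt(2 * log(2)))
    lo <- min(env$mz) - 5 * sdw
    hi <- max(env$mz) + 5 * sdw
    grid <- seq(lo, hi, length.out = resolution_points)
    y <- rowSums(vapply(seq_len(nrow(env)), function(i) {
      env$intensity[i] * exp(-0.5 * ((grid - env$mz[i]) / sdw)^2)
    }, numeric(length(grid))))
    env <- tibble(mz = grid, intensity = y / sum(y))
  }
  structure(env, class = c("isotope_envelope", class(env)), charge = charge)
}

#' Intensity-weighted centroid of an isotope envelope
#'
#' Computes the intensity-weighted mean m/z of an envelope and converts it to
#' a neutral mass as `mean_mz * charge - charge * 1.007276`. Deuteration
#' levels in HDX-MS are conventionally read off this centroid.
#'
#' @param envelope An `isotope_envelope`, or any data frame with ascending
#'   `mz` and nonnegative `intensity` columns.
#' @param charge Charge state; defaults to the envelope's `charge` attribute.
#' @return Neutral centroid mass in Da.
#' @export
envelope_centroid <- function(envelope, charge = attr(envelope, "charge")) {
  mz <- envelope$mz
  intensity <- envelope$intensity
  if (is.null(charge)) abort("envelope_centroid(): charge must be supplied")
  charge <- as.integer(charge)
  if (charge < 1L) abort("envelope_centroid(): charge must be >= 1")
  if (length(mz) != length(intensity) || length(mz) == 0) {
    abort("envelope_centroid(): mz and intensity must be nonempty, same length")
  }
  if (any(diff(mz) <= 0)) abort("envelope_centroid(): mz must be strictly ascending")
  if (any(intensity < 0)) abort("envelope_centroid(): negative intensities")
  tot <- sum(intensity)
  if (tot <= 0) abort("envelope_centroid(): all intensities are zero")
  mean_mz <- sum(mz * intensity) / tot
  mean_mz * charge - charge * PROTON_MASS
}
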