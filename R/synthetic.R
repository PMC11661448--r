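# Synthetic-data module: forward models with known ground truth for every
# downstream stage (exchange kinetics, isotope envelopes via isotopes.R, toy
# interfaces, dose-response curves).

#' Define ground truth for a two-state exchange simulation
#'
#' Sets up the forward model of amide exchange for one protein in an apo and
#' a bound state. Each exchangeable amide i exchanges with intrinsic rate
#' `k_i` slowed by a protection factor `P_i >= 1`; binding is planted as an
#' extra protection factor on a chosen residue range. Defaults mirror a
#' four-timepoint design (30, 300, 3000, 10000 s) at a final deuterium
#' fraction of 0.680 with triplicate measurements.
#'
#' Intrinsic rates are drawn log-uniformly over `rate_range` rather than from
#' sequence-based reference rates: the analysis consumes only relative
#' uptake, so phenomenological rates suffice (a precomputed `rates` vector
#' can be supplied for sequence-based rates).
#'
#' @param sequence Protein amino-acid sequence (one-letter).
#' @param protected_range Integer residue range (e.g. `21:35`) carrying extra
#'   protection in the bound state; `NULL` for a null (no-difference) truth.
#' @param protection_factor Multiplicative extra protection applied to
#'   `protected_range` in the bound state (>= 1).
#' @param apo_protection Baseline per-residue protection factors (length 1 or
#'   `nchar(sequence)`, all >= 1).
#' @param rate_range Range (1/s) for log-uniform intrinsic rates.
#' @param rates Optional explicit per-residue intrinsic rates (1/s).
#' @param d2o_fraction Final deuterium fraction of the labeling reaction.
#' @param timepoints Labeling durations in seconds, all > 0.
#' @param n_replicates Replicates per peptide/state/timepoint.
#' @param replicate_sd Gaussian noise SD (Da) added to each measured uptake.
#' @param seed Integer seed for rate draw and measurement noise.
#'
#' @return An object of class `exchange_truth`.
#' @export
exchange_ground_truth <- function(sequence,
                                  protected_range = NULL,
                                  protection_factor = 50,
                                  apo_protection = 1,
                                  rate_range = c(1e-3, 1e1),
                                  rates = NULL,
                                  d2o_fraction = 0.680,
                                  timepoints = c(30, 300, 3000, 10000),
                                  n_replicates = 3L,
                                  replicate_sd = 0.05,
                                  seed = 1L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (any(timepoints <= 0)) abort("exchange_ground_truth(): timepoints must be > 0")
  if (d2o_fraction <= 0 || d2o_fraction > 1) {
    abort("exchange_ground_truth(): d2o_fraction must be in (0, 1]")
  }
  if (is.null(rates)) {
    set.seed(as.integer(seed))
    rates <- exp(stats::runif(n, log(rate_range[1]), log(rate_range[2])))
  }
  if (length(rates) != n) abort("exchange_ground_truth(): rates length != sequence length")
  if (any(rates <= 0)) abort("exchange_ground_truth(): rates must be > 0")
  p_apo <- rep_len(apo_protection, n)
  if (any(p_apo < 1)) abort("exchange_ground_truth(): protection factors must be >= 1")
  p_bound <- p_apo
  if (!is.null(protected_range)) {
    if (protection_factor < 1) abort("exchange_ground_truth(): protection_factor must be >= 1")
    if (any(protected_range < 1 | protected_range > n)) {
      abort("exchange_ground_truth(): protected_range outside sequence")
    }
    p_bound[protected_range] <- p_bound[protected_range] * protection_factor
  }
  structure(list(sequence = sequence,
                 rates = rates,
                 protection = list(apo = p_apo, bound = p_bound),
                 protected_range = protected_range,
                 d2o_fraction = d2o_fraction,
                 timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 replicate_sd = replicate_sd,
                 seed = as.integer(seed)),
            class = "exchange_truth")
}

#' @export
print.exchange_truth <- function(x, ...) {
  cat("<exchange_truth> ", nchar(x$sequence), " residues, ",
      length(x$timepoints), " timepoints, fD = ", x$d2o_fraction, "\n", sep = "")
  if (!is.null(x$protected_range)) {
    cat("  planted protection: residues ", min(x$protected_range), "-",
        max(x$protected_range), "\n", sep = "")
  }
  invisible(x)
}

#' Noise-free deuteron uptake of a peptide over time
#'
#' The deterministic forward model: at labeling time t the expected number of
#' incorporated deuterons is
#' `D(t) = fD * sum_i (1 - exp(-k_i t / P_i))` over the peptide's
#' exchangeable amides (positions 3..end of the peptide, prolines excluded).
#'
#' @param truth An [exchange_ground_truth()] object.
#' @param peptide One row of a [peptide_table()] (span within the sequence).
#' @param timepoints Labeling times (s); defaults to the truth's design.
#' @param state `"apo"` or `"bound"`.
#' @return Numeric vector of expected deuteron counts, one per timepoint.
#' @export
uptake_curve <- function(truth, peptide, timepoints = truth$timepoints,
                         state = "apo") {
  state <- match.arg(state, names(truth$protection))
  n <- nchar(truth$sequence)
  if (peptide$start < 1 || peptide$end > n) {
    abort("uptake_curve(): peptide span outside the ground-truth sequence")
  }
  idx <- exchangeable_positions(peptide)
  if (length(idx) == 0) return(rep(0, length(timepoints)))
  k <- truth$rates[idx]
  p <- truth$protection[[state]][idx]
  vapply(timepoints, function(t) {
    truth$d2o_fraction * sum(1 - exp(-k * t / p))
  }, numeric(1))
}

# protein residue indices of a peptide's exchangeable amides
exchangeable_positions <- function(peptide, skip_n_term = 2L) {
  if (peptide$end - peptide$start + 1L <= skip_n_term) return(integer(0))
  pos <- (peptide$start + skip_n_term):peptide$end
  aa <- strsplit(peptide$sequence, "")[[1]][(skip_n_term + 1L):nchar(peptide$sequence)]
  pos[aa != "P"]
}

#' Simulate uptake records for one state
#'
#' Applies the forward model of [uptake_curve()] to every peptide, timepoint
#' and replicate, adds Gaussian measurement noise of SD `truth$replicate_sd`
#' (Da) to the mass uptake, and returns records in the same tidy form as
#' [uptake_records()]: the centroid mass is the undeuterated centroid plus
#' 1.00628 Da per incorporated deuteron.
#'
#' @param truth An [exchange_ground_truth()] object.
#' @param peptides A [peptide_table()] whose spans lie within the sequence.
#' @param state `"apo"` or `"bound"`.
#' @param protein Protein identifier stamped on the records.
#' @param seed Seed for the measurement noise; defaults to the truth's seed
#'   offset by the state so apo and bound draws are independent.
#' @return A tibble of uptake records (see [uptake_records()]).
#' @export
simulate_uptake <- function(truth, peptides, state = c("apo", "bound"),
                            protein = peptides$protein[1], seed = NULL) {
  state <- match.arg(state, names(truth$protection))
  if (nrow(peptides) == 0) abort("simulate_uptake(): empty peptide table")
  if (any(peptides$start < 1) || any(peptides$end > nchar(truth$sequence))) {
    abort("simulate_uptake(): peptide span outside the ground-truth sequence")
  }
  if (is.null(seed)) {
    seed <- truth$seed + 1000L * match(state, names(truth$protection))
  }
  tps <- truth$timepoints
  nrep <- truth$n_replicates
  # expected deuteron counts per peptide x timepoint
  d_expect <- t(vapply(seq_len(nrow(peptides)), function(i) {
    uptake_curve(truth, peptides[i, ], tps, state)
  }, numeric(length(tps))))
  grid <- tidyr::expand_grid(pep = seq_len(nrow(peptides)),
                             timepoint = tps,
                             replicate = seq_len(nrep))
  grid$deuterons <- d_expect[cbind(grid$pep, match(grid$timepoint, tps))]
  set.seed(as.integer(seed) %% .Machine$integer.max)
  noise <- rnorm(nrow(grid), 0, truth$replicate_sd)
  pep <- peptides[grid$pep, ]
  undeut <- vapply(unique(pep$sequence), peptide_mass, numeric(1))
  und <- undeut[pep$sequence]
  mass_uptake <- grid$deuterons * DEUTERIUM_MASS_SHIFT + noise
  max_uptake <- pep$n_ex * DEUTERIUM_MASS_SHIFT * truth$d2o_fraction
  tibble(protein = pep$protein, start = pep$start, end = pep$end,
         sequence = pep$sequence, charge = pep$charge,
         state = state, timepoint = grid$timepoint, replicate = grid$replicate,
         centroid_mass = und + mass_uptake,
         uptake = mass_uptake,
         percent_exchange = ifelse(pep$n_ex > 0, 100 * mass_uptake / max_uptake,
                                   NA_real_),
         flagged = pep$n_ex == 0 & abs(mass_uptake) > 0,
         n_ex = pep$n_ex, d2o_fraction = truth$d2o_fraction)
}

#' Random peptide coverage of a sequence
#'
#' Tiles a sequence with overlapping peptides of realistic pepsin-like
#' lengths, guaranteeing full coverage.
#'
#' @param sequence Protein sequence.
#' @param protein Protein identifier.
#' @param mean_length,step Mean peptide length and start-to-start step.
#' @param seed Seed for length jitter.
#' @return A [peptide_table()].
#' @export
tile_peptides <- function(sequence, protein = "prot", mean_length = 12L,
                          step = 5L, seed = 1L) {
  n <- nchar(sequence)
  set.seed(as.integer(seed))
  starts <- seq(1L, max(1L, n - 4L), by = step)
  lens <- pmax(6L, round(rnorm(length(starts), mean_length, 2)))
  ends <- pmin(n, starts + lens - 1L)
  keep <- ends - starts >= 4L
  starts <- starts[keep]; ends <- ends[keep]
  peptide_table(protein, starts, ends,
                substring(sequence, starts, ends), charge = 2L)
}

#' Simulate a one-site dose-response curve
#'
#' Forward model of an equilibrium binding titration: the specific response
#' at analyte concentration C is `rmax * C / (kd + C)`, plus Gaussian noise.
#'
#' @param kd Equilibrium dissociation constant (nM), > 0.
#' @param rmax Maximal response (response units).
#' @param concentrations Analyte concentrations (nM), >= 0.
#' @param noise_sd Gaussian noise SD in response units.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration` and `response`.
#' @export
#' @examples
#' simulate_dose_response(23.5, 1, c(10, 50, 250, 1250, 2500), noise_sd = 0)
simulate_dose_response <- function(kd, rmax, concentrations, noise_sd = 0,
                                   seed = 1L) {
  if (kd <= 0) abort("simulate_dose_response(): kd must be > 0")
  if (any(concentrations < 0)) {
    abort("simulate_dose_response(): negative concentrations")
  }
  set.seed(as.integer(seed))
  resp <- rmax * concentrations / (kd + concentrations) +
    rnorm(length(concentrations), 0, noise_sd)
  tibble(concentration = concentrations, response = resp)
}
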