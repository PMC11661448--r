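#' Deuterium uptake and percent exchange from centroid masses
#'
#' Converts a measured neutral centroid mass into deuterium uptake (Da) and
#' percent exchange relative to the theoretical maximum. The theoretical
#' maximum accounts for the deuterium fraction of the labeling reaction,
#' which is the only back-exchange control applied: maximal uptake is
#' `n_ex * 1.00628 * d2o_fraction` Da.
#'
#' @param record_centroid Measured neutral centroid mass (Da); vectorised.
#' @param undeut_centroid Undeuterated centroid mass of the same peptide (Da).
#' @param n_ex Exchangeable amides of the peptide ([exchangeable_amides()]).
#' @param d2o_fraction Final deuterium fraction of the labeling reaction,
#'   in (0, 1].
#' @param flag_limits Percent-exchange interval outside which a record is
#'   flagged as suspect (default below -10 or above 110).
#'
#' @return A tibble with columns `uptake` (Da), `percent_exchange` (% of
#'   theoretical maximum; `NA` and flagged when `n_ex` is 0) and `flagged`.
#' @export
#' @examples
#' relative_uptake(502.754, 500, n_ex = 7, d2o_fraction = 0.782)
relative_uptake <- function(record_centroid, undeut_centroid, n_ex,
                            d2o_fraction, flag_limits = c(-10, 110)) {
  if (any(d2o_fraction <= 0 | d2o_fraction > 1)) {
    abort("relative_uptake(): d2o_fraction must be in (0, 1]")
  }
  if (any(n_ex < 0)) abort("relative_uptake(): n_ex must be >= 0")
  uptake <- record_centroid - undeut_centroid
  max_uptake <- n_ex * DEUTERIUM_MASS_SHIFT * d2o_fraction
  percent <- ifelse(n_ex > 0, 100 * uptake / max_uptake, NA_real_)
  flagged <- (n_ex == 0 & abs(uptake) > 0) |
    (!is.na(percent) & (percent < flag_limits[1] | percent > flag_limits[2]))
  tibble(uptake = uptake, percent_exchange = percent, flagged = flagged)
}

#' Final deuterium fraction of a labeling reaction
#'
#' The exchange reaction dilutes the deuterated buffer with the protiated
#' protein stock, so the final deuterium fraction is the buffer's fraction
#' scaled by the volume ratio: `buffer_d2o * v_buffer / (v_buffer + v_protein)`.
#'
#' @param v_buffer Volume of deuterated exchange buffer added (microlitres).
#' @param v_protein Volume of protein stock (microlitres).
#' @param buffer_d2o Deuterium fraction of the exchange buffer, in (0, 1].
#' @return Final deuterium fraction of the reaction (unitless).
#' @export
#' @examples
#' labeling_fraction(12.55, 2.45, 0.9347)  # ~0.782
labeling_fraction <- function(v_buffer, v_protein, buffer_d2o) {
  if (any(v_buffer <= 0)) abort("labeling_fraction(): v_buffer must be > 0")
  if (any(v_protein < 0)) abort("labeling_fraction(): v_protein must be >= 0")
  if (any(buffer_d2o <= 0 | buffer_d2o > 1)) {
    abort("labeling_fraction(): buffer_d2o must be in (0, 1]")
  }
  if (any(v_buffer + v_protein <= 0)) abort("labeling_fraction(): zero total volume")
  buffer_d2o * v_buffer / (v_buffer + v_protein)
}

#' Assemble uptake records from measured centroid masses
#'
#' The table path of the uptake module: takes per-measurement centroid masses
#' (already computed, e.g. exported from an HDX platform, or produced by
#' [envelope_centroid()]) and builds the tidy uptake-record table the
#' differential stage consumes. Centroid and envelope inputs yield identical
#' record structures.
#'
#' @param measurements A data frame with columns `protein`, `start`, `end`,
#'   `sequence`, `charge`, `state`, `timepoint` (s), `replicate`, and
#'   `centroid_mass` (neutral Da).
#' @param d2o_fraction Final deuterium fraction of the labeling reaction.
#' @param undeut Optional data frame of undeuterated centroids (`protein`,
#'   `start`, `end`, `sequence`, `undeut_centroid`); when missing, the
#'   undeuterated centroid is computed from the sequence via [peptide_mass()].
#'
#' @return A tibble of uptake records: the peptide columns plus `state`,
#'   `timepoint`, `replicate`, `centroid_mass`, `uptake`, `percent_exchange`,
#'   `flagged`, `n_ex`, `d2o_fraction`.
#' @export
uptake_records <- function(measurements, d2o_fraction, undeut = NULL) {
  required <- c("protein", "start", "end", "sequence", "charge", "state",
                "timepoint", "replicate", "centroid_mass")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("uptake_records(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as_tibble(measurements)
  if (nrow(m) == 0) abort("uptake_records(): empty measurement table")
  m$n_ex <- vapply(m$sequence, exchangeable_amides, integer(1), USE.NAMES = FALSE)
  if (is.null(undeut)) {
    seqs <- unique(m$sequence)
    und <- tibble(sequence = seqs,
                  undeut_centroid = vapply(seqs, peptide_mass, numeric(1),
                                           USE.NAMES = FALSE))
    m <- left_join(m, und, by = "sequence")
  } else {
    m <- left_join(m, undeut,
                   by = intersect(c("protein", "start", "end", "sequence"),
                                  names(undeut)))
  }
  ru <- relative_uptake(m$centroid_mass, m$undeut_centroid, m$n_ex, d2o_fraction)
  m$uptake <- ru$uptake
  m$percent_exchange <- ru$percent_exchange
  m$flagged <- ru$flagged
  m$d2o_fraction <- d2o_fraction
  select(m, dplyr::all_of(c(required, "uptake", "percent_exchange",
                            "flagged", "n_ex", "d2o_fraction")))
}
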