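# Differential exchange: two-state comparison, three-criterion significance
# filter, Woods-plot summaries, per-residue consensus.

#' Significance criteria for differential exchange
#'
#' The three-gate filter: a peptide is significant when, at some timepoint,
#' the absolute uptake difference, the absolute percent-exchange difference,
#' and the t-test p-value all pass simultaneously (|dD| >= `min_da`,
#' |d%| >= `min_percent`, p < `max_p`). Defaults are the widely used
#' 0.45 Da / 5% / 0.01 thresholds.
#'
#' @param min_da Minimum absolute uptake difference (Da), > 0.
#' @param min_percent Minimum absolute percent-exchange difference (%), > 0.
#' @param max_p Maximum t-test p-value, > 0.
#' @param any_timepoint If `TRUE` (default) a single passing timepoint makes
#'   the peptide significant; all three gates must pass at that same
#'   timepoint.
#' @return An object of class `significance_criteria`.
#' @export
significance_criteria <- function(min_da = 0.45, min_percent = 5,
                                  max_p = 0.01, any_timepoint = TRUE) {
  if (min_da <= 0 || min_percent <= 0 || max_p <= 0) {
    abort("significance_criteria(): all thresholds must be > 0")
  }
  structure(list(min_da = min_da, min_percent = min_percent, max_p = max_p,
                 any_timepoint = any_timepoint),
            class = "significance_criteria")
}

# Vectorised unpaired two-tailed t test from group summary statistics.
# Welch (default) or pooled-variance Student. Zero variance in both groups is
# resolved deterministically: p = 1 if the means agree, p = 0 otherwise
# (perfect separation). Returns NA when either group has < 2 replicates.
welch_p <- function(m1, s1, n1, m2, s2, n2, pooled = FALSE) {
  v1 <- s1^2; v2 <- s2^2
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  both_zero <- !is.na(se) & se == 0
  p[both_zero] <- ifelse(m1[both_zero] == m2[both_zero], 1, 0)
  p[n1 < 2 | n2 < 2] <- NA_real_
  p
}

#' Compare deuterium exchange between two states
#'
#' Per peptide and timepoint, computes the mean uptake difference (state b
#' minus state a, so protection upon binding is negative), the difference on
#' the percent-exchange scale, and an unpaired two-tailed t-test p-value on
#' the replicate uptakes (Welch by default; `pooled = TRUE` for the classic
#' equal-variance Student test). A peptide is flagged significant when some
#' timepoint passes all three gates of `criteria` simultaneously. Summed
#' quantities per peptide: `sum_delta_d` is the sum of per-timepoint
#' differences over the shared time course, and `sum_sd` the sum of the
#' per-timepoint SDs of the difference, each propagated as
#' `sqrt(sd_a^2/n_a + sd_b^2/n_b)`.
#'
#' Cells (peptide x timepoint) present in only one state are dropped and
#' reported in attribute `dropped_cells`; peptides present in only one state
#' are kept in the output with `NA` statistics and can never be significant.
#' With a single replicate the p-value is `NA` and the peptide cannot be
#' significant.
#'
#' @param records Tidy uptake records (see [uptake_records()] /
#'   [simulate_uptake()]) containing both states, or the state-a records if
#'   `records_b` is given.
#' @param records_b Optional records of the second state.
#' @param state_a,state_b State labels; defaults are the first two states in
#'   order of appearance, so `compare_states(bind_rows(apo, bound))`
#'   compares bound minus apo.
#' @param criteria A [significance_criteria()].
#' @param pooled Use pooled-variance Student t instead of Welch.
#' @param adjust P-value adjustment method applied across all cells
#'   (`"none"`, the default and the conventional choice for the three-gate
#'   filter, or any `stats::p.adjust` method such as `"BH"`).
#' @return A tibble of class `hdx_comparison`, one row per peptide x
#'   timepoint: peptide columns, `center_residue`, group means/SDs/sizes,
#'   `delta_d`, `delta_percent`, `p_value`, `passes` (all three gates at this
#'   timepoint), and per-peptide `significant`, `sum_delta_d`, `sum_sd`.
#' @export
compare_states <- function(records, records_b = NULL, state_a = NULL,
                           state_b = NULL, criteria = significance_criteria(),
                           pooled = FALSE, adjust = "none") {
  if (!is.null(records_b)) records <- bind_rows(records, records_b)
  states <- unique(records$state)
  if (is.null(state_a)) state_a <- states[1]
  if (is.null(state_b)) state_b <- setdiff(states, state_a)[1]
  if (is.na(state_b) || !all(c(state_a, state_b) %in% states)) {
    abort("compare_states(): need records for two states")
  }
  rec <- filter(records, .data$state %in% c(state_a, state_b))
  cell <- summarise(
    group_by(rec, .data$protein, .data$start, .data$end, .data$sequence,
             .data$state, .data$timepoint),
    mean_d = mean(.data$uptake), sd_d = sd(.data$uptake),
    mean_pct = mean(.data$percent_exchange), n = dplyr::n(),
    .groups = "drop")
  cell$sd_d[is.na(cell$sd_d)] <- 0   # single replicate; p handled via n
  wide <- tidyr::pivot_wider(
    mutate(cell, state = ifelse(.data$state == state_a, "a", "b")),
    names_from = "state",
    values_from = c("mean_d", "sd_d", "mean_pct", "n"))
  for (col in c("mean_d_a", "mean_d_b", "sd_d_a", "sd_d_b",
                "mean_pct_a", "mean_pct_b", "n_a", "n_b")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  complete <- !is.na(wide$n_a) & !is.na(wide$n_b)
  dropped <- select(wide[!complete, ], dplyr::all_of(
    c("protein", "start", "end", "sequence", "timepoint")))
  if (nrow(dropped) > 0) {
    warn(paste0("compare_states(): dropped ", nrow(dropped),
                " cell(s) present in only one state (see attr 'dropped_cells')"))
  }
  cmp <- wide[complete, ]
  # keep peptides that lost every timepoint visible, but never significant
  lost <- dplyr::anti_join(
    distinct(dropped, .data$protein, .data$start, .data$end, .data$sequence),
    distinct(cmp, .data$protein, .data$start, .data$end, .data$sequence),
    by = c("protein", "start", "end", "sequence"))
  cmp <- mutate(cmp,
                center_residue = (.data$start + .data$end) / 2,
                delta_d = .data$mean_d_b - .data$mean_d_a,
                delta_percent = .data$mean_pct_b - .data$mean_pct_a,
                p_value = welch_p(.data$mean_d_a, .data$sd_d_a, .data$n_a,
                                  .data$mean_d_b, .data$sd_d_b, .data$n_b,
                                  pooled = pooled),
                diff_sd = sqrt(.data$sd_d_a^2 / .data$n_a +
                                 .data$sd_d_b^2 / .data$n_b))
  if (adjust != "none") cmp$p_value <- stats::p.adjust(cmp$p_value, adjust)
  cmp <- mutate(cmp,
                passes = !is.na(.data$p_value) &
                  abs(.data$delta_d) >= criteria$min_da &
                  abs(.data$delta_percent) >= criteria$min_percent &
                  .data$p_value < criteria$max_p)
  per_pep <- summarise(
    group_by(cmp, .data$protein, .data$start, .data$end, .data$sequence),
    significant = if (criteria$any_timepoint) any(.data$passes)
                  else all(.data$passes),
    sum_delta_d = sum(.data$delta_d),
    sum_sd = sum(.data$diff_sd),
    .groups = "drop")
  cmp <- left_join(cmp, per_pep,
                   by = c("protein", "start", "end", "sequence"))
  if (nrow(lost) > 0) {
    lost <- mutate(lost, timepoint = NA_real_,
                   center_residue = (.data$start + .data$end) / 2,
                   significant = FALSE)
    cmp <- bind_rows(cmp, lost)
  }
  cmp <- arrange(cmp, .data$protein, .data$start, .data$end, .data$timepoint)
  structure(cmp,
            class = c("hdx_comparison", class(tibble())),
            criteria = criteria, states = c(a = state_a, b = state_b),
            dropped_cells = dropped, pooled = pooled)
}

#' Woods-plot summary of a state comparison
#'
#' Collapses an [compare_states()] result to one row per peptide: the center
#' residue `(start + end) / 2`, the summed uptake difference over the time
#' course, its summed SD, and the significance flag. Sorted by center
#' residue; `autoplot()` draws the Woods plot with significant peptides in
#' red.
#'
#' @param comparison An `hdx_comparison`.
#' @return A tibble of class `hdx_woods`, one row per peptide.
#' @export
woods_summary <- function(comparison) {
  if (nrow(comparison) == 0) abort("woods_summary(): empty comparison")
  out <- distinct(as_tibble(comparison), .data$protein, .data$start,
                  .data$end, .data$sequence, .data$center_residue,
                  .data$sum_delta_d, .data$sum_sd, .data$significant)
  out <- arrange(out, .data$protein, .data$center_residue, .data$start)
  structure(out, class = c("hdx_woods", class(tibble())),
            states = attr(comparison, "states"),
            criteria = attr(comparison, "criteria"))
}

#' Per-residue significance consensus
#'
#' Projects significant peptides onto residues: a residue is called
#' protected (negative summed uptake difference, i.e. less exchange upon
#' binding) or deprotected (positive) when covered by at least one
#' significant peptide of that sign over its full span; residues covered by
#' significant peptides of both signs are reported as `"conflict"`.
#'
#' @param comparison An `hdx_comparison` or `hdx_woods` table.
#' @return A tibble with `protein`, `residue`, `n_protected`,
#'   `n_deprotected`, `call` (`"protected"`, `"deprotected"`, `"conflict"`);
#'   empty when nothing is significant.
#' @export
residue_consensus <- function(comparison) {
  peps <- if (inherits(comparison, "hdx_woods")) comparison
          else woods_summary(comparison)
  sig <- filter(as_tibble(peps), .data$significant, !is.na(.data$sum_delta_d))
  if (nrow(sig) == 0) {
    return(tibble(protein = character(), residue = integer(),
                  n_protected = integer(), n_deprotected = integer(),
                  call = character()))
  }
  expanded <- tidyr::unnest(
    mutate(sig, residue = purrr::map2(.data$start, .data$end, seq)),
    "residue")
  out <- summarise(group_by(expanded, .data$protein, .data$residue),
                   n_protected = sum(.data$sum_delta_d < 0),
                   n_deprotected = sum(.data$sum_delta_d > 0),
                   .groups = "drop")
  out <- mutate(out, call = dplyr::case_when(
    .data$n_protected > 0 & .data$n_deprotected > 0 ~ "conflict",
    .data$n_protected > 0 ~ "protected",
    TRUE ~ "deprotected"))
  arrange(out, .data$protein, .data$residue)
}
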