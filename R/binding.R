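# Equilibrium binding fits, mutant response comparison, reporter-ratio
# normalisation.

#' Fit a one-site specific binding model
#'
#' Least-squares fit of `R(C) = rmax * C / (kd + C)` to a dose-response
#' table. Initialisation is deterministic: `rmax0` is the maximum response
#' and `kd0` the concentration nearest half-maximum. Matched nonspecific
#' (background) responses, when present, are subtracted before fitting.
#' Standard errors come from the fit covariance. Non-convergence yields an
#' explicit failure object (`converged = FALSE`), never a silent best guess.
#'
#' @param curve Data frame with columns `concentration` (nM) and `response`;
#'   optional `background` column of matched nonspecific-control responses.
#' @return An object of class `hdx_binding_fit` with elements `kd`, `rmax`,
#'   `kd_se`, `rmax_se`, `rss`, `n_points`, `converged`, `data`, and (on
#'   success) the underlying `nls` fit. `tidy()` gives the parameter table,
#'   `glance()` the one-row summary, `autoplot()` the curve.
#' @export
#' @examples
#' curve <- simulate_dose_response(23.5, 1, c(10, 50, 156, 625, 2500), 0)
#' glance(fit_one_site(curve))
fit_one_site <- function(curve) {
  stopifnot(all(c("concentration", "response") %in% names(curve)))
  curve <- as_tibble(curve)
  if (any(curve$concentration < 0)) abort("fit_one_site(): negative concentrations")
  resp <- curve$response
  if ("background" %in% names(curve)) resp <- resp - curve$background
  conc <- curve$concentration
  dat <- tibble(concentration = conc, response = resp)
  failed <- function(msg) {
    structure(list(kd = NA_real_, rmax = NA_real_, kd_se = NA_real_,
                   rmax_se = NA_real_, rss = NA_real_, n_points = nrow(dat),
                   converged = FALSE, message = msg, data = dat, fit = NULL),
              class = "hdx_binding_fit")
  }
  if (length(unique(conc)) < 3) {
    warn("fit_one_site(): fewer than 3 distinct concentrations")
  }
  if (all(resp == 0) || max(resp) <= 0) {
    return(failed("degenerate responses (all zero or non-positive)"))
  }
  rmax0 <- max(resp)
  kd0 <- conc[which.min(abs(resp - rmax0 / 2))]
  if (kd0 <= 0) kd0 <- max(min(conc[conc > 0], na.rm = TRUE), 1e-3)
  fit <- tryCatch(
    nls(response ~ rmax * concentration / (kd + concentration), data = dat,
        start = list(rmax = rmax0, kd = kd0), algorithm = "port",
        lower = c(rmax = 0, kd = 1e-12),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(rmax = NA, kd = NA))
  kd_hat <- unname(est["kd"])
  if (!is.finite(kd_hat) || kd_hat <= 0) {
    return(failed("fit converged to a non-positive kd"))
  }
  # eventual-estimate span check (precondition as a warning, not an error)
  if (kd_hat < min(conc[conc > 0]) || kd_hat > max(conc)) {
    warn("fit_one_site(): concentration grid does not span the kd estimate")
  }
  structure(list(kd = kd_hat, rmax = unname(est["rmax"]),
                 kd_se = unname(se["kd"]), rmax_se = unname(se["rmax"]),
                 rss = sum(stats::residuals(fit)^2), n_points = nrow(dat),
                 converged = TRUE, message = "ok", data = dat, fit = fit),
            class = "hdx_binding_fit")
}

#' @export
print.hdx_binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hdx_binding_fit> FAILED: ", x$message, "\n", sep = "")
  } else {
    cat(sprintf("<hdx_binding_fit> kd = %.4g +/- %.2g nM, rmax = %.4g +/- %.2g (n = %d)\n",
                x$kd, x$kd_se, x$rmax, x$rmax_se, x$n_points))
  }
  invisible(x)
}

#' @export
tidy.hdx_binding_fit <- function(x, ...) {
  tibble(term = c("kd", "rmax"),
         estimate = c(x$kd, x$rmax),
         std.error = c(x$kd_se, x$rmax_se))
}

#' @export
glance.hdx_binding_fit <- function(x, ...) {
  tibble(kd = x$kd, rmax = x$rmax, kd_se = x$kd_se, rmax_se = x$rmax_se,
         rss = x$rss, n_points = x$n_points, converged = x$converged)
}

#' Predicted response of a binding fit
#' @param object An `hdx_binding_fit`.
#' @param newdata Optional data frame with a `concentration` column.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.hdx_binding_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else newdata$concentration
  object$rmax * conc / (object$kd + conc)
}

#' Compare mutant maximum responses to wild type
#'
#' Welch's unpaired two-tailed t test of mutant versus wild-type replicate
#' responses, with the effect reported as the mutant/wild-type mean ratio
#' and a significance label using the thresholds ns > 0.01, `*` < 0.01,
#' `**` < 0.001, `***` < 0.0001. Zero within-group variance (typical of toy
#' fixtures) is floored at `.Machine$double.eps * mean^2` so the test stays
#' defined and deterministic.
#'
#' @param wt,mut Numeric vectors of replicate responses (>= 2 each for a
#'   p-value).
#' @return One-row tibble: `effect`, `p_value`, `stars`, `n_wt`, `n_mut`.
#' @export
compare_max_response <- function(wt, mut) {
  n_wt <- length(wt); n_mut <- length(mut)
  effect <- mean(mut) / mean(wt)
  if (n_wt < 2 || n_mut < 2) {
    return(tibble(effect = effect, p_value = NA_real_, stars = NA_character_,
                  n_wt = n_wt, n_mut = n_mut))
  }
  if (var(wt) == 0 || var(mut) == 0) {
    floorv <- function(x) {
      v <- var(x)
      if (v > 0) v else .Machine$double.eps * mean(x)^2
    }
    p <- welch_p(mean(wt), sqrt(floorv(wt)), n_wt,
                 mean(mut), sqrt(floorv(mut)), n_mut)
    if (mean(wt) == mean(mut)) p <- 1
    warn("compare_max_response(): zero within-group variance floored")
  } else {
    p <- stats::t.test(mut, wt, var.equal = FALSE)$p.value
  }
  tibble(effect = effect, p_value = p, stars = response_stars(p),
         n_wt = n_wt, n_mut = n_mut)
}

response_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 1e-4 ~ "***",
                   p < 1e-3 ~ "**",
                   p < 1e-2 ~ "*",
                   TRUE ~ "ns")
}

#' Normalise two-channel reporter ratios
#'
#' Per well, the reporter ratio is the 530 nm intensity divided by the
#' 485 nm intensity. Ratios are normalised to the mean ratio of the internal
#' control condition (biosensor alone), and fold changes are expressed
#' relative to the mean normalised ratio of the baseline control (e.g. the
#' empty-vector wells). Uniform channel gains cancel, so fold changes are
#' gain-invariant.
#'
#' @param wells Data frame with columns `condition`, `intensity_530`,
#'   `intensity_485` (both > 0), one row per well.
#' @param internal_control Condition label of the internal normalisation
#'   wells.
#' @param baseline_control Condition label of the baseline (fold-change
#'   reference) wells.
#' @return Per-well tibble with `ratio`, `normalized_ratio`, `fold_change`,
#'   carrying a `summary` attribute (per-condition mean, SEM, n of the fold
#'   change) also available via [bret_condition_summary()].
#' @export
bret_normalize <- function(wells, internal_control, baseline_control) {
  stopifnot(all(c("condition", "intensity_530", "intensity_485") %in%
                  names(wells)))
  wells <- as_tibble(wells)
  if (any(wells$intensity_530 <= 0) || any(wells$intensity_485 <= 0)) {
    abort("bret_normalize(): intensities must be > 0")
  }
  for (ctl in c(internal_control, baseline_control)) {
    if (!ctl %in% wells$condition) {
      abort(paste0("bret_normalize(): missing control condition: ", ctl))
    }
  }
  wells <- mutate(wells, ratio = .data$intensity_530 / .data$intensity_485)
  int_mean <- mean(wells$ratio[wells$condition == internal_control])
  wells <- mutate(wells, normalized_ratio = .data$ratio / int_mean)
  base_mean <- mean(wells$normalized_ratio[wells$condition == baseline_control])
  wells <- mutate(wells, fold_change = .data$normalized_ratio / base_mean)
  summary <- summarise(group_by(wells, .data$condition),
                       mean_fold = mean(.data$fold_change),
                       sem_fold = sd(.data$fold_change) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
  structure(wells, summary = summary)
}

#' Per-condition summary of normalised reporter ratios
#' @param normalized Output of [bret_normalize()].
#' @return Tibble with `condition`, `mean_fold`, `sem_fold`, `n`.
#' @export
bret_condition_summary <- function(normalized) attr(normalized, "summary")
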