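# helper to build replicate records directly on the uptake/percent scale
make_records <- function(uptakes_by_state, percents_by_state,
                         timepoint = 300, start = 1, end = 12) {
  purrr::imap_dfr(uptakes_by_state, function(u, st) {
    tibble::tibble(protein = "p", start = start, end = end,
                   sequence = strrep("G", end - start + 1), charge = 2,
                   state = st, timepoint = timepoint,
                   replicate = seq_along(u), uptake = u,
                   percent_exchange = percents_by_state[[st]],
                   flagged = FALSE, n_ex = end - start - 1,
                   d2o_fraction = 0.68)
  })
}

test_that("identical states yield zero differences and no significance", {
  u <- c(1.00, 1.02, 0.98)
  rec <- make_records(list(apo = u, bound = u),
                      list(apo = u * 10, bound = u * 10))
  cmp <- compare_states(rec, state_a = "apo", state_b = "bound")
  expect_equal(cmp$delta_d, 0)
  expect_equal(cmp$delta_percent, 0)
  expect_false(any(cmp$significant))
})

test_that("all three gates must pass at the same timepoint", {
  u_a <- c(1.00, 1.01, 0.99)
  u_b <- u_a + 0.50
  # Da and p gates pass; percent gate decides
  sig <- compare_states(make_records(list(apo = u_a, bound = u_b),
                                     list(apo = c(10, 10.1, 9.9),
                                          bound = c(16, 16.1, 15.9))),
                        state_a = "apo", state_b = "bound")
  expect_equal(unique(sig$delta_d), 0.5, tolerance = 1e-9)
  expect_equal(unique(sig$delta_percent), 6, tolerance = 1e-9)
  expect_true(all(sig$p_value < 0.01))
  expect_true(all(sig$significant))
  not <- compare_states(make_records(list(apo = u_a, bound = u_b),
                                     list(apo = c(10, 10.1, 9.9),
                                          bound = c(14, 14.1, 13.9))),
                        state_a = "apo", state_b = "bound")
  expect_equal(unique(not$delta_percent), 4, tolerance = 1e-9)
  expect_false(any(not$significant))  # 0.50 Da, p < 0.01, but only 4%
})

test_that("summed deuteron difference adds per-timepoint deltas", {
  deltas <- c(0.1, 0.2, 0.3, 0.4)
  rec <- purrr::map_dfr(seq_along(deltas), function(i) {
    make_records(list(apo = c(1, 1, 1), bound = c(1, 1, 1) + deltas[i]),
                 list(apo = rep(10, 3), bound = rep(10, 3) + deltas[i]),
                 timepoint = c(30, 300, 3000, 10000)[i])
  })
  cmp <- compare_states(rec, state_a = "apo", state_b = "bound")
  expect_equal(unique(cmp$sum_delta_d), 1.0, tolerance = 1e-12)
  # noise-free replicates: per-timepoint diff SD is 0, so the sum is 0
  expect_equal(unique(cmp$sum_sd), 0)
})

test_that("vectorised Welch p-values agree with stats::t.test", {
  set.seed(11)
  for (rep in 1:20) {
    a <- rnorm(3, 1, 0.1)
    b <- rnorm(4, 1.2, 0.2)
    rec <- dplyr::bind_rows(
      tibble::tibble(protein = "p", start = 1, end = 10,
                     sequence = strrep("G", 10), charge = 2, state = "apo",
                     timepoint = 30, replicate = seq_along(a), uptake = a,
                     percent_exchange = a * 10, flagged = FALSE, n_ex = 8,
                     d2o_fraction = 0.68),
      tibble::tibble(protein = "p", start = 1, end = 10,
                     sequence = strrep("G", 10), charge = 2, state = "bound",
                     timepoint = 30, replicate = seq_along(b), uptake = b,
                     percent_exchange = b * 10, flagged = FALSE, n_ex = 8,
                     d2o_fraction = 0.68))
    cmp <- compare_states(rec, state_a = "apo", state_b = "bound")
    expect_equal(cmp$p_value, t.test(b, a)$p.value, tolerance = 1e-12)
    pooled <- compare_states(rec, state_a = "apo", state_b = "bound",
                             pooled = TRUE)
    expect_equal(pooled$p_value, t.test(b, a, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("single replicates give undefined p and can never be significant", {
  rec <- make_records(list(apo = 1, bound = 2), list(apo = 10, bound = 30))
  cmp <- compare_states(rec, state_a = "apo", state_b = "bound")
  expect_true(is.na(cmp$p_value))
  expect_false(any(cmp$significant))
})

test_that("mismatched grids drop cells with an explicit report", {
  rec <- dplyr::bind_rows(
    make_records(list(apo = c(1, 1.1, 0.9)), list(apo = rep(10, 3)),
                 timepoint = 30),
    make_records(list(apo = c(1, 1.1, 0.9), bound = c(1, 1.1, 0.9)),
                 list(apo = rep(10, 3), bound = rep(10, 3)), timepoint = 300),
    make_records(list(bound = c(2, 2.1, 1.9)), list(bound = rep(20, 3)),
                 timepoint = 3000, start = 50, end = 60))
  expect_warning(cmp <- compare_states(rec, state_a = "apo",
                                       state_b = "bound"), "dropped")
  dropped <- attr(cmp, "dropped_cells")
  expect_identical(nrow(dropped), 2L)
  # the peptide present in only one state is reported but never significant
  lone <- dplyr::filter(cmp, start == 50)
  expect_identical(nrow(lone), 1L)
  expect_false(lone$significant)
})

test_that("raising any threshold never grows the significant set", {
  truth <- fixture_truth(replicate_sd = 0.05)
  peps <- fixture_peptides()
  rec <- dplyr::bind_rows(simulate_uptake(truth, peps, "apo"),
                          simulate_uptake(truth, peps, "bound"))
  base <- significance_criteria()
  sig0 <- woods_summary(compare_states(rec, state_a = "apo",
                                       state_b = "bound",
                                       criteria = base))$significant
  for (crit in list(significance_criteria(min_da = 0.9),
                    significance_criteria(min_percent = 15),
                    significance_criteria(max_p = 1e-4))) {
    sig1 <- woods_summary(compare_states(rec, state_a = "apo",
                                         state_b = "bound",
                                         criteria = crit))$significant
    expect_true(all(!sig1 | sig0))
  }
  # a Benjamini-Hochberg option exists and is also no less conservative
  sig_bh <- woods_summary(compare_states(rec, state_a = "apo",
                                         state_b = "bound", adjust = "BH"))
  expect_true(all(!sig_bh$significant | sig0))
})

test_that("woods summary centers peptides and flags only significant ones", {
  rec <- make_records(list(apo = c(1, 1.01, 0.99), bound = c(1, 1.01, 0.99)),
                      list(apo = rep(10, 3), bound = rep(10, 3)),
                      start = 89, end = 102)
  w <- woods_summary(compare_states(rec, state_a = "apo", state_b = "bound"))
  expect_equal(w$center_residue, 95.5)
  expect_identical(sum(w$significant), 0L)
})

test_that("noise-free planted protection flags exactly the overlapping peptides", {
  truth <- exchange_ground_truth(fixture_sequence(), protected_range = 41:60,
                                 protection_factor = 1000,
                                 rates = rep(0.1, 120), replicate_sd = 0)
  peps <- fixture_peptides()
  rec <- dplyr::bind_rows(simulate_uptake(truth, peps, "apo"),
                          simulate_uptake(truth, peps, "bound"))
  w <- woods_summary(compare_states(rec, state_a = "apo", state_b = "bound"))
  w <- dplyr::arrange(w, start)
  expected <- overlaps_planted(dplyr::arrange(peps, start), 41:60)
  expect_identical(w$significant, expected)
  # protection upon binding is negative by convention
  expect_true(all(w$sum_delta_d[w$significant] < 0))
})

test_that("residue consensus unions spans and reports conflicts", {
  empty <- residue_consensus(
    compare_states(make_records(list(apo = c(1, 1, 1), bound = c(1, 1, 1)),
                                list(apo = rep(10, 3), bound = rep(10, 3))),
                   state_a = "apo", state_b = "bound"))
  expect_identical(nrow(empty), 0L)
  # one significant protected peptide spanning 539..544
  rec <- make_records(list(apo = c(2.0, 2.01, 1.99), bound = c(1.0, 1.01, 0.99)),
                      list(apo = rep(40, 3), bound = rep(20, 3)),
                      start = 539, end = 544)
  cons <- residue_consensus(compare_states(rec, state_a = "apo",
                                           state_b = "bound"))
  expect_identical(cons$residue, 539:544)
  expect_true(all(cons$call == "protected"))
  # overlapping same-sign peptides mark the union of spans
  rec2 <- dplyr::bind_rows(
    rec, make_records(list(apo = c(2.0, 2.01, 1.99), bound = c(1.0, 1.01, 0.99)),
                      list(apo = rep(40, 3), bound = rep(20, 3)),
                      start = 542, end = 550))
  cons2 <- residue_consensus(compare_states(rec2, state_a = "apo",
                                            state_b = "bound"))
  expect_identical(cons2$residue, 539:550)
})
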