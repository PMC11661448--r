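# Shared fixtures and independent oracles, built in code at test time.

# 120-residue protein with a central segment that gains protection on binding
fixture_sequence <- function() {
  paste(rep("ACDEFGHIKLMNQRSTVWYA", 6), collapse = "")
}

fixture_truth <- function(protected_range = 41:60, replicate_sd = 0.02,
                          seed = 7L, ...) {
  exchange_ground_truth(fixture_sequence(), protected_range = protected_range,
                        protection_factor = 100, replicate_sd = replicate_sd,
                        seed = seed, ...)
}

fixture_peptides <- function(seed = 3L) {
  tile_peptides(fixture_sequence(), "prot", seed = seed)
}

# TRUE for peptides whose exchangeable amides (positions start+2..end,
# prolines excluded) overlap the planted range
overlaps_planted <- function(peptides, range) {
  peptides$start + 2L <= max(range) & peptides$end >= min(range)
}

test_path_extdata <- function(f) {
  system.file("extdata", f, package = "hdxstruct", mustWork = TRUE)
}

# random two-chain heavy-atom cloud (for contact/SASA oracles)
random_atom_model <- function(n_atoms, box = 25, seed = 1L) {
  set.seed(seed)
  el <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
               prob = c(0.6, 0.2, 0.15, 0.05))
  structure_model(tibble::tibble(
    chain = rep(c("A", "B"), length.out = n_atoms),
    resno = seq_len(n_atoms), insert = "", resid = "ALA", atom = "CA",
    element = el,
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box)))
}

# Independent Shrake-Rupley oracle: straight loops over random sphere points
# (its own point set, not the implementation's deterministic lattice).
brute_force_sasa <- function(model, probe = 1.4, n_points = 4000L,
                             seed = 99L) {
  set.seed(seed)
  a <- model$atoms
  r <- a$radius + probe
  z <- runif(n_points, -1, 1)
  th <- runif(n_points, 0, 2 * pi)
  pts <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    p <- sweep(pts * r[i], 2, c(a$x[i], a$y[i], a$z[i]), "+")
    buried <- rep(FALSE, n_points)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      d2 <- (p[, 1] - a$x[j])^2 + (p[, 2] - a$y[j])^2 + (p[, 3] - a$z[j])^2
      buried <- buried | d2 < r[j]^2
    }
    out[i] <- mean(!buried) * 4 * pi * r[i]^2
  }
  out
}

expect_same_contacts <- function(observed, expected, tol = 1e-9) {
  key <- function(x) paste(x$chain_a, x$resno_a, x$insert_a,
                           x$chain_b, x$resno_b, x$insert_b)
  expect_identical(key(observed), key(expected))
  expect_equal(observed$min_dist, expected$min_dist, tolerance = tol)
}
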