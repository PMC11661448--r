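test_that("SASA of isolated and distant atoms is exact", {
  # isolated carbon, probe 1.4: full sphere 4*pi*(1.70+1.40)^2
  one <- structure_model(tibble::tibble(chain = "A", resno = 1, resid = "ALA",
                                        atom = "CA", element = "C",
                                        x = 0, y = 0, z = 0))
  expect_equal(sasa(one)$atoms$sasa, 4 * pi * 3.1^2, tolerance = 1e-9)
  # two atoms 100 A apart: no occlusion, sum of isolated spheres
  two <- structure_model(tibble::tibble(chain = "A", resno = 1:2,
                                        resid = "ALA", atom = "CA",
                                        element = c("C", "N"),
                                        x = c(0, 100), y = 0, z = 0))
  res <- sasa(two)$atoms$sasa
  expect_equal(res, 4 * pi * c(3.1^2, (1.55 + 1.4)^2), tolerance = 1e-9)
})

test_that("fully superposed atoms keep one sphere of area, split by tie rule", {
  dup <- structure_model(tibble::tibble(chain = "A", resno = 1:2,
                                        resid = "ALA", atom = "CA",
                                        element = "C", x = 0, y = 0, z = 0))
  res <- sasa(dup)$atoms$sasa
  expect_equal(sum(res), 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_equal(res[2], 0)  # the earlier atom keeps the surface
})

test_that("SASA agrees with a brute-force point-in-sphere oracle", {
  model <- random_atom_model(40, box = 18, seed = 5)
  fast <- sasa(model, n_points = 1920L)$atoms$sasa
  slow <- brute_force_sasa(model, n_points = 6000L)
  expect_lt(abs(sum(fast) - sum(slow)) / sum(slow), 0.005)
})

test_that("SASA converges in the number of sphere points", {
  toy <- make_toy_interface(8, separation = 4, seed = 3)
  s1 <- sum(sasa(toy$model, n_points = 960L)$atoms$sasa)
  s2 <- sum(sasa(toy$model, n_points = 1920L)$atoms$sasa)
  expect_lt(abs(s2 - s1) / s1, 0.005)
})

test_that("unknown elements fall back to a configurable radius with a warning", {
  expect_warning(
    m <- structure_model(tibble::tibble(chain = "A", resno = 1, resid = "HEM",
                                        atom = "FE", element = "FE",
                                        x = 0, y = 0, z = 0),
                         fallback_radius = 2.0),
    "fallback")
  expect_equal(m$atoms$radius, 2.0)
})

test_that("contacts honor the cutoff boundary exactly", {
  pair <- function(d) structure_model(tibble::tibble(
    chain = c("A", "B"), resno = 1, resid = "ALA", atom = "CA",
    element = "C", x = c(0, d), y = 0, z = 0))
  expect_identical(nrow(contacts(pair(5.9), "A", "B", 6)), 1L)
  expect_identical(nrow(contacts(pair(6.1), "A", "B", 6)), 0L)
  expect_equal(contacts(pair(5.9), "A", "B", 6)$min_dist, 5.9)
})

test_that("cell-list contacts equal all-pairs brute force on random models", {
  for (seed in 1:3) {
    model <- random_atom_model(500, box = 40, seed = seed)
    cl <- contacts(model, "A", "B", cutoff = 6)
    bf <- hdxstruct:::brute_force_contacts(model, "A", "B", cutoff = 6)
    expect_gt(nrow(cl), 0)
    expect_same_contacts(cl, bf)
  }
})

test_that("contacts are invariant under rigid-body motion", {
  toy <- make_toy_interface(10, separation = 4, seed = 4)
  base <- contacts(toy$model, "A", "B", 5)
  # rotate by an arbitrary rotation and translate
  th <- 0.7; ph <- 1.2
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  xyz <- as.matrix(toy$model$atoms[, c("x", "y", "z")]) %*% (rz %*% rx)
  moved <- toy$model$atoms
  moved$x <- xyz[, 1] + 11.3; moved$y <- xyz[, 2] - 4.2; moved$z <- xyz[, 3] + 2
  rot <- contacts(structure_model(moved), "A", "B", 5)
  expect_same_contacts(rot, base, tol = 1e-6)
})

test_that("chain errors list the available chains", {
  toy <- make_toy_interface(6, separation = 5)
  expect_error(contacts(toy$model, "A", "Q", 6), "available: A, B")
  expect_error(buried_surface(toy$model, "A", "A", n_points = 120),
               "disjoint")
})

test_that("toy interfaces carry correct ground truth", {
  far <- make_toy_interface(8, separation = 100)
  expect_identical(nrow(far$true_contacts), 0L)
  near <- make_toy_interface(8, separation = 4)
  expect_gt(nrow(near$true_contacts), 0)
  expect_equal(min(near$true_contacts$min_dist), 4, tolerance = 1e-6)
})

test_that("buried surface area localises to the interface and balances sides", {
  far <- make_toy_interface(8, separation = 100)
  bsa_far <- buried_surface(far$model, "A", "B", n_points = 480L)
  expect_equal(bsa_far$total_bsa, 0, tolerance = 0.1)
  toy <- make_toy_interface(10, separation = 3.5, seed = 6)
  ifc <- buried_surface(toy$model, "A", "B", n_points = 480L)
  expect_gt(ifc$total_bsa, 0)
  expect_equal(ifc$total_bsa_half, ifc$total_bsa / 2)
  per <- ifc$per_residue
  expect_true(all(per$bsa > -0.1))
  # every ground-truth interface residue buries area; residues far from the
  # interface bury essentially none
  key <- paste(per$chain, per$resno)
  truth_key <- paste(toy$interface_residues$chain, toy$interface_residues$resno)
  expect_true(all(per$bsa[key %in% truth_key] > 0))
  expect_true(all(per$bsa[!key %in% truth_key] < 1))
  # geometric near-symmetry of the two sides
  a_tot <- sum(per$bsa[per$side == "a"])
  b_tot <- sum(per$bsa[per$side == "b"])
  expect_lt(abs(a_tot - b_tot) / max(a_tot, b_tot), 0.2)
})

test_that("duplicated chains bury every residue", {
  # chain B superposed on chain A (tiny offset: at exactly zero the tie rule
  # deliberately hands the whole surface to the first copy)
  one <- hdxstruct:::helix_chain(6, "A")
  dup <- dplyr::mutate(one, chain = "B", x = x + 0.05)
  model <- structure_model(dplyr::bind_rows(one, dup))
  ifc <- buried_surface(model, "A", "B", n_points = 480L)
  expect_true(all(ifc$per_residue$bsa > 0))
})

test_that("merging chains into a side never shrinks the buried area", {
  toy <- make_toy_interface(8, separation = 3.5, seed = 8)
  third <- hdxstruct:::helix_chain(8, "C")
  third$y <- third$y + 9  # flanking the A/B interface
  model <- structure_model(dplyr::bind_rows(toy$model$atoms, third))
  ab_c <- buried_surface(model, c("A", "B"), "C", n_points = 480L)$total_bsa
  a_c <- buried_surface(
    structure_model(dplyr::filter(model$atoms, chain != "B")),
    "A", "C", n_points = 480L)$total_bsa
  b_c <- buried_surface(
    structure_model(dplyr::filter(model$atoms, chain != "A")),
    "B", "C", n_points = 480L)$total_bsa
  expect_gte(ab_c + 0.5, max(a_c, b_c))
})

test_that("PDB and mmCIF encodings of the same model read identically", {
  pdb <- read_structure(test_path_extdata("toy_interface_synthetic.pdb"))
  cif <- suppressWarnings(
    read_structure(test_path_extdata("toy_interface_synthetic.cif")))
  expect_equal(as.data.frame(pdb$atoms), as.data.frame(cif$atoms),
               tolerance = 1e-9)
})

test_that("exchange results project onto structures with overlap statistics", {
  toy <- make_toy_interface(10, separation = 4, seed = 2)
  # an empty comparison yields an all-sentinel annotation
  empty <- map_hdx_to_structure(
    tibble::tibble(protein = character(), start = integer(), end = integer(),
                   sequence = character(), center_residue = numeric(),
                   sum_delta_d = numeric(), sum_sd = numeric(),
                   significant = logical()) |>
      structure(class = c("hdx_woods", class(tibble::tibble()))),
    toy$model, c(prot = "A"))
  expect_true(all(empty$residues$annotation == -100))
  expect_true(all(!empty$residues$covered))
  # planted significant peptides exactly on chain A's interface residues
  ifc_a <- dplyr::filter(toy$interface_residues, chain == "A")
  woods <- tibble::tibble(protein = "prot",
                          start = min(ifc_a$resno), end = max(ifc_a$resno),
                          sequence = strrep("A", max(ifc_a$resno) -
                                              min(ifc_a$resno) + 1),
                          center_residue = mean(range(ifc_a$resno)),
                          sum_delta_d = -2.5, sum_sd = 0.1,
                          significant = TRUE)
  class(woods) <- c("hdx_woods", class(tibble::tibble()))
  contiguous <- nrow(ifc_a) == max(ifc_a$resno) - min(ifc_a$resno) + 1
  m <- map_hdx_to_structure(woods, toy$model, c(prot = "A"),
                            interface_residues = ifc_a)
  if (contiguous) expect_equal(m$overlap$jaccard, 1)
  covered <- dplyr::filter(m$residues, covered)
  expect_true(all(covered$annotation == -2.5))
  # spans absent from the model count as uncovered, not as an error
  woods2 <- dplyr::mutate(woods, start = 900L, end = 905L,
                          sequence = strrep("A", 6))
  class(woods2) <- class(woods)
  m2 <- map_hdx_to_structure(woods2, toy$model, c(prot = "A"))
  expect_true(all(!m2$residues$covered))
  expect_error(map_hdx_to_structure(woods, toy$model, c(other = "A")),
               "no chain mapping")
})

test_that("annotated PDB files round-trip through the reader", {
  toy <- make_toy_interface(6, separation = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_annotated_pdb(toy$model, path)
  back <- read_structure(path)
  expect_equal(as.data.frame(back$atoms[, c("chain", "resno", "element")]),
               as.data.frame(toy$model$atoms[, c("chain", "resno", "element")]))
  expect_equal(back$atoms$x, toy$model$atoms$x, tolerance = 1e-3)
})
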