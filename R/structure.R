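# Structure module: atom-table model, Shrake-Rupley SASA, interchain
# contacts, buried surface area, HDX-to-structure projection.

#' Default van der Waals radii (Angstrom)
#'
#' Fixed published heavy-atom radii used for SASA; override per call.
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer), `resid`
#'   (3-letter residue name), `atom` (atom name), `element`, `x`, `y`, `z`
#'   (Angstrom); optional `insert` (insertion code, `""` when absent). The
#'   residue key is (chain, resno, insert) so insertion codes are preserved.
#' @param radii Named vdW radius table; elements missing from it fall back to
#'   `fallback_radius` with a warning.
#' @param fallback_radius Radius for unknown elements (Angstrom).
#' @return An object of class `structure_model` wrapping the atom tibble.
#' @export
structure_model <- function(atoms, radii = default_vdw_radii(),
                            fallback_radius = 1.70) {
  required <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("structure_model(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("structure_model(): non-finite coordinates")
  }
  atoms$element <- toupper(atoms$element)
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown)) {
    warn(paste0("structure_model(): no vdW radius for element(s) ",
                paste(unknown, collapse = ", "), "; using fallback ",
                fallback_radius, " A"))
    radii[unknown] <- fallback_radius
  }
  atoms$radius <- unname(radii[atoms$element])
  structure(list(atoms = atoms, radii = radii), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("<structure_model> ", nrow(x$atoms), " heavy atoms, chains: ",
      paste0(names(ch), " (", as.integer(ch), ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Thin wrapper over bio3d's readers. Hydrogens and non-protein (HETATM)
#' records are stripped; residue numbering is taken verbatim from the file
#' (no renumbering) and insertion codes are kept as part of the residue key.
#'
#' @param path Path to a `.pdb` or `.cif` file (format chosen by extension).
#' @param keep_hetatm Keep HETATM records (default FALSE).
#' @inheritParams structure_model
#' @return A `structure_model`.
#' @export
read_structure <- function(path, keep_hetatm = FALSE,
                           radii = default_vdw_radii()) {
  if (!file.exists(path)) abort(paste0("read_structure(): no such file: ", path))
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  elem <- toupper(trimws(a$elesy))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- toupper(substr(trimws(a$elety[bad]), 1, 1))
  keep <- elem != "H" & elem != "D"
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  ins <- if ("insert" %in% names(a)) a$insert else ""
  ins[is.na(ins)] <- ""
  structure_model(tibble(chain = a$chain, resno = as.integer(a$resno),
                         insert = ins, resid = a$resid, atom = a$elety,
                         element = elem, x = a$x, y = a$y, z = a$z),
                  radii = radii)
}

# deterministic quasi-uniform unit sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's sphere is expanded by the probe radius and
#' sampled with `n_points` quasi-uniform points; the accessible fraction is
#' the fraction of points not inside any neighbouring expanded sphere, and
#' the atom's SASA is that fraction times `4*pi*(r_vdw + probe)^2`.
#' Exactly coincident spheres are resolved by atom order (the earlier atom
#' keeps the surface), so duplicated atoms never double-count area.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius (Angstrom, default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @return A list with `atoms` (atom tibble plus `sasa` column) and
#'   `residues` (per-residue totals: chain, resno, insert, resid, sasa).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(model, "structure_model"), probe >= 0, n_points >= 100)
  a <- model$atoms
  n <- nrow(a)
  xyz <- cbind(a$x, a$y, a$z)
  r_exp <- a$radius + probe
  pts <- sphere_points(n_points)
  # neighbour lists via a cell grid of size max expanded diameter
  nb <- neighbor_pairs(xyz, r_exp)
  area <- numeric(n)
  eps <- 1e-8
  for (i in seq_len(n)) {
    p <- sweep(pts * r_exp[i], 2, xyz[i, ], "+")
    js <- nb[[i]]
    acc <- rep(TRUE, n_points)
    for (j in js) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      r2 <- r_exp[j]^2
      inside <- d2 < r2 - eps
      if (j < i) inside <- inside | (abs(d2 - r2) <= eps)  # tie to earlier atom
      acc <- acc & !inside
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * r_exp[i]^2
  }
  atoms <- mutate(a, sasa = area)
  residues <- summarise(group_by(atoms, .data$chain, .data$resno, .data$insert,
                                 .data$resid),
                        sasa = sum(.data$sasa), .groups = "drop")
  list(atoms = atoms, residues = arrange(residues, .data$chain, .data$resno,
                                         .data$insert))
}

# for each atom, indices of atoms whose expanded spheres can occlude it
neighbor_pairs <- function(xyz, r_exp) {
  n <- nrow(xyz)
  cut <- 2 * max(r_exp)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cut)
  key <- cell[, 1] + 10000 * (cell[, 2] + 10000 * cell[, 3])
  buckets <- split(seq_len(n), key)
  cellkey <- function(cx, cy, cz) cx + 10000 * (cy + 10000 * cz)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- cellkey(cell[i, 1] + off[, 1], cell[i, 2] + off[, 2],
                  cell[i, 3] + off[, 3])
    cand <- unlist(buckets[as.character(ks)], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (r_exp[cand] + r_exp[i])^2]
    }
    out[[i]] <- cand
  }
  out
}

#' Interchain residue contacts
#'
#' A residue pair across the two sides is a contact when any heavy-atom pair
#' is within `cutoff`; the minimum heavy-atom distance is reported. Uses a
#' cell-list neighbour search, so the cost is linear in atom count for
#' globular models; ordering of the output is deterministic (chain, residue
#' number, insertion code of side a, then side b).
#'
#' @param model A `structure_model`.
#' @param side_a,side_b Disjoint character vectors of chain ids.
#' @param cutoff Distance cutoff (Angstrom), > 0.
#' @return A tibble with `chain_a`, `resno_a`, `insert_a`, `resid_a`,
#'   `chain_b`, `resno_b`, `insert_b`, `resid_b`, `min_dist`.
#' @export
contacts <- function(model, side_a, side_b, cutoff = 6) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) abort("contacts(): cutoff must be > 0")
  check_sides(model, side_a, side_b)
  a <- filter(model$atoms, .data$chain %in% side_a)
  b <- filter(model$atoms, .data$chain %in% side_b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_contacts())
  xyz_b <- cbind(b$x, b$y, b$z)
  origin <- apply(rbind(cbind(a$x, a$y, a$z), xyz_b), 2, min)
  cell_b <- floor(sweep(xyz_b, 2, origin) / cutoff)
  key_b <- cell_b[, 1] + 1e4 * (cell_b[, 2] + 1e4 * cell_b[, 3])
  buckets <- split(seq_len(nrow(b)), key_b)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    ci <- floor((c(a$x[i], a$y[i], a$z[i]) - origin) / cutoff)
    ks <- (ci[1] + off[, 1]) + 1e4 * ((ci[2] + off[, 2]) + 1e4 * (ci[3] + off[, 3]))
    cand <- unlist(buckets[as.character(ks)], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (xyz_b[cand, 1] - a$x[i])^2 + (xyz_b[cand, 2] - a$y[i])^2 +
      (xyz_b[cand, 3] - a$z[i])^2
    hit <- d2 <= cutoff^2
    if (!any(hit)) next
    res[[i]] <- tibble(ia = i, ib = cand[hit], dist = sqrt(d2[hit]))
  }
  pairs <- bind_rows(res)
  if (nrow(pairs) == 0) return(empty_contacts())
  pairs <- mutate(pairs,
                  chain_a = a$chain[.data$ia], resno_a = a$resno[.data$ia],
                  insert_a = a$insert[.data$ia], resid_a = a$resid[.data$ia],
                  chain_b = b$chain[.data$ib], resno_b = b$resno[.data$ib],
                  insert_b = b$insert[.data$ib], resid_b = b$resid[.data$ib])
  out <- summarise(group_by(pairs, .data$chain_a, .data$resno_a, .data$insert_a,
                            .data$resid_a, .data$chain_b, .data$resno_b,
                            .data$insert_b, .data$resid_b),
                   min_dist = min(.data$dist), .groups = "drop")
  arrange(out, .data$chain_a, .data$resno_a, .data$insert_a,
          .data$chain_b, .data$resno_b, .data$insert_b)
}

empty_contacts <- function() {
  tibble(chain_a = character(), resno_a = integer(), insert_a = character(),
         resid_a = character(), chain_b = character(), resno_b = integer(),
         insert_b = character(), resid_b = character(), min_dist = numeric())
}

check_sides <- function(model, side_a, side_b) {
  chains <- unique(model$atoms$chain)
  if (length(side_a) == 0 || length(side_b) == 0) {
    abort("empty chain set for one interface side")
  }
  if (length(intersect(side_a, side_b))) {
    abort("interface sides must be disjoint chain sets")
  }
  missing_ch <- setdiff(c(side_a, side_b), chains)
  if (length(missing_ch)) {
    abort(paste0("chain(s) not in model: ", paste(missing_ch, collapse = ", "),
                 "; available: ", paste(chains, collapse = ", ")))
  }
}

#' Buried surface area of an interface
#'
#' Per residue, BSA is the SASA of the residue with its own side isolated
#' minus its SASA in the complex. The total is reported under two
#' conventions: `total_bsa` sums the loss over both partners (the convention
#' used for the headline interface areas) and `total_bsa_half` is half that
#' value; both appear in `glance()`.
#'
#' @inheritParams contacts
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere sample points per atom.
#' @param bsa_threshold Per-residue annotation threshold (Angstrom^2,
#'   default 30): residues burying more than this are listed in
#'   `annotated_residues`.
#' @param contact_cutoff Cutoff (Angstrom) for the companion contact list.
#' @return An object of class `hdx_interface` with elements `per_residue`
#'   (tibble: chain, resno, insert, resid, side, sasa_alone, sasa_complex,
#'   bsa), `contacts`, `annotated_residues`, `total_bsa`, `total_bsa_half`,
#'   and the parameters used. `tidy()` returns the per-residue table,
#'   `glance()` the totals.
#' @export
buried_surface <- function(model, side_a, side_b, probe = 1.4,
                           n_points = 960L, bsa_threshold = 30,
                           contact_cutoff = 6) {
  check_sides(model, side_a, side_b)
  sub_model <- function(chs) {
    structure_model(filter(model$atoms, .data$chain %in% chs),
                    radii = model$radii)
  }
  both <- sub_model(c(side_a, side_b))
  res_complex <- sasa(both, probe, n_points)$residues
  res_a <- sasa(sub_model(side_a), probe, n_points)$residues
  res_b <- sasa(sub_model(side_b), probe, n_points)$residues
  alone <- bind_rows(mutate(res_a, side = "a"), mutate(res_b, side = "b"))
  per <- left_join(rename(alone, sasa_alone = "sasa"),
                   rename(res_complex, sasa_complex = "sasa"),
                   by = c("chain", "resno", "insert", "resid"))
  per <- mutate(per, bsa = .data$sasa_alone - .data$sasa_complex)
  per <- arrange(per, .data$side, .data$chain, .data$resno, .data$insert)
  if (any(per$bsa < -0.1 * max(1, n_points / 960))) {
    warn("buried_surface(): negative per-residue BSA beyond numerical tolerance")
  }
  out <- list(per_residue = per,
              contacts = contacts(model, side_a, side_b, contact_cutoff),
              annotated_residues = filter(per, .data$bsa > bsa_threshold),
              total_bsa = sum(per$bsa),
              total_bsa_half = sum(per$bsa) / 2,
              side_a = side_a, side_b = side_b, probe = probe,
              n_points = n_points, bsa_threshold = bsa_threshold,
              contact_cutoff = contact_cutoff)
  class(out) <- "hdx_interface"
  out
}

#' @export
print.hdx_interface <- function(x, ...) {
  cat("<hdx_interface> ", paste(x$side_a, collapse = "+"), " vs ",
      paste(x$side_b, collapse = "+"), "\n",
      "  total BSA (both sides): ", round(x$total_bsa, 1), " A^2  (half: ",
      round(x$total_bsa_half, 1), ")\n",
      "  contacts (cutoff ", x$contact_cutoff, " A): ", nrow(x$contacts),
      " residue pairs; residues with BSA > ", x$bsa_threshold, " A^2: ",
      nrow(x$annotated_residues), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hdx_interface <- function(x, ...) x$per_residue

#' @export
glance.hdx_interface <- function(x, ...) {
  tibble(total_bsa = x$total_bsa, total_bsa_half = x$total_bsa_half,
         n_contacts = nrow(x$contacts),
         n_annotated = nrow(x$annotated_residues),
         probe = x$probe, n_points = x$n_points,
         bsa_threshold = x$bsa_threshold, contact_cutoff = x$contact_cutoff)
}
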