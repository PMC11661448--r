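# Toy two-chain structures with known interface ground truth.

# idealized alpha-helix heavy atoms for one residue index i (0-based):
# cylindrical placement with 100 deg twist and 1.5 A rise per residue.
helix_residue <- function(i) {
  place <- function(r, dphi, dz) {
    phi <- (100 * i + dphi) * pi / 180
    c(r * cos(phi), r * sin(phi), 1.5 * i + dz)
  }
  rbind(N  = place(1.46, -27, -0.90),
        CA = place(2.30, 0, 0),
        C  = place(1.65, 26, 1.05),
        O  = place(2.00, 32, 2.20),
        CB = place(3.30, -10, -0.45))
}

helix_chain <- function(n_res, chain, resid = "ALA") {
  rows <- lapply(seq_len(n_res) - 1L, helix_residue)
  xyz <- do.call(rbind, rows)
  tibble(chain = chain,
         resno = rep(seq_len(n_res), each = 5L),
         insert = "",
         resid = resid,
         atom = rep(c("N", "CA", "C", "O", "CB"), n_res),
         element = rep(c("N", "C", "C", "O", "C"), n_res),
         x = as.vector(xyz[, 1]), y = as.vector(xyz[, 2]),
         z = as.vector(xyz[, 3]))
}

#' Build a toy two-helix interface with known ground truth
#'
#' Generates two idealized alpha-helical chains (backbone N, CA, C, O plus a
#' C-beta pseudo-atom per residue) and places chain B so that the minimum
#' interchain heavy-atom distance equals `separation` exactly (solved
#' numerically on the translation axis). Ground truth shipped alongside the
#' model: the residue-pair contact list at `contact_cutoff` (computed by
#' brute-force all-pairs distances, independently of the cell-list search)
#' and the candidate interface residues, i.e. residues with any cross-chain
#' expanded-sphere overlap (`d < r_i + r_j + 2 * probe`), the geometric
#' prerequisite for positive buried area.
#'
#' @param n_res_per_chain Residues per chain (5 heavy atoms each).
#' @param separation Realized minimum interchain heavy-atom distance
#'   (Angstrom, >= 0).
#' @param contact_cutoff Cutoff for the ground-truth contact list.
#' @param probe Probe radius used for the interface-residue ground truth.
#' @param seed Integer seed (small random jitter of side-chain atoms).
#' @return A list with `model` (a [structure_model()]), `true_contacts`
#'   (tibble like [contacts()]), and `interface_residues` (tibble with
#'   `chain`, `resno`).
#' @export
make_toy_interface <- function(n_res_per_chain = 12L, separation = 4,
                               contact_cutoff = 5, probe = 1.4, seed = 1L) {
  if (separation < 0) abort("make_toy_interface(): separation must be >= 0")
  set.seed(as.integer(seed))
  a <- helix_chain(n_res_per_chain, "A")
  b <- helix_chain(n_res_per_chain, "B")
  # jitter CB pseudo-atoms slightly so toy models are not exactly degenerate
  cb <- b$atom == "CB"
  b$x[cb] <- b$x[cb] + rnorm(sum(cb), 0, 0.05)
  b$y[cb] <- b$y[cb] + rnorm(sum(cb), 0, 0.05)
  # flip chain B to face chain A, then solve the x-offset so the realized
  # minimum interchain distance equals `separation`
  b$x <- -b$x
  min_dist_at <- function(dx) {
    min(cross_dist2(cbind(a$x, a$y, a$z), cbind(b$x + dx, b$y, b$z)))^0.5
  }
  lo <- 0
  hi <- separation + 30
  while (min_dist_at(lo) > separation && lo > -30) lo <- lo - 5
  dx <- uniroot(function(d) min_dist_at(d) - separation, c(lo, hi),
                tol = 1e-10)$root
  b$x <- b$x + dx
  model <- structure_model(bind_rows(a, b))
  true_contacts <- brute_force_contacts(model, "A", "B", contact_cutoff)
  # residues with any cross-chain expanded-sphere overlap
  ra <- model$atoms[model$atoms$chain == "A", ]
  rb <- model$atoms[model$atoms$chain == "B", ]
  d2 <- cross_dist2(cbind(ra$x, ra$y, ra$z), cbind(rb$x, rb$y, rb$z))
  lim <- outer(ra$radius + probe, rb$radius + probe, "+")^2
  hit <- d2 < lim
  iface <- bind_rows(
    distinct(tibble(chain = "A", resno = ra$resno[apply(hit, 1, any)])),
    distinct(tibble(chain = "B", resno = rb$resno[apply(hit, 2, any)])))
  list(model = model, true_contacts = true_contacts,
       interface_residues = arrange(iface, .data$chain, .data$resno))
}

cross_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
}

# reference all-pairs contact search (no spatial hashing); doubles as the
# oracle for the cell-list implementation
brute_force_contacts <- function(model, side_a, side_b, cutoff) {
  a <- filter(model$atoms, .data$chain %in% side_a)
  b <- filter(model$atoms, .data$chain %in% side_b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_contacts())
  d2 <- cross_dist2(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z))
  idx <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_contacts())
  pairs <- tibble(chain_a = a$chain[idx[, 1]], resno_a = a$resno[idx[, 1]],
                  insert_a = a$insert[idx[, 1]], resid_a = a$resid[idx[, 1]],
                  chain_b = b$chain[idx[, 2]], resno_b = b$resno[idx[, 2]],
                  insert_b = b$insert[idx[, 2]], resid_b = b$resid[idx[, 2]],
                  dist = sqrt(d2[idx]))
  out <- summarise(group_by(pairs, .data$chain_a, .data$resno_a,
                            .data$insert_a, .data$resid_a, .data$chain_b,
                            .data$resno_b, .data$insert_b, .data$resid_b),
                   min_dist = min(.data$dist), .groups = "drop")
  arrange(out, .data$chain_a, .data$resno_a, .data$insert_a,
          .data$chain_b, .data$resno_b, .data$insert_b)
}
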