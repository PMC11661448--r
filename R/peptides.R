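#' Build a validated peptide table
#'
#' A peptide table is the unit of bookkeeping for HDX-MS: one row per
#' proteolytic peptide with its protein of origin, residue span (1-based,
#' inclusive at both ends), sequence and charge state.
#'
#' @param protein Character vector of protein identifiers.
#' @param start,end Integer residue indices (1-based, inclusive); the sequence
#'   length must equal `end - start + 1`.
#' @param sequence Amino-acid sequences (one-letter code, uppercase).
#' @param charge Positive integer charge states (default 2).
#'
#' @return A tibble with columns `protein`, `start`, `end`, `sequence`,
#'   `charge` and a derived `n_ex` column (exchangeable backbone amides, see
#'   [exchangeable_amides()]).
#' @export
#' @examples
#' peptide_table("prot", start = c(1, 10), end = c(8, 21),
#'               sequence = c("GASPLKVI", "LLDKQWERTYGA"))
peptide_table <- function(protein, start, end, sequence, charge = 2L) {
  start <- as.integer(start); end <- as.integer(end)
  charge <- as.integer(charge)
  sequence <- toupper(sequence)
  tbl <- tibble(protein = as.character(protein), start = start, end = end,
                sequence = sequence, charge = charge)
  if (any(tbl$end < tbl$start)) {
    abort("peptide table: `end` must be >= `start` for every peptide")
  }
  if (any(nchar(tbl$sequence) != tbl$end - tbl$start + 1L)) {
    abort("peptide table: sequence length must equal end - start + 1")
  }
  if (any(tbl$charge < 1L)) abort("peptide table: charge must be >= 1")
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tbl$sequence)
  if (any(bad)) {
    abort(paste0("peptide table: unknown residue letters in sequence(s): ",
                 paste(unique(tbl$sequence[bad]), collapse = ", ")))
  }
  tbl$n_ex <- vapply(tbl$sequence, exchangeable_amides, integer(1),
                     USE.NAMES = FALSE)
  tbl
}

#' Number of exchangeable backbone amides of a peptide
#'
#' Counts the backbone amide hydrogens that contribute measurable deuterium
#' uptake under the common fast-back-exchange convention: the first two
#' residues of the peptide are excluded (the N-terminal amine and the second
#' amide back-exchange too quickly), as is every proline from position 3
#' onwards (no amide hydrogen).
#'
#' @param sequence One-letter amino-acid sequence (a single string).
#' @param skip_n_term Number of N-terminal residues excluded (default 2).
#'
#' @return Integer count, never negative.
#' @export
#' @examples
#' exchangeable_amides("GGGGG")  # 3
#' exchangeable_amides("GPGPG")  # 1
exchangeable_amides <- function(sequence, skip_n_term = 2L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) <= skip_n_term) return(0L)
  tail_aa <- aa[(skip_n_term + 1L):length(aa)]
  as.integer(sum(tail_aa != "P"))
}

# Residue elemental compositions (residue = amino acid - H2O), heavy-atom
# bookkeeping for isotope patterns. Columns C,H,N,O,S.
residue_formula_table <- function() {
  m <- rbind(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
}

#' Elemental composition of a peptide
#'
#' Sums residue formulas and adds one water for the termini.
#'
#' @param sequence One-letter amino-acid sequence.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
peptide_composition <- function(sequence) {
  tab <- residue_formula_table()
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, rownames(tab))
  if (length(unknown)) {
    abort(paste0("unknown residue letters: ", paste(unknown, collapse = ", ")))
  }
  comp <- colSums(tab[aa, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1
  setNames(as.integer(comp), names(comp))
}

#' Peptide neutral mass
#'
#' @param sequence One-letter amino-acid sequence.
#' @param type `"centroid"` for the abundance-weighted mean over the natural
#'   isotope distribution (matches the centroid of a simulated envelope) or
#'   `"monoisotopic"` for the lightest-isotope mass.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, type = c("centroid", "monoisotopic")) {
  type <- match.arg(type)
  comp <- peptide_composition(sequence)
  iso <- isotope_table()
  m <- 0
  for (el in names(comp)) {
    tab <- iso[[el]]
    m_el <- if (type == "centroid") sum(tab$mass * tab$abundance) else tab$mass[1]
    m <- m + comp[[el]] * m_el
  }
  unname(m)
}
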