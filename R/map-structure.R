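# Projection of differential-exchange results onto structure coordinates.

#' Map differential exchange onto a structure
#'
#' Writes each covered residue's summed uptake difference into a per-residue
#' annotation destined for the B-factor field (mean over covering peptides
#' when several overlap), with a sentinel value for residues not covered by
#' any peptide. When `interface_residues` is supplied, also reports the
#' overlap between residues called significant and the interface set
#' (Jaccard index and counts). Residue numbering of the exchange results
#' must match the model's numbering through `chain_map`; peptide spans
#' absent from the model (e.g. disordered regions) count as uncovered, not
#' as errors.
#'
#' @param comparison An `hdx_comparison` or `hdx_woods` table.
#' @param model A [structure_model()].
#' @param chain_map Named character vector protein id -> chain id.
#' @param interface_residues Optional tibble with `chain`, `resno` columns
#'   (e.g. from [make_toy_interface()] or `buried_surface()$annotated_residues`).
#' @param sentinel Annotation value for uncovered residues (default -100).
#' @return A list of class `hdx_structure_map`: `residues` (chain, resno,
#'   insert, resid, `annotation`, `covered`, `significant`), `atoms` (atom
#'   tibble with a `b` column ready for [write_annotated_pdb()]), and
#'   `overlap` (tibble with `n_significant`, `n_interface`, `n_overlap`,
#'   `jaccard`; `NA`s when no interface set was given).
#' @export
map_hdx_to_structure <- function(comparison, model, chain_map,
                                 interface_residues = NULL,
                                 sentinel = -100) {
  peps <- if (inherits(comparison, "hdx_woods")) as_tibble(comparison)
          else if (nrow(comparison) > 0) as_tibble(woods_summary(comparison))
          else tibble(protein = character(), start = integer(),
                      end = integer(), sum_delta_d = numeric(),
                      significant = logical())
  unmapped <- setdiff(unique(peps$protein), names(chain_map))
  if (length(unmapped)) {
    abort(paste0("map_hdx_to_structure(): no chain mapping for protein(s): ",
                 paste(unmapped, collapse = ", ")))
  }
  res <- distinct(model$atoms, .data$chain, .data$resno, .data$insert,
                  .data$resid)
  if (nrow(peps) > 0) {
    cover <- tidyr::unnest(
      mutate(peps, chain = unname(chain_map[.data$protein]),
             resno = purrr::map2(.data$start, .data$end, seq)),
      "resno")
    per_res <- summarise(group_by(cover, .data$chain, .data$resno),
                         annotation = mean(.data$sum_delta_d),
                         significant = any(.data$significant),
                         .groups = "drop")
    res <- left_join(res, per_res, by = c("chain", "resno"))
  } else {
    res$annotation <- NA_real_
    res$significant <- NA
  }
  res <- mutate(res,
                covered = !is.na(.data$annotation),
                significant = !is.na(.data$significant) & .data$significant,
                annotation = ifelse(.data$covered, .data$annotation, sentinel))
  atoms <- left_join(model$atoms,
                     select(res, dplyr::all_of(c("chain", "resno", "insert",
                                                 "annotation"))),
                     by = c("chain", "resno", "insert"))
  atoms <- rename(atoms, b = "annotation")
  overlap <- tibble(n_significant = NA_integer_, n_interface = NA_integer_,
                    n_overlap = NA_integer_, jaccard = NA_real_)
  if (!is.null(interface_residues)) {
    sig_key <- with(filter(res, .data$significant), paste(chain, resno))
    ifc_key <- with(interface_residues, paste(chain, resno))
    inter <- length(intersect(sig_key, ifc_key))
    uni <- length(union(sig_key, ifc_key))
    overlap <- tibble(n_significant = length(unique(sig_key)),
                      n_interface = length(unique(ifc_key)),
                      n_overlap = inter,
                      jaccard = if (uni > 0) inter / uni else NA_real_)
  }
  structure(list(residues = res, atoms = atoms, overlap = overlap,
                 sentinel = sentinel),
            class = "hdx_structure_map")
}

#' @export
print.hdx_structure_map <- function(x, ...) {
  cat("<hdx_structure_map> ", nrow(x$residues), " residues, ",
      sum(x$residues$covered), " covered, ",
      sum(x$residues$significant), " significant\n", sep = "")
  if (!is.na(x$overlap$jaccard)) {
    cat("  overlap with interface set: ", x$overlap$n_overlap, "/",
        x$overlap$n_interface, " (Jaccard ",
        round(x$overlap$jaccard, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Write an annotated PDB file
#'
#' Emits standard fixed-width ATOM records with the annotation channel in
#' the B-factor column (occupancy 1.00), for coloring in molecular-graphics
#' programs. Input is either an `hdx_structure_map` or any atom tibble with
#' a `b` column.
#'
#' @param x An `hdx_structure_map`, a `structure_model` (B-factors 0), or an
#'   atom tibble with a `b` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_pdb <- function(x, path) {
  atoms <- if (inherits(x, "hdx_structure_map")) x$atoms
           else if (inherits(x, "structure_model")) mutate(x$atoms, b = 0)
           else x
  if (!"b" %in% names(atoms)) abort("write_annotated_pdb(): no `b` column")
  b <- pmax(pmin(atoms$b, 999.99), -99.99)  # field width limit
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom), atoms$atom),
    atoms$resid, atoms$chain, atoms$resno, atoms$insert,
    atoms$x, atoms$y, atoms$z, 1.00, b, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
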