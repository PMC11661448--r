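# Workflow front end: run configuration, the two composed pipelines, and
# delimited-text plumbing with provenance headers.

#' Build a run configuration
#'
#' Collects the knobs of the two workflows (differential HDX analysis;
#' interface characterisation) in one validated object. Residue coordinates
#' are 1-based and inclusive everywhere. Tables are comma-separated UTF-8
#' with a mandatory header row and `.` decimal.
#'
#' @param measurements Path to a measurement CSV (see [uptake_records()] for
#'   the required columns) or an in-memory data frame of uptake records.
#' @param state_a,state_b State labels to compare (difference is b - a).
#' @param d2o_fraction Final deuterium fraction; alternatively give
#'   `volumes = c(v_buffer, v_protein)` plus `buffer_d2o` and it is computed
#'   with [labeling_fraction()].
#' @param volumes,buffer_d2o Reaction volumes (ul) and buffer deuterium
#'   fraction, used when `d2o_fraction` is `NULL`.
#' @param criteria A [significance_criteria()].
#' @param structure Optional path to a PDB/mmCIF file (or a
#'   `structure_model`).
#' @param chain_map Named character vector protein id -> chain id.
#' @param side_a,side_b Chain sets of the interface report.
#' @param contact_cutoff Contact distance cutoff (Angstrom; 6 and 5 are the
#'   conventional choices).
#' @param bsa_threshold Per-residue buried-area annotation threshold
#'   (Angstrom^2).
#' @param sasa_n_points Sphere sample points for SASA.
#' @param out_dir Output directory for written tables.
#' @param seed Integer seed recorded in provenance and used for any
#'   randomness.
#' @return A list of class `hdx_config`.
#' @export
hdx_config <- function(measurements = NULL, state_a = "apo", state_b = "bound",
                       d2o_fraction = NULL, volumes = NULL, buffer_d2o = NULL,
                       criteria = significance_criteria(),
                       structure = NULL, chain_map = NULL,
                       side_a = NULL, side_b = NULL,
                       contact_cutoff = 6, bsa_threshold = 30,
                       sasa_n_points = 960L,
                       out_dir = tempfile("hdxstruct-"), seed = 1L) {
  if (is.null(d2o_fraction) && !is.null(volumes)) {
    d2o_fraction <- labeling_fraction(volumes[1], volumes[2], buffer_d2o)
  }
  if (contact_cutoff <= 0 || bsa_threshold <= 0) {
    abort("hdx_config(): cutoffs/thresholds must be positive")
  }
  for (p in c(if (is.character(measurements)) measurements,
              if (is.character(structure)) structure)) {
    if (!file.exists(p)) abort(paste0("hdx_config(): file not found: ", p))
  }
  structure(list(measurements = measurements, state_a = state_a,
                 state_b = state_b, d2o_fraction = d2o_fraction,
                 criteria = criteria, structure = structure,
                 chain_map = chain_map, side_a = side_a, side_b = side_b,
                 contact_cutoff = contact_cutoff,
                 bsa_threshold = bsa_threshold,
                 sasa_n_points = as.integer(sasa_n_points),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "hdx_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

provenance_header <- function(config) {
  c(paste0("# hdxstruct ",
           as.character(utils::packageVersion("hdxstruct"))),
    paste0("# config ", config_hash(config), " seed ", config$seed))
}

#' Write a table with a provenance header
#'
#' Comma-separated UTF-8 with `#`-prefixed provenance lines (package
#' version, configuration hash, seed) ahead of the header row; read back
#' with [read_hdx_table()].
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config The `hdx_config` of the run.
#' @return `path`, invisibly.
#' @export
write_hdx_table <- function(x, path, config) {
  writeLines(provenance_header(config), path)
  readr::write_csv(round_num(as_tibble(x)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

# fixed decimal rendering keeps reruns byte-identical across platforms
round_num <- function(x) mutate(x, across(dplyr::where(is.numeric),
                                          ~ round(.x, 6)))

#' Read a table written by [write_hdx_table()]
#' @param path File path.
#' @return A tibble (provenance lines skipped).
#' @export
read_hdx_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the differential HDX workflow
#'
#' Reads (or takes) the measurement table, computes uptake if only centroid
#' masses are present, compares the two states with the three-gate filter,
#' and writes the full comparison table, the Woods-plot summary, the
#' per-residue consensus and, when a structure and chain map are configured,
#' a B-factor-annotated PDB. Deterministic given inputs and seed; every
#' output table carries a provenance header.
#'
#' @param config An [hdx_config()].
#' @return A list with `comparison`, `woods`, `consensus`, `structure_map`
#'   (or `NULL`) and `files` (written paths), invisibly classed
#'   `hdx_pipeline_result`.
#' @export
run_hdx_pipeline <- function(config) {
  stopifnot(inherits(config, "hdx_config"))
  m <- config$measurements
  if (is.character(m)) m <- read_hdx_table(m)
  if (is.null(m) || nrow(m) == 0) abort("run_hdx_pipeline(): empty measurement table")
  if (!"uptake" %in% names(m)) {
    if (is.null(config$d2o_fraction)) {
      abort("run_hdx_pipeline(): d2o_fraction (or volumes) required to compute uptake")
    }
    m <- uptake_records(m, config$d2o_fraction)
  }
  check_measurement_schema(m)
  cmp <- compare_states(m, state_a = config$state_a, state_b = config$state_b,
                        criteria = config$criteria)
  woods <- woods_summary(cmp)
  consensus <- residue_consensus(cmp)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    comparison = write_hdx_table(cmp, file.path(config$out_dir, "comparison.csv"),
                                 config),
    woods = write_hdx_table(woods, file.path(config$out_dir, "woods.csv"),
                            config),
    consensus = write_hdx_table(consensus,
                                file.path(config$out_dir, "consensus.csv"),
                                config))
  smap <- NULL
  if (!is.null(config$structure) && !is.null(config$chain_map)) {
    model <- if (inherits(config$structure, "structure_model")) config$structure
             else read_structure(config$structure)
    smap <- map_hdx_to_structure(cmp, model, config$chain_map)
    pdb_path <- file.path(config$out_dir, "annotated.pdb")
    write_annotated_pdb(smap, pdb_path)
    files <- c(files, annotated_pdb = pdb_path)
  }
  out <- list(comparison = cmp, woods = woods, consensus = consensus,
              structure_map = smap, files = files, config = config)
  class(out) <- "hdx_pipeline_result"
  invisible(out)
}

check_measurement_schema <- function(m) {
  required <- c("protein", "start", "end", "sequence", "state", "timepoint",
                "replicate", "uptake", "percent_exchange")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    abort(paste0("measurement table: missing column(s) ",
                 paste(missing_cols, collapse = ", "),
                 " (have: ", paste(names(m), collapse = ", "), ")"))
  }
  bad <- which(!is.finite(m$uptake))
  if (length(bad)) {
    abort(paste0("measurement table: non-finite uptake at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
}

#' Run the interface characterisation workflow
#'
#' Computes the interchain contact table and per-residue/total buried
#' surface area for the configured chain sets and writes both tables plus a
#' PDB annotated with per-residue buried area. Tables are sorted
#' deterministically.
#'
#' @param config An [hdx_config()] with `structure`, `side_a`, `side_b` set.
#' @return A list with `interface` (an `hdx_interface`), `files`, invisibly.
#' @export
run_interface_report <- function(config) {
  stopifnot(inherits(config, "hdx_config"))
  if (is.null(config$structure)) abort("run_interface_report(): no structure configured")
  model <- if (inherits(config$structure, "structure_model")) config$structure
           else read_structure(config$structure)
  ifc <- buried_surface(model, config$side_a, config$side_b,
                        n_points = config$sasa_n_points,
                        bsa_threshold = config$bsa_threshold,
                        contact_cutoff = config$contact_cutoff)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    contacts = write_hdx_table(ifc$contacts,
                               file.path(config$out_dir, "contacts.csv"),
                               config),
    bsa = write_hdx_table(ifc$per_residue,
                          file.path(config$out_dir, "bsa_per_residue.csv"),
                          config),
    totals = write_hdx_table(glance(ifc),
                             file.path(config$out_dir, "bsa_totals.csv"),
                             config))
  atoms <- left_join(model$atoms,
                     select(ifc$per_residue,
                            dplyr::all_of(c("chain", "resno", "insert", "bsa"))),
                     by = c("chain", "resno", "insert"))
  atoms$b <- ifelse(is.na(atoms$bsa), 0, atoms$bsa)
  pdb_path <- file.path(config$out_dir, "interface_annotated.pdb")
  write_annotated_pdb(atoms, pdb_path)
  files <- c(files, annotated_pdb = pdb_path)
  invisible(list(interface = ifc, files = files, config = config))
}
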