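# File parsing and persistence: PDB protein clouds (via bio3d), SMILES and
# SDF ligand input (via ChemmineR/OpenBabel), embedding tables with JSON
# sidecars, YAML run configuration, and provenance records.

WATER_IONS <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN",
                "MN", "FE", "CO", "NI", "CU", "SO4", "PO4")

pdb_element <- function(elesy, elety) {
  el <- trimws(elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    guess <- sub("^[0-9']*", "", trimws(elety[miss]))
    two <- toupper(substr(guess, 1L, 2L)) %in% c("CL", "BR")
    el[miss] <- ifelse(two, substr(guess, 1L, 2L), substr(guess, 1L, 1L))
  }
  paste0(toupper(substr(el, 1L, 1L)),
         tolower(substr(el, 2L, nchar(el))))
}

check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(
      c(substr(ln, 31L, 38L), substr(ln, 39L, 46L), substr(ln, 47L, 54L))))
    if (nchar(ln) < 54L || any(is.na(coords))) {
      stop(sprintf("malformed ATOM record at line %d of %s", i, path),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a protein heavy-atom point cloud from a PDB file
#'
#' Keeps `ATOM` records only (waters, ions and other `HETATM` records are
#' skipped), drops hydrogens, keeps altloc 'A' (or blank), and preserves
#' file order. Coordinates are Angstrom, as read.
#'
#' @param path PDB file.
#' @return list with `coords` (n x 3), `elements`, `resid`, `resno`,
#'   `atom_names`.
#' @export
read_protein_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  el <- pdb_element(at$elesy, at$elety)
  heavy <- el != "H" & el != "D"
  at <- at[heavy, , drop = FALSE]
  list(coords = as.matrix(at[, c("x", "y", "z")]),
       elements = el[heavy],
       resid = at$resid, resno = at$resno, atom_names = at$elety)
}

#' Read the pocket-defining bound ligand from a PDB file's HETATM records
#'
#' Waters and common ions are excluded; hydrogens dropped.
#'
#' @param path PDB file.
#' @param resname optional residue name filter.
#' @return list with `coords` and `elements`.
#' @export
read_pdb_ligand <- function(path, resname = NULL) {
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "HETATM" & !(at$resid %in% WATER_IONS)
  if (!is.null(resname)) keep <- keep & at$resid == resname
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no ligand HETATM records found in ", path,
                      call. = FALSE)
  el <- pdb_element(at$elesy, at$elety)
  heavy <- el != "H"
  list(coords = as.matrix(at[heavy, c("x", "y", "z")]),
       elements = el[heavy])
}

#' Write a point cloud as a minimal PDB file
#'
#' @param path output file.
#' @param coords n x 3 matrix (Angstrom).
#' @param elements atomic species codes.
#' @param record `"ATOM"` (protein) or `"HETATM"` (ligand).
#' @param resid residue name used for all atoms.
#' @return `path` invisibly.
#' @export
write_pdb_cloud <- function(path, coords, elements, record = "ATOM",
                            resid = if (record == "ATOM") "POC" else "LIG") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  name <- sprintf("%s%d", elements, seq_len(n))
  lines <- sprintf(
    "%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, seq_len(n), substr(name, 1L, 4L), resid,
    if (record == "ATOM") seq_len(n) else rep(1L, n),
    coords[, 1L], coords[, 2L], coords[, 3L], 1, 0, elements)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read molecules from a SMILES file
#'
#' One record per line: `SMILES<TAB>id` (id optional; defaults to
#' `mol_<line>`); blank lines and `#` comments are skipped (count logged to
#' stderr).
#'
#' @param path SMILES file.
#' @return list of `MoleculeGraph` in file order.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  if (any(!keep)) {
    message(sprintf("skipped %d blank/comment line(s) in %s",
                    sum(!keep), path))
  }
  lines <- lines[keep]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "[\t ]+")[[1]]
    id <- if (length(fields) >= 2L) fields[2L] else sprintf("mol_%d", i)
    build_compound_graph(fields[1L], id)
  })
}

#' Read molecules (with coordinates when present) from an SDF file
#'
#' Explicit hydrogens are folded into per-heavy-atom H counts and dropped.
#'
#' @param path SDF file.
#' @return list of `MoleculeGraph`; `coords` attached when the file carries
#'   3D coordinates.
#' @export
read_sdf_ligands <- function(path) {
  txt <- readLines(path, warn = FALSE)
  recs <- split(txt, cumsum(c(0, head(txt, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!any(grepl("V2000", rec, fixed = TRUE))) next
    id <- trimws(rec[1L])
    p <- parse_molblock(paste(rec, collapse = "\n"))
    has_coords <- any(abs(p$coords) > 1e-8)
    out[[length(out) + 1L]] <- new_molecule_graph(
      if (nzchar(id)) id else sprintf("mol_%d", length(out) + 1L),
      p$elements, p$h_counts, p$bonds,
      coords = if (has_coords) p$coords else NULL)
  }
  out
}

#' Write molecule graphs to an SDF file (V2000)
#'
#' Coordinate-free molecules are written with zero coordinates. Bond orders
#' are written as single bonds; hop edges are reconstructed at read time
#' from the covalent bond list, which is what the model consumes.
#'
#' @param molecules list of `MoleculeGraph`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_sdf_ligands <- function(molecules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in molecules) {
    co <- g$coords %||% matrix(0, g$n_nodes, 3L)
    nb <- nrow(g$bonds)
    writeLines(c(
      g$mol_id, "  atomscreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n_nodes, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              co[, 1L], co[, 2L], co[, 3L], g$elements),
      if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                      g$bonds[, 1L], g$bonds[, 2L], rep(1L, nb)),
      "M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Write an atom-embedding table with a JSON metadata sidecar
#'
#' The table is TSV (`parent_id`, `atom_index`, `e1..ed`); the sidecar
#' (`<path>.json`) records the dimension, row count and checkpoint id.
#'
#' @param embeddings n x d matrix.
#' @param parent_id,atom_index per-row atom identity.
#' @param path output TSV path.
#' @param checkpoint_id model id recorded in the sidecar.
#' @return `path` invisibly.
#' @export
write_embeddings <- function(embeddings, parent_id, atom_index, path,
                             checkpoint_id = NULL) {
  d <- ncol(embeddings)
  df <- data.frame(parent_id = parent_id, atom_index = atom_index,
                   embeddings)
  names(df) <- c("parent_id", "atom_index", paste0("e", seq_len(d)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(format = "atomscreen-embeddings-v1", d = d, n = nrow(df),
         checkpoint_id = checkpoint_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an embedding table written by [write_embeddings()]
#'
#' @param path TSV path.
#' @return list with `embeddings`, `parent_id`, `atom_index`,
#'   `checkpoint_id`.
#' @export
read_embeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  list(embeddings = as.matrix(df[, paste0("e", seq_len(meta$d)),
                                 drop = FALSE]),
       parent_id = df$parent_id, atom_index = df$atom_index,
       checkpoint_id = meta$checkpoint_id)
}

run_config_defaults <- function() {
  list(x = 8L, y = 4L, z = 4L,
       embed_dim = 64L, n_blocks = 3L, n_heads = 4L, head_dim = 8L,
       dropout_p = 0.1, edge_mlp_dim = 8L,
       m = 1.0, n = 2.0, k = 128L, cutoff = 4.0,
       epochs = 30L, batch_size = 8L, lr = 3e-3, seed = 1L,
       shard_capacity = 100000L, percentile = 0.99,
       hard_start = 99, hard_end = 5, hard_end_epoch = 50L)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; every value is validated against the
#' preconditions of the module that consumes it.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @param overrides named list of values taking precedence over the file.
#' @return validated named list (a `RunConfig`).
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  user <- user %||% list()
  # YAML 1.1 parses bare keys y/n as booleans; map them back to the
  # neighbourhood (y) and negative-margin (n) parameter names
  names(user)[names(user) == "TRUE"] <- "y"
  names(user)[names(user) == "FALSE"] <- "n"
  user <- utils::modifyList(user, overrides)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, user)
  with(cfg, {
    stopifnot(x >= 1, y >= 1, z >= 1, embed_dim >= 1, n_blocks >= 1,
              n_heads >= 1, head_dim >= 1, dropout_p >= 0, dropout_p < 1,
              edge_mlp_dim >= 1, m > 0, n > m, k >= 1, cutoff > 0,
              epochs >= 1, batch_size >= 2, lr >= 0,
              shard_capacity >= 1, percentile > 0, percentile < 1,
              hard_start > hard_end, hard_end > 0, hard_end_epoch >= 1)
  })
  cfg
}

#' Write a provenance record for a pipeline step
#'
#' @param path output JSON path.
#' @param command the CLI/step name.
#' @param config the run configuration used.
#' @param checkpoint_id model id, when applicable.
#' @return `path` invisibly.
#' @export
write_provenance <- function(path, command, config, checkpoint_id = NULL) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  jsonlite::write_json(
    list(command = command, config = config,
         config_hash = unname(tools::md5sum(tf)),
         checkpoint_id = checkpoint_id,
         package_version = as.character(utils::packageVersion("atomscreen")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
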