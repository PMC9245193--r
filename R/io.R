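#' Read and write molecular topologies as JSON
#'
#' A small JSON dialect for toy topologies: atom names, masses, 1-based
#' bond pairs, backbone flags, residue labels and probe annotations.  This
#' is the native exchange format of the package; structures with explicit
#' CONECT records can be converted externally.
#'
#' @param path file path.
#' @return `read_topology_json`: a [molecular_system()].
#' @export
read_topology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  molecular_system(
    atom_names = x$atom_names,
    masses = x$masses,
    bonds = matrix(as.integer(x$bonds), ncol = 2),
    backbone = x$backbone,
    residue_index = x$residue_index,
    residue_name = x$residue_name,
    methyl_probes = if (length(x$methyl_probes))
      matrix(as.integer(x$methyl_probes), ncol = 2) else NULL,
    nh_probes = if (length(x$nh_probes))
      matrix(as.integer(x$nh_probes), ncol = 2) else NULL
  )
}

#' @rdname read_topology_json
#' @param system a [molecular_system()].
#' @export
write_topology_json <- function(system, path) {
  stopifnot(inherits(system, "molecular_system"))
  jsonlite::write_json(list(
    atom_names = system$atom_names,
    masses = system$masses,
    bonds = system$bonds,
    backbone = system$backbone,
    residue_index = system$residue_index,
    residue_name = system$residue_name,
    methyl_probes = system$methyl_probes,
    nh_probes = system$nh_probes
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Minimal multi-model PDB writer (MODEL/ATOM/ENDMDL records, coordinates
#' in Angstroms).  Readable by standard tools; [read_ensemble_pdb()] reads
#' it back.
#'
#' @param ens a [cartesian_ensemble()] (coordinates in nm).
#' @param system the matching [molecular_system()] (names and residues).
#' @param path output file path.
#' @export
write_ensemble_pdb <- function(ens, system, path) {
  stopifnot(inherits(ens, "cartesian_ensemble"),
            inherits(system, "molecular_system"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(ens$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$frames[f, , , drop = TRUE] * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(system$n_atoms),
      substr(system$atom_names, 1, 4),
      substr(system$residue_name, 1, 4),
      system$residue_index,
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into an ensemble
#'
#' @param path PDB file with MODEL/ENDMDL blocks, coordinates in Angstroms.
#' @param temperature temperature attached to the ensemble (default 300).
#' @return A [cartesian_ensemble()] in nm.
#' @export
read_ensemble_pdb <- function(path, temperature = 300) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  at <- lines[is_atom]
  mid <- model_id[is_atom]
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  f <- length(unique(mid))
  n <- length(at) / f
  if (n != round(n)) stop("inconsistent atom counts across models")
  arr <- array(NA_real_, dim = c(f, n, 3))
  for (i in seq_len(f)) {
    sel <- mid == unique(mid)[i]
    arr[i, , ] <- cbind(x[sel], y[sel], z[sel]) / 10  # Angstrom -> nm
  }
  cartesian_ensemble(arr, temperature = temperature)
}

#' Read a DCD trajectory (via bio3d) into an ensemble
#'
#' @param path DCD file with coordinates in Angstroms.
#' @param temperature temperature attached to the ensemble.
#' @return A [cartesian_ensemble()] in nm.
#' @export
read_ensemble_dcd <- function(path, temperature = 300) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading DCD trajectories requires the bio3d package")
  }
  m <- bio3d::read.dcd(path, verbose = FALSE)
  f <- nrow(m); n <- ncol(m) / 3
  arr <- array(NA_real_, dim = c(f, n, 3))
  for (i in seq_len(f)) arr[i, , ] <- matrix(m[i, ], ncol = 3, byrow = TRUE) / 10
  cartesian_ensemble(arr, temperature = temperature)
}

#' Serialize a MIST result to JSON
#'
#' @param x a `mist_result`.
#' @param path output path.
#' @export
write_mist_json <- function(x, path) {
  stopifnot(inherits(x, "mist_result"))
  jsonlite::write_json(list(
    s_1d = x$s_1d, s_mist = x$s_mist, n_dof = x$n_dof,
    n_bins = x$n_bins, n_frames = x$n_frames,
    tree_edges = as.data.frame(x$tree_edges)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
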