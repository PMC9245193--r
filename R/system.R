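#' Molecular system: atoms, masses, bonded topology and probe annotations
#'
#' Container for the static description of a molecule: atom identifiers,
#' masses, the covalent bond list, backbone flags, residue labels, and the
#' probe annotations (methyl symmetry axes and backbone N-H pairs) used by
#' the order-parameter machinery.  The bond graph must be connected and
#' acyclic: the internal-coordinate tree is only defined for ring-free
#' topologies, and ring-containing systems are rejected with an error.
#'
#' @param atom_names character vector of atom names (one per atom).
#' @param masses numeric vector of atomic masses in g/mol, strictly positive.
#' @param bonds two-column integer matrix of bonded atom index pairs
#'   (1-based, unordered).
#' @param backbone logical vector flagging main-chain atoms.
#' @param residue_index integer vector, residue number per atom.
#' @param residue_name character vector, residue name per atom.
#' @param methyl_probes two-column integer matrix of (heavy-atom neighbor,
#'   methyl carbon) pairs, or `NULL`; each pair must be a bonded pair.
#' @param nh_probes two-column integer matrix of (amide N, amide H) pairs,
#'   or `NULL`; each pair must be a bonded pair.
#'
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atom_names, masses, bonds, backbone,
                             residue_index = rep(1L, length(atom_names)),
                             residue_name = rep("RES", length(atom_names)),
                             methyl_probes = NULL, nh_probes = NULL) {
  n <- length(atom_names)
  bonds <- as_pair_matrix(bonds, "bonds")
  if (length(masses) != n || length(backbone) != n) {
    stop("masses and backbone flags must have one entry per atom")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("atomic masses must be strictly positive and finite")
  }
  if (nrow(bonds) > 0 && (max(bonds) > n || min(bonds) < 1)) {
    stop("bond indices out of range")
  }
  check_bond_graph(n, bonds)
  methyl_probes <- check_probes(methyl_probes, bonds, "methyl")
  nh_probes <- check_probes(nh_probes, bonds, "NH")
  structure(list(
    atom_names = as.character(atom_names),
    masses = as.numeric(masses),
    bonds = bonds,
    backbone = as.logical(backbone),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    methyl_probes = methyl_probes,
    nh_probes = nh_probes,
    n_atoms = n
  ), class = "molecular_system")
}

as_pair_matrix <- function(x, what) {
  if (is.null(x)) return(matrix(integer(0), ncol = 2))
  x <- as.matrix(x)
  if (ncol(x) != 2) stop(what, " must be a two-column matrix of atom indices")
  storage.mode(x) <- "integer"
  unname(x)
}

# Connected + acyclic check; rings are rejected because the BAT tree is
# undefined on cycles.
check_bond_graph <- function(n, bonds) {
  if (n < 3) stop("a molecular system needs at least 3 atoms")
  if (nrow(bonds) != n - 1) {
    if (nrow(bonds) < n - 1) stop("bond graph is disconnected (too few bonds)")
    stop("bond graph contains a ring; cyclic topologies are not supported")
  }
  # BFS connectivity; with n-1 edges, connected implies acyclic
  adj <- adjacency_list(n, bonds)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    a <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[a]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen)) stop("bond graph is disconnected")
  invisible(TRUE)
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

check_probes <- function(probes, bonds, what) {
  probes <- as_pair_matrix(probes, paste(what, "probes"))
  if (nrow(probes) == 0) return(probes)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  if (!all(key(probes) %in% key(bonds))) {
    stop("every ", what, " probe pair must be a bonded atom pair")
  }
  probes
}

#' Cartesian conformational ensemble
#'
#' @param frames numeric array of dimension F x N x 3 (frames, atoms, xyz)
#'   holding coordinates in nm.
#' @param temperature simulation temperature in K (default 300).
#' @param frame_interval time per frame in ps, informational only.
#'
#' @return An object of class `cartesian_ensemble`.
#' @export
cartesian_ensemble <- function(frames, temperature = 300,
                               frame_interval = NA_real_) {
  d <- dim(frames)
  if (length(d) != 3 || d[3] != 3) stop("frames must be an F x N x 3 array")
  if (d[1] < 2) stop("an ensemble needs at least 2 frames")
  if (any(!is.finite(frames))) stop("non-finite coordinates in ensemble")
  structure(list(
    frames = frames,
    n_frames = d[1],
    n_atoms = d[2],
    temperature = temperature,
    frame_interval = frame_interval
  ), class = "cartesian_ensemble")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", x$n_atoms, " atoms, ", nrow(x$bonds), " bonds, ",
      length(unique(x$residue_index)), " residues\n",
      "  probes: ", nrow(x$methyl_probes), " methyl, ",
      nrow(x$nh_probes), " NH\n", sep = "")
  invisible(x)
}

#' @export
print.cartesian_ensemble <- function(x, ...) {
  cat("<cartesian_ensemble> ", x$n_frames, " frames x ", x$n_atoms,
      " atoms (nm), T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}
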