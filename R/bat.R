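#' Build a bond-angle-torsion (BAT) coordinate tree
#'
#' Maps a connected, acyclic bonded topology onto 3N-6 internal degrees of
#' freedom: N-1 bond lengths, N-2 bond angles and N-3 torsion angles.  The
#' tree is rooted at a deterministic triplet -- the lowest-indexed atom with
#' at least two bonded neighbors together with its two lowest-indexed
#' neighbors -- and the remaining atoms are visited breadth-first with
#' children in ascending index order, so the construction is reproducible
#' for a fixed atom ordering.  Each atom beyond the root triplet receives
#' exactly one bond, one angle and one torsion, defined against its parent,
#' grandparent and great-grandparent reference atoms (no phase-angle
#' re-parameterization of branches).
#'
#' @param system a [molecular_system()].
#'
#' @return An object of class `bat_tree` with elements `root_triplet`
#'   (atom indices t1, t2, t3 with t2 the root), `placement_order` (atom
#'   placement sequence for reconstruction), and a `dofs` data frame with
#'   one row per degree of freedom (kind, defining atoms a1..a4, and the
#'   placed atom).  Degrees of freedom are ordered bonds, then angles, then
#'   torsions.
#' @export
build_bat_tree <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  n <- system$n_atoms
  if (n < 3) stop("BAT coordinates require at least 3 atoms")
  adj <- adjacency_list(n, system$bonds)
  deg <- lengths(adj)
  root <- which(deg >= 2)[1]
  if (is.na(root)) stop("no atom with two bonded neighbors; invalid topology")
  nb <- adj[[root]]
  t1 <- nb[1]; t2 <- root; t3 <- nb[2]

  # reference atoms (ref1 = parent direction, ref2 = torsion anchor)
  ref1 <- integer(n); ref2 <- integer(n)
  ref1[t1] <- t2; ref2[t1] <- t3
  ref1[t2] <- t1; ref2[t2] <- t3
  ref1[t3] <- t2; ref2[t3] <- t1

  placed <- logical(n)
  placed[c(t1, t2, t3)] <- TRUE
  parent <- integer(n)
  parent[t3] <- t2; parent[t1] <- t2

  order_out <- integer(0)
  queue <- c(t1, t2, t3)
  while (length(queue) > 0) {
    p <- queue[1L]
    queue <- queue[-1L]
    for (c_atom in adj[[p]]) {
      if (placed[c_atom]) next
      placed[c_atom] <- TRUE
      parent[c_atom] <- p
      ref1[c_atom] <- p
      ref2[c_atom] <- ref1[p]
      order_out <- c(order_out, c_atom)
      queue <- c(queue, c_atom)
    }
  }

  bonds <- rbind(c(t1, t2, NA, NA), c(t2, t3, NA, NA))
  angles <- rbind(c(t1, t2, t3, NA))
  torsions <- matrix(numeric(0), ncol = 4)
  placed_atom_bond <- c(NA_integer_, NA_integer_)
  placed_atom_angle <- NA_integer_
  placed_atom_torsion <- integer(0)
  for (a in order_out) {
    p <- ref1[a]; g <- ref1[p]; h <- ref2[p]
    bonds <- rbind(bonds, c(a, p, NA, NA))
    angles <- rbind(angles, c(a, p, g, NA))
    torsions <- rbind(torsions, c(a, p, g, h))
    placed_atom_bond <- c(placed_atom_bond, a)
    placed_atom_angle <- c(placed_atom_angle, a)
    placed_atom_torsion <- c(placed_atom_torsion, a)
  }

  dofs <- data.frame(
    kind = c(rep("bond", nrow(bonds)), rep("angle", nrow(angles)),
             rep("torsion", nrow(torsions))),
    a1 = c(bonds[, 1], angles[, 1], torsions[, 1]),
    a2 = c(bonds[, 2], angles[, 2], torsions[, 2]),
    a3 = c(bonds[, 3], angles[, 3], torsions[, 3]),
    a4 = c(bonds[, 4], angles[, 4], torsions[, 4]),
    atom = c(placed_atom_bond, placed_atom_angle, placed_atom_torsion),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(dofs) == 3 * n - 6)

  structure(list(
    root_triplet = c(t1, t2, t3),
    placement_order = order_out,
    ref1 = ref1, ref2 = ref2,
    dofs = dofs,
    n_atoms = n,
    n_dof = nrow(dofs)
  ), class = "bat_tree")
}

#' @export
print.bat_tree <- function(x, ...) {
  k <- table(x$dofs$kind)
  cat("<bat_tree> ", x$n_atoms, " atoms -> ", x$n_dof, " DOFs (",
      k[["bond"]], " bonds, ", k[["angle"]], " angles, ",
      if ("torsion" %in% names(k)) k[["torsion"]] else 0L, " torsions)\n",
      sep = "")
  invisible(x)
}

# vector helpers operating on F x 3 matrices, vectorized over frames
.vnorm <- function(v) sqrt(rowSums(v * v))
.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
.vdot <- function(a, b) rowSums(a * b)

# Dihedral of point columns p1-p2-p3-p4 (F x 3 each), IUPAC sign convention,
# in (-pi, pi].  Invariant under reversal of the atom order.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  b2n <- b2 / .vnorm(b2)
  atan2(.vdot(.vcross(n1, n2), b2n), .vdot(n1, n2))
}

wrap_angle <- function(x) {
  # wrap to [-pi, pi)
  y <- (x + pi) %% (2 * pi) - pi
  y[y >= pi] <- y[y >= pi] - 2 * pi
  y
}

#' Convert a Cartesian ensemble to BAT internal coordinates
#'
#' Computes, frame by frame, the exact bond lengths, bond angles and torsion
#' angles defined by a [build_bat_tree()] tree.  Torsions are wrapped to
#' `[-pi, pi)`.  A collinear bond angle (0 or pi) leaves the dependent
#' torsion undefined and raises an error naming the frame and degree of
#' freedom.
#'
#' @param ens a [cartesian_ensemble()] with the same atom count as the tree.
#' @param tree a [bat_tree][build_bat_tree()].
#' @param system optionally, the [molecular_system()] the tree was built
#'   from; if supplied, per-DOF chain (main-/side-chain) labels are attached.
#'
#' @return An object of class `bat_ensemble`: a list with `values`
#'   (F x (3N-6) matrix; bonds in nm, angles/torsions in rad), `dof_classes`,
#'   and `chain_classes` (NA when `system` is not given).
#' @export
cartesian_to_bat <- function(ens, tree, system = NULL) {
  stopifnot(inherits(ens, "cartesian_ensemble"), inherits(tree, "bat_tree"))
  if (ens$n_atoms != tree$n_atoms) {
    stop("ensemble atom count does not match the BAT tree")
  }
  X <- ens$frames
  at <- function(i) X[, i, , drop = TRUE]
  # guard for F==... X[, i, ] with F frames gives F x 3 matrix
  vals <- matrix(NA_real_, nrow = ens$n_frames, ncol = tree$n_dof)
  d <- tree$dofs
  for (k in seq_len(nrow(d))) {
    kind <- d$kind[k]
    if (kind == "bond") {
      vals[, k] <- .vnorm(at(d$a1[k]) - at(d$a2[k]))
    } else if (kind == "angle") {
      u <- at(d$a1[k]) - at(d$a2[k])
      v <- at(d$a3[k]) - at(d$a2[k])
      vals[, k] <- atan2(.vnorm(.vcross(u, v)), .vdot(u, v))
    } else {
      # check the two internal angles that the dihedral requires
      p1 <- at(d$a1[k]); p2 <- at(d$a2[k]); p3 <- at(d$a3[k]); p4 <- at(d$a4[k])
      n1 <- .vcross(p2 - p1, p3 - p2)
      n2 <- .vcross(p3 - p2, p4 - p3)
      bad <- .vnorm(n1) < 1e-12 | .vnorm(n2) < 1e-12
      if (any(bad)) {
        stop(sprintf(
          "degenerate (collinear) geometry: torsion DOF %d undefined in frame %d",
          k, which(bad)[1]))
      }
      vals[, k] <- wrap_angle(.dihedral(p1, p2, p3, p4))
    }
  }
  chain <- rep(NA_character_, tree$n_dof)
  if (!is.null(system)) chain <- classify_dofs(tree, system)$chain_classes
  structure(list(
    values = vals,
    dof_classes = d$kind,
    chain_classes = chain,
    n_frames = ens$n_frames,
    n_dof = tree$n_dof,
    temperature = ens$temperature
  ), class = "bat_ensemble")
}

#' @export
print.bat_ensemble <- function(x, ...) {
  cat("<bat_ensemble> ", x$n_frames, " frames x ", x$n_dof, " DOFs\n", sep = "")
  invisible(x)
}

#' Reconstruct Cartesian coordinates from BAT values
#'
#' Places the root triplet in a fixed canonical frame (first root atom at
#' the origin, root bond along +z, third atom in the xz plane) and grows the
#' remaining atoms by natural extension of reference frames, so the result
#' is the inverse of [cartesian_to_bat()] up to a rigid-body motion.
#'
#' @param bat a `bat_ensemble` (or plain F x (3N-6) matrix of values).
#' @param tree the [bat_tree][build_bat_tree()] the values refer to.
#' @param temperature temperature attached to the returned ensemble.
#'
#' @return A [cartesian_ensemble()].
#' @export
bat_to_cartesian <- function(bat, tree, temperature = 300) {
  vals <- if (inherits(bat, "bat_ensemble")) bat$values else as.matrix(bat)
  if (inherits(bat, "bat_ensemble") && !is.null(bat$temperature)) {
    temperature <- bat$temperature
  }
  stopifnot(inherits(tree, "bat_tree"))
  if (ncol(vals) != tree$n_dof) stop("BAT value matrix does not match tree")
  d <- tree$dofs
  kinds <- d$kind
  is_angle <- kinds == "angle"
  if (any(vals[, is_angle] <= 0 | vals[, is_angle] >= pi)) {
    stop("bond angles must lie strictly inside (0, pi)")
  }
  if (any(vals[, kinds == "bond"] <= 0)) stop("bond lengths must be positive")

  f <- nrow(vals)
  n <- tree$n_atoms
  X <- array(NA_real_, dim = c(f, n, 3))
  t1 <- tree$root_triplet[1]; t2 <- tree$root_triplet[2]; t3 <- tree$root_triplet[3]

  # columns: first two bonds and the first angle belong to the triplet
  b12 <- vals[, 1]   # bond t1-t2
  b23 <- vals[, 2]   # bond t2-t3
  th  <- vals[, which(is_angle)[1]]  # angle t1-t2-t3

  X[, t1, ] <- 0
  X[, t2, 1] <- 0; X[, t2, 2] <- 0; X[, t2, 3] <- b12
  # angle at t2 between t2->t1 = (0,0,-1) and t2->t3
  X[, t3, 1] <- b23 * sin(th)
  X[, t3, 2] <- 0
  X[, t3, 3] <- b12 - b23 * cos(th)

  # per-placed-atom DOF columns, in placement order
  n_b <- sum(kinds == "bond"); n_a <- sum(is_angle)
  extra <- tree$placement_order
  for (i in seq_along(extra)) {
    a <- extra[i]
    p <- tree$ref1[a]; g <- tree$ref1[p]; h <- tree$ref2[p]
    r   <- vals[, 2 + i]          # bond a-p
    ang <- vals[, 1 + n_b + i]    # angle a-p-g
    tor <- vals[, n_b + n_a + i]  # torsion a-p-g-h
    A <- X[, h, , drop = TRUE]; B <- X[, g, , drop = TRUE]; C <- X[, p, , drop = TRUE]
    if (f == 1) { A <- rbind(A); B <- rbind(B); C <- rbind(C) }
    bc <- (C - B); bc <- bc / .vnorm(bc)
    ab <- (B - A)
    nrm <- .vcross(ab, bc)
    nrm <- nrm / .vnorm(nrm)
    m <- .vcross(nrm, bc)
    d2x <- -r * cos(ang)
    d2y <- r * sin(ang) * cos(tor)
    d2z <- r * sin(ang) * sin(tor)
    X[, a, ] <- C + bc * d2x + m * d2y + nrm * d2z
  }
  cartesian_ensemble(X, temperature = temperature)
}

#' Label BAT degrees of freedom by kind and chain class
#'
#' A degree of freedom is main-chain when the atoms that localize it are all
#' backbone-flagged: both atoms for a bond, all three for an angle, and the
#' two central-bond atoms for a torsion (the torsion rotates about its
#' central bond, so terminal reference atoms do not enter the rule).
#'
#' @param tree a [bat_tree][build_bat_tree()].
#' @param system the [molecular_system()] the tree was built from.
#'
#' @return A list with `dof_classes` (bond/angle/torsion) and
#'   `chain_classes` (`"main-chain"` / `"side-chain"`).
#' @export
classify_dofs <- function(tree, system) {
  stopifnot(inherits(tree, "bat_tree"), inherits(system, "molecular_system"))
  if (tree$n_atoms != system$n_atoms) stop("tree was not built from this system")
  bb <- system$backbone
  d <- tree$dofs
  mc <- vapply(seq_len(nrow(d)), function(k) {
    switch(d$kind[k],
      bond = bb[d$a1[k]] && bb[d$a2[k]],
      angle = bb[d$a1[k]] && bb[d$a2[k]] && bb[d$a3[k]],
      torsion = bb[d$a2[k]] && bb[d$a3[k]]
    )
  }, logical(1))
  list(
    dof_classes = d$kind,
    chain_classes = ifelse(mc, "main-chain", "side-chain")
  )
}
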