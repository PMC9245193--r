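#' Histogram estimate of a one-dimensional differential entropy
#'
#' Discretizes the samples into `n_bins` equal-width bins spanning the
#' sample range and evaluates `S = -R * sum_i p_i * ln(p_i / dx)`, with
#' `0 * ln 0 = 0`.  For bond and angle degrees of freedom the BAT
#' configuration-space Jacobian (b^2 for bonds, sin(theta) for angles;
#' torsions carry none) enters as the correction `+R<ln J>` added to the
#' naive histogram entropy, which is equivalent at histogram resolution to
#' weighting the density itself.  A degenerate sample (all values equal,
#' e.g. a constrained bond) yields the single-bin value computed with a bin
#' width of `max(range, 1e-9)` and a degeneracy warning; such terms cancel
#' in free-minus-bound entropy differences.
#'
#' @param samples numeric vector of per-frame values.
#' @param kind one of `"torsion"`, `"angle"`, `"bond"`; selects the Jacobian.
#' @param n_bins number of bins (>= 1).
#' @param jacobian logical; apply the BAT Jacobian correction (default TRUE).
#'
#' @return Entropy in J K^-1 mol^-1.
#' @export
histogram_entropy_1d <- function(samples, kind = c("torsion", "angle", "bond"),
                                 n_bins = 50, jacobian = TRUE) {
  kind <- match.arg(kind)
  if (any(!is.finite(samples))) stop("non-finite samples")
  if (n_bins < 1) stop("n_bins must be >= 1")
  f <- length(samples)
  if (f < 2) stop("need at least 2 samples")
  rng <- range(samples)
  width_total <- rng[2] - rng[1]
  if (width_total == 0 || n_bins == 1) {
    if (width_total == 0) {
      warning("degenerate degree of freedom: all samples identical")
    }
    dx <- max(width_total, 1e-9)
    s <- .R_GAS * log(dx)
  } else {
    dx <- width_total / n_bins
    idx <- pmin(floor((samples - rng[1]) / dx) + 1L, n_bins)
    p <- tabulate(idx, n_bins) / f
    nz <- p > 0
    s <- -.R_GAS * sum(p[nz] * log(p[nz] / dx))
  }
  if (jacobian) s <- s + jacobian_correction(samples, kind)
  s
}

jacobian_correction <- function(samples, kind) {
  switch(kind,
    torsion = 0,
    bond = 2 * .R_GAS * mean(log(samples)),
    angle = .R_GAS * mean(log(sin(samples)))
  )
}

# bin assignment over the sample range; degenerate -> all ones
.bin_index <- function(x, n_bins) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  dx <- (rng[2] - rng[1]) / n_bins
  pmin(floor((x - rng[1]) / dx) + 1L, n_bins)
}

.discrete_entropy_nats <- function(counts, f) {
  p <- counts[counts > 0] / f
  -sum(p * log(p))
}

#' Histogram estimate of the mutual information of two samples
#'
#' Evaluates `I = S1 + S2 - S12` on a shared `n_bins x n_bins` grid.  Bin
#' widths (and hence the BAT Jacobian weights) cancel between the marginal
#' and joint terms, so the result is a pure discrete mutual information
#' scaled to J K^-1 mol^-1.  A degenerate variable yields exactly zero.
#'
#' @param x,y numeric vectors of equal length (paired per-frame values).
#' @param n_bins bins per dimension.
#'
#' @return Mutual information in J K^-1 mol^-1 (non-negative).
#' @export
histogram_mi_2d <- function(x, y, n_bins = 50) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite samples")
  f <- length(x)
  ix <- .bin_index(x, n_bins)
  iy <- .bin_index(y, n_bins)
  .mi_from_index(ix, iy, n_bins, f)
}

.mi_from_index <- function(ix, iy, n_bins, f) {
  h1 <- .discrete_entropy_nats(tabulate(ix, n_bins), f)
  h2 <- .discrete_entropy_nats(tabulate(iy, n_bins), f)
  h12 <- .discrete_entropy_nats(tabulate(ix + n_bins * (iy - 1L), n_bins^2), f)
  .R_GAS * (h1 + h2 - h12)
}

#' All 1D entropies and pairwise mutual informations of a BAT ensemble
#'
#' Computes the per-DOF marginal entropy (Jacobian-corrected) and the full
#' symmetric matrix of pairwise mutual informations on `n_bins` (1D) and
#' `n_bins x n_bins` (2D) grids.  This is the single expensive pass of the
#' entropy pipeline; every downstream quantity (MIST, truncated pairwise
#' expansion, subset decompositions) is assembled from these terms.
#'
#' @param bat a `bat_ensemble` from [cartesian_to_bat()] or
#'   [sample_bat_ensemble()].
#' @param n_bins bins per dimension (default 50; use 3 for the
#'   vibration-suppressed variant).
#'
#' @return An object of class `entropy_terms`: `s1` (per-DOF entropies),
#'   `mi` (symmetric matrix, diagonal NA), `n_bins`, `n_frames`, plus the
#'   DOF kind and chain labels carried over from the ensemble.
#' @export
pairwise_entropy_terms <- function(bat, n_bins = 50) {
  stopifnot(inherits(bat, "bat_ensemble"))
  v <- bat$values
  f <- nrow(v)
  if (f < 2) stop("need at least 2 frames")
  n_dof <- ncol(v)
  idx <- matrix(0L, nrow = f, ncol = n_dof)
  s1 <- numeric(n_dof)
  marg_h <- numeric(n_dof)   # discrete marginal entropies in nats, reused
  for (k in seq_len(n_dof)) {
    s1[k] <- withCallingHandlers(
      histogram_entropy_1d(v[, k], kind = bat$dof_classes[k], n_bins = n_bins),
      warning = function(w) {
        if (grepl("degenerate degree of freedom", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    idx[, k] <- .bin_index(v[, k], n_bins)
    marg_h[k] <- .discrete_entropy_nats(tabulate(idx[, k], n_bins), f)
  }
  mi <- matrix(0, n_dof, n_dof)
  if (n_dof > 1) {
    nb2 <- n_bins^2
    for (i in seq_len(n_dof - 1)) {
      ixi <- idx[, i]
      for (j in seq.int(i + 1, n_dof)) {
        h12 <- .discrete_entropy_nats(tabulate(ixi + n_bins * (idx[, j] - 1L), nb2), f)
        mi[i, j] <- mi[j, i] <- .R_GAS * (marg_h[i] + marg_h[j] - h12)
      }
    }
  }
  diag(mi) <- NA_real_
  structure(list(
    s1 = s1, mi = mi, n_bins = n_bins, n_frames = f,
    dof_classes = bat$dof_classes, chain_classes = bat$chain_classes
  ), class = "entropy_terms")
}

#' Assemble an `entropy_terms` object from precomputed values
#'
#' Useful for worked examples and for exact (enumerated) discrete
#' distributions where the marginal entropies and mutual informations are
#' known analytically.
#'
#' @param s1 per-DOF 1D entropies (J K^-1 mol^-1).
#' @param mi symmetric mutual-information matrix (J K^-1 mol^-1).
#' @param n_bins,n_frames bookkeeping fields (defaults NA).
#' @param dof_classes,chain_classes optional per-DOF labels.
#'
#' @return An `entropy_terms` object.
#' @export
entropy_terms <- function(s1, mi, n_bins = NA_integer_, n_frames = NA_integer_,
                          dof_classes = NULL, chain_classes = NULL) {
  mi <- as.matrix(mi)
  n <- length(s1)
  if (!all(dim(mi) == n)) stop("mi must be an n x n matrix matching s1")
  off <- mi[upper.tri(mi)]
  if (max(abs(mi - t(mi)), na.rm = TRUE) > 1e-8) stop("mi must be symmetric")
  if (any(off < -1e-6 * .R_GAS, na.rm = TRUE)) {
    warning("mutual information estimates more negative than -1e-6 R")
  }
  diag(mi) <- NA_real_
  structure(list(
    s1 = as.numeric(s1), mi = mi, n_bins = n_bins, n_frames = n_frames,
    dof_classes = dof_classes, chain_classes = chain_classes
  ), class = "entropy_terms")
}

#' @export
print.entropy_terms <- function(x, ...) {
  cat("<entropy_terms> ", length(x$s1), " DOFs, ", x$n_bins, " bins, ",
      x$n_frames, " frames\n", sep = "")
  invisible(x)
}

# Kruskal maximum spanning tree on the clamped MI graph.  Deterministic
# tie-break: higher MI first, then lower (i, j) pair order.
.max_spanning_tree <- function(mi_sub) {
  n <- nrow(mi_sub)
  if (n <= 1) return(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("i", "j", "mi"))))
  iu <- which(upper.tri(mi_sub), arr.ind = TRUE)
  w <- pmax(mi_sub[iu], 0)
  ord <- order(-w, iu[, 1], iu[, 2])
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  edges <- matrix(NA_real_, nrow = n - 1, ncol = 3,
                  dimnames = list(NULL, c("i", "j", "mi")))
  taken <- 0L
  for (e in ord) {
    ra <- find(iu[e, 1]); rb <- find(iu[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      taken <- taken + 1L
      edges[taken, ] <- c(iu[e, 1], iu[e, 2], w[e])
      if (taken == n - 1L) break
    }
  }
  edges[seq_len(taken), , drop = FALSE]
}

#' MIST entropy from pairwise terms
#'
#' The maximum information spanning tree approximation: the sum of all 1D
#' entropies minus the mutual-information sum over the maximum spanning tree
#' of the complete pairwise-MI graph.  Truncated at pairwise order, this is
#' a guaranteed upper bound to the exact configurational entropy.  Negative
#' MI estimates (possible from discretization noise) are clamped to zero for
#' tree weighting; values below `-1e-6 * R` trigger a warning.
#'
#' @param terms an [entropy_terms()] object.
#' @param subset optional integer vector restricting the calculation to a
#'   subset of degrees of freedom.
#'
#' @return An object of class `mist_result`: `s_1d` (sum of 1D entropies),
#'   `tree_edges` (matrix of tree DOF pairs with their MI), `s_mist`,
#'   `n_dof`, and the bin/frame bookkeeping.
#' @export
mist_entropy <- function(terms, subset = NULL) {
  stopifnot(inherits(terms, "entropy_terms"))
  n <- length(terms$s1)
  if (is.null(subset)) subset <- seq_len(n)
  if (length(subset) == 0) stop("empty degree-of-freedom subset")
  if (any(subset < 1 | subset > n)) stop("subset indices out of range")
  off <- terms$mi[upper.tri(terms$mi)]
  if (any(off < -1e-6 * .R_GAS, na.rm = TRUE)) {
    warning("mutual information estimates more negative than -1e-6 R; clamped to 0")
  }
  mi_sub <- terms$mi[subset, subset, drop = FALSE]
  edges <- .max_spanning_tree(mi_sub)
  # map edge indices back to the original DOF numbering
  if (nrow(edges) > 0) {
    edges[, 1] <- subset[edges[, 1]]
    edges[, 2] <- subset[edges[, 2]]
  }
  s_1d <- sum(terms$s1[subset])
  s_mist <- s_1d - sum(edges[, "mi"])
  structure(list(
    s_1d = s_1d, tree_edges = edges, s_mist = s_mist,
    n_dof = length(subset), n_bins = terms$n_bins, n_frames = terms$n_frames
  ), class = "mist_result")
}

#' @export
print.mist_result <- function(x, ...) {
  cat("<mist_result> ", x$n_dof, " DOFs: S_1D = ", format(x$s_1d, digits = 6),
      ", S_MIST = ", format(x$s_mist, digits = 6), " J K^-1 mol^-1 (",
      nrow(x$tree_edges), " tree edges)\n", sep = "")
  invisible(x)
}

#' Pairwise-truncated mutual information expansion (MIE) entropy
#'
#' The sum of 1D entropies minus the mutual information over *all* pairs
#' (not just the spanning tree).  Unlike MIST this truncation carries no
#' upper-bound guarantee and typically overcorrects: since every clamped MI
#' is non-negative and the tree is a subset of all pairs, the pairwise MIE
#' value never exceeds the MIST value.
#'
#' @inheritParams mist_entropy
#' @return Entropy in J K^-1 mol^-1.
#' @export
mie2_entropy <- function(terms, subset = NULL) {
  stopifnot(inherits(terms, "entropy_terms"))
  n <- length(terms$s1)
  if (is.null(subset)) subset <- seq_len(n)
  mi_sub <- terms$mi[subset, subset, drop = FALSE]
  off <- pmax(mi_sub[upper.tri(mi_sub)], 0)
  sum(terms$s1[subset]) - sum(off)
}

#' MIST entropy of a subset of degrees of freedom
#'
#' Restricts the estimate to the marginals and pairwise mutual informations
#' within `dof_subset` only; with the full index set this equals
#' [mist_entropy()] on all terms, and a singleton subset returns that DOF's
#' 1D entropy.
#'
#' @param bat a `bat_ensemble`.
#' @param dof_subset nonempty integer vector of DOF indices.
#' @param n_bins bins per dimension.
#'
#' @return A `mist_result` for the subset.
#' @export
subset_entropy <- function(bat, dof_subset, n_bins = 50) {
  if (length(dof_subset) == 0) stop("empty degree-of-freedom subset")
  terms <- pairwise_entropy_terms(bat, n_bins = n_bins)
  mist_entropy(terms, subset = dof_subset)
}

#' Mutual-information coupling between two DOF subsets
#'
#' Defined operationally as
#' `S_MIST(A) + S_MIST(B) - S_MIST(A union B)`, the amount by which the
#' joint MIST estimate is lowered by tree edges crossing between the two
#' subsets.  Non-negative up to estimator noise; approximately zero for
#' independent subsets.
#'
#' @param bat a `bat_ensemble`.
#' @param subset_a,subset_b disjoint nonempty DOF index vectors.
#' @param n_bins bins per dimension.
#' @param terms optionally, precomputed [pairwise_entropy_terms()] for `bat`
#'   at the same `n_bins` (avoids recomputation in decomposition loops).
#'
#' @return Coupling in J K^-1 mol^-1.
#' @export
coupling_between <- function(bat, subset_a, subset_b, n_bins = 50,
                             terms = NULL) {
  if (length(intersect(subset_a, subset_b)) > 0) {
    stop("subsets must be disjoint")
  }
  if (length(subset_a) == 0 || length(subset_b) == 0) {
    stop("subsets must be nonempty")
  }
  if (is.null(terms)) terms <- pairwise_entropy_terms(bat, n_bins = n_bins)
  sa <- mist_entropy(terms, subset = subset_a)$s_mist
  sb <- mist_entropy(terms, subset = subset_b)$s_mist
  sab <- mist_entropy(terms, subset = c(subset_a, subset_b))$s_mist
  sa + sb - sab
}

#' Vibration-suppressed (3-bin) MIST entropy
#'
#' Re-runs the full MIST pipeline with 3 bins per dimension (3 x 3 in 2D).
#' The coarse grid suppresses small-amplitude vibrational features of the
#' sampled distributions and retains rotamer-level (conformational)
#' structure, so differences of this quantity isolate conformational
#' entropy changes.
#'
#' @param bat a `bat_ensemble`.
#' @param n_bins coarse bin count (default 3).
#'
#' @return A `mist_result`.
#' @export
vibration_suppressed_entropy <- function(bat, n_bins = 3) {
  mist_entropy(pairwise_entropy_terms(bat, n_bins = n_bins))
}
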