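#' Least-squares superposition of an ensemble onto a reference frame
#'
#' Removes overall rigid-body motion by the Kabsch algorithm: each frame is
#' rotated and translated to minimize the mass-unweighted sum of squared
#' deviations of all atoms from the reference (by default the first frame).
#' Internal dynamics analyses (order parameters, RMSF, quasi-harmonic
#' entropy) operate on the superposed ensemble.
#'
#' @param ens a [cartesian_ensemble()].
#' @param reference frame index (default 1) or an N x 3 coordinate matrix.
#'
#' @return A superposed [cartesian_ensemble()].
#' @export
superpose_ensemble <- function(ens, reference = 1L) {
  stopifnot(inherits(ens, "cartesian_ensemble"))
  X <- ens$frames
  ref <- if (is.matrix(reference)) reference else X[reference, , , drop = TRUE]
  if (!all(dim(ref) == c(ens$n_atoms, 3))) {
    stop("reference atom count does not match ensemble")
  }
  refc <- colMeans(ref)
  Y <- sweep(ref, 2, refc)
  # degenerate reference (all atoms collinear) has rank < 2
  sv_ref <- svd(Y, nu = 0, nv = 0)$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    stop("degenerate (collinear) reference frame; superposition undefined")
  }
  out <- X
  for (fi in seq_len(ens$n_frames)) {
    Z <- X[fi, , , drop = TRUE]
    zc <- colMeans(Z)
    Zc <- sweep(Z, 2, zc)
    H <- crossprod(Zc, Y)        # 3 x 3
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    Q <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    out[fi, , ] <- sweep(Zc %*% Q, 2, refc, FUN = "+")
  }
  res <- ens
  res$frames <- out
  res
}

#' Lipari-Szabo generalized order parameter of a bond-vector series
#'
#' Direct second-rank tensor formula over the whole series:
#' `O^2 = (3 [<x^2>^2 + <y^2>^2 + <z^2>^2 + 2<xy>^2 + 2<xz>^2 + 2<yz>^2] - 1) / 2`
#' with x, y, z the unit bond-vector components.  Equals 1 for a rigid
#' vector and tends to 0 for isotropic reorientation.
#'
#' @param unit_vectors F x 3 matrix of unit-length bond vectors (after
#'   superposition).
#'
#' @return The order parameter, a scalar in \[0, 1\] up to 1e-9 tolerance.
#' @export
order_parameter <- function(unit_vectors) {
  V <- as.matrix(unit_vectors)
  if (ncol(V) != 3 || nrow(V) < 2) stop("need an F x 3 matrix with F >= 2")
  nrm <- .vnorm(V)
  if (any(abs(nrm - 1) > 1e-6)) stop("bond vectors must be unit length")
  x <- V[, 1]; y <- V[, 2]; z <- V[, 3]
  m <- c(mean(x * x), mean(y * y), mean(z * z),
         mean(x * y), mean(x * z), mean(y * z))
  (3 * (m[1]^2 + m[2]^2 + m[3]^2 + 2 * m[4]^2 + 2 * m[5]^2 + 2 * m[6]^2) - 1) / 2
}

#' Extract unit probe vectors from a superposed ensemble
#'
#' For each annotated probe pair (a, b) returns the per-frame unit vector
#' from atom a to atom b.  Methyl probes run from the heavy-atom neighbor
#' to the methyl carbon (the methyl symmetry axis, appropriate for
#' united-atom representations); NH probes from amide N to amide H.
#'
#' @param ens_superposed a superposed [cartesian_ensemble()].
#' @param system the [molecular_system()] carrying probe annotations.
#' @param kind `"methyl"` or `"nh"`.
#'
#' @return A list of F x 3 unit-vector matrices, one per probe, named by
#'   the probe atom pair; an empty list (with a message attribute) when the
#'   system has no probes of that kind.
#' @export
extract_probe_vectors <- function(ens_superposed, system,
                                  kind = c("methyl", "nh")) {
  kind <- match.arg(kind)
  stopifnot(inherits(ens_superposed, "cartesian_ensemble"),
            inherits(system, "molecular_system"))
  probes <- if (kind == "methyl") system$methyl_probes else system$nh_probes
  if (is.null(probes) || nrow(probes) == 0) {
    out <- list()
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (max(probes) > ens_superposed$n_atoms) stop("probe atoms missing from ensemble")
  X <- ens_superposed$frames
  out <- vector("list", nrow(probes))
  for (k in seq_len(nrow(probes))) {
    a <- probes[k, 1]; b <- probes[k, 2]
    v <- X[, b, , drop = TRUE] - X[, a, , drop = TRUE]
    nrm <- .vnorm(v)
    if (any(nrm < 1e-12)) stop("zero-length probe bond vector in a frame")
    out[[k]] <- v / nrm
  }
  names(out) <- paste(probes[, 1], probes[, 2], sep = "-")
  out
}

#' Per-probe and mean order parameters of a system's probe set
#'
#' @inheritParams extract_probe_vectors
#' @return A list with `o2` (named per-probe values), `mean` (mean over
#'   probes, `NA` for an empty set), and `kind`.
#' @export
order_parameter_set <- function(ens_superposed, system,
                                kind = c("methyl", "nh")) {
  kind <- match.arg(kind)
  vecs <- extract_probe_vectors(ens_superposed, system, kind)
  o2 <- vapply(vecs, order_parameter, numeric(1))
  list(o2 = o2, mean = if (length(o2)) mean(o2) else NA_real_, kind = kind)
}

#' Per-coordinate root-mean-square fluctuations
#'
#' `RMSF_ij = sqrt(< (r_ij - <r_ij>)^2 >)` over frames, with population
#' (divide-by-F) normalization, for each atom i and Cartesian coordinate j.
#' The ensemble should be superposed first.
#'
#' @param ens_superposed a superposed [cartesian_ensemble()].
#' @return An N x 3 matrix of RMSF values in nm.
#' @export
rmsf <- function(ens_superposed) {
  stopifnot(inherits(ens_superposed, "cartesian_ensemble"))
  X <- ens_superposed$frames
  f <- dim(X)[1]
  mu <- colMeans(X)                       # N x 3 means
  dev2 <- sweep(X, c(2, 3), mu)^2
  sqrt(apply(dev2, c(2, 3), sum) / f)
}

# quantum harmonic oscillator entropy per mode, R * [a/(e^a - 1) - ln(1 - e^-a)]
.qho_entropy <- function(alpha) {
  out <- numeric(length(alpha))
  ok <- is.finite(alpha) & alpha < 700
  a <- alpha[ok]
  out[ok] <- .R_GAS * (a / expm1(a) - log1p(-exp(-a)))
  out  # alpha -> Inf limit is 0
}

#' Diagonal (B-factor style) quasi-harmonic entropy
#'
#' Treats every Cartesian coordinate of every atom as an independent quantum
#' harmonic oscillator whose frequency is set by its positional fluctuation:
#' `alpha_ij = hbar / (RMSF_ij * sqrt(M_i * kB * T))`, and sums
#' `R * [alpha/(e^alpha - 1) - ln(1 - e^-alpha)]` over coordinates.
#' Coordinates with zero RMSF contribute nothing (the `alpha -> Inf` limit).
#' Because all covariances are neglected this is an upper bound to the
#' full-covariance quasi-harmonic value of the same ensemble.
#'
#' @param rmsf_matrix N x 3 matrix of RMSF values in nm (from [rmsf()] or
#'   [rmsf_from_bfactor()]).
#' @param masses atomic masses in g/mol.
#' @param temperature temperature in K.
#'
#' @return Entropy in J K^-1 mol^-1.
#' @export
qh_entropy_diagonal <- function(rmsf_matrix, masses, temperature = 300) {
  rmsf_matrix <- as.matrix(rmsf_matrix)
  if (any(rmsf_matrix < 0)) stop("RMSF values must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  if (any(masses <= 0)) stop("masses must be positive")
  if (nrow(rmsf_matrix) != length(masses)) stop("one mass per atom required")
  m_kg <- masses / 1000 / .N_AVOGADRO          # g/mol -> kg per particle
  x_m <- rmsf_matrix * 1e-9                    # nm -> m
  alpha <- .HBAR / (x_m * sqrt(m_kg * .KB * temperature))  # recycles by column
  alpha[x_m == 0] <- Inf
  sum(.qho_entropy(alpha))
}

#' Full-covariance quasi-harmonic entropy
#'
#' Diagonalizes the mass-weighted covariance matrix of the superposed
#' Cartesian coordinates; each positive eigenvalue lambda defines a
#' quasi-harmonic mode with `alpha = hbar / sqrt(lambda * kB * T)` fed into
#' the same oscillator entropy formula.  Zero and negative eigenvalues
#' (rigid-body remnants, rank deficiency) are dropped.  Correlations can
#' only lower the estimate, so the result never exceeds
#' [qh_entropy_diagonal()] on the same ensemble.
#'
#' @param ens_superposed a superposed [cartesian_ensemble()].
#' @param masses atomic masses in g/mol.
#' @param temperature temperature in K.
#'
#' @return Entropy in J K^-1 mol^-1.
#' @export
qh_entropy_full <- function(ens_superposed, masses, temperature = 300) {
  stopifnot(inherits(ens_superposed, "cartesian_ensemble"))
  X <- ens_superposed$frames
  f <- dim(X)[1]; n <- dim(X)[2]
  if (f <= 3 * n) {
    warning("fewer frames than Cartesian degrees of freedom; ",
            "covariance is rank-deficient")
  }
  m_kg <- masses / 1000 / .N_AVOGADRO
  W <- matrix(X, nrow = f)                     # f x 3N, atom-major blocks
  W <- sweep(W, 2, colMeans(W))
  W <- sweep(W, 2, rep(sqrt(m_kg), 3), FUN = "*")
  C <- crossprod(W) / f                        # mass-weighted covariance, kg m^2 scale below
  C <- C * (1e-9)^2                            # nm^2 -> m^2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev) * 1e-12
  ev <- ev[ev > max(tol, 0)]
  alpha <- .HBAR / sqrt(ev * .KB * temperature)
  sum(.qho_entropy(alpha))
}

#' Convert RMSF to crystallographic B-factors and back
#'
#' `B_i = (8 pi^2 / 3) * sum_j RMSF_ij^2` with RMSF in nm converted to
#' Angstroms, so B is in the conventional Angstrom^2 units.  The inverse
#' distributes the total positional variance isotropically over the three
#' coordinates (the anisotropy information is not recoverable from B), but
#' the round trip conserves `sum_j RMSF_ij^2` exactly.
#'
#' @param rmsf_matrix N x 3 RMSF matrix in nm.
#' @return `bfactor_from_rmsf`: per-atom B-factors in Angstrom^2.
#' @export
bfactor_from_rmsf <- function(rmsf_matrix) {
  rmsf_matrix <- as.matrix(rmsf_matrix)
  if (any(rmsf_matrix < 0)) stop("RMSF values must be non-negative")
  (8 * pi^2 / 3) * rowSums((rmsf_matrix * 10)^2)
}

#' @rdname bfactor_from_rmsf
#' @param bfactors per-atom B-factors in Angstrom^2.
#' @return `rmsf_from_bfactor`: N x 3 matrix of isotropic RMSF values in nm.
#' @export
rmsf_from_bfactor <- function(bfactors) {
  if (any(bfactors < 0)) stop("B-factors must be non-negative")
  msf_total <- bfactors / (8 * pi^2 / 3)       # Angstrom^2, summed over xyz
  iso <- sqrt(msf_total / 3) / 10              # Angstrom -> nm, per coordinate
  matrix(iso, nrow = length(bfactors), ncol = 3)
}

#' All dynamics proxies of one ensemble
#'
#' Convenience wrapper: superposes the ensemble, then computes methyl and NH
#' order-parameter sets, per-coordinate RMSF, per-atom B-factors and both
#' quasi-harmonic entropies.
#'
#' @param ens a [cartesian_ensemble()].
#' @param system the matching [molecular_system()].
#' @param temperature temperature in K (default: the ensemble's).
#' @param full_qh also compute the full-covariance quasi-harmonic entropy
#'   (default TRUE).
#'
#' @return A list: `methyl`, `nh` (order-parameter sets), `rmsf`,
#'   `bfactors`, `s_bfact`, `s_qh_full`, and `qh_per_coord` (per-coordinate
#'   oscillator entropies, used for reporter undersampling).
#' @export
proxy_result <- function(ens, system, temperature = NULL, full_qh = TRUE) {
  if (is.null(temperature)) temperature <- ens$temperature
  sup <- superpose_ensemble(ens)
  r <- rmsf(sup)
  m_kg <- system$masses / 1000 / .N_AVOGADRO
  alpha <- .HBAR / ((r * 1e-9) * sqrt(m_kg * .KB * temperature))
  alpha[r == 0] <- Inf
  per_coord <- matrix(.qho_entropy(alpha), nrow = nrow(r))
  list(
    methyl = order_parameter_set(sup, system, "methyl"),
    nh = order_parameter_set(sup, system, "nh"),
    rmsf = r,
    bfactors = bfactor_from_rmsf(r),
    s_bfact = sum(per_coord),
    s_qh_full = if (full_qh) qh_entropy_full(sup, system$masses, temperature)
                else NA_real_,
    qh_per_coord = per_coord,
    temperature = temperature
  )
}
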