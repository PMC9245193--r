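# Shared fixture builders: tiny molecules and ensembles, all generated in code.

chain_system <- function(n, masses = rep(12.011, n)) {
  molecular_system(paste0("C", seq_len(n)), masses,
                   cbind(seq_len(n - 1), seq.int(2, n)),
                   backbone = rep(TRUE, n))
}

branched_system_10 <- function() {
  # backbone 1-2-3-4-5 with branches: 6,7 on 2; 8 on 3; 9,10 chain on 4
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                 c(2, 6), c(2, 7), c(3, 8), c(4, 9), c(9, 10))
  molecular_system(paste0("A", 1:10), rep(12, 10), bonds,
                   backbone = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                FALSE, FALSE, FALSE, FALSE, FALSE))
}

# random (but geometrically sane) ensemble for a system: jitter around a
# stretched-out reference built by small random displacements of a helix-like
# curve, so no angles are near 0 or pi
random_ensemble <- function(system, n_frames, jitter = 0.03, seed = 1) {
  n <- system$n_atoms
  with_seed(seed, {
    t <- seq_len(n)
    ref <- cbind(0.25 * cos(t), 0.25 * sin(t), 0.1 * t) +
      matrix(rnorm(n * 3, sd = 0.05), ncol = 3)
    arr <- array(NA_real_, dim = c(n_frames, n, 3))
    for (f in seq_len(n_frames)) {
      arr[f, , ] <- ref + matrix(rnorm(n * 3, sd = jitter), ncol = 3)
    }
    cartesian_ensemble(arr)
  })
}

rigid_copies_ensemble <- function(coords, n_frames, seed = 1) {
  n <- nrow(coords)
  with_seed(seed, {
    arr <- array(NA_real_, dim = c(n_frames, n, 3))
    for (f in seq_len(n_frames)) {
      Q <- random_rotation()
      shift <- rnorm(3)
      arr[f, , ] <- sweep(coords %*% Q, 2, shift, "+")
    }
    cartesian_ensemble(arr)
  })
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# uniform sampling of unit vectors inside a cone of semi-angle theta0 about +z
cone_vectors <- function(n, theta0, seed = 1) {
  with_seed(seed, {
    z <- runif(n, cos(theta0), 1)
    ph <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(s * cos(ph), s * sin(ph), z)
  })
}

R_GAS <- gas_constant()
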