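test_that("superposition removes rigid-body motion and inverts known rotations", {
  sys <- branched_system_10()
  ref <- random_ensemble(sys, 2, jitter = 0, seed = 3)$frames[1, , ]
  ens <- rigid_copies_ensemble(ref, 8, seed = 2)
  sup <- superpose_ensemble(ens, reference = ref)
  for (f in 1:8) {
    expect_lt(sqrt(mean((sup$frames[f, , ] - ref)^2)), 1e-9)
  }
  # superposition never increases the total squared deviation
  jit <- random_ensemble(sys, 10, jitter = 0.05, seed = 6)
  supj <- superpose_ensemble(jit)
  reff <- jit$frames[1, , ]
  for (f in 2:10) {
    before <- sum((jit$frames[f, , ] - reff)^2)
    after <- sum((supj$frames[f, , ] - reff)^2)
    expect_lte(after, before + 1e-12)
  }
  # idempotence
  sup2 <- superpose_ensemble(supj)
  expect_lt(max(abs(sup2$frames - supj$frames)), 1e-9)
  # collinear reference is rejected
  line <- array(rep(cbind(0, 0, seq(0, 0.9, length.out = 10)), each = 2),
                dim = c(2, 10, 3))
  expect_error(superpose_ensemble(cartesian_ensemble(line)), "degenerate")
})

test_that("order parameter closed forms: rigid, isotropic, cone", {
  # rigid vector
  v_fix <- matrix(rep(c(0, 0, 1), each = 50), ncol = 3)
  expect_equal(order_parameter(v_fix), 1, tolerance = 1e-12)
  # isotropic: tends to 0 (tolerance from a 30-replicate oracle, sd 7.5e-6)
  v_iso <- with_seed(13, {
    m <- matrix(rnorm(3e5), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  o_iso <- order_parameter(v_iso)
  expect_gte(o_iso, 0)
  expect_lt(o_iso, 5e-5)
  # uniform cone of semi-angle 60 deg: closed form 0.140625
  # (tolerance 3x the replicate-oracle sd of 6e-4 at 1e5 frames)
  o_cone <- order_parameter(cone_vectors(1e5, pi / 3, seed = 14))
  expect_equal(o_cone, 0.140625, tolerance = 0.002 / 0.140625)
  # rotation invariance
  Q <- with_seed(15, random_rotation())
  expect_lt(abs(order_parameter(v_iso %*% Q) - o_iso), 1e-12)
  expect_error(order_parameter(v_iso * 2), "unit length")
})

test_that("probe vector extraction matches direct geometry", {
  sys <- make_toy_system(3, sidechain_size = 1, methyl_fraction = 1)
  ens <- random_ensemble(sys, 5, seed = 8)
  vec <- extract_probe_vectors(ens, sys, "methyl")
  expect_length(vec, 3)
  p <- sys$methyl_probes[1, ]
  v_direct <- ens$frames[, p[2], ] - ens$frames[, p[1], ]
  v_direct <- v_direct / sqrt(rowSums(v_direct^2))
  expect_equal(vec[[1]], v_direct, tolerance = 1e-12)
  # empty probe set signals explicitly
  sys0 <- make_toy_system(3, sidechain_size = 1, methyl_fraction = 0)
  ev <- extract_probe_vectors(ens, sys0, "methyl")
  expect_length(ev, 0)
  expect_true(isTRUE(attr(ev, "empty")))
  ops <- order_parameter_set(ens, sys0, "methyl")
  expect_true(is.na(ops$mean))
  # a single static probe gives set mean 1
  still <- cartesian_ensemble(array(rep(ens$frames[1, , ], each = 3),
                                    dim = c(3, sys$n_atoms, 3)))
  expect_equal(order_parameter_set(still, sys, "methyl")$mean, 1,
               tolerance = 1e-9)
})

test_that("RMSF follows its definition with population normalization", {
  sys <- chain_system(4)
  base <- random_ensemble(sys, 2, jitter = 0, seed = 1)$frames[1, , ]
  # static ensemble
  stat <- cartesian_ensemble(array(rep(base, each = 4), dim = c(4, 4, 3)))
  expect_true(all(rmsf(stat) == 0))
  # alternating +/- a around the mean in one coordinate
  arr <- array(rep(base, each = 4), dim = c(4, 4, 3))
  arr[, 2, 1] <- base[2, 1] + c(0.05, -0.05, 0.05, -0.05)
  r <- rmsf(cartesian_ensemble(arr))
  expect_equal(r[2, 1], 0.05, tolerance = 1e-12)
  # Gaussian jitter converges to sigma
  with_seed(22, {
    arr2 <- array(rep(base, each = 2000), dim = c(2000, 4, 3))
    arr2 <- arr2 + array(rnorm(2000 * 12, sd = 0.02), dim = c(2000, 4, 3))
    r2 <- rmsf(cartesian_ensemble(arr2))
    expect_equal(mean(r2), 0.02, tolerance = 0.02)
  })
})

test_that("oscillator entropy: alpha = 1 value, limits, monotonicity", {
  masses <- 12.011
  T <- 300
  m_kg <- masses / 1000 / 6.02214076e23
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  # choose RMSF so that alpha = 1 exactly
  x1 <- hbar / sqrt(m_kg * kB * T) * 1e9  # nm
  s1 <- qh_entropy_diagonal(matrix(c(x1, 0, 0), 1), masses, T)
  expect_equal(s1, R_GAS * (1 / (exp(1) - 1) - log(1 - exp(-1))),
               tolerance = 1e-12)
  expect_equal(s1, 8.6525, tolerance = 1e-4)
  # zero RMSF contributes nothing
  expect_equal(qh_entropy_diagonal(matrix(0, 2, 3), c(1, 1), T), 0)
  # classical limit: alpha << 1 -> R (1 - ln alpha) within 1%
  for (alpha in c(1e-3, 1e-4)) {
    x <- x1 / alpha
    s <- qh_entropy_diagonal(matrix(c(x, 0, 0), 1), masses, T)
    expect_equal(s, R_GAS * (1 - log(alpha)), tolerance = 0.01)
  }
  # strict monotonicity in each RMSF entry
  r0 <- matrix(abs(with_seed(2, rnorm(6, 0.05, 0.01))), 2, 3)
  s0 <- qh_entropy_diagonal(r0, c(12, 14), T)
  for (i in seq_len(6)) {
    r1 <- r0; r1[i] <- r1[i] * 1.1
    expect_gt(qh_entropy_diagonal(r1, c(12, 14), T), s0)
  }
  expect_error(qh_entropy_diagonal(matrix(-1, 1, 3), 1, T), "non-negative")
})

test_that("full-covariance QH never exceeds the diagonal value", {
  T <- 300
  with_seed(33, {
    for (rep in 1:10) {
      n <- sample(3:6, 1)
      f <- 400
      masses <- runif(n, 1, 20)
      base <- matrix(rnorm(n * 3, sd = 0.3), ncol = 3)
      arr <- array(rep(base, each = f), dim = c(f, n, 3)) +
        array(rnorm(f * n * 3, sd = 0.03), dim = c(f, n, 3))
      ens <- cartesian_ensemble(arr)
      s_diag <- qh_entropy_diagonal(rmsf(ens), masses, T)
      s_full <- qh_entropy_full(ens, masses, T)
      expect_lte(s_full, s_diag + 1e-9)
    }
    # perfectly correlated coordinate pair: full treatment loses a mode
    f <- 500
    arr <- array(0.0, dim = c(f, 3, 3))
    base <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(0, 0.25, 0.1))
    arr <- array(rep(base, each = f), dim = c(f, 3, 3))
    z <- rnorm(f, sd = 0.02)
    arr[, 1, 1] <- arr[, 1, 1] + z
    arr[, 2, 1] <- arr[, 2, 1] + z   # exact copy of atom 1's x motion
    arr[, 3, 2] <- arr[, 3, 2] + rnorm(f, sd = 0.02)
    ens <- cartesian_ensemble(arr)
    expect_lt(qh_entropy_full(ens, rep(12, 3), T),
              qh_entropy_diagonal(rmsf(ens), rep(12, 3), T) - 1)
    # analytic check: isotropic 1-atom Gaussian, full == diagonal as f grows
    f2 <- 20000
    arr1 <- array(rnorm(f2 * 3, sd = 0.05), dim = c(f2, 1, 3))
    ens1 <- cartesian_ensemble(arr1)
    expect_equal(qh_entropy_full(ens1, 12, T),
                 qh_entropy_diagonal(rmsf(ens1), 12, T), tolerance = 0.002)
  })
})

test_that("B-factor conversions: scalar value, zero case, variance conservation", {
  # <dr^2> = 0.3 A^2 -> B = 8 pi^2 * 0.1
  r_nm <- sqrt(0.3 / 3) / 10  # isotropic per-coordinate RMSF in nm
  B <- bfactor_from_rmsf(matrix(r_nm, 1, 3))
  expect_equal(B, 8 * pi^2 * 0.1, tolerance = 1e-12)
  expect_equal(B, 7.8957, tolerance = 1e-4)
  expect_equal(rmsf_from_bfactor(0), matrix(0, 1, 3))
  # anisotropic round trip: isotropic redistribution, exact total
  r_aniso <- matrix(c(0.07, 0, 0), 1, 3)
  rt <- rmsf_from_bfactor(bfactor_from_rmsf(r_aniso))
  expect_equal(rowSums(rt^2), rowSums(r_aniso^2), tolerance = 1e-12)
  expect_equal(unname(rt[1, ]), rep(0.07 / sqrt(3), 3), tolerance = 1e-12)
  expect_error(rmsf_from_bfactor(-1), "non-negative")
})

test_that("order parameters stay in [0,1] for random unit-vector inputs", {
  with_seed(44, {
    for (rep in 1:20) {
      f <- sample(5:50, 1)
      v <- matrix(rnorm(f * 3), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      o <- order_parameter(v)
      expect_gte(o, -1e-9)
      expect_lte(o, 1 + 1e-9)
    }
  })
})
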