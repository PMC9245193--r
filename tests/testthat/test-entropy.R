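test_that("1D histogram entropy recovers analytic differential entropies", {
  with_seed(21, {
    u <- runif(1e6, -pi, pi)
    expect_equal(histogram_entropy_1d(u, "torsion", 50),
                 R_GAS * log(2 * pi), tolerance = 0.01 / 15)
    g <- rnorm(1e6, 0, 0.1)
    # tolerance frozen from a 10-replicate oracle run: bias +0.013, sd 0.006
    expect_equal(histogram_entropy_1d(g, "torsion", 50),
                 R_GAS * 0.5 * log(2 * pi * exp(1) * 0.01^2 * 1e2),
                 tolerance = 0.05 / 7.35)
  })
})

test_that("fine-graining a resolved piecewise-constant density leaves entropy unchanged", {
  # two-level density on [0,1): 3/2 on the first half, 1/2 on the second,
  # sampled exactly by inverse transform on a fine deterministic grid
  u <- (seq_len(4e4) - 0.5) / 4e4
  x <- ifelse(u < 0.75, u / 1.5, 0.5 + (u - 0.75) * 2)
  # force the sample range to span [0,1) so bins align with the density steps
  x[1] <- 0; x[length(x)] <- 1
  s10 <- histogram_entropy_1d(x, "torsion", 10)
  s20 <- histogram_entropy_1d(x, "torsion", 20)
  s40 <- histogram_entropy_1d(x, "torsion", 40)
  expect_lt(abs(s20 - s10) / abs(s10), 1e-6)
  expect_lt(abs(s40 - s20) / abs(s20), 1e-6)
})

test_that("Jacobian corrections enter as R<ln J> for bonds and angles", {
  with_seed(8, {
    b <- rnorm(5e4, 0.15, 0.001)
    expect_equal(histogram_entropy_1d(b, "bond", 50) -
                   histogram_entropy_1d(b, "torsion", 50),
                 2 * R_GAS * mean(log(b)), tolerance = 1e-12)
    a <- rnorm(5e4, 1.9, 0.05)
    expect_equal(histogram_entropy_1d(a, "angle", 50) -
                   histogram_entropy_1d(a, "torsion", 50),
                 R_GAS * mean(log(sin(a))), tolerance = 1e-12)
  })
})

test_that("degenerate samples yield the single-bin value with a warning", {
  expect_warning(s <- histogram_entropy_1d(rep(0.1, 100), "torsion", 50),
                 "degenerate")
  expect_equal(s, R_GAS * log(1e-9))
  expect_error(histogram_entropy_1d(c(1, NA, 2), "torsion"), "non-finite")
})

test_that("2D mutual information matches closed forms and nulls", {
  with_seed(31, {
    # perfect dependence: MI equals the discrete entropy of the binned variable
    x <- rnorm(2e4)
    mi_xx <- histogram_mi_2d(x, x, 50)
    idx <- pmin(floor((x - min(x)) / ((max(x) - min(x)) / 50)) + 1L, 50L)
    p <- tabulate(idx, 50) / length(x)
    expect_equal(mi_xx, -R_GAS * sum(p[p > 0] * log(p[p > 0])),
                 tolerance = 1e-12)
    # bivariate Gaussian rho = 0.8; tolerance frozen from a 10-replicate
    # oracle (bias -0.04, sd 0.006)
    z1 <- rnorm(1e6); z2 <- 0.8 * z1 + 0.6 * rnorm(1e6)
    expect_equal(histogram_mi_2d(z1, z2, 50),
                 -0.5 * R_GAS * log(1 - 0.8^2), tolerance = 0.08 / 4.25)
    # independent samples: MI below 3 permutation-null quantiles
    a <- rnorm(5e3); bnd <- rnorm(5e3)
    mi_obs <- histogram_mi_2d(a, bnd, 20)
    null <- replicate(200, histogram_mi_2d(a, sample(bnd), 20))
    expect_lt(mi_obs, mean(null) + 3 * sd(null))
  })
})

test_that("pairwise terms have the right shape and flag duplicated columns", {
  spec <- ensemble_spec(rep("gauss", 3), rep(0, 3), rep(1, 3))
  s <- sample_spec_ensemble(spec, rep("torsion", 3), 2000, seed = 2)
  terms <- pairwise_entropy_terms(s$bat, 30)
  expect_length(terms$s1, 3)
  expect_equal(sum(!is.na(terms$mi[upper.tri(terms$mi)])), 3)
  # duplicated column has maximal MI among all pairs
  bat <- s$bat
  bat$values[, 3] <- bat$values[, 1]
  t2 <- pairwise_entropy_terms(bat, 30)
  expect_equal(max(t2$mi[upper.tri(t2$mi)]), t2$mi[1, 3])
  expect_gt(t2$mi[1, 3], max(t2$mi[1, 2], t2$mi[2, 3]))
})

test_that("MIST worked example: tree selection and totals by enumeration", {
  s1 <- c(10, 20, 30)
  mi <- matrix(0, 3, 3)
  mi[1, 2] <- mi[2, 1] <- 2
  mi[1, 3] <- mi[3, 1] <- 1
  mi[2, 3] <- mi[3, 2] <- 3
  terms <- entropy_terms(s1, mi)
  m <- mist_entropy(terms)
  # all three spanning trees: {12,13}=3, {12,23}=5, {13,23}=4 -> max is 5
  expect_equal(m$s_mist, 60 - 5)
  edges <- m$tree_edges[order(m$tree_edges[, "mi"], decreasing = TRUE), ]
  expect_equal(unname(edges[1, c("i", "j")]), c(2, 3))
  expect_equal(unname(edges[2, c("i", "j")]), c(1, 2))
  expect_equal(mie2_entropy(terms), 60 - 6)
  # zero MI: MIST collapses to the 1D sum
  t0 <- entropy_terms(s1, matrix(0, 3, 3))
  expect_equal(mist_entropy(t0)$s_mist, 60)
  expect_equal(mie2_entropy(t0), 60)
})

test_that("MIST upper-bounds exact entropy on enumerated joints; pairwise MIE does not", {
  for (s in 1:50) {
    nv <- with_seed(1000 + s, sample(3:6, 1))
    ns <- with_seed(2000 + s, sample(2:4, 1))
    j <- brute_force_discrete_joint(nv, ns, seed = s)
    m <- mist_entropy(j$terms)
    expect_gte(m$s_mist, j$s_exact - 1e-9)
    expect_lte(m$s_mist, m$s_1d + 1e-9)
    expect_lte(mie2_entropy(j$terms), m$s_mist + 1e-9)
  }
  # pairwise MIE can undershoot the exact entropy: three near-copies of one
  # variable (each pair carries almost the full marginal information, so the
  # all-pairs sum overcorrects)
  q <- c(0.5, 0.3, 0.2)
  p <- array(1e-4, dim = c(3, 3, 3))
  for (i in 1:3) p[i, i, i] <- p[i, i, i] + q[i]
  p <- p / sum(p)
  ent <- function(z) { z <- z[z > 0]; -R_GAS * sum(z * log(z)) }
  s_exact <- ent(p)
  s1 <- vapply(1:3, function(i) ent(apply(p, i, sum)), numeric(1))
  mi <- matrix(NA_real_, 3, 3)
  for (i in 1:2) for (jj in (i + 1):3) {
    mi[i, jj] <- mi[jj, i] <- s1[i] + s1[jj] - ent(apply(p, c(i, jj), sum))
  }
  terms <- entropy_terms(s1, mi)
  expect_lt(mie2_entropy(terms), s_exact)
  expect_gte(mist_entropy(terms)$s_mist, s_exact - 1e-9)
})

test_that("estimated MIST converges to the analytic total on a copula chain", {
  # 10-DOF torsion chain, rho = 0.6; tolerance follows the same bias oracle
  # as the acceptance chain (relative error well under 1%)
  spec <- ensemble_spec(rep("wrapped_gauss", 10), rep(0, 10), rep(0.1, 10),
                        edges = data.frame(i = 1:9, j = 2:10, rho = 0.6))
  s <- sample_spec_ensemble(spec, rep("torsion", 10), 5e4, seed = 3)
  m <- mist_entropy(pairwise_entropy_terms(s$bat, 50))
  expect_equal(m$s_mist, s$truth$total, tolerance = 0.01)
  expect_lte(m$s_mist, m$s_1d)
})

test_that("entropy terms are invariant under DOF permutation", {
  spec <- ensemble_spec(rep("wrapped_gauss", 5), rep(0, 5), c(0.1, 0.2, 0.3, 0.15, 0.25),
                        edges = data.frame(i = c(1, 2), j = c(2, 4), rho = c(0.5, -0.4)))
  s <- sample_spec_ensemble(spec, rep("torsion", 5), 5000, seed = 12)
  terms <- pairwise_entropy_terms(s$bat, 40)
  m <- mist_entropy(terms)
  perm <- c(4, 2, 5, 1, 3)
  bat_p <- s$bat
  bat_p$values <- bat_p$values[, perm]
  bat_p$dof_classes <- bat_p$dof_classes[perm]
  terms_p <- pairwise_entropy_terms(bat_p, 40)
  expect_equal(sort(terms_p$s1), sort(terms$s1))
  expect_equal(mist_entropy(terms_p)$s_mist, m$s_mist, tolerance = 1e-12)
  expect_equal(mie2_entropy(terms_p), mie2_entropy(terms), tolerance = 1e-12)
})

test_that("subset entropies: identity, singleton, additivity and coupling", {
  spec <- ensemble_spec(rep("wrapped_gauss", 6), rep(0, 6), rep(0.2, 6),
                        edges = data.frame(i = c(1, 4), j = c(2, 5),
                                           rho = c(0.7, 0.7)))
  s <- sample_spec_ensemble(spec, rep("torsion", 6), 3e4, seed = 6)
  terms <- pairwise_entropy_terms(s$bat, 50)
  full <- mist_entropy(terms)
  expect_equal(subset_entropy(s$bat, 1:6, 50)$s_mist, full$s_mist)
  expect_equal(subset_entropy(s$bat, 3, 50)$s_mist, terms$s1[3])
  # independent halves are additive within sampling tolerance
  sa <- mist_entropy(terms, subset = 1:3)$s_mist
  sb <- mist_entropy(terms, subset = 4:6)$s_mist
  expect_equal(sa + sb, full$s_mist, tolerance = 0.02)
  expect_equal(coupling_between(s$bat, 1:3, 4:6, 50, terms = terms),
               sa + sb - full$s_mist)
  # a correlated pair split across subsets: coupling ~ Gaussian MI
  expect_equal(coupling_between(s$bat, c(1, 3), c(2, 6), 50, terms = terms),
               -0.5 * R_GAS * log(1 - 0.7^2), tolerance = 0.25)
  expect_error(coupling_between(s$bat, 1:3, 3:5), "disjoint")
  expect_error(mist_entropy(terms, subset = integer(0)), "empty")
})

test_that("perfect subset duplication makes coupling equal the subset entropy", {
  # effectively discrete samples (integer levels + within-bin jitter, so the
  # bin width is ~1 and the histogram entropy is the discrete entropy, the
  # regime where S(A) + S(B) - S(A u B) = S(A) holds exactly for B == A)
  vals <- with_seed(7, cbind(sample(0:9, 1e4, TRUE) + runif(1e4),
                             sample(0:9, 1e4, TRUE) + runif(1e4)))
  bat <- structure(list(values = cbind(vals, vals),
                        dof_classes = rep("torsion", 4),
                        chain_classes = rep(NA_character_, 4),
                        n_frames = 1e4L, n_dof = 4L, temperature = 300),
                   class = "bat_ensemble")
  terms <- pairwise_entropy_terms(bat, 10)
  sa <- mist_entropy(terms, subset = 1:2)$s_mist
  expect_equal(coupling_between(bat, 1:2, 3:4, 10, terms = terms), sa,
               tolerance = 0.01)
})

test_that("3-bin coarse graining isolates rotamer-level entropy", {
  # three equally populated well-separated rotamers: each well falls into
  # one coarse bin, so the discrete part of the 3-bin entropy is the
  # analytic 3-state value R ln 3
  spec3 <- ensemble_spec("rotamer", 0, 0.15, k = 3L)
  s3 <- sample_spec_ensemble(spec3, "torsion", 5e4, seed = 9)
  v3 <- vibration_suppressed_entropy(s3$bat)
  dx3 <- diff(range(s3$bat$values)) / 3
  expect_equal(v3$s_mist - R_GAS * log(dx3), R_GAS * log(3),
               tolerance = 0.01)
  # consistency with the generic estimator at n_bins = 3
  expect_equal(v3$s_mist,
               mist_entropy(pairwise_entropy_terms(s3$bat, 3))$s_mist)
  # vibration suppression: narrowing the within-well width (a vibrational
  # change) moves the 50-bin entropy by the full R ln 2 but barely moves
  # the 3-bin entropy, whose range is pinned by the rotamer wells
  spec3n <- ensemble_spec("rotamer", 0, 0.075, k = 3L)
  s3n <- sample_spec_ensemble(spec3n, "torsion", 5e4, seed = 9)
  d3 <- vibration_suppressed_entropy(s3$bat)$s_mist -
    vibration_suppressed_entropy(s3n$bat)$s_mist
  d50 <- mist_entropy(pairwise_entropy_terms(s3$bat, 50))$s_mist -
    mist_entropy(pairwise_entropy_terms(s3n$bat, 50))$s_mist
  expect_equal(d50, R_GAS * log(2), tolerance = 0.15)
  expect_lt(abs(d3), 0.3 * abs(d50))
})

test_that("triplet mutual information identity holds on enumerated joints", {
  for (s in 1:20) {
    j <- brute_force_discrete_joint(3, 3, seed = 300 + s)
    s123 <- discrete_subset_entropy(j, 1:3)
    s12 <- discrete_subset_entropy(j, c(1, 2))
    s13 <- discrete_subset_entropy(j, c(1, 3))
    s23 <- discrete_subset_entropy(j, c(2, 3))
    i_triplet <- sum(j$s1) - s12 - s13 - s23 + s123
    i_1_23 <- j$s1[1] + s23 - s123
    expect_equal(i_triplet, j$mi[1, 2] + j$mi[1, 3] - i_1_23,
                 tolerance = 1e-12)
  }
})
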