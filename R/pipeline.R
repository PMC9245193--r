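#' Evaluate entropy and dynamics proxies for one ensemble
#'
#' Runs the full single-ensemble pipeline: all-atom superposition, BAT
#' conversion, pairwise entropy terms, MIST total, order-parameter sets and
#' quasi-harmonic quantities.
#'
#' @param system a [molecular_system()].
#' @param ens a [cartesian_ensemble()] of the system.
#' @param tree optionally a prebuilt [bat_tree][build_bat_tree()].
#' @param n_bins bins for the entropy estimator (default 50).
#' @param keep_terms retain the full `entropy_terms` object (needed for
#'   decompositions; default FALSE to save memory).
#' @param coarse_bins if not `NULL`, also compute the vibration-suppressed
#'   MIST total with this many bins.
#'
#' @return A list with `mist`, `s_1d`, `proxies`, `bat` metadata, and
#'   optionally `terms`, `mist_coarse`.
#' @export
evaluate_ensemble <- function(system, ens, tree = NULL, n_bins = 50,
                              keep_terms = FALSE, coarse_bins = NULL) {
  if (is.null(tree)) tree <- build_bat_tree(system)
  sup <- superpose_ensemble(ens)
  bat <- cartesian_to_bat(sup, tree, system)
  terms <- pairwise_entropy_terms(bat, n_bins = n_bins)
  mist <- mist_entropy(terms)
  out <- list(
    mist = mist,
    s_1d = mist$s_1d,
    proxies = proxy_result(ens, system),
    n_dof = tree$n_dof,
    n_atoms = system$n_atoms,
    dof_classes = bat$dof_classes,
    chain_classes = bat$chain_classes
  )
  if (!is.null(coarse_bins)) {
    out$terms_coarse <- pairwise_entropy_terms(bat, n_bins = coarse_bins)
    out$mist_coarse <- mist_entropy(out$terms_coarse)
  }
  if (keep_terms) out$terms <- terms
  out
}

#' Assemble a binding process from free and bound ensembles
#'
#' A binding process is the transition of one molecule from its free state
#' to its state within a complex; all difference quantities are
#' bound minus free, evaluated for that molecule alone (the bound-state
#' ensemble contains only the constituent's atoms, superposed on itself).
#'
#' @param system the constituent's [molecular_system()].
#' @param free_ens,bound_ens [cartesian_ensemble()]s of the constituent in
#'   the free state and within the complex.
#' @param protein_id identifier string.
#' @param n_bins estimator bins (default 50).
#' @param coarse_bins bins for the vibration-suppressed totals, or `NULL`
#'   to skip.
#' @param keep_terms retain full pairwise terms for decompositions.
#'
#' @return An object of class `binding_process`.
#' @export
binding_process <- function(system, free_ens, bound_ens, protein_id = "protein",
                            n_bins = 50, coarse_bins = NULL,
                            keep_terms = FALSE) {
  if (free_ens$n_atoms != system$n_atoms || bound_ens$n_atoms != system$n_atoms) {
    stop("free/bound atom inventories do not match the system")
  }
  tree <- build_bat_tree(system)
  structure(list(
    protein_id = protein_id,
    system = system,
    n_atoms = system$n_atoms,
    n_dof = tree$n_dof,
    temperature = free_ens$temperature,
    free = evaluate_ensemble(system, free_ens, tree, n_bins,
                             keep_terms, coarse_bins),
    bound = evaluate_ensemble(system, bound_ens, tree, n_bins,
                              keep_terms, coarse_bins)
  ), class = "binding_process")
}

#' @export
print.binding_process <- function(x, ...) {
  cat("<binding_process> ", x$protein_id, ": ", x$n_atoms, " atoms, dS_MIST = ",
      format(x$bound$mist$s_mist - x$free$mist$s_mist, digits = 5),
      " J K^-1 mol^-1\n", sep = "")
  invisible(x)
}

#' Bound-minus-free differences for one binding process
#'
#' @param proc a [binding_process()].
#' @return A one-row data frame: `ds_mist`, `ds_1d`, `d_o2_ch3`, `d_o2_nh`,
#'   `ds_bfact`, `ds_qh_full`, the per-DOF normalized variants
#'   (`*_per_dof`, divided by 3N-6), and bookkeeping columns.
#' @export
binding_delta <- function(proc) {
  stopifnot(inherits(proc, "binding_process"))
  fr <- proc$free; bo <- proc$bound
  if (fr$n_dof != bo$n_dof ||
      length(fr$proxies$methyl$o2) != length(bo$proxies$methyl$o2) ||
      length(fr$proxies$nh$o2) != length(bo$proxies$nh$o2)) {
    stop("free and bound inventories do not match")
  }
  nd <- proc$n_dof
  ds_mist <- bo$mist$s_mist - fr$mist$s_mist
  ds_1d <- bo$s_1d - fr$s_1d
  ds_bfact <- bo$proxies$s_bfact - fr$proxies$s_bfact
  ds_coarse <- if (!is.null(fr$mist_coarse)) {
    bo$mist_coarse$s_mist - fr$mist_coarse$s_mist
  } else NA_real_
  data.frame(
    protein_id = proc$protein_id,
    n_atoms = proc$n_atoms,
    n_dof = nd,
    ds_mist = ds_mist,
    ds_1d = ds_1d,
    d_o2_ch3 = bo$proxies$methyl$mean - fr$proxies$methyl$mean,
    d_o2_nh = bo$proxies$nh$mean - fr$proxies$nh$mean,
    ds_bfact = ds_bfact,
    ds_qh_full = bo$proxies$s_qh_full - fr$proxies$s_qh_full,
    ds_mist_3bin = ds_coarse,
    ds_mist_per_dof = ds_mist / nd,
    ds_1d_per_dof = ds_1d / nd,
    ds_bfact_per_dof = ds_bfact / nd,
    stringsAsFactors = FALSE
  )
}

proxy_column <- function(proxy = c("methyl", "nh", "bfactor")) {
  switch(match.arg(proxy),
         methyl = "d_o2_ch3", nh = "d_o2_nh", bfactor = "ds_bfact_per_dof")
}

#' Least-squares relation between per-DOF entropy change and a proxy
#'
#' Ordinary least squares of the per-DOF MIST entropy change on the proxy
#' change across binding processes, with the Pearson correlation
#' coefficient.
#'
#' @param deltas data frame of per-process differences ([binding_delta()]
#'   rows bound together).
#' @param proxy `"methyl"`, `"nh"`, or `"bfactor"`.
#' @param response column name of the response (default
#'   `"ds_mist_per_dof"`).
#'
#' @return A list of class `regression_report`: `slope`, `intercept`,
#'   `pearson_r`, `slope_se`, `residuals`, `rms_error`, `n`,
#'   `underdetermined`.
#' @export
fit_proxy_relation <- function(deltas, proxy = c("methyl", "nh", "bfactor"),
                               response = "ds_mist_per_dof") {
  x <- deltas[[proxy_column(proxy)]]
  y <- deltas[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 processes to fit")
  if (stats::var(x) == 0) stop("degenerate fit: predictor has zero variance")
  underdetermined <- n < 3
  if (underdetermined) warning("fit on fewer than 3 processes is underdetermined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # summary.lm warns on numerically perfect fits; the SE is still valid
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["x", "Std. Error"]),
    error = function(e) NA_real_)
  res <- stats::residuals(fit)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    pearson_r = stats::cor(x, y), slope_se = se,
    residuals = res, rms_error = sqrt(mean(res^2)),
    n = n, underdetermined = underdetermined
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report> slope = ", format(x$slope, digits = 4),
      " (se ", format(x$slope_se, digits = 3), "), intercept = ",
      format(x$intercept, digits = 4), ", Pearson r = ",
      format(x$pearson_r, digits = 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Absolute entropy change estimated from a proxy via a fitted relation
#'
#' Rescales the intensive fitted relation to an extensive entropy change:
#' `dS_est = (slope * d_proxy + intercept) * (3 N - 6)`.
#'
#' @param d_proxy proxy change value(s).
#' @param fit a `regression_report` from [fit_proxy_relation()].
#' @param n_atoms atom count(s) of the process(es).
#'
#' @return Estimated entropy change(s), J K^-1 mol^-1.
#' @export
estimate_entropy_from_proxy <- function(d_proxy, fit, n_atoms) {
  (fit$slope * d_proxy + fit$intercept) * (3 * n_atoms - 6)
}

#' Error and coupling analysis of proxy-based entropy estimates
#'
#' For each process computes the absolute error `|dS_est - dS_MIST|`, the
#' fractional error `|dS_est - dS_MIST| / |dS_MIST|`, and the fractional
#' coupling `|dS_MIST - dS_1D| / |dS_1D|`; reports the root-mean-square
#' absolute error (also as T*dS in kJ/mol) and medians/quartiles of the
#' fractional quantities.  Entries with vanishing denominators are reported
#' as `NA`, counted, and excluded from the summaries.
#'
#' @param deltas per-process difference table.
#' @param fit fitted `regression_report` for the chosen proxy.
#' @param proxy which proxy the fit used.
#' @param temperature temperature for the kJ/mol conversion (default 300).
#' @param denom_tol denominators with absolute value below this are treated
#'   as vanishing (default 1e-12).
#'
#' @return A list: `per_process` data frame, `rms_error`,
#'   `rms_error_kj_mol`, `median_frac_error`, `median_frac_coupling`,
#'   `quartiles_frac_error`, `quartiles_frac_coupling`, `n_undefined`.
#' @export
error_analysis <- function(deltas, fit, proxy = c("methyl", "nh", "bfactor"),
                           temperature = 300, denom_tol = 1e-12) {
  proxy <- match.arg(proxy)
  x <- deltas[[proxy_column(proxy)]]
  ds_est <- estimate_entropy_from_proxy(x, fit, deltas$n_atoms)
  abs_err <- abs(ds_est - deltas$ds_mist)
  frac_err <- ifelse(abs(deltas$ds_mist) > denom_tol,
                     abs_err / abs(deltas$ds_mist), NA_real_)
  frac_coup <- ifelse(abs(deltas$ds_1d) > denom_tol,
                      abs(deltas$ds_mist - deltas$ds_1d) / abs(deltas$ds_1d),
                      NA_real_)
  per <- data.frame(
    protein_id = deltas$protein_id,
    ds_est = ds_est, abs_error = abs_err,
    frac_error = frac_err, frac_coupling = frac_coup,
    stringsAsFactors = FALSE
  )
  list(
    per_process = per,
    rms_error = sqrt(mean(abs_err^2)),
    rms_error_kj_mol = sqrt(mean((temperature * abs_err / 1000)^2)),
    median_frac_error = stats::median(frac_err, na.rm = TRUE),
    median_frac_coupling = stats::median(frac_coup, na.rm = TRUE),
    quartiles_frac_error = stats::quantile(frac_err, c(0.25, 0.75),
                                           na.rm = TRUE, names = FALSE),
    quartiles_frac_coupling = stats::quantile(frac_coup, c(0.25, 0.75),
                                              na.rm = TRUE, names = FALSE),
    n_undefined = sum(is.na(frac_err)) + sum(is.na(frac_coup))
  )
}

#' Free energy contribution of an entropy change
#'
#' `|T * dS| / 1000` in kJ/mol: the magnitude of the entropic contribution
#' to the binding free energy at temperature T.
#'
#' @param ds entropy change, J K^-1 mol^-1.
#' @param temperature temperature in K.
#' @return Magnitude in kJ/mol.
#' @export
tds_contribution <- function(ds, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  abs(temperature * ds) / 1000
}

#' Robustness of the proxy correlation under reporter undersampling
#'
#' Repeatedly selects a random subset (a fraction of the reporters, drawn
#' without replacement with round-half-up and a per-molecule floor of one)
#' of each process's experimental reporters -- order-parameter probes for
#' the methyl/NH proxies, atoms for the B-factor proxy -- recomputes the
#' proxy change from the subset only, and correlates it across processes
#' against the full-inventory per-DOF MIST entropy change.  Subsets are
#' drawn from per-(repetition, molecule) substreams so that runs are
#' reproducible and subsets are nested across fractions.
#'
#' @param processes list of [binding_process()] objects.
#' @param proxy `"methyl"`, `"nh"`, or `"bfactor"`.
#' @param fraction fraction of reporters retained, in (0, 1].
#' @param n_reps number of repetitions.
#' @param seed RNG seed.
#'
#' @return A list of class `undersampling_report`: `fraction`, `n_reps`,
#'   `r_values`, `slope_values`, `median_abs_r`, `full_r`.
#' @export
undersample_reporters <- function(processes, proxy = c("methyl", "nh", "bfactor"),
                                  fraction, n_reps = 1000, seed = 1) {
  proxy <- match.arg(proxy)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  n_proc <- length(processes)
  y <- vapply(processes, function(p) {
    (p$bound$mist$s_mist - p$free$mist$s_mist) / p$n_dof
  }, numeric(1))
  # per-process reporter-wise difference values
  reporter_deltas <- lapply(processes, function(p) {
    if (proxy == "bfactor") {
      # per-atom difference of summed per-coordinate oscillator entropies,
      # averaged per retained coordinate
      d_atom <- rowSums(p$bound$proxies$qh_per_coord) -
        rowSums(p$free$proxies$qh_per_coord)
      list(values = d_atom, scale = 3)  # 3 coordinates per atom
    } else {
      list(values = p$bound$proxies[[proxy]]$o2 - p$free$proxies[[proxy]]$o2,
           scale = 1)
    }
  })
  k_all <- vapply(reporter_deltas, function(r) length(r$values), integer(1))
  if (any(k_all == 0)) stop("a process has no reporters of this kind")
  sizes <- pmax(1L, as.integer(floor(fraction * k_all + 0.5)))
  if (any(fraction * k_all < 1)) {
    warning("fraction yields < 1 reporter for some molecule(s); floor of 1 enforced")
  }
  sub_seeds <- with_seed(seed,
                         matrix(sample.int(2^31 - 1, n_reps * n_proc),
                                nrow = n_reps))
  r_values <- numeric(n_reps)
  slope_values <- numeric(n_reps)
  for (rep_i in seq_len(n_reps)) {
    x <- numeric(n_proc)
    for (pi in seq_len(n_proc)) {
      rd <- reporter_deltas[[pi]]
      pick <- with_seed(sub_seeds[rep_i, pi],
                        sample.int(k_all[pi], sizes[pi]))
      x[pi] <- mean(rd$values[pick]) / rd$scale
    }
    r_values[rep_i] <- stats::cor(x, y)
    slope_values[rep_i] <- stats::cov(x, y) / stats::var(x)
  }
  x_full <- vapply(seq_len(n_proc), function(pi) {
    rd <- reporter_deltas[[pi]]
    mean(rd$values) / rd$scale
  }, numeric(1))
  structure(list(
    proxy = proxy, fraction = fraction, n_reps = n_reps,
    r_values = r_values, slope_values = slope_values,
    median_abs_r = stats::median(abs(r_values)),
    full_r = stats::cor(x_full, y)
  ), class = "undersampling_report")
}

#' @export
print.undersampling_report <- function(x, ...) {
  cat("<undersampling_report> ", x$proxy, " fraction = ", x$fraction,
      ", reps = ", x$n_reps, ", median |r| = ",
      format(x$median_abs_r, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Decomposition of the entropy change into contribution classes
#'
#' For each process, splits the MIST entropy change into torsional and
#' angular subset contributions with their mutual coupling, main-chain and
#' side-chain contributions with their coupling, the uncoupled (1D) change
#' and the 3-bin vibration-suppressed change, all per degree of freedom,
#' and fits each contribution linearly against the total per-DOF MIST
#' change.  The slope measures the average share of the total carried by
#' that contribution; for an exhaustive additive partition (main-chain +
#' side-chain - coupling) the slopes sum to 1 by linearity of least
#' squares.
#'
#' Requires processes built with `keep_terms = TRUE` and `coarse_bins`.
#'
#' @param processes list of [binding_process()] objects.
#'
#' @return A list with `per_process` (data frame of per-DOF-normalized
#'   contribution changes) and `table` (slope and Pearson r per
#'   contribution).
#' @export
decomposition_table <- function(processes) {
  rows <- lapply(processes, function(p) {
    if (is.null(p$free$terms)) {
      stop("decomposition needs binding_process(..., keep_terms = TRUE)")
    }
    contribs_one <- function(ev) {
      kinds <- ev$dof_classes
      chain <- ev$chain_classes
      tor <- which(kinds == "torsion")
      ang <- which(kinds == "angle")
      mc <- which(chain == "main-chain")
      sc <- which(chain == "side-chain")
      s <- function(sub) mist_entropy(ev$terms, subset = sub)$s_mist
      s_tor <- s(tor); s_ang <- s(ang)
      s_angtor <- s(c(ang, tor))
      s_mc <- s(mc); s_sc <- s(sc)
      c(tor = s_tor, ang = s_ang,
        coup_angtor = s_ang + s_tor - s_angtor,
        mc = s_mc, sc = s_sc,
        coup_mcsc = s_mc + s_sc - ev$mist$s_mist,
        s1d = ev$s_1d,
        bin3 = if (!is.null(ev$mist_coarse)) ev$mist_coarse$s_mist else NA_real_,
        total = ev$mist$s_mist)
    }
    d <- (contribs_one(p$bound) - contribs_one(p$free)) / p$n_dof
    as.data.frame(as.list(d))
  })
  per <- do.call(rbind, rows)
  per$protein_id <- vapply(processes, function(p) p$protein_id, character(1))
  contribs <- setdiff(names(per), c("total", "protein_id"))
  tab <- do.call(rbind, lapply(contribs, function(cn) {
    fit <- stats::lm(per[[cn]] ~ per$total)
    data.frame(contribution = cn,
               slope = unname(stats::coef(fit)[2]),
               pearson_r = stats::cor(per[[cn]], per$total),
               stringsAsFactors = FALSE)
  }))
  list(per_process = per, table = tab)
}
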