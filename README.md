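# mistent

Configurational entropy of conformational ensembles, and how well the
experimentally accessible proxies of protein dynamics report on it.

## The problem

Protein–ligand and protein–protein binding typically rigidifies the
partners; the configurational entropy lost can contribute hundreds of
kJ/mol to the binding free energy at 300 K.  NMR spectroscopists estimate
this loss from changes in average methyl and backbone-NH Lipari–Szabo
order parameters, and crystallographers from B-factors — but none of these
observables sees intramolecular couplings, and the order parameters see
only a subset of the degrees of freedom.  `mistent` implements a
self-consistent framework in which a detailed configurational entropy and
all three proxies are computed from the *same* conformational ensembles,
so the fidelity of proxy-based entropy estimation can be measured
directly.

The entropy estimator is the **maximum information spanning tree (MIST)**
approximation in **bond–angle–torsion (BAT)** internal coordinates.  With
marginal entropies S(X_i) and pairwise mutual informations
I(X_i, X_j) = S(X_i) + S(X_j) − S(X_i, X_j) estimated from 50-bin
(50×50 in 2D) histograms with the BAT Jacobian,

    S_MIST = Σ_i S(X_i) − Σ_{(i,j) ∈ MST} I(X_i, X_j)

where the maximum spanning tree of the complete MI graph maximizes the
subtracted sum.  Truncated at pairwise order, S_MIST is a guaranteed upper
bound to the exact entropy (verified here against brute-force enumeration
of exact discrete joints).  Proxies: the direct tensor formula for O², the
quantum-harmonic-oscillator entropy of per-coordinate RMSF values
(α = ħ / (RMSF · √(M k_B T))) for the B-factor route, and a
full-covariance quasi-harmonic variant.

Because no trajectories are distributable, the package ships a
synthetic-ensemble generator with *analytically known* entropies (Gaussian
copula on a dependency forest; closed-form marginals), which both the test
suite and the analysis workflow run on.

## Worked example

Thirty toy binding processes are generated so that the exact per-DOF
entropy change follows ΔS/(3N−6) = −2.09 Δ⟨O²_CH3⟩ − 0.019 (J/K/mol) with
scatter 0.02, then everything is re-estimated from the raw Cartesian
ensembles:

```r
library(mistent)
study  <- make_binding_set(n_processes = 30, seed = 101)
procs  <- lapply(study, function(p)
  binding_process(p$system, p$free, p$bound, p$protein_id))
deltas <- do.call(rbind, lapply(procs, binding_delta))
fit_proxy_relation(deltas, "methyl")
#> <regression_report> slope = -1.963 (se 0.0516), intercept = -0.03853,
#>   Pearson r = -0.9905, n = 30
tds_contribution(-0.7 * (3 * 788 - 6), 300)   # extreme case, 788-atom protein
#> [1] 495.18
```

The recovered slope agrees with the design value −2.09 within its
uncertainty, and the correlation (|r| ≈ 0.99) shows that at these noise
levels the mean methyl order-parameter change is an excellent linear
reporter of the per-DOF entropy change.  The second number is the entropic
free-energy contribution T·|ΔS| for the most extreme per-DOF change (−0.7
J/K/mol) applied to a 788-atom protein — roughly 500 kJ/mol, which is why
proxy-based entropy estimation matters at all.

## Analysis workflow

The `analysis/` scripts run the full study and write tab-separated tables
under `results/`:

```sh
Rscript analysis/01_simulate.R        # generate the 30-process study
Rscript analysis/02_entropy_proxies.R # MIST entropies + all proxies
Rscript analysis/03_compare.R         # proxy fits, errors, decomposition
Rscript analysis/04_undersample.R     # reporter-undersampling robustness
```

On the default study this prints, e.g., estimated-vs-true per-DOF entropy
change r = 0.991 (median |error| 0.014 J/K/mol), a main-chain/side-chain
decomposition whose slopes sum to one (0.609 + 0.372 − (−0.019)), and
median |r| of the methyl correlation staying above 0.98 even when only 5%
of the methyl reporters are retained (1000 random subsets per fraction).

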