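---
title: "Configurational entropy from conformational ensembles and its experimental proxies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurational entropy from conformational ensembles and its experimental proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mistent)
```

## The problem

When a protein binds a partner it typically loses conformational freedom,
and the associated configurational entropy change $\Delta S$ can contribute
hundreds of kJ/mol to the binding free energy at room temperature.  Direct
experimental access to $\Delta S$ is impossible; what experiments deliver
are *proxies* of protein dynamics: NMR Lipari–Szabo order parameters of
methyl symmetry axes ($O^2_{\mathrm{CH_3}}$) and backbone N–H bonds
($O^2_{\mathrm{NH}}$), and crystallographic B-factors.  This package
implements a self-consistent computational framework in which both the
configurational entropy and all three proxies are evaluated from the same
conformational ensembles, so the quality of proxy-based entropy estimation
can be quantified without any experimental confound.

## Configurational entropy in internal coordinates

For a molecule in the absence of external fields, the spatial
(configurational) entropy separates from momentum and overall
roto-translational terms, and the part that survives in *differences* is
the entropy of the probability density over the $3N-6$ internal degrees of
freedom.  We use bond–angle–torsion (BAT) coordinates: $N-1$ bond lengths,
$N-2$ bond angles and $N-3$ torsions, built on a rooted tree over the
bonded topology (`build_bat_tree()`, `cartesian_to_bat()`).  BAT
coordinates decouple stiff from soft motions far better than Cartesians and
make the configuration-space Jacobian simple:
$J = \prod b^2 \prod \sin\theta$, with no torsion contribution.

The tree is rooted deterministically (lowest-indexed atom with two
neighbors, plus its two lowest-indexed neighbors); branches are visited in
ascending atom order, and each branch atom's torsion is defined against its
own reference atom rather than a phase-angle re-parameterization.  Ring
topologies are rejected explicitly: ring closure makes the BAT map
redundant, and no convention for cutting rings is imposed silently.

## The MIST estimator

The joint density over $3N-6$ coupled coordinates is unknowable from finite
sampling.  The mutual information expansion writes the exact entropy as

$$S = \sum_i S(X_i) \;-\; \sum_{i<j} I(X_i, X_j) \;+\; \text{higher order},$$

and the **maximum information spanning tree** (MIST) approximation keeps,
of the pairwise terms, only those on the spanning tree of the complete
mutual-information graph that maximizes the subtracted MI sum:

$$S_{\mathrm{MIST}} = \sum_i S(X_i) - \sum_{(i,j)\in\mathrm{MST}} I(X_i, X_j).$$

Truncated at pairwise order this is a *guaranteed upper bound* to the true
entropy — the central property the test suite verifies by brute-force
enumeration of exact discrete joints.  The pairwise-truncated expansion
over *all* pairs (`mie2_entropy()`) has no such guarantee and the suite
exhibits a case where it undershoots the exact value.

Marginal entropies and pairwise MIs are estimated by histograms: 50 bins in
1D, $50\times 50$ in 2D (3 and $3\times3$ for the vibration-suppressed
variant).  Design choices worth stating explicitly:

* **Bin edges** span the per-DOF sample range `[min, max]` with equal
  widths.  Whether fixed theoretical ranges (e.g. $[0, 2\pi)$ for torsions)
  would be preferable is genuinely open; sample ranges adapt to stiff DOFs
  whose fluctuations would otherwise be unresolved at 50 bins, and the
  difference cancels in free-minus-bound comparisons of like DOFs.  The
  consequence for the 3-bin coarse-grained entropy is discussed below.
* **Jacobian handling**: the correction enters as $+R\langle\ln J\rangle$
  added to the naive histogram entropy ($2R\langle\ln b\rangle$ for bonds,
  $R\langle\ln\sin\theta\rangle$ for angles), which is equivalent at
  histogram resolution to weighting the density and much easier to test; in
  difference quantities the Jacobian terms essentially cancel.
* **Negative MI estimates** (possible at floating-point level, since the
  plug-in discrete MI is mathematically non-negative) are clamped to zero
  for tree construction; values below $-10^{-6}R$ trigger a warning.
* **Degenerate DOFs** (all samples identical, e.g. constrained bonds) get
  the single-bin entropy with a bin width floored at $10^{-9}$ nm and zero
  MI to all partners; they cancel exactly in differences.
* **Ties** in the Kruskal edge sort are broken on ascending (i, j) pair
  order, so the tree is deterministic without any seed.
* **No finite-sample bias correction** is applied.  The estimator bias
  (which grows with bins-per-sample) is nearly identical between free and
  bound states of the same molecule and cancels in $\Delta S$; the
  tree-exactness test quantifies the residual absolute bias (about 0.4% of
  the total on a 20-DOF Gaussian chain at $10^5$ frames).
* **Higher-order couplings** are not computed; the triplet-MI identity is
  used only as a test on enumerated discrete toys.

Subset entropies (`subset_entropy()`) restrict the same machinery to a DOF
subset, and the coupling between two disjoint subsets is defined
operationally as
$S_{\mathrm{MIST}}(A) + S_{\mathrm{MIST}}(B) - S_{\mathrm{MIST}}(A\cup B)$
— the amount the joint tree gains from cross-subset edges.  Several
operational definitions of a subset coupling are conceivable; this
subset-difference form is the package's choice because by construction
main-chain + side-chain − coupling reproduces the total exactly, so the
decomposition slopes sum to one.

## Dynamics proxies

All proxies are computed after mass-unweighted least-squares (Kabsch)
superposition of every frame onto the first analyzed frame — the reference
choice is arbitrary and immaterial after convergence, but it is stated
because order parameters are frame-dependent quantities.

* **Order parameters** use the direct second-rank tensor formula
  $O^2 = \tfrac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
  \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
  2\langle yz\rangle^2\right] - \tfrac{1}{2}$
  over unit bond vectors, i.e. the infinite-time plateau of the orientation
  correlation function, with no time-scale separation beyond the rigid
  superposition.  Methyl probes are the heavy-atom-neighbor → methyl-carbon
  axis (the united-atom symmetry axis; no axis-to-CH rescaling is applied).
  NH probes are explicit N–H pairs, one per residue that has them.
* **RMSF** is the per-coordinate root-mean-square fluctuation about the
  mean, population-normalized (divide by $F$), matching the time-average
  definition.
* **B-factor entropy** treats every Cartesian coordinate as an independent
  quantum harmonic oscillator: $\alpha_{ij} = \hbar / (\mathrm{RMSF}_{ij}
  \sqrt{M_i k_B T})$ and
  $S = R\sum \left[\alpha/(e^\alpha-1) - \ln(1-e^{-\alpha})\right]$.
  B-factors interconvert with RMSF via $B = \tfrac{8\pi^2}{3}\langle\Delta
  r^2\rangle$; the inverse necessarily distributes the variance
  isotropically, but conserves the per-atom total exactly.
* **Full-covariance quasi-harmonic entropy** diagonalizes the
  mass-weighted covariance and feeds each positive eigenvalue into the same
  oscillator formula; rigid-body and rank-deficient modes (non-positive or
  numerically zero eigenvalues) are dropped.  Since correlations can only
  reduce entropy, this never exceeds the diagonal value — a property tested
  on random ensembles.

Physical constants are CODATA values; the default temperature is 300 K.
Entropies are in J K$^{-1}$ mol$^{-1}$ throughout; coordinates in nm;
B-factors in Å$^2$.

## The synthetic study: what it emulates and what it does not

No trajectories are shipped.  The generator (`make_binding_set()`)
constructs toy "proteins" (peptide-like acyclic chains: backbone N, H, CA,
C per residue plus a two-carbon united-atom side chain, about 40% of
residues methyl-bearing, matching the typical abundance in real proteins)
and paired free/bound ensembles with *exactly known* entropies:

* Marginals are Gaussian (bonds, angles, stiff torsions), wrapped Gaussian
  (methyl torsions) or well-separated k-well rotamer mixtures (available
  for torsions), and dependencies are imposed by a Gaussian copula on a
  forest of DOF pairs.  Forests are the largest dependency class with
  closed-form joint entropy ($S = \sum_i S_i - \sum_{\mathrm{edges}}
  \tfrac{-R}{2}\ln(1-\rho^2)$), and they match MIST's pairwise scope.  The
  Jacobian expectations entering bond/angle ground truths have no closed
  form for Gaussian marginals and are computed by deterministic quadrature
  to $10^{-10}$ relative tolerance.
* The bound state narrows the methyl-axis azimuthal wobble — raising each
  methyl $O^2$ by a target drawn between about 0 and 0.3 — and rescales
  the widths of the stiff DOFs so that the exact per-DOF entropy change
  follows $\Delta S/(3N-6) = -2.09\,\Delta\langle O^2_{\mathrm{CH_3}}\rangle
  - 0.019$ J K$^{-1}$ mol$^{-1}$ plus Gaussian scatter (0.02 by default),
  spanning roughly 0 to $-0.7$ per degree of freedom.  These constants are
  the study conditions the generator is built to emulate; the scatter is
  set so that the synthetic set's overall correlation strength, *including*
  desk-scale estimator noise, lands near the $|R| \approx 0.95$ regime
  observed for real protein sets.
* The methyl wobble model is a fixed polar angle with wrapped-Gaussian
  azimuth, because it is simultaneously (a) realizable exactly by torsional
  sampling in the BAT construction and (b) closed-form invertible for
  $O^2$ via wrapped-normal trigonometric moments.  The uniform-in-cone
  model (also closed form, $O^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2$) is
  used as an independent check of the order-parameter code.
* Non-methyl degrees of freedom are kept stiff by design, so that the
  probe reference frames barely wobble and the measured order-parameter
  changes stay close to their targets.  A deliberate consequence is that
  the toy backbone is *much* stiffer than a real protein backbone: NH
  order-parameter changes are an order of magnitude smaller than methyl
  changes, and the NH- and B-factor-based fits on the synthetic set are
  correspondingly noisier than the methyl fit (they carry signal, but at
  desk scale their correlations are visibly weaker).  Passing tests
  therefore demonstrate estimator correctness and methyl-relation
  recovery, not that a 30-molecule toy set reproduces every regression a
  microsecond-scale study of real proteins would.
* All randomness flows through one explicit seed; functions restore the
  caller's RNG state.

Problem sizes were chosen to keep the full study comfortably inside a
desktop run: 30 processes of 24–48 atoms and 5000 frames per ensemble
(about two to three minutes for the complete entropy/proxy evaluation),
$10^5$ frames for the chain-recovery check, $10^6$ samples for the
closed-form MI recovery.

## Numerical and degenerate-input conventions

* Angles must lie strictly inside $(0,\pi)$; an exactly collinear angle
  makes the dependent torsion undefined and raises an error naming the
  frame and DOF rather than guessing a convention.
* Torsions are wrapped to $[-\pi, \pi)$; round trips
  (`bat_to_cartesian()` then `cartesian_to_bat()`) are exact to $10^{-9}$
  and preserve chirality.
* Undersampling subset sizes use round-half-up with a floor of one
  reporter per molecule (with a warning); subsets are drawn from
  per-(repetition, molecule) substreams, which makes runs bit-reproducible
  and subsets nested across retention fractions.  For the B-factor proxy,
  atoms are subset after superposition (superposition always uses all
  atoms) and the subset's per-coordinate oscillator-entropy changes are
  averaged.
* Fractional errors and couplings with vanishing denominators are reported
  as `NA`, counted, and excluded from medians.

## Two properties that only hold in the right regime

Two textbook identities about the estimator are stated loosely in the
continuous setting and are tested in the regime where they are exact:

* *Duplicated subsets*: for discrete variables,
  $S(A) + S(B) - S(A \cup B) = S(A)$ when $B$ duplicates $A$.  For
  continuous DOFs the histogram MI of a duplicated column is regularized
  by the bin width ($-R\ln\Delta x$), so the identity is tested on
  effectively discrete samples where $\Delta x \approx 1$.
* *Vibration suppression*: with sample-range bins, coarse-graining to 3
  bins suppresses a width change only when the sample range is pinned by
  conformational structure (e.g. rotamer wells) rather than by the
  vibration itself.  The suite scales the within-well width of a 3-well
  rotamer: the 50-bin entropy moves by the full $R\ln 2$ while the 3-bin
  entropy barely moves, which is precisely the vibration/conformation
  separation the coarse grid is meant to achieve on real torsions, whose
  sampled ranges are set by rotamer transitions.

## Known limitations

* No ring topologies, no phase-angle BAT variant, no solvent.
* No kernel-density or nearest-neighbor entropy estimators; no
  finite-sample (Miller–Madow style) bias correction.
* No triplet or higher mutual information; MIST is pairwise throughout.
* No NMR relaxation back-calculation; the order parameter is the direct
  tensor formula, not a fitted correlation-function plateau.
* The B-factor route inherits every caveat of interpreting real
  crystallographic B-factors (rigid-body motions, refinement artifacts are
  not modeled); here B-factors are always *derived from the ensembles
  themselves*.
* XTC/TRR trajectory formats are not readable in this R environment;
  multi-model PDB and DCD (via bio3d) are supported, plus a JSON topology
  dialect.
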