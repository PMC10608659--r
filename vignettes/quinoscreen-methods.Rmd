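---
title: "Screening quinone redox potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening quinone redox potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Quinones are cyclic conjugated diketones that can be reversibly reduced —
in the lithium-battery context by two electrons and two lithium ions — and
whose electrode potential shifts systematically with substitution:
electron-withdrawing groups such as nitrile (−CN) or methyl-capped alkynyl
(−C≡CMe) stabilise the reduced form and raise the potential. A screening
campaign over substituted quinones therefore needs (i) a systematic,
duplicate-free enumeration of derivatives, (ii) machine-readable structure
descriptors, (iii) a route from species thermochemistry to the potential,
and (iv) regression models relating descriptors to potential.
`quinoscreen` implements all four stages plus a synthetic-data generator so
that every stage is testable without quantum-chemistry calculations.

# Molecular substrate and enumeration

Molecules are hydrogen-suppressed labelled graphs (`molgraph`): elements,
formal charges, attached-H counts, aromatic flags, and bonds of order
1/2/3 or aromatic. The SMILES reader covers the organic subset used by the
quinone chemistry (B, C, N, O, F, Si, P, S, Cl, Br, I, aromatic
lowercase, branches, ring closures, bracket atoms with H counts and
charges); stereo markers are ignored because every implemented descriptor
is topological. Aromaticity is taken from lowercase notation and
additionally perceived on kekulé 6-rings whose bond orders strictly
alternate — this covers benzene-like carbocycles and pyridine-type rings
while quinoid rings (which do not alternate) correctly stay non-aromatic.
Charged and unparsable records are rejected with a diagnostic and the
reader continues; radicals are outside the model.

Canonicalization uses Morgan-style iterative partition refinement over
(element, charge, H count, aromatic flag, degree) with neighbour bond-type
multisets, followed by branch-and-minimum tie-breaking: remaining ties are
resolved by branching over the members of the smallest tied class and
keeping the lexicographically smallest emitted SMILES. All internal string
comparisons use byte (radix) order, so canonical forms do not depend on
the session locale. Symmetry classes (automorphism orbits) come from
marked canonicalization — atom *i* is marked by a charge offset and two
atoms are equivalent exactly when their marked canonical forms coincide —
which the test suite checks against an exhaustive automorphism search.

Derivative generation substitutes carbon-bound hydrogens only (O−H/N−H
substitution would leave the compound class), one symmetry-unique position
representative per class, and deduplicates globally by canonical form. The
default is monosubstitution; the synthetic generator uses up to two
substituents per molecule to reach a realistic dataset size (~500
derivatives from 12 scaffolds, matching the scale of a typical screening
set).

# The descriptor panel

The panel has 32 descriptors in a fixed registry order. Definitions follow
the cited conventions of each family:

* **Intrinsic/E-state block.** Kier–Hall intrinsic state
  $I = ((2/N)^2\,\delta^v + 1)/\delta$ with $\delta^v$ the valence
  electrons minus attached hydrogens and $\delta$ the heavy-atom degree;
  E-state $S_i = I_i + \sum_j (I_i - I_j)/d_{ij}^2$ with $d$ the
  topological distance plus one. `meanI` averages $I$; `MAXDP2`/`MAXDN2`
  are the largest positive/negative per-atom sums of adjacent intrinsic
  state differences (electrophilicity/nucleophilicity proxies). Atom-type
  counts and sums (`ndssC`, `SaasC`, `StN`, `mindO`, ...) use the s/d/t/a
  bond-letter grammar. Hydrogen E-states (for `SHdsCH`, `SHother`,
  `min/maxHother`) are a simplified H E-state built from the Kier–Hall
  electronegativity $(\delta^v-\delta)/N^2$ of the bearing atom with the
  same distance damping; they keep the perturbation structure of the
  original formalism and are validated on hand-derived cases only —
  bit-parity with any particular descriptor software is not a goal.
  `SwHBa` sums E-states over weak hydrogen-bond acceptors, defined here as
  N/O atoms carrying no hydrogen (carbonyl and ether oxygens, nitrile and
  pyridinic nitrogens); the membership rule is deliberately simple and
  documented rather than inherited from an unpublished table.
* **Topology.** `ECCEN` $=\sum_i \mathrm{ecc}(i)\,\mathrm{deg}(i)$;
  `topoDiameter` = max eccentricity; `nRing` = circuit rank; `nBondsD2`
  counts double bonds excluding aromatic ones; `C1SP1`/`C3SP2` count sp
  carbons with one carbon neighbour and sp² carbons with three; `JGI2` is
  the mean Galvez topological charge index of order two,
  $G_2/(N-1)$ with $G_2=\sum_{d_{ij}=2}|m_{ij}-m_{ji}|$, $M = A D^{*}$,
  $D^*_{ij}=d_{ij}^{-2}$; `fragC` is the fragment complexity
  $|B^2 - A^2 + A| + H/100$ (bonds, heavy atoms, heteroatoms).
* **Surface/volume/mass.** Ertl-type TPSA from N/O/S fragment
  contributions; Zhao van der Waals volume
  $V = \sum_{\text{atoms}} v_a - 5.92\,N_b - 14.7\,R_a - 3.8\,R_{na}$ with
  bonds counted including hydrogens; molecular weight from average atomic
  masses.
* **Electronic.** `BCUTc-1l/1h` are the extreme eigenvalues of the Burden
  matrix with Gasteiger-type partial charges (PEOE, 8 damped iterations
  over the hydrogen-expanded graph) on the diagonal; off-diagonal entries
  are 0.1 × bond order (1.5 aromatic), +0.01 for terminal bonds, 0.001 for
  non-bonded pairs. `LUMO` is a **pseudo-LUMO**: the lowest unoccupied
  eigenvalue of a topological Hückel Hamiltonian over the conjugated π
  system with Streitwieser-style heteroatom parameters (h = 0.5/1.5 for
  1-/2-electron N, 1.0/2.0 for carbonyl/ether O; bond factor 0.8 to
  two-electron donors) and $\alpha = -6.6$ eV, $\beta = -2.7$ eV. It is a
  deterministic surrogate for a semi-empirical LUMO; it reproduces
  analytic solutions (ethylene $\alpha-\beta$, butadiene
  $\alpha-0.618\beta$) and, importantly, preserves the
  electron-withdrawing trend — adding −CN lowers it. Externally computed
  LUMO values can be injected via `compute_descriptor_table(..., lumo =)`.

Descriptors that can be undefined (no π system, no atoms of a type) are
emitted as 0 with a parallel `na_*` flag column rather than dropping rows,
so the low-variance filter handles them uniformly downstream.

# Thermochemistry and labels

For each species, $H = E_0 + \mathrm{ZPE} + H_{trans} + H_{rot} + H_{vib}
+ RT$, $S = S_{trans} + S_{rot} + S_{vib} + S_{el}$, $G = H - TS$ at
$T = 298$ K; the two-lithium reaction free energy is
$\Delta G = G_{red} - G_{ox} - 2G_{Li}$ and the potential
$\Delta E = -\Delta G/(nF)$ with $n = 2$ and
$F = 96485.332$ C·mol⁻¹. Internal unit is J/mol; readers accept `hartree`
and `eV` tags and convert on ingest (1 hartree = 2 625 499.6 J/mol) so
that quantum-chemistry output and battery-scale voltages never mix units
silently.

# The synthetic-data generator

The generator emulates the statistical structure a DFT-labelled quinone
screening set would have, so that selection and model comparison are
exercised under realistic conditions:

* **Structures**: all ≤2-substituted −CN/−C≡CMe derivatives of the first
  12 bundled quinone scaffolds (509 molecules) — benzo-, naphtho- and
  anthraquinones with common simple substitutions.
* **Labels**: $\Delta E = b_0 + b_{CN} n_{CN} + b_{alk} n_{alk} +
  b_L \cdot \mathrm{LUMO} + \varepsilon$, $\varepsilon \sim N(0,\sigma^2)$,
  clipped to the physical 0.3–2.8 V window (clip events are counted and
  stay around 1 % under the defaults). The linear form is deliberate: the
  screening literature's conclusion is that the structure–potential
  relationship is predominantly linear in electronic-structure
  descriptors, and a linear ground truth makes the expected
  ridge-over-trees ordering a recoverable property. A `nonlinear` switch
  adds an interaction term for contrast experiments.
* **Defaults** ($b_0 = -2.98$ V, $b_{CN} = +0.55$ V, $b_{alk} = +0.12$ V,
  $b_L = -0.50$ V/eV, $\sigma = 0.22$ V) were calibrated once against the
  target distribution — labels inside 0.3–2.8 V with the bulk (about two
  thirds) between 0.75 and 1.60 V, a right-skewed asymmetric bell, rare
  clipping — and against the recoverability of the linear ordering; the
  signs encode the chemistry (electron-withdrawing groups and lower LUMO
  raise the potential).
* **Thermochemistry**: records for each oxidized/reduced pair are
  back-solved from the labels around fixed bookkeeping constants
  (gas-phase lithium free energy, a size-dependent baseline for the
  oxidized species) with realistic-looking ZPE/enthalpy/entropy
  components; the electronic energy absorbs the remainder so the
  free-energy arithmetic reproduces every label to numerical precision
  (the round-trip test asserts 1e−9 V).

What the generator does **not** emulate: DFT error structure (systematic
functional/basis biases, conformer effects), solvation, and — importantly
for model comparison — the high-dimensional weakly-correlated continuous
descriptor structure of a real 750-descriptor panel. The synthetic truth
has three structural degrees of freedom, so all well-tuned models approach
the noise ceiling $1 - \sigma^2/\mathrm{var}(y)$ and the margins between
the top families are small (~0.01 R²); the ordering test is therefore a
majority-of-seeds check, not a claim about effect size on real data.
Passing it shows the pipeline recovers a planted linear structure and
ranks a correctly-specified linear model first — not that ridge would beat
boosting by a wide margin on any real dataset.

# Descriptor selection

The four stages run in a fixed order on training rows only:

1. **Low variance**: a column whose modal value covers ≥ 60 % of rows is
   removed (the boundary is removed, per the "60 % or more" rule).
2. **Target correlation**: normalization is $(V - \bar V)/\sigma_V$ with
   the *population* sd (divide by $n$), under which the covariance of two
   normalized vectors equals the Pearson correlation exactly; columns with
   $|r| < 0.25$ against the label are removed, the boundary kept.
   Absolute values are used by default — a strong negative predictor is
   informative, and a literal signed reading would discard it; a signed
   mode is available (`use_absolute_correlations = FALSE`).
3. **Mutual correlation**: survivors are ranked by decreasing $|r|$ with
   the label (ties by column order) and scanned greedily; a column is kept
   iff its $|r|$ with every already-kept column is ≤ 0.7 (strictly greater
   is removed, so the boundary survives). The greedy keep-best rule keeps
   the most label-relevant representative of each correlated cluster and
   is fully deterministic.
4. **Backward stepwise**: repeatedly drop the column whose removal gives
   the highest mean 5-fold CV R² of an OLS fit (the ridge machinery at
   $\lambda = 0$, pseudo-inverse fallback on singular designs); stop when
   the best removal would cost more than the tolerance
   $\varepsilon = 0.001$, or at the survivor floor (default 1). The
   tolerance is the smallest stopping rule consistent with "keep reducing
   while it does not hurt"; it prunes aggressively on plateaus, which is
   intended — the audit report records every removal with its statistic.

# The regressors

* **Ridge** is the closed form $\beta = (X^TX + \lambda I)^{-1}X^Ty$ with
  a leading ones column. The penalty includes the intercept — the printed
  closed form is implemented literally — with an `penalize_intercept =
  FALSE` switch for the textbook convention; at the default small
  $\lambda = 0.1$ on roughly unit-scale descriptors the difference is
  negligible. Standardization is off by default (the selection stages
  already work on correlations, i.e. implicitly normalized quantities) and
  available by flag with parameters stored in the model.
* **CART** examines every feature and every threshold (midpoints of
  consecutive sorted unique values; vectorized via cumulative sums) and
  keeps the split maximizing $n H(Q) - n_l H(Q_l) - n_r H(Q_r)$; rows with
  $x_j < t$ go left; leaves predict their training mean. Ties break
  deterministically: first feature in column order, lowest threshold,
  strict improvement required (1e−12 guard). MSE is the default cost; the
  Poisson option uses the standard half-deviance
  $2(y\log(y/\bar y) - y + \bar y)$ — the commonly printed variant without
  the sign-corrected last terms is not a proper deviance, so the standard
  form is implemented and documented here.
* **Random forest**: bootstrap samples of size $n$, random feature subset
  of $\lceil m/3 \rceil$ per split (the regression convention;
  configurable), exhaustive thresholds, mean prediction.
* **Extra trees**: subsamples without replacement (fraction 0.8 by
  default, 1.0 disables subsampling), random feature subset per split, one
  uniform random threshold per candidate feature, best candidate kept.
* **Gradient boosting**: $F_0 = \bar y$ (the standard squared-error
  start), then each stage fits a CART tree to the residuals and
  $F_m = F_{m-1} + \gamma h_m$. Training MSE is provably non-increasing
  for $\gamma \in (0, 1]$, which the tests assert numerically.

All stochastic fits are reproducible from (data, parameters, seed); the
RNG state is saved and restored around each fit so that fitting does not
perturb the caller's stream. Models serialize to JSON at 17 significant
digits, which round-trips doubles exactly (`model_to_json()` /
`model_from_json()`), and trees export as an indented text listing
(`tree_export()`).

# Evaluation protocol

The 80/20 split uses a seeded shuffle with train size
$\lfloor 0.8 n \rfloor$; fold assignment is an independent seeded shuffle
chunked into folds whose sizes differ by at most one; fold-wise R² values
are averaged, not pooled. Grid search evaluates every point and selects by
maximum validation R², or — for the ridge penalty — by the minimum
train–validation gap, the protocol under which a small penalty
($\lambda \approx 0.1$) comes out as neither under- nor overfitted; ties
break toward stronger regularization / smaller models. The test-set
trendline regresses the reference potential on the model prediction (the
`(E_model, E_reference)` orientation; the reverse is a flag) and reports
slope, intercept and R² — an ideal model gives 1, 0, 1. The pipeline seals
test rows away from selection and tuning by construction and refuses to
run if asked to leak them.

Default problem sizes keep the full pipeline interactive: 509 molecules,
five folds, 10/15-tree forests, 50 boosting stages; the one-off derivative
enumeration and descriptor pass takes ~30 s and a full five-family
comparison ~2 s thereafter.

# Known limitations

* The SMILES dialect is the organic subset without stereochemistry or
  radicals; aromaticity perception covers alternating 6-rings, not exotic
  aromatic systems (azulenes, 5-rings written in kekulé form).
* The pseudo-LUMO is a topological Hückel surrogate: trends and orderings
  are meaningful, absolute values are not PM6-comparable.
* Hydrogen E-states are a documented simplification of the full
  Kier–Hall H E-state formalism.
* The backward stepwise criterion is a plateau-pruner; on strongly
  redundant panels it retains far fewer descriptors than a
  minimum-description analysis of a real dataset might.
* Synthetic-data conclusions about model ordering transfer to real data
  only qualitatively (see the generator section above).
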