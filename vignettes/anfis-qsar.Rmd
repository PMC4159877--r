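---
title: "Neuro-fuzzy QSAR for anthocyanin radical scavenging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy QSAR for anthocyanin radical scavenging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfisqsar)
```

## The chemistry being modelled

Anthocyanins are glycosylated anthocyanidins on a flavylium-cation
skeleton. Unlike most flavonoids they are not one molecule but a
pH-dependent family of tautomers: the flavylium cation (FC) below pH 2,
quinoidal bases formed by deprotonating the 4'-, 5- or 7-hydroxyl (QB4',
QB5, QB7), the hydrated carbinol pseudobase (CP) and the ring-opened
chalcone (Ch) at higher pH. Radical scavenging proceeds by hydrogen atom
transfer (probed by O–H bond dissociation energies) and by single electron
transfer (probed by ionization potential, electron affinity and the other
conceptual-DFT descriptors), and different tautomers carry different
electronic structure — so the pipeline treats *(compound, form)* as the
unit for which descriptors exist.

Two structural rules are encoded rather than assumed from data:

* a quinoidal base exists only where the corresponding position carries a
  free hydroxyl, so a 5-glycosylated compound has no QB5 (`available_forms()`
  applies this generically per deprotonation site, even though in the
  packaged panel only position 5 is ever glycosylated);
* the hydroxyl count `nOH` is derived from the substituent pattern over the
  positional slots 3, 5, 7, 3', 4', 5', with 7-OH and 4'-OH constitutive
  for this compound class. The registry loader recomputes `nOH` and refuses
  a file whose stated counts disagree.

Acylated sugars (e.g. coumaroyl-sambubioside) are opaque labels: the
pipeline only ever needs OH-versus-glycoside at a position, so no sugar
chemistry is modelled. There is no SMILES parsing, no 3-D structure, no
pKa/speciation model, and no quantum chemistry — energies arrive as tables
(or via `read_mopac_heat()` from program output text) in kcal/mol and are
only ever subtracted.

## Descriptors and their conventions

`descriptor_set()` computes I, A, η, S, χ, μ, ω from the three total
energies of each record. Two conventions matter:

* **Units are kcal/mol throughout.** Semi-empirical heats of formation are
  already unit-consistent with the BDE table; converting to eV would buy
  nothing and risk mixed-unit tables.
* **η = 0 makes S and ω undefined.** They are returned as `NA` with a
  warning — never ±Inf — so a downstream correlation cannot silently ingest
  an infinity.

Whether the underlying energies are adiabatic (each species at its own
optimized geometry) or vertical is irrelevant to the arithmetic and is left
to the data producer; the default hydrogen-atom energy for BDEs is the
standard semi-empirical heat of formation 52.1 kcal/mol, overridable per
call. `bde_min()` breaks ties by ring-position order 3 < 5 < 7 < 3' < 4'
< 5', making the reported site deterministic on tied inputs.

## Feature screening

`screen_descriptors()` correlates every descriptor column with activity;
p-values come from `stats::cor.test`'s exact t-transform
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n-2\) degrees of freedom. Two levels of
significance stars (defaults 0.01 and 0.05) annotate the report. No
multiple-testing correction is applied across the descriptor × form grid —
the screen is exploratory and feeds a fixed, configured feature set rather
than an automatic selection — but the report carries a note so users can
apply their own.

Because χ and μ are equal and opposite by construction, their squared
correlation is exactly 1 in any non-degenerate table;
`eliminate_collinear()` removes such duplicates greedily, keeping the
higher-ranked member of any pair whose squared correlation reaches the
threshold (default 1, i.e. exact duplicates/negations only; the comparison
carries a 1e-12 slack so floating-point rounding of an exact negation still
counts). The default modelling feature set — electron affinity and
electronegativity of FC, ionization potential of QB7, and `nOH` — is
configuration, not hard-coded: `nOH` enters a priori as an established
structural predictor of polyphenol activity, not via the screen.

## The ANFIS

`anfis()` fits a first-order Takagi–Sugeno system:

1. **Grid partition.** Each input gets \(k\) triangular membership
   functions (default 2) on its min–max-scaled range. For \(k = 2\) the
   vertices are \((\mathrm{min}-\Delta, \mathrm{min}, \mathrm{max})\) and
   \((\mathrm{min}, \mathrm{max}, \mathrm{max}+\Delta)\) with
   \(\Delta = \mathrm{max}-\mathrm{min}\): the pair sums to exactly 1
   everywhere on the observed range, so no in-range point can leave all
   rules silent. Inputs are min–max scaled by default so one learning rate
   serves descriptors of very different magnitudes; the scaling is stored
   in the model and applied transparently at prediction.
2. **Rule base.** Every combination of per-input membership functions is
   one rule — \(2^4 = 16\) for the default four inputs — with a linear
   consequent \(c_0 + \sum_j c_j x_j\).
3. **Inference.** Rule firing is the product of its antecedent degrees;
   the output is the normalized-firing-weighted sum of consequents. A
   point outside the fuzzified range (possible only beyond the training
   range extended by \(\Delta\)) raises an error naming the offending
   values rather than returning 0/0.
4. **Hybrid training (default).** Per epoch: the consequents are solved
   exactly by least squares on the normalized-firing design matrix, then
   the membership vertices take one gradient step on the training MSE.
   With 16 rules × 5 coefficients = 80 consequent parameters against a
   21-row panel the least-squares system is underdetermined, so a small
   ridge penalty (default \(\lambda = 10^{-6}\)) selects the
   minimum-coefficient interpolant; \(\lambda = 0\) requests the exact
   minimum-norm solution via the pseudoinverse, with a warning when the
   system is singular. A pure-gradient solver (`solver = "gradient"`)
   is retained for experiments with plain backpropagation, which is
   ill-posed as the sole estimator at this parameter-to-sample ratio.
5. **Numerical details.** The triangular membership is non-differentiable
   at its vertices; the subgradient 0 is used there (measure-zero points).
   Vertex ordering \(a \le b \le c\) is re-enforced after every update by
   sorting, with a widening epsilon if a triangle collapses. Initialization
   is deterministic; randomness enters training only through optional
   stochastic solver components, so the same data and configuration always
   reproduce the same model.

The per-epoch training MSE is recorded in `$trace`. With premises frozen
(`learning_rate = 0`) repeated least squares on a fixed design cannot
increase the MSE — an exact property the test suite asserts — and in the
hybrid mode the trace is non-increasing up to numerical noise on the
packaged problem sizes.

Training fit on a 21-compound panel is close to interpolation (the README
example ends near machine-zero MSE); this is expected at 80 parameters for
21 rows and is precisely why model quality is judged by the bootstrap, not
the training error.

## Validation

`mae()` and `q_square()` implement
\(\mathrm{MAE} = \frac1n\sum_i|y_i-y'_i|\) and
\(Q^2 = 1-\sum_i(y_i-y'_i)^2/\sum_i(y_i-\bar y)^2\) with \(\bar y\) the
observed mean. `bootstrap_validate()` resamples the (observed, predicted)
**pairs** of the already-fitted model with replacement — it does not
retrain per replicate. This choice is deliberate: the dispersion of the
resampled-pair MAE has the analytic approximation
\(\sqrt{\mathrm{Var}(|r_i|)/n}\) (asserted in the tests), making the
reported ± values interpretable as sampling noise of the error statistic on
an n-compound panel, and it is reproducible from a seed without retraining
variance. A retraining bootstrap — refit on each compound resample, score
on the full panel — is available behind `run_qsar(bootstrap_mode =
"refit")` for comparison; its dispersions additionally contain refitting
variance and are generally wider. k-fold cross-validation is intentionally
absent: on a panel of 21 compounds the folds are too small to be
informative. A resample whose
observed values are all equal has no Q²; such replicates are skipped and
counted.

## The synthetic generator

`generate_qsar_data()` exists so that every stage is testable with no
quantum-chemical input. It draws descriptor columns jointly Gaussian and
builds the activity as the linear combination whose *population*
correlation with each descriptor equals its target, plus an optional
centred product interaction (uncorrelated with every linear term, so it
perturbs the targets only through a slight variance inflation) and optional
extra measurement noise.

The defaults are fixed once and define the emulated study conditions:

* target correlations 0.67 (A of FC), 0.70 (χ of FC), 0.67 (I of QB7) —
  the magnitudes observed for the retained descriptors — and 0.60 for
  `nOH`, a literature-scale value for hydroxyl-count correlations chosen
  because the reference correlation table does not list one;
* exchangeable inter-descriptor correlation 0.4: conceptual-DFT descriptors
  derived from the same energies are substantially inter-correlated, and
  the target vector is infeasible for independent descriptors (the
  feasibility check is an eigenvalue test on the full joint correlation
  matrix, run before any sampling; infeasible requests error rather than
  being clipped). These defaults leave a residual variance of about 0.21,
  i.e. a population Q² of about 0.79 — the same performance regime as the
  reference panel;
* activity mean 27, SD 7 (percent DPPH scavenged), matching the
  experimental panel's spread so simulated MAEs are on a comparable scale.

Because the correlation structure itself fixes the residual variance, the
"noise-free limit" used in recovery tests is reached by target correlations
near the feasibility boundary (residual SD → 0), not by a separate noise
dial; `noise_sd` adds measurement noise *on top* and defaults to 0.

What the generator does **not** emulate: discreteness of `nOH` (simulated
as continuous), any relation between descriptors and actual molecular
energies, heteroscedastic assay error, and panel composition effects
(aglycone/glycoside clusters). Passing tests on synthetic data therefore
demonstrate correctness of the algorithms under the assumed correlation
structure, not chemical validity on new compound classes.

## Problem sizes and determinism

The shipped tests and the acceptance script run at the study's own scales:
21-compound panels, 1000 bootstrap resamples, 100 training epochs, and
synthetic checks at n = 100–500 (n = 2000 only for moment checks of the
generator). These sizes were chosen as the smallest at which each asserted
property is stable under its fixed seed. All stochastic steps take explicit
seeds, restore the caller's RNG state, and reproduce byte-identical results
from the same seed.

## Known limitations

* The generic "quinoidal base needs a free OH" rule is exercised only at
  position 5 by the packaged panel; its behaviour for hypothetical 4'- or
  7-glycosylated compounds is an extrapolation.
* The ANFIS offers only triangular membership functions and grid partition
  — no Gaussian/bell shapes, no subtractive clustering, no rule pruning.
* With two membership functions per input the model is piecewise-blended
  linear; strongly non-monotone activity surfaces would need more MFs per
  input, at an exponential cost in rules.
* Pair-resampling bootstrap quantifies sampling dispersion of the error
  statistics, not model-refitting variance; a retraining bootstrap would
  be wider.
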