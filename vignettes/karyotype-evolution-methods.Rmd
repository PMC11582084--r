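---
title: "Models and methods for karyotype evolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for karyotype evolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevo)
```

`karyevo` studies how karyotypes — the number and morphology of a species'
chromosomes — evolve along a time-calibrated phylogeny. Its motivating
system is the leafcutting-ant clade (*Amoimyrmex*, *Atta*, *Acromyrmex*),
whose genera are strikingly uniform in haploid chromosome number (n = 11,
11, and 18–19 respectively) yet diverse in chromosome morphology. The
package bundles the published cytogenetic compilation for these species as
a fixture and implements the full comparative tool chain around it. This
vignette records the models, their assumptions, and the design choices
taken where the methodology left genuine freedom.

## Karyotype traits

Karyotypes are recorded as diploid formula strings in the Levan
nomenclature, e.g. `"12 m + 10sm + 14st + 2 t"`: counts of metacentric
(m), submetacentric (sm), subtelocentric (st) and telocentric (t)
chromosomes, classified by the long/short arm-length ratio r with bands
m: [1, 1.7), sm: [1.7, 3), st: [3, 7), t: [7, Inf). Acrocentric entries
are recorded as telocentric. Six quantitative traits are derived per
species: the haploid number n, the four haploid per-class counts, and the
fundamental number fn (arm count), computed with m/sm/st as two-armed and
t as one-armed.

Two conventions deserve note:

* **fn is stored on the diploid scale.** The published table prints
  haploid class counts but a diploid arm count (e.g. *Amoimyrmex
  striatus*: nm = 10 yet fn = 44), and we follow that scale so the
  packaged values reproduce print. The karyograph model divides by two on
  ingestion.
* **Inconsistent rows are flagged, not corrected.** Five records print an
  fn that contradicts the two-armed-st convention (the four *Atta* rows
  printing 40 where the convention gives 44, and one *Acromyrmex
  ambiguus* record printing 68 instead of 72). `leafcutter_karyotypes()`
  carries both values and a `fn_consistent` flag; derived analyses use
  the convention-computed value.
* **Duplicate records.** Several species have two published karyotypes.
  The compilation's stated baseline is measurement-based records; since
  the per-species choice is not recoverable, the first listed record is
  the default `preferred` one, and the choice is overridable.

Counts are treated as continuous characters in the trait models (a
standard move for chromosome numbers), optionally log(x + 1)-transformed —
the +1 because several traits are exactly zero in whole genera (nt in
*Atta*), so a plain log is undefined.

## Phylogenetic signal

Four complementary statistics ask whether closely related species have
more similar karyotypes than expected by chance:

* **Moran's I** with weights $w_{ij} = 1/d_{ij}$ (inverse patristic
  distance, unnormalised rows, the $n/S_0$ scaling in the statistic).
  The weighting scheme is a package choice — the statistic's name alone
  does not fix one — and is the common phylogenetic default.
* **Abouheif's $C_{mean}$**, a topology-only Moran-type statistic whose
  proximity is the product, over interior nodes on the nodal path between
  two tips (MRCA included), of one over the node's number of direct
  descendants. Several dialects of this proximity exist in the
  literature; the one implemented here is pinned by a hand-computed
  oracle in the test suite (for `((A,B),C)`: $a_{AB} = 1/2$,
  $a_{AC} = 1/4$).
* **Blomberg's K**, the observed/expected variance ratio calibrated so
  Brownian data have K near 1.
* **Pagel's λ**, estimated by maximum likelihood on [0, 1] and tested by
  likelihood ratio against λ = 0 on χ² with 1 df (no boundary
  correction, matching how such tests are conventionally reported).

Permutation tests (default 999 relabellings, mandatory seed) are
one-sided "greater", because the scientific hypothesis is positive
autocorrelation; exceedances are counted with ≥ so ties are conservative,
and p = (1 + exceedances)/(1 + reps) never returns zero.

## Trait models and model selection

Continuous traits are fitted by phylogenetic GLS under Brownian motion
and four covariance transformations — λ (phylogenetic dependence), δ
(time-dependent rate), κ (speciational change), OU (attraction to an
optimum) — with the root state and σ² profiled analytically and the
transformation parameter optimised by bounded 1-D search restarted on
five sub-intervals, so boundary optima are found reliably. Bounds are
λ ∈ [0, 1], δ ∈ (0, 5], κ ∈ [0, 3], α ∈ [0, 2]; the δ and α ceilings are
deliberately the values at which published tables report pinned
estimates, and all bounds are arguments. The δ transform is applied
without tree-height renormalisation (the simplest reading; the κ and δ
columns of a model table should be read with their bounds in mind).

Model choice uses AICc with n = number of tips; k = 2 for BM and 3 for
each transformed model. Published tables in this area store −lnL in their
"Likelihood" rows; `trait_model_table()` therefore prints `minus_lnL`,
while fit objects store signed lnL.

## Clade rate shifts

`scan_rate_shifts()` is a greedy traitMEDUSA-style forward search: every
internal node except the root is a candidate stem of a clade evolving at
its own multiplicative Brownian rate (the shifted rate applies to the
stem branch and the whole clade; nested shifts follow the innermost
enclosing clade). At each step the candidate's rate is profiled by 1-D ML
with previously accepted rates held fixed, the winner is re-optimised
jointly, and the shift is accepted only if AICc improves by more than the
cut-off (4 by default; 9 as the conservative alternative). Each accepted
shift is charged two parameters (rate plus location, the MEDUSA
convention; configurable to one).

## Chromosome-number CTMC

Haploid chromosome number evolves as a continuous-time Markov chain on
a bounded ladder of counts with single-chromosome gain and loss
(dysploidy, optionally linear in the count), whole-set duplication
(polyploidy), and demi-duplication i → 1.5i, odd counts splitting
equally between the two neighbouring integers. Bounds default to
[1, 2·max observed + 2] so a duplication from the largest observed count
is representable; transitions beyond the ceiling are dropped rather than
absorbed (absorbing would inflate the top state). The likelihood is
Felsenstein pruning with per-branch transition operators obtained from a
single eigendecomposition of the generator, validated by reconstruction
error and falling back to uniformization when the generator is not
reliably diagonalisable. The root prior is uniform by default, with
FitzJohn data-weighted and explicit-prior modes. Families (dysploidy
only, ± duplication, ± demi-duplication, linear variants) are compared by
AIC; ancestral states are marginal posteriors from the standard up-down
algorithm.

A caution established during validation and worth stating: on a single
tree, gain and loss are individually weakly identified (their sum is
estimated well; the split converges slowly because deep history is shared
across the whole tree). Pooled likelihoods over independent replicate
trees recover both rates accurately — the test suite demonstrates this —
but single-tree estimates can wander considerably, and plug-in ancestral
reconstructions under ML estimates are correspondingly anti-conservative.
The coverage tests therefore validate the credible sets of the
reconstruction algorithm under the generating model; propagating
parameter uncertainty (e.g. by MCMC) is out of scope.

## The karyograph model

The package's centrepiece treats a karyotype as a point on the
bidimensional lattice (y, x) = (haploid chromosome number, haploid arm
number), constrained by y ≤ x ≤ 2y because every chromosome has one or
two arms. Moves are:

* Robertsonian **fusion** (y−1, x) at rate k1·(2y−x), requiring at least
  two uni-armed chromosomes;
* **fission** (y+1, x) at k2·(x−y);
* **telocentric→metacentric transition** (y, x+1) at k3·(2y−x);
* the **reverse transition** (y, x−1) at k4·(x−y);
* **polyploidisation** (2y, 2x) at k5 — present only in model M2.

The per-chromosome multipliers (counts of eligible chromosomes) are the
natural mechanistic choice but are not uniquely dictated by the method's
description, so they are isolated behind a `multiplier` argument with a
per-karyotype-constant alternative.

The karyotype chain is embedded in a multi-state speciation–extinction
(MuSSE) likelihood with state-independent speciation rate λ and
extinction rate μ: along each branch the standard extinction and data
ODEs are integrated, at nodes D ← λ·D_left·D_right, and the root is
combined with FitzJohn weighting (flat weighting is an option; no
survival conditioning is applied, because conditioning is undefined in
the λ → 0 limit that the cross-validation oracles rely on).

Because λ and μ do not depend on the karyotype, the log-likelihood
separates exactly into (i) the karyotype pruning likelihood on the
karyograph generator and (ii) a birth–death factor depending only on
(λ, μ) — the E equation loses its state dependence and the D system
factorises into a scalar times the CTMC propagator. `musse_loglik()`
exposes both routes: `"ode"` (general, per-branch `deSolve` integration)
and `"factorized"` (the closed decomposition, default), which the tests
hold to agree to 10⁻⁶ and better. Fitting exploits the separability —
the k-rates are optimised on the CTMC part and (λ, μ) on the birth–death
part, which is the exact joint ML because the objective is additively
separable; bounded quasi-Newton search on log-rates replaced the more
traditional Nelder–Mead simplex here after profiling showed it reaches
the same optima in a fraction of the evaluations.

M1 (no polyploidisation) is nested in M2 (k5 ≥ 0), and the comparison is
a likelihood-ratio test on χ² with 1 df as conventionally reported; the
k5 = 0 null sits on the parameter boundary, so the boundary-corrected
halved p-value is also returned. M2's optimisation is additionally
started from M1's optimum with a small k5, so the nesting inequality
lnL(M2) ≥ lnL(M1) holds; when the optimum is the boundary itself the M2
fit is reported at k5 = 0. Ancestral karyographs are CTMC marginals
(exact under state-independent λ, μ), summarised per node as the
posterior mean chromosome number and mean arm number — the quantities
heat-mapped in karyotype-evolution figures — plus the argmax state.

## Synthetic data

The generator module creates every input the pipeline consumes. Trees
come from a forward Gillespie birth–death simulation stopped at the
instant the (n+1)-th extant lineage would appear (so pure-birth root
heights have expectation Σ_{k=2..n} 1/(kλ)), extinct lineages pruned,
whole-tree extinctions retried; the conditioning bias of this simple
stopping rule is accepted for validation purposes. Continuous traits are
simulated edge-recursively for BM and OU (exact transition law), and by
exact multivariate-normal draws from the transformed covariance for
λ/δ/κ — equivalent in distribution to simulating on the transformed
tree. Discrete histories use Gillespie jumps along every branch and
return the true internal states so estimators can be scored. Karyotype
tables are emitted by distributing bi-armed chromosomes among m/sm/st
with a seeded multinomial, and round-trip exactly through the parser.
Every simulator is a pure function of its arguments and seed.

## Validation scales

The replicated calibration suites run at the following problem sizes,
chosen to make each check informative while keeping the whole suite
comfortably runnable on a laptop core: Pagel's λ recovery on 50-tip trees
(200 replicates per condition); Blomberg's K calibration on 100-tip trees
(500 replicates); chromosome-CTMC rate recovery on 200-tip trees (50
replicates); rate-shift false-positive calibration on 50-tip trees and
power against a 20× clade of ~30 tips in a 100-tip tree (100 replicates
each); polyploidisation-LRT null calibration on 30-tip trees (50
replicates, boundary-tolerant ≤15% nominal-5% rejection). Oracle
equivalences (GLS vs dense multivariate normal, pruning vs enumeration,
ODE vs factorized SSE) run at tolerances 10⁻⁸–10⁻¹⁰ on small instances.

## Known limitations

* Tree inference and dating are out of scope; the tree is an input.
* The MuSSE embedding has state-independent λ and μ throughout; true
  state-dependent diversification would break the factorisation and is
  deliberately not claimed.
* Single-tree ML estimates of directional CTMC rates are noisy (see
  above); report them with that caveat.
* The traitMEDUSA-style scan is greedy and shares the usual
  stepwise-selection caveats; the AICc cut-off, not a formal test,
  controls acceptance.
* Genome sizes in the fixture are metadata only; no genome-size analysis
  is performed.
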