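---
title: "Models and methods behind trimevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trimevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trimevol` packages the evolutionary analyses commonly applied to fish
tripartite-motif (TRIM) gene families — the large, fast-evolving class IV
repertoires (finTRIM/*ftr*, bloodthirsty-related/*btr*, *trim35*/*hltr*) of
teleost genomes — as a tested, reusable pipeline with a synthetic-data
generator. This vignette explains the models, the tunable parameters, the
numerical choices, and what the simulation calibrations do and do not show.

## Domain-architecture classification

TRIM proteins are classified into nine structural classes by the domain
content downstream of the RING/B-box/coiled-coil (RBCC) module:
COS+FN3+B30.2 is class I, COS alone class II, COS+FN3 class III, B30.2 alone
class IV, no specific C-terminal domain class V, PHD+BROMO class VI,
FILAMIN+NHL class VII, MATH class VIII and ARF class IX. `trimevol` ships
this mapping as an editable table (`trim_class_table()`) rather than code,
because the boundaries for unusual combinations (e.g. COS with B30.2 but no
FN3) are not settled; the table keys on the *set* of class-defining
C-terminal domains, ignoring internal order anomalies.

Design choices worth stating:

* Classification consumes annotated domain tables (e.g. from an external
  domain scanner); the coiled-coil is a token, not a prediction — sequence-
  based CC prediction is out of scope.
* An incomplete RBCC does not block classification. Losses of single RBCC
  components (the RING in particular) are common in these repertoires, so
  `missing_RING` / `missing_BBOX` / `missing_CC` are recorded as flags.
  A protein with neither RING nor B-box is `non-TRIM`, even if it carries a
  B30.2 — counting bare B30.2 proteins as class IV would inflate the class.
* Any token outside the RBCC and class-defining sets (TM, CHROMO, RANBD,
  CYPA, ...) raises `novel_combination`. Three gain-of-domain patterns seen
  in zebrafish are recognized by name: a C-terminal chromodomain replacing
  the B30.2 (*ftr06*-like), a C-terminal RanBD + cyclophilin-A pair
  (*ftr52*-like), and a transmembrane segment replacing the B-box/coiled-coil
  between RING and B30.2 (*btr31*-like).
* Truncated proteins are paired to full-length co-orthologues ("like"
  variants) by pairwise identity; the threshold (default 0.7) is a free
  parameter because no published value exists. Ties break to the smallest id
  and are logged.

## Shannon-entropy hypervariability profiles

Per-column entropy is computed in bits, $H = -\sum_a f_a \log_2 f_a$ over
the 20 amino acids. Base 2 is the only base in which the hypervariability
threshold of 2 reads naturally: $H = 2$ is exactly a four-state uniform
column and the maximum is $\log_2 20 \approx 4.32$. The threshold is strict
($H > 2$), so the four-state boundary case is *not* hypervariable. Gaps and
ambiguity codes (X, B, Z, ...) are excluded from the frequency denominators;
columns above a gap fraction of 0.5 (configurable `max_gap_fraction`) are
masked and reported as `NA`, never as 0 — a masked column is "no data", not
"perfectly conserved". Whether entropy should be computed before or after
removing gapped columns is genuinely ambiguous for this kind of data; both
behaviours are reachable through `max_gap_fraction` (1 keeps every column
with at least one residue).

## Codon site models

The selection analysis is a from-scratch implementation of the standard
site-model framework: a GY94-type codon substitution process on the 61 sense
codons (universal code; stops excluded) with HKY85 nucleotide
exchangeabilities — rate $\kappa \pi_j$ for single-nucleotide transitions,
$\pi_j$ for transversions, multiplied by $\omega = d_N/d_S$ when the change
is nonsynonymous — and a site mixture over $\omega$ classes:

* M0: one $\omega$;
* M1a: $\omega_0 < 1$ and $\omega_1 = 1$;
* M2a: M1a plus $\omega_2 \ge 1$;
* M7: $\omega \sim \mathrm{beta}(p, q)$, discretized into 10
  equal-probability categories (category medians);
* M8: M7 plus an extra class at $\omega_s \ge 1$.

Per-site likelihoods come from Felsenstein pruning, vectorized across sites
with per-site rescaling; transition matrices are computed by spectral
decomposition of the symmetrized (reversible) generator. Equilibrium codon
frequencies default to F3x4 estimated from the alignment (F61 optional) —
the conventional default of codon-model software, adopted here because the
data themselves rarely support estimating 60 free frequencies.

Nested pairs (M1a–M2a, M7–M8) are compared by the likelihood-ratio test,
$2\Delta \ln L$ against $\chi^2_2$. Positively selected sites are identified
from the M2a fit by Bayes empirical Bayes (BEB) over the published discrete
grid prior — 10-point grids on the $(p_0, p_1)$ triangle, on
$\omega_0 \in (0,1)$ and on $\omega_+ \in (1,11)$, with $\kappa$ and branch
lengths fixed at their MLEs — calling sites at posterior $> 0.95$ (strict).
For M8 the default is naive empirical Bayes (NEB) at the MLEs, with a BEB
variant that integrates over $(p_0, \omega_s)$ while holding the beta shape
at its MLE: the exact M8 grid used in the original BEB software is not
recoverable from its description, so the M8 integration is documented as
this package's own choice.

Numerical choices:

* **Trees.** The topology is fixed: user-supplied, or neighbor-joining on
  codon p-distances. Branch lengths are taken as *relative* from that tree
  and a single global scale is re-optimized under every model. This replaces
  full per-model branch-length optimization ($2n-3$ extra parameters); with
  a fixed topology the global scale is the dominant likelihood dimension,
  and the mixture parameters are insensitive to residual relative-length
  error at the divergences these families span. The reported `tree_scale`
  is converted to expected substitutions per codon under the fitted mixture.
* **Optimizer.** Box-free quasi-Newton (`nlminb`) on log/logit-transformed
  parameters, so every constraint (proportions on the simplex, $\omega_0 <
  1$, $\omega_+ \ge 1$) is built into the parameterization. Per-class
  site-likelihood vectors are memoised on $(\kappa, \omega, \nu)$, which
  makes finite-difference gradient steps cheap: perturbing a mixture weight
  recomputes nothing, perturbing one $\omega$ recomputes one class. The
  default is one deterministic start, plus up to two seeded-jitter restarts
  taken only when the first optimization fails to converge; alternative
  models of a nested pair should be warm-started from the null fit (the
  calibration studies and the pipeline do this), which makes blind
  multistarts redundant in practice. Convergence is to ~1e-6 in log
  likelihood.
* **Degenerate cases.** $2\Delta\ln L$ slightly below 0 (optimizer noise) is
  clipped to 0 with a warning. A mixture weight of exactly 0 gives exactly
  zero posterior for that class (the NEB computation uses `log(0) = -Inf`
  deliberately). The M1a–M2a null distribution is non-regular (the true
  $p_+$ sits on the boundary), so the $\chi^2_2$ reference is conservative —
  the type-I calibration below checks rejection stays *at or below* nominal.

## Recombination-aware segmentation

Recombination breaks the single-tree assumption of the site models, so the
alignment is first scanned for breakpoints: a greedy forward search on a
codon grid (default step 3, minimum segment 10 codons) that accepts a
breakpoint only when it strictly lowers the small-sample corrected AIC of
the partitioned fit relative to the current one. Per-segment likelihoods use
the nucleotide HKY85 model with four discrete-gamma rate categories
(via `phangorn`) on per-segment NJ trees; $\kappa$, base frequencies and the
gamma shape are estimated once on the whole alignment and held fixed, making
the scan fully deterministic. The c-AIC charges each segment $2n-3$ branch
lengths plus $\kappa$ and the gamma shape, with the alignment's nucleotide
column count as the sample size — the parameter/sample counting convention
is logged in the output because no standard exists. This greedy,
deterministic search is a deliberate substitution for genetic-algorithm
breakpoint screening: it is reproducible at desk scale, and the calibration
study shows it recovers single switches within ±10 codons in ≥80% of
replicates while accepting no breakpoint on ≥90% of non-recombinant
alignments.

Each resulting segment is then re-tested for positive selection
independently (M1a–M2a, M7–M8 per segment, sites reported in
whole-alignment coordinates). Joint partitioned models that share a
selection regime across segments while allowing synonymous-rate variation
are out of scope; independent per-segment testing is the analysis the
fragment-level results are based on.

## Marker-neighbourhood enrichment

Genomic neighbourhoods are built as ±5 Mb windows (the size of the MHC
proper; configurable `flank`) around each marker, clipped to chromosome ends
and merged when overlapping. A gene is inside iff its start coordinate lies
in a merged interval (a midpoint rule is available; the choice matters only
for genes straddling a boundary). Tandem clusters of one family — runs with
inter-gene gaps ≤ 500 kb by default, a free parameter since "tandemly
duplicated" has no published distance — collapse to single occurrences at
the cluster midpoint, preventing recent duplications from pseudo-replicating
the signal. The test is the 2×2 Pearson χ² of independence (df = 1) of
family occurrences vs total genes, inside vs outside, **without** continuity
correction: on the published class-IV table (31/31 occurrences among
7,884/16,263 genes) the uncorrected statistic reproduces the reported
p = 0.0035 exactly (χ² = 8.51), while the Yates-corrected one gives ≈0.005.
When clusters are collapsed, the family margin uses occurrences while the
gene totals stay raw gene counts, mirroring the published construction
(62 occurrences against 24,147 genes). Coordinates are 0-based half-open
internally; 1-based input is accepted behind a flag.

## The synthetic-data generator

The generator exists so that every stage can be exercised and calibrated
offline; its defaults are the package's study conditions.

* `simulate_codon_alignment()` draws each site's $\omega$ class i.i.d. from
  the regime (matching the site-model assumption under test), the root codon
  from the equilibrium distribution, and evolves sites down the tree by
  exact matrix exponentials of the per-class generators, all sharing one
  normalization so branch lengths are expected substitutions per codon under
  the mixture. No indels, no rate variation beyond the $\omega$ mixture, no
  autocorrelation along the sequence — the simulator deliberately matches
  the inference model, so parameter-recovery results validate the
  implementation, *not* the model's robustness on real data (real alignments
  violate i.i.d. sites, frequency stationarity and tree correctness in ways
  these tests cannot see).
* `simulate_recombinant_alignment()` concatenates simulations on topologies
  sharing a leaf set; breakpoint metadata depends only on the construction,
  never on the RNG seed.
* `simulate_genome_annotation()` places background genes uniformly
  (chromosome probability proportional to length) and places the designated
  family by rejection sampling from that same distribution, accepting
  positions inside marker neighbourhoods with relative probability equal to
  the enrichment factor. Factor 1 therefore reduces *exactly* to the
  background distribution (the χ² null), and factor 0 forbids inside
  placement. Clustered families are emitted as tandem runs with a stated
  intra-cluster gap.
* All randomness flows from one integer seed per call; per-segment and
  per-replicate seeds are derived arithmetically, and draw order (classes,
  root states, then branch transitions in postorder-reversed edge order) is
  fixed so fixtures are stable.

## Calibration studies and their problem sizes

The packaged studies (run by the test suite and the acceptance script) use:
50 null replicates (12 taxa, 200 codons) for the M1a–M2a type-I error;
20 replicates (24 taxa, 400 codons, total tree length > 5,
$\omega_+ = 4$ on 15% of sites) for power at α = 0.001 and MLE recovery;
20 + 20 replicates of 200/300-codon alignments for breakpoint recovery and
false positives; and 500 + 50 synthetic genomes (2,000 genes, 50 family
genes, 4 × 50 Mb chromosomes, 8 markers) for the enrichment calibration.
These sizes give binomial standard errors comfortably inside the asserted
bands while keeping each study to minutes on a single core.

## Known limitations

* Site models assume one tree per segment and stationary F3x4 frequencies;
  no branch models, branch-site models, or selection on synonymous rates.
* The breakpoint search is greedy: closely spaced breakpoints (closer than
  the minimum segment length) cannot both be found, and the c-AIC counting
  convention affects sensitivity near that limit.
* The classifier trusts its input domain annotations; it cannot recover
  domains the upstream scanner missed, and its class table, while editable,
  does not enumerate every conceivable domain combination.
* Entropy profiles treat columns independently; no correction for
  phylogenetic non-independence of the sequences is attempted (all published
  profiles of this kind share that caveat).
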