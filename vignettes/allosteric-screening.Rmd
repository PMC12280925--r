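---
title: "Quantifying allosteric pharmacology and screening enrichment with allomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allosteric pharmacology and screening enrichment with allomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomod)
```

# Scope

allomod implements the quantitative analysis behind a structure-based
discovery campaign for positive allosteric modulators (PAMs) of a
G protein-coupled receptor — concretely, the extrahelical allosteric
site of the A1 adenosine receptor probed with the orthosteric agonist
NECA and the antagonist radioligand [3H]DPCPX. Three stages are covered:
equilibrium model fitting of binding and functional interaction data,
early-enrichment evaluation of ensemble docking screens, and the triage
funnel that turns a ranked docking library into a diverse candidate
list. A seeded synthetic-data layer emulates each input, so the whole
pipeline is testable in isolation.

# The pharmacological models

## Allosteric ternary complex model

Specific radioligand binding over an (agonist I x modulator B) grid at
fixed radioligand A is modelled as

$$Y = \frac{B_{max}[A]}{[A] + \dfrac{K_A K_B}{\alpha_A[B] + K_B}
  \left(1 + \frac{[I]}{K_I} + \frac{[B]}{K_B} +
  \frac{\alpha_I [I][B]}{K_I K_B}\right)}$$

with equilibrium dissociation constants $K_A$ (radioligand), $K_B$
(modulator), $K_I$ (agonist) and binding cooperativities $\alpha_A$
(modulator vs radioligand) and $\alpha_I$ (modulator vs agonist);
$\alpha > 1$ is positive, $< 1$ negative, $= 1$ neutral cooperativity.
The model assumes equilibrium, a single allosteric site, and mass-action
behaviour; it has no kinetic component.

`fit_atcm()` fits the model globally — one shared parameter vector
across all replicates and modulator concentrations — which is what makes
$pK_B$ and $\log\alpha_I$ separable. The radioligand affinity $pK_A$ is
always supplied and fixed, mirroring how it is determined independently
by saturation binding. $\alpha_A$ is *free* by default: PAMs of this
receptor that prefer active states show a modest negative cooperativity
with the antagonist radioligand, and forcing $\alpha_A = 1$ would fold
that effect into the other parameters. `fix_alpha_A = TRUE` restores the
neutral-cooperativity variant. The fit refuses data without a
modulator-free control or with fewer than two non-zero modulator
concentrations, since the cooperativity is not identified there.

## Operational model of allosterism

Normalized functional responses (cAMP accumulation mapped so the
forskolin-alone control is 0% and buffer alone 100%, `normalize_camp()`)
are modelled as

$$E = \frac{E_m(\tau_A[A](K_B + \alpha\beta[B]) + \tau_B[B]K_A)^n}
 {([A]K_B + K_AK_B + [B]K_A + \alpha[A][B])^n +
  (\tau_A[A](K_B + \alpha\beta[B]) + \tau_B[B]K_A)^n}$$

where $\tau_A$, $\tau_B$ are operational efficacies (so $\tau_B$
quantifies allosteric agonism), $\beta$ scales agonist efficacy, and $n$
is the transducer slope. `fit_operational()` constrains $pK_A$ and
$pK_B$ to the binding estimates — the standard identifiability device
for this model — and by default also fixes $n = 1$ and
$\log\alpha$ at its binding value, leaving $E_m$, $\log\tau_A$,
$\log\tau_B$ and $\log\beta$ free. The composite
$\log\alpha\beta = \log\alpha + \log\beta$ is the reported functional
cooperativity. Whether the original analyses fitted or fixed $n$ and
$\alpha$ is not documented; both treatments are exposed
(`fit_n`, `fit_alpha`) and the defaults are the declared convention.

## Numerical protocol

All equilibrium constants and cooperativities are estimated in log10
space ($pK \in [3, 12]$, $\log\alpha, \log\tau \in [-4, 4]$), which
keeps the problem well-scaled and the parameters positive by
construction. Optimization is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, relative tolerance $10^{-10}$) from 20 starts: the
data-driven center plus 19 points of a seeded Latin hypercube over the
box. Ties between starts are broken by lowest objective, then lowest
start index, so fits are reproducible. Standard errors come from the
Gauss–Newton Hessian at the optimum. Degenerate outcomes — flat curves,
parameters pinned at a box bound — are returned with
`converged = FALSE` and a reason code rather than raising, so screening
loops can skip them without try/catch scaffolding. The operational-model
numerator and denominator are rescaled before the `^n` power to avoid
overflow at extreme $\tau$.

## Hit calling

`screen_deltas()` forms per-replicate differences of agonist affinity
($\Delta pK_I$, from competition binding) and potency
($\Delta pEC_{50}$, from Hill fits of the functional curves) between
modulator-treated and control conditions, and applies a two-sided
one-sample t test against zero per endpoint (at least 3 matched
replicates required; zero-variance deltas yield `NA` and are flagged).
`call_hits()` declares a PAM only when *both* endpoints are significant
at $\alpha = 0.05$ *and* both mean shifts are positive — enhancement,
not mere significance. Hit rates are reported as percentages to one
decimal: 3 of 26 gives 11.5%, 1 of 26 gives 3.8%.

# Enrichment metrics

`roc_enrichment()` ranks by docking energy (lower is better; a
`higher_is_better` switch inverts) and handles tied scores by letting
all tied molecules advance simultaneously, tracing a diagonal ROC
segment; the resulting AUC equals the Mann–Whitney normalization with
half-credit ties. Decoys and experimentally confirmed inactives are both
negatives.

`adjusted_logauc()` integrates TPR against $\log_{10}$ FPR from
$\lambda = 0.001$ to 1, normalizes to percent, and subtracts the
random-ranking expectation $100(1-\lambda)/(\ln 10 \cdot
\log_{10}(1/\lambda)) \approx 14.462$. The integral is evaluated in
closed form on each linear ROC segment; a ranking whose first negative
appears above FPR $= \lambda$ is clamped at $\lambda$ (TPR interpolated
on the containing segment). A perfect classifier therefore scores
$100 - 14.462 = 85.54$ and a random one 0. $\lambda$ is configurable;
0.001 is the conventional early-enrichment choice.

Missing scores mean "did not dock": the molecule is absent from that
snapshot's ranking rather than ranked last, matching docking practice
and keeping sparse snapshots comparable. `ensemble_combine()` takes the
best (minimum) energy per molecule over snapshots — the
best-pose-across-snapshots rule — and excludes molecules that docked
nowhere, with a warning count. `select_snapshots()` ranks snapshots by
their individual adjusted logAUC (ties by snapshot id) to pick the
ensemble used prospectively.

`match_decoys()` follows the property-matching idea of the DUD-E
protocol: the six properties (MW, cLogP, H-bond donors/acceptors, net
charge, rotatable bonds) are z-scored over the candidate pool, each
active takes its `n_per_active` nearest pool molecules by Euclidean
distance, pool molecules with circular-fingerprint Tanimoto $\ge 0.35$
to *any* active are excluded first, and decoys are never reused across
actives. The published protocol does not print its thresholds; 0.35 and
40–50 decoys per active are the declared, configurable defaults.

# The triage funnel

The funnel mirrors a large-library docking campaign and every stage is a
subset of its input:

1. `partition_library()` — lipophilicity window $2.5 \le \mathrm{LogP}
   \le 4.5$ (inclusive both ends) with fragment (MW $< 250$) and
   lead-like ($250 \le$ MW $< 350$) classes. MW exactly 250 is assigned
   to lead-like: the source windows ("MW < 250", "250 < MW < 350") leave
   the boundary ambiguous, and the inclusive-lower convention is chosen
   and documented here.
2. `top_fraction()` — keeps $\lceil 0.005\,N \rceil$ molecules; ties at
   the cut are admitted in molecule-id order, so the cut is
   deterministic under input permutation.
3. `hbond_filter()` — retains molecules whose best pose hydrogen-bonds
   at both conserved anchor sites (S246 side chain, L276 backbone
   carbonyl). Poses arrive as precomputed contact records; the geometric
   defaults (heavy-atom distance $\le 3.5$ Å, donor angle $\ge 120°$)
   are declared package defaults since the original filter's criteria
   are not printed.
4. `leader_cluster()` — greedy leader clustering on 2048-bit radius-2
   circular (ECFP4-type) fingerprints at Tanimoto 0.5: the best-scoring
   unassigned molecule founds a cluster and absorbs everything at or
   above the threshold. Founding order equals representative-score
   order, representatives are pairwise below threshold, and all ties
   break on (score, id), making the clustering bit-reproducible.
   Fingerprints come from Open Babel's ECFP4 implementation, folded from
   4096 to the declared 2048 bits.
5. `select_representatives()` — the best-scoring representative of each
   of the top 1,000 clusters. The final visual-inspection step of a real
   campaign is deliberately out of scope; the funnel emits the annotated
   list that inspection would consume.

`analog_search()` supports the hit-expansion step: substructure matches
(Open Babel SMARTS) unioned with fingerprint similarity at
$T_c \ge 0.5$.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical* structure each analysis
assumes, with defaults copying the published assay designs:

- `gen_interaction_binding()` / `gen_functional()`: the ternary-complex
  and operational surfaces over the published grids (binding agonist
  0.3 nM–10 µM in half-log steps plus an agonist-free point, functional
  agonist 0.01 nM–100 µM; modulator 0/3/10/30 µM; ~1 nM radioligand;
  n = 4 replicates) with independent proportional Gaussian noise,
  $y = \mu(1 + \varepsilon)$, $\varepsilon \sim N(0, 0.05)$. The true
  assay noise magnitude is unpublished; 5% CV is the declared assumption
  and is configurable, and duplicate-well correlation, plate effects and
  nonspecific-binding subtraction error are *not* modelled — recovery
  tests therefore demonstrate estimator correctness under the declared
  noise, not robustness to real assay pathology.
- `pam_truth()` carries the characterized compounds' reported estimates
  as generating truths (compound 1: $pK_B$ 5.18, $\log\alpha$ 2.09,
  $\log\tau_B$ 0.56; compound 12: 4.63, 0.99, $-0.65$,
  $\log\alpha\beta$ 0.68; compound 54: 5.15, 1.15; compound 56:
  $\log\alpha$ 1.30). Constants those reports do not determine are
  package choices, stated once: radioligand $pK_A = 8.70$ (a
  literature-typical DPCPX affinity; the K_D is a required user input
  for real data), NECA $pK_I = pK_A = 6.50$, $\log\tau_A = 1.0$ (full
  agonist with reserve), $\alpha_A = 0.7$, $E_m = B_{max} = 100$%, and
  compound 56's unprinted affinity set to $pK_B = 4.60$, comparable to
  compound 12.
- `gen_screen()` draws replicate-level control/treated $pK_I$ and
  $pEC_{50}$ estimates with Gaussian replicate noise (SD 0.1 log units,
  n = 4) — the regime in which a +0.5 log-unit effect is reliably
  detected and nulls are calibrated.
- `gen_score_library()` draws cross-snapshot-correlated Gaussian docking
  scores with actives shifted toward better energies, plus a missing-at-
  random "failed docking" mechanism. It is a statistical stand-in: no
  docking physics, pose geometry or chemical realism is implied.
- `gen_molecule_table()` builds template SMILES (2-aminothiazole-like
  and related scaffolds with small decorations) so fingerprints,
  substructure searches and clustering operate on real chemistry, while
  properties are *sampled* to populate the fragment/lead-like windows
  and pose contacts are sampled with a controllable probability of
  satisfying the hydrogen-bond filter. Snapshot counts are config
  values, not constants: benchmarking and prospective ensembles of any
  size are supported.

Every generator is a pure function of (specification, seed), and
`run_pipeline()` fans one top-level seed into per-stage child seeds so
end-to-end runs are byte-reproducible.

# Problem sizes and verification

The test suite checks each operation against an independent brute-force
oracle (literal formula evaluation, pair counting, fine-grid quadrature,
exhaustive greedy re-implementation, literal predicates) on small
synthetic sets, and the package's own recovery claims are simulation
experiments: 20 seeded rounds of 4-replicate experiments per compound
for the binding and functional models — enough for Monte-Carlo standard
errors of ~0.01–0.02 log units — plus 1,000 label permutations for the
null behaviour of the adjusted logAUC and 1,000 null screens for the
type-I calibration of hit calling. `scripts/acceptance.R` re-runs the
recovery protocol from scratch and writes the recovered means as JSON.

# Known limitations

- Equilibrium models only: no binding kinetics, Schild analysis or
  biased-signalling quantification.
- Standard errors are asymptotic (Gauss–Newton); no profile likelihood
  or bootstrap intervals.
- `log_alphabeta`'s SE ignores the $\alpha$–$\beta$ covariance when both
  are free (exact when $\log\alpha$ is fixed, the default).
- Docking scores are consumed, never computed; pose geometry arrives as
  precomputed contact records.
- The decoy matcher is a faithful nearest-neighbour implementation of
  property matching, not a re-implementation of the full DUD-E pipeline
  (no protonation-state enumeration or charge binning).
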