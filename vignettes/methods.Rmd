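---
title: "Null-space reaction geometry and phenotype-correlated metabolic sub-networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-space reaction geometry and phenotype-correlated metabolic sub-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsubnet)
```

## The problem

Cancer cell lines proliferate at very different rates, and panels such as
NCI-60 pair genome-wide expression profiles with measured doubling times.
Single-gene correlation screens find genes whose expression tracks the
growth rate, but metabolic interpretation needs more than single genes: a
pathway is causally interesting when *several* of its reactions move
together with the phenotype. A genome-scale metabolic network is, however,
not a graph but a Petri net: two reactions can be functionally locked
together (their fluxes proportional in every steady state) without sharing
a single metabolite, as in a linear pathway interrupted by spontaneous
steps. This package implements a similarity measure between reactions that
respects this structure, integrates it with per-gene phenotype association
statistics, and derives downstream consequences: sub-network robustness,
essential metabolites, metabolite-overlap statistics between analyses, and
the cofactor energetics of a closed fatty-acid synthesis/degradation cycle.

## Reaction similarity from the null space of S

Steady-state fluxes of a stoichiometric matrix $S$ (rows: non-boundary
metabolites, columns: reactions) satisfy $S v = 0$. Let $K$ be an
orthonormal basis of this null space, computed by SVD with singular values
below $10^{-9}\,\sigma_{\max}$ treated as zero. The unit vector $e_i$ of
reaction $i$ is projected into the null space, $p_i = K K^\top e_i$, and
the similarity between reactions $i$ and $j$ is the angle

$$\theta_{ij} = \arccos\frac{|p_i \cdot p_j|}{\lVert p_i\rVert\,\lVert p_j\rVert} \in [0^\circ, 90^\circ].$$

Fully coupled reactions — proportional fluxes in every steady state — have
collinear projections and $\theta = 0$ even with no shared metabolite. A
reaction whose projection norm is at most `tol_blocked` ($10^{-8}$) is
*blocked*: it carries zero flux in every steady state and has no defined
angle.

Two conventions deserve emphasis because the construction is not unique:

* **Folding.** The absolute value in the cosine folds angles to
  $[0^\circ, 90^\circ]$, so a reversible reaction written in the opposite
  orientation (its column negated) keeps all its angles. Without folding,
  rewriting `B <=> A` as `A <=> B` would flip a $0^\circ$ pair to
  $180^\circ$.
* **Column normalization.** Each column of $S$ is scaled to unit norm
  before the decomposition. Multiplying a reaction equation through by a
  constant rescales its flux coordinate and would otherwise change the
  angles between non-coupled reactions; normalization makes the measure
  exactly invariant to this arbitrary choice. Blocked sets and
  full-coupling classes are unaffected either way.

A consequence worth stating plainly: two *identical parallel* routes are
**not** fully coupled — flux can shift freely between them — and they sit
at a positive angle. Zero angle characterizes proportional fluxes, not
identical stoichiometry. The test suite cross-checks all full-coupling
classes on small fixtures against an independent flux-coupling oracle that
samples random steady-state vectors through a QR-based projector and tests
for a fixed flux ratio.

Full-coupling classes are the transitive closure of
$\theta_{ij} \le$ `tol_angle` ($10^{-4}$ degrees by default, the scale of
double-precision orthogonalization error). The null space is computed once
per model and can be cached on disk keyed by a content hash.

## Gene scores, FDR and h-values

Two scoring modes cover the two study designs:

* **Correlation mode.** Specific growth rate is $\mu = \ln 2 / t_d$ from
  the doubling time $t_d$ (hours). Each gene receives a Spearman rank
  correlation $\rho$ with $\mu$ (midranks for ties) and a two-sided
  p-value from the $t$ approximation on $n-2$ degrees of freedom —
  standard at the panel sizes involved (tens of samples). Zero-variance
  genes are flagged undefined and excluded from selection.
* **Two-group mode.** Welch's unequal-variance $t$ between two sample
  groups, with an explicit `positive_group` fixing the sign convention
  (for survival cohorts: positive = higher in the deceased group).

False-discovery control is Benjamini–Hochberg, the standard choice for
microarray-era screens. Directional selection ("positively correlated
genes at FDR 0.05") uses one-sided p-values — $p/2$ for concordant signs,
$1 - p/2$ otherwise — with BH applied over all defined genes, so the
tested family does not shrink with the observed signs. Cross-platform
analyses intersect the selections after probe-to-gene mapping; probes
collapse to genes by minimum p, which preserves any significant probe.

Gene evidence lifts to reactions through the gene–reaction (GPR) rules as
the *h-value*

$$h(r) = 1 - \min\{\,p^{\text{one-sided}}(g) : g \in \text{leaves of } r\text{'s rule}\,\},$$

an OR-like, most permissive aggregation: one strongly associated isozyme
suffices, matching how single-gene evidence (a single transporter or
synthase) is treated in growth-correlation screens. Reactions with no
scored gene carry $h = 0$ and are flagged unscored. A Fisher combination
is available behind the `aggregate` argument for users who prefer to
require joint evidence; min-p is the default because GPR rules do not
distinguish complexes from isozymes at this stage.

## Sub-network detection

Detection is two-phase:

1. **Seeding.** Restrict to non-blocked reactions with $h \ge h_{\min}$
   (default 0.95 in correlation mode) and connect pairs with
   $\theta_{ij} \le \theta_{\max}$ (default $15^\circ$); seeds are the
   connected components with at least `min_seed` (2) members. Single-linkage
   components were chosen over parametric clustering because they add no
   free parameters beyond the two thresholds and directly express
   "clusters of mutually close significant reactions".
2. **Expansion.** Each seed is completed with the full-coupling classes of
   all its members, so the output is the closed set of reactions whose
   fluxes necessarily move with the seed; the added reactions are reported
   separately from the seed.

Sub-networks are ranked by reaction count (ties: mean seed h, then first
reaction id) and may overlap; no merging is performed. The two-group mode
reuses the machinery with a laxer default $h_{\min} = 0.80$, reflecting
the weaker per-gene significance of patient cohorts — the method is not
built on a stringent single-gene cut-off.

$h_{\min}$ and $\theta_{\max}$ are calibration choices: the seeding
behaviour changes smoothly and monotonically in both (tests assert the
monotonicity), and both are exposed in the configuration.

## Robustness and essential metabolites

A metabolite *unique* to a sub-network (touched by no outside reaction,
boundary species excluded; identities are compartment-qualified)
contributes one steady-state mass balance over the sub-network fluxes.
With $U$ the restriction of $S$ to unique-metabolite rows and sub-network
columns,

$$\mathrm{DOF} = n_{\text{reactions}} - \operatorname{rank}(U).$$

Only unique metabolites contribute constraints — shared metabolites have
their balance closed by outside reactions. This is the convention under
which the two canonical cases come out right: a series pathway has
DOF 1 (one rate sets the whole chain; disabling any reaction stops it) and
$n$ parallel routes have DOF $n$ (disabling one barely matters). Low DOF
therefore flags fragile, drug-attractive sub-networks.

A unique metabolite is *essential* when removing every sub-network
reaction that produces or consumes it — the structural mimic of
competitive inhibition of the enzymes processing it — drives the DOF of
the remainder to zero (an emptied reaction set counts as zero). Ranks are
SVD-based with the same $10^{-9}$ relative tolerance throughout; the test
suite cross-checks every DOF against a pivoted-QR rank oracle.

## Metabolite overlap between analyses

Two analyses (e.g. growth-correlated vs mortality-correlated) are compared
through the metabolites unique to their top-$n$ sub-network collections.
The intersection is tested against an upper-tail hypergeometric null —
draws of fixed set sizes from the model's non-boundary metabolite universe
— evaluated via `phyper(..., log.p = TRUE)` so genome-scale
configurations (universes in the thousands, overlaps in the hundreds) do
not underflow. A fixed-size null was chosen over a per-metabolite
Bernoulli null as the standard enrichment convention.

## Cycle energetics

The packaged fixture encodes one elongation/β-oxidation round of the
futile cycle linking cytosolic fatty-acid synthesis to mitochondrial
degradation: acetyl-CoA carboxylase and FAS elongation in the cytosol, the
carnitine shuttle, one β-oxidation round, citrate synthase, the
citrate–malate antiporter, ATP-citrate lyase, and the two malate
dehydrogenases. Cofactors (ATP, NAD(P)H, FADH$_2$, CoA, CO$_2$) are
boundary metabolites whose ids carry their physiological compartment, so
the carbon skeleton alone defines a one-dimensional steady-state flux
space; the flux is oriented by the irreversible steps and normalized to
one cycled unit of cytosolic acetyl-CoA. Amortized per cycled unit, the
ledger is: 2 ATP and 2 cytosolic NADPH consumed, 1 cytosolic NADH
consumed, 2 mitochondrial NADH and 1 FADH$_2$ produced — three cytosolic
redox equivalents oxidized for three mitochondrial ones reduced.
Fatty-acid activation ATP (2 per molecule, not per C$_2$ unit) is
chain-length-amortized and deliberately excluded from the per-unit count.

Respiration converts the mitochondrial pool at an NADH P/O ratio $r$ with
FADH$_2$ yielding $\tfrac{2}{3} r$ (entry past complex I); this is the
unique linear convention reproducing both standard operating points, 8 ATP
per cycle at $r = 3$ and 4 ATP at $r = 1.5$, the latter leaving a net gain
of 2 ATP over the cycle's driving cost.

## Synthetic benchmarks

`make_toy_model()` composes series chains (with exchange reactions),
diamonds and parallel duplicate routes; each chain is one full-coupling
class. Interior reactions carry a trivial one-gene rule; exchanges carry
none, so they can enter sub-networks only through coupling expansion —
mirroring the unannotated transport steps of real reconstructions.
`make_expression()` draws growth rates log-uniformly over a 4-fold range
(the spread between the fastest and slowest proliferating lines;
log-uniform for rank spread — the marginal is immaterial to a rank
statistic), plants `effect`·z(rank(μ)) on the genes of chosen reactions
(default effect 2 in noise-SD units, noise SD 1, 60 samples, 20 decoy
genes) and leaves all other genes as pure noise. Scenarios are
deterministic in their seed, and the generator verifies at build time that
the planted pathway is a single full-coupling class.

What the benchmark does *not* emulate: probe-level effects, batch
structure, correlated backgrounds, many-to-many GPRs, or genome-scale
topology. Passing the planted-recovery test therefore shows the pipeline's
internal consistency (scores → h-values → seeds → expansion recovers
exactly the planted class), not field performance on real reconstructions.

## Numerical choices and degenerate inputs

* Rank/nullity: relative SVD tolerance $10^{-9}$ everywhere; geometry,
  DOF and cycle audits share the policy.
* `tol_blocked` $= 10^{-8}$ on projection norms; `tol_angle` $= 10^{-4}$
  degrees for full coupling; both configurable.
* A model whose null space is empty is legal: every reaction is blocked.
* Welch t with one constant group stays finite; both groups constant gives
  $t = 0, p = 1$ at equal means.
* Ties in ranking break by mean seed h, then lexicographic first reaction
  id, so reports are byte-deterministic.
* Problem sizes in the tests: toy models of 6–30 reactions, statistical
  simulations of 200 genes × 60 samples × 100 replicates — sizes at which
  every oracle (enumeration, QR rank, Monte-Carlo) is exact or
  well-resolved.

## Known limitations

* The angle similarity is a geometric surrogate for flux coupling;
  intermediate angles have no sharp probabilistic interpretation and only
  the thresholded relation is used downstream.
* h-values inherit the min-p aggregation's optimism for reactions with
  many isozymes.
* Uniqueness of metabolites is per compartment; a pooled-across-compartment
  variant would change unique-metabolite counts for shuttle-heavy
  sub-networks.
* SBML support covers Level 3 core plus `fbc` gene associations; kinetic
  laws, flux bounds and annotations are ignored by design.
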