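---
title: "Scoring and screening druggable cancer-specific pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and screening druggable cancer-specific pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsp)
```

## The model

A drug can only act through a pathway it can reach: its targets must sit
inside (or feed into) the pathway, and the pathway must actually be
active in the tumor. `dcsp` encodes this in a per-sample, per-(drug,
pathway) **pathway activation score**. Pathway genes are partitioned by
directed-network reachability into an upstream set $G_u$ (the targets
that are pathway members, plus every pathway gene with a directed path
into a target) and a downstream set $G_d$ (genes reachable from the
targets). Writing $S(G)$ for the summed expression of $G$ in one sample,

$$\mathrm{PAS}_u = S(G_u)\,(1 + w_1 + w_2 + w_3), \qquad
  \mathrm{PAS} = \mathrm{PAS}_u - \mathrm{PAS}_d ,$$

so a positive PAS means the part of the pathway at or above the drug's
point of attack is more active than the part below it. The negation of
PAS is the downstream-activation variant, used as a negative control:
if the model captures drug action, downstream-only activation should
not predict response.

The weights are connectivity terms: network-enrichment z-scores between
(targets, drivers), (drivers, pathway) and (targets, pathway) on an
undirected functional gene network, each mapped through the standard
normal CDF to $[0,1]$. $\Phi(z)$ is the natural "normal probability
score": 0 for strong depletion, 0.5 for no signal, 1 for strong
enrichment, and monotone in $z$, so well-connected
driver–target–pathway triples amplify the expression signal by up to a
factor of 4 while disconnected ones leave it essentially unweighted.

The NEA z-score is $z = (d_{AF} - \bar d_{AF})/\sigma_{AF}$, where
$d_{AF}$ counts network links between the two sets (each undirected edge
once, including edges inside the sets' intersection). Two null models
are provided:

* **permute_network** — the reference null: repeated degree-preserving
  randomization (double-edge swaps, $10\,|E|$ swap attempts per
  replicate) and the Monte-Carlo mean/SD of the link count;
* **analytic** (default) — a degree-based closed form,
  $\bar d_{AF} = \sum k_a k_f / (2E)$ over qualifying unordered pairs,
  with a Poisson-style $\sigma = \sqrt{\bar d_{AF}}$. This approximates
  the permutation null at a tiny fraction of its cost and is the default
  in `pas_matrix()`; the package's tests verify the permutation mode
  against exhaustive enumeration on small graphs and use the analytic
  mode for the large factorial screens.

When $\sigma_{AF} = 0$ (isolated gene sets) the z-score is defined as 0,
so the weight falls back to the neutral 0.5 and PAS stays computable.

## The screen

A triplet (drug $D_i$, pathway $P_j$, cancer $C_z$) is
**cancer-specific** when $C_z$ is overactivated *and* the remaining
cancers agree with each other. Two statistics per triplet:

* $T_1$: one-sided Yuen-Welch robust t (10% trimming per tail,
  winsorized variances, Welch–Satterthwaite degrees of freedom on the
  trimmed sizes) of the target cancer's PAS against the pooled rest.
  With `trim = 0` this is exactly Welch's t. The winsorized-variance
  form matters: a trimmed mean with the naive trimmed-sample variance is
  anti-conservative on the skewed sums that PAS values are, and the
  screen's type-I control depends on it.
* $T_2$: a one-way χ² homogeneity statistic over the remaining cancers,
  $T_2 = \sum_c n_c (m_c - \bar m)^2 / s^2_{pooled}$, approximately
  $\chi^2_{k-1}$ under homogeneity. If the pooled variance is zero with
  unequal means, $T_2 = \infty$ and the triplet can never pass.

Selection: BH-FDR of the one-sided $T_1$ p-values below 0.01, $T_2$
within the first quartile, every supporting cancer with more than 5
samples (cancers at or below that size are excluded from both the rest
pool and $T_2$ before testing), and at least 3 supporting cancers.

**Design choices that were genuinely open.**

* *BH family and quartile scope.* Adjustment is per target cancer (all
  drug–pathway pairs competing for that cancer) by default; a `family =
  "global"` option pools everything. The $T_2$ quartile is taken over
  the FDR-passing triplets of the family (`t2_scope = "fdr_pass"`,
  default). The alternative — quartile over the whole family before the
  FDR filter — is also implemented (`t2_scope = "family"`), but as a
  default it has an undesirable property: for a triplet whose remaining
  cancers are genuinely homogeneous, $T_2$ is an exchangeable draw from
  the family's null, so even a perfect cancer-specific signal would
  survive the quartile cut only ~25% of the time. Taking the quartile
  among the triplets that already passed the FDR filter keeps the
  homogeneity requirement ("the most homogeneous quarter of the
  candidates") without vetoing strong signals at random.
* *One-sided testing.* DCSPs are defined by overactivation in a single
  cancer, so $T_1$'s p-value is one-sided for target > rest.
* *Partition conventions.* Reachability is full transitive closure
  (configurable `max_depth`); on cycles, genes both upstream and
  downstream of a target join $G_u$ (target-side precedence); pathway
  genes reachable in neither direction default to $G_d$ (they cannot be
  argued to feed the targets; `unreached_policy = "exclude"` drops them
  instead). Targets outside the pathway still anchor the partition via
  network paths; only pathway members are summed.

## Response statistics

For a DCSP's samples, PAS and AUC are separately rank-transformed to
van der Waerden scores $\Phi^{-1}(r_i/(n+1))$ (average ranks for ties)
and Pearson-correlated; only positively activated samples enter
(PAS > 0 for the upstream direction). The transform makes the
correlation invariant to any monotone rescaling of either variable —
appropriate since neither PAS's scale nor the assay's AUC scale is
meaningful in itself.

The **rediscovery rate** at fraction $f$ is the proportion of the top
$\lceil f m \rceil$ discovery-ranked DCSPs whose validation correlation
is one-sided significant at level $\alpha$ in the discovery direction.
Under a null validation cohort RDR tracks $\alpha$ at every fraction
(the "target line"); genuine coupling lifts the top fractions above it.
Validation significance is one-sided in the discovery direction by
design — rediscovery of a directional effect — with the two-sided
variant available by supplying precomputed `p_one`.

The **specificity permutation test** compares a DCSP's PAS records with
one of three comparison groups (other drugs/same pathway, same
drug/other pathways, other drugs/other pathways) using the
pooled-variance two-sample t; under label permutation exchangeability
makes the plain t exact, so no robustification is needed. The one-sided
empirical p-value $(1 + \#\{t^* \ge t\})/(n_{perm}+1)$ is never below
$1/(n_{perm}+1)$ — with the default 10,000 permutations, a floor of
about $10^{-4}$.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates every input the pipeline needs. Defaults
describe the compact study conditions used throughout the tests: 6
cancers × 12 samples (within the 6–64 range typical of pan-cancer cell
line panels), 4 drugs × 5 disjoint 10-gene pathways in a 400-gene
genome, log-normal expression (per-gene log-mean ~ N(2, 0.5), within-group
log-SD 0.5), an Erdős–Rényi functional network at density 0.02, driver
sets of 3 background genes per cancer, and AUC ~ N(10, 1).

A planted signal (`planted_triplet()`) upshifts the planted pathway's
$G_u$ genes by $\delta$ within-cancer SDs *on the log scale* in the
planted cancer only (keeping values positive; $\delta = 3$ in the
recovery experiments), overlays driver–target–pathway links on the
functional network so all three weights exceed 0.5, and couples the
planted drug's AUC negatively to the standardized upstream activation
($\beta = 1$, noise SD 1).

Three structural choices keep *non-planted* triplets genuinely null,
which is what the calibration and recovery experiments assume:

1. Genes within a pathway share one baseline abundance (a co-regulated
   module at a comparable expression level). Otherwise the
   multiplicative upshift would unbalance other drugs' $G_u$/$G_d$
   splits by the random differences in gene means, creating spurious
   secondary signals.
2. Each drug taps into every pathway at a drug-specific anchor depth
   (the planted drug mid-pathway, with its target a pathway member;
   other drugs at half that depth), so the planted upshift lands evenly
   across other drugs' splits and cancels in their signed PAS.
3. The planted connectivity enrichment is degree-balanced: other
   cancers' drivers receive the same number of decoy links to background
   genes. Without this, the planted cancer's inflated driver degrees
   depress its NEA z-scores against every *other* pathway (the
   degree-based null grows) and bias those triplets' $T_1$ upward.

The simulator does **not** attempt realistic marginal distributions
beyond positivity and group structure: no gene–gene correlation within
samples, no overlapping pathways, no batch effects, no dose–response
curve shape behind the AUC, and cancers differ only through the planted
signal. Passing tests therefore demonstrate the statistical machinery —
calibration, recovery, invariances — not performance on real cohorts,
where pathway overlap, driver miscalling and expression covariance will
lower power and can distort the connectivity weights.

## Numerical conventions and degenerate inputs

* Expression is taken as provided (TPM or array intensity); the package
  filters (`filter_unexpressed_genes()`, threshold 1e-2 in more than 90%
  of samples) but never renormalizes, and summation treats values
  as-is — if the input is log-scale, $S(G)$ is a log-expression sum.
* Gene symbols are opaque and case-sensitive; no alias resolution.
* Driver frequency filters use the total sample count across cancers
  (mutations: ≥ 2% by default, 1% recommended for large patient
  cohorts; fusions: ≥ 2 occurrences plus an optional identifier
  whitelist standing in for a curated fusion database).
* Replicated (sample, drug) response profiles are dropped entirely, not
  averaged (`dedupe_monotherapy()`).
* Ties in ranks use averages everywhere; a constant vector maps to all
  zeros under the normal-score transform.
* Degenerate comparisons are defined, not fatal: zero variance with
  equal means gives $T_1 = 0, p = 1$; with unequal means
  $T_1 = \pm\infty$; an all-constant permutation test returns $p = 1$;
  correlations with fewer than 3 usable samples are flagged
  not-computable rather than invented.
* All randomized components (simulator, rewiring null, permutation
  test) take explicit seeds and restore the caller's RNG state; fixed
  seed means bit-identical output, which the pipeline manifest's file
  digests make checkable.

## Problem sizes in the shipped experiments

The packaged tests and `scripts/acceptance.R` run the screen on 100–200
simulated cohorts (6 × 12 samples, 20 drug–pathway pairs each), the
correlation/permutation calibrations on 500–1000 replicates (n = 50 and
18 + 18; 2,000–10,000 permutations), RDR on 200 matched pairs across
25–50 replicates, and the NEA enumeration check on a 6-node graph with
10,000 rewiring replicates — sizes chosen so the full suite completes in
a few minutes on a single core while leaving the Monte-Carlo error well
inside each criterion's tolerance.

## Known limitations

* The analytic NEA null is a degree-based approximation; for very
  heterogeneous degree sequences its Poisson SD can misstate the
  rewiring null's spread. Use `mode = "permute_network"` where accuracy
  matters more than speed.
* The screen treats drug–pathway pairs as exchangeable within a family;
  strongly overlapping pathways violate that silently.
* `PAS_u/S_u` is constant within a (drug, pathway, cancer) — weights
  modulate between cancers, not between samples, so within-cancer
  correlation with response is driven entirely by expression.
* The positivity restriction ("activation only") conditions on PAS > 0
  per triplet; with few activated samples the correlation record is
  dropped rather than estimated from 2 points.
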