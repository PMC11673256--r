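---
title: "Methods: co-occurrence analysis of diagnoses and comorbidities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence analysis of diagnoses and comorbidities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

`comorbnet` describes a hospital cohort — one record per
hospitalization, each carrying a set of canonical diagnosis terms and a
set of comorbidity terms — at three levels: marginal statistics
(detection rates, sex odds ratios, stratified rankings), pairwise
structure (weighted co-occurrence networks), and mesoscale structure
(communities by modularity and by the map equation). This vignette
documents the models, the defaults, and the design decisions, so that a
reader can judge what the numbers mean and where the method's
assumptions bind.

## Unit of analysis and normalization

The unit throughout is the **hospitalization record**, not the patient:
the package attempts no patient-level linkage because record-level EMR
extracts typically provide none. Term sets are deduplicated within each
record, so a record contributes at most 1 to any node frequency or edge
weight.

Raw EMR terms are normalized by a deterministic mapping table
(`raw_term → canonical_term, category`), matched case-insensitively
after whitespace trimming, with the table's casing kept on output. This
is a reproducible surrogate for the manual, clinician-guided synonym
resolution that real EMR curation requires; no fuzzy matching or
language processing is attempted, and any shipped mapping table is
illustrative rather than authoritative. Unmapped terms pass through
unchanged by default so partial maps remain usable; `strict = TRUE`
turns them into a single error listing every unmapped term, for
validation runs.

## Detection rates and sex odds ratios

The detection rate of a condition is the percentage of records
containing it, $DR = 100\,N_{cond}/N$. Its interval is the Wilson score
interval by default (Wald available for comparison): Wilson behaves
sensibly at the small counts that dominate the tail of a condition
table, and with no stated convention to follow, the better-calibrated
default wins.

Sex contrasts use the odds ratio of the 2×2 sex-by-condition table with
the **Haldane–Anscombe correction applied to every cell**, not only to
zero cells:

$$\widehat{OR} = \frac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)},
\qquad
CI = \exp\!\Big(\ln\widehat{OR} \pm z_{.975}
\sqrt{\tfrac1{a+.5}+\tfrac1{b+.5}+\tfrac1{c+.5}+\tfrac1{d+.5}}\Big).$$

Always-on correction is a deliberate choice: recomputing the reference
cohort's printed odds ratios from its printed sex-specific counts
reproduces every finite printed value to two decimals only under
always-on correction (e.g. renal cysts print 4.06, the corrected value,
where the crude ratio is 4.94; metabolic diseases print 2.00 vs the
crude 2.08). When one sex has zero events the estimate is reported as an
`INF`/`ZERO`/`UNDEFINED` sentinel with no interval, mirroring the
reference tables' convention, rather than as a finite corrected value
that would suggest spurious precision. Rendered tables round half-up to
two decimals; internal values keep full precision. No multiple-testing
correction is applied, matching the descriptive character of the
analysis.

Age stratification uses decade bins `30–39 … 80–89`. Decade alignment
follows the stratified reference tables' own row labels (their methods
prose mentions a 35–44-style example, but the results tables are
decade-aligned, and results win over prose). Rankings within a stratum
order by descending record count with alphabetical tie-break — an
arbitrary but deterministic rule — and short strata are padded with an
explicit `"/"` marker.

## Co-occurrence networks

An edge joins two terms when they appear together in at least one
record; the weight counts such records. Monopartite networks connect
terms of one category; the bipartite network connects
diagnosis–comorbidity pairs only (it is analyzed directly, never
projected). Isolated nodes are kept — both at construction and after
edge filtering — because component counts are a headline metric of the
sensitivity analysis and dropping isolates would silently change them.
A term legitimately present in both vocabularies (e.g. myocardial
infarction as index diagnosis and as comorbid history) keeps one node
per role in the bipartite graph, suffixed `[dx]`/`[cm]`.

Structural metrics are unweighted where they count topology (degree,
path length in steps, local clustering, betweenness, components) and
weighted where mass matters (weighted degree, modularity, map
equation). Path length averages over connected pairs only; betweenness
is Brandes-style, endpoints excluded, each unordered pair counted once.
Density uses $2m/n(n-1)$ for monopartite networks and $m/(n_d n_c)$
for bipartite ones.

## Communities: modularity and the map equation

Weighted Newman–Girvan modularity
$Q = \sum_c \left[ W_c/W - \gamma (S_c/2W)^2 \right]$ is optimized by a
Louvain implementation written for this package, because the analysis'
contracts — resolution $\gamma = 1$ (the Gephi default the reference
analysis evidently used), edge weights used, determinism under a
recorded seed, and exact agreement between the reported $Q$ and
`modularity_q()` of the returned partition — are easier to guarantee in
a dedicated implementation than to retrofit onto library calls. The
node visit order is shuffled once per aggregation level from the seed;
ties keep the first-encountered best community. The test suite
cross-checks `modularity_q()` against both `igraph::modularity()` and a
literal double-sum oracle, and checks Louvain against brute-force
enumeration of all 203 partitions of the six-node two-triangle bridge
graph (optimum $Q = 5/14$). Bipartite networks are scored with the same
unipartite modularity applied to the bipartite adjacency (Gephi's
behavior); Barber's bipartite modularity is out of scope.

The description length of a partition is the two-level map equation for
an undirected weighted graph without teleportation,

$$L(M) = q_\curvearrowleft H(Q) + \sum_i p^i_\circlearrowright H(P^i),$$

with node visit rates proportional to weighted degree (the stationary
distribution of the undirected walk) and module exit probabilities
proportional to boundary weight; units are bits. This is the simplest
form consistent with the map-equation literature, and nothing in the
reference analysis pins down a more elaborate variant. A single-module
partition has no exit terms and reduces to the visit-rate entropy
($\log_2 3$ bits for a triangle — a hand-checkable anchor). The
minimizer reuses the Louvain scaffold with the codelength as its
objective, recomputing $L$ from per-module aggregates at each candidate
move. The reported description length belongs to the partition that
minimizes it, not to the modularity partition; both partitions are
attached to the report so either reading of a "description length"
column can be inspected. Degenerate conventions: an edgeless network
has $Q = 0$ and $L = 0$, and its path length is reported as `NA`.

## Sensitivity analysis

`threshold_sweep()` filters the network at each threshold and recomputes
the full report. The default grid `{1, 2, 3, 5, 10}` spans unit weights
up to the ≥ 10 regime used by the printed pair tables; the reference
analysis does not print its own grid. Edge count, average degree,
average weighted degree and density are non-increasing in the threshold
and component count non-decreasing — these are mathematical
consequences of filtering and the test suite asserts them — whereas
modularity and description-length trends are data-dependent and are
reported without being asserted monotone. `hub_stable` records whether
the maximum-weighted-degree node is identical across thresholds.

## The synthetic cohort generator

Real record-level EMR data of this kind are not redistributable, so the
generator is a first-class module, not a test fixture. Per record it
draws sex (Bernoulli, default male share 138/195), age from sex-specific
truncated normals — male mean 60, SD 11; female mean 65, SD 10; truncated
to [30, 89] to match both the observed peaks (males near 60, females
60–70) and the decade-binned tables — an admission year uniform on
2013–2020, and each condition from
$\mathrm{logit}^{-1}(\mathrm{logit}(p_c) + s_c[\text{male}] + \lambda_c z)$
with one shared frailty $z \sim N(0, \sigma_f^2)$ per record. The shared
frailty is the single interpretable knob that induces positive pairwise
co-occurrence concentrated on high-loading conditions, reproducing the
hub structure of real comorbidity networks; with $\sigma_f = 0$
conditions are independent given sex, which the property tests exploit.

`cad_cohort_config()` calibrates intercepts numerically (solving the
frailty-averaged marginal per sex by integration and root-finding) so
that expected per-sex prevalences match the reference cohort's printed
detection rates to three decimals; sexes with zero printed events use
the continuity-corrected rate $0.5/(n+1)$. Defaults $\sigma_f = 0.8$,
loading 1.0 (1.5 for the two hub conditions, hypertension and unstable
angina) are tuning choices, not estimates — the reference analysis
reports no dispersion or correlation parameters — chosen once to give
visible but not degenerate co-occurrence concentration. The generator
therefore emulates marginal prevalences, sex effects, age structure and
qualitative hub structure; it does **not** reproduce the reference
cohort's exact pairwise co-occurrence weights, its community
memberships, or any temporal or within-patient correlation (records are
exchangeable). Passing tests consequently validate the *machinery* on
data with known structure, not the reference cohort's specific network
values: reported unfiltered modularities or description lengths of the
original networks cannot be checked without the raw records.

## Numerical choices and problem sizes

Odds-ratio reversal symmetry ($OR \cdot OR^{swap} = 1$) holds exactly
before rounding; rendered tables round half-up. Louvain and the
codelength minimizer use a $10^{-12}$ improvement tolerance so that
floating-point ties cannot cause seed-dependent drift. Community ids
are contiguous integers from 1 in order of first appearance. The test
suite exercises brute-force oracles on graphs of up to 8 nodes (exact
set-partition enumeration, literal double sums, exhaustive path
enumeration), marginal calibration at $n = 195$, parameter recovery at
$n = 20{,}000$, CI coverage over 500 replicates of $n = 2{,}000$, and
sweep properties on calibrated cohorts of $n = 1{,}000$ — sizes chosen
to make Monte-Carlo noise small relative to the tested tolerances while
keeping the default suite fast.

## Limitations

Hospitalization-level analysis overweights frequently readmitted
patients; the co-occurrence unit inherits that bias. Odds ratios are
descriptive sex contrasts, not adjusted effect estimates. The map
equation implementation is two-level (no hierarchical modules) and
undirected. The example mapping table ships for illustration; real use
requires a clinically curated table.
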