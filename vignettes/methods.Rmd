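---
title: "Methods: predicting interacting transcription factor pairs from promoter binding affinity"
author: "affipair developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting interacting TF pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affipair)
```

## The model in one paragraph

Two transcription factors (TFs) that act together on promoters should share
an unusually large fraction of their target genes. affipair operationalizes
this with sequence data alone: every promoter is scored against every TF's
position weight matrix (PWM) with a biophysical occupancy model, each TF's
promoters are sorted into a ranked target list, and every unordered TF pair
is scored by the smallest hypergeometric overlap p-value over a grid of
top-list cutoffs. A motif-similarity filter removes pairs whose overlap is
explained by near-identical binding motifs rather than genuine
co-targeting. Finally, tissue-specific gene sets enter through a 2x2x2
contingency table over (X = in TF-a's top targets, Y = in TF-b's top
targets, Z = tissue-specific), tested for partial independence of the
composite XY from Z; pairs whose shared top targets are enriched among
tissue-specific genes become tissue-specific interaction calls.

## Affinity model

For a window $w$ of promoter sequence and a PWM with per-position
probabilities $p_j(b)$ over background $\pi(b)$, the occupancy contribution
is

$$ p_w = \frac{R\,K_w}{1 + R\,K_w}, \qquad
   K_w = \exp\!\Big(\tfrac{1}{\lambda}\sum_j \log \tfrac{p_j(b_j)}{\pi(b_j)}\Big), $$

summed over all windows on both strands. The promoter's affinity for the TF
is $\sum_w p_w$, a continuous quantity that avoids any hard site/non-site
call. Windows containing an ambiguous base (N) contribute 0 — a
conservative convention that never invents affinity.

Tunable parameters (`affinity_params()`):

* `lambda` (default 0.7, dimensionless): flattens the binding-energy
  landscape, i.e. sets mismatch tolerance. The default follows the common
  TRAP-style calibration.
* `R0` (default `1e-4`, dimensionless concentration-times-binding-constant):
  Our default deliberately keeps scoring in the **dilute regime**, where
  $p_w \approx R K_w$ and the per-TF *ranking* reduces to the rank of the
  total Boltzmann weight $\sum_w K_w$ — essentially independent of the
  exact constant. The width-derived calibration of the original TRAP
  software, $R_0 = e^{0.584\,w - 5.66}$, is available as `R0 = "trap"`;
  with soft motifs it saturates $p_w \to 1$ for windows within roughly
  three mismatches of consensus, so on short promoters the score becomes a
  count of chance near-sites (about 20 spurious saturated windows per
  500 bp at width 8) and a single genuine site moves a promoter's rank by
  almost nothing. Since everything downstream consumes ranks only, the
  dilute default is the robust choice; both options are exposed.
* `pseudocount` (default 1 count per matrix cell) guarantees strictly
  positive probabilities, hence finite log-odds.
* Background defaults to uniform (0.25 each) and is configurable, e.g. to
  the promoter-set composition.

Whether to score one or both strands is not dictated by the method
description we follow; both strands are scored (and the choice is
symmetric: a promoter and its reverse complement receive identical
scores). An externally computed gene-by-TF affinity TSV can replace the
internal scorer entirely; all downstream modules depend only on the
affinity table.

Ties in the ranking are broken lexicographically by gene identifier using
a locale-independent radix sort, so ranked lists are byte-reproducible
across platforms and input orderings.

## Pairwise rank-overlap scan

For each unordered pair the hypergeometric upper tail
$P(K \ge k)$ — $k$ shared genes between the top-$L_1$ and top-$L_2$ sets
in a universe of $N$ promoters — is evaluated on the grid
$L_1, L_2 \in \{10, 20, \ldots, 1000\}$ (so $10^4$ cells), and the minimum
is reported as the pair's similarity score. Three numerical conventions
matter:

* the tail is inclusive ($\ge k$) and computed in log space, so scores far
  below $10^{-20}$ remain representable;
* the minimum over $10^4$ dependent tests is reported *uncorrected*,
  exactly as the method uses it — it is a similarity score, not a
  calibrated p-value;
* equal minima are resolved to the smallest $L_1$, then the smallest
  $L_2$, which makes results deterministic (the method description is
  silent on ties; this is our convention).

Overlap counts for all cells are accumulated from one pass over the two
rank vectors (a bucketed two-dimensional cumulative sum), so a pair costs
$O(N + |\mathrm{grid}|^2)$ rather than $10^4$ set intersections.

## Motif-similarity confounder filter

Near-identical PWMs produce overlapping target lists with no biological
cooperation. We quantify motif similarity with a log-odds-of-overlap
statistic in the spirit of the S^max measure: each motif receives a score
threshold calibrated so the expected number of hit events per position
(both strands) under the background equals `hit_p` (default 0.01); for
every start-position offset $\delta$ with $|\delta| \le (w_a+w_b)/2$ the
joint probability that both motifs hit is compared with the independence
product, and the statistic is the maximum over offsets of
$\log\big(P_{\mathrm{joint}}(\delta) / (q_a q_b)\big)$. Offsets whose
windows share no base give exactly the independence product, anchoring
unrelated motifs at 0; aligned near-identical motifs score
$\approx \log(1/q)$.

Numerics: scores are discretized on an integer grid (2048 bins over the
motif's score span), distributions are exact convolutions, and joint
probabilities enumerate only the $4^o$ shared bases of the overlap region
while convolving the remaining positions independently — exact up to grid
resolution whenever $w_a + w_b \le 16$. Wider motif pairs use a seeded
Monte Carlo scan of a long background sequence, which reports a rough
standard error. Hit events are counted per (position, strand) as expected
counts, which keeps the statistic exactly symmetric in its arguments and
invariant under reverse-complementing either motif. The printed range of
the original measure on a 2010-era motif collection is *not* a
reproduction target; only the filtering semantics are.

Filtering keeps pairs with similarity strictly below the cutoff (default
4.0) and *flags* — never silently drops — the rest. For other motif
collections `quantile_cutoff()` reproduces the "90%-quantile of the
off-diagonal similarities" rule with linear interpolation between order
statistics. Because our similarity values are not numerically identical to
the original implementation's, a user-supplied similarity TSV is the
recommended source when exact values matter; downstream code depends only
on the `similarity_matrix` contract.

## Tissue-stratified test

With top-list length fixed at $L = 1000$ (one test per pair per tissue; no
grid, hence no extra multiplicity), the 2x2x2 table counts every universe
gene by (X, Y, Z) membership. Under partial independence of the composite
XY from Z the expected frequencies are
$\hat\mu_{xyz} = \mu_{++z}\,\mu_{xy+}/n$, which preserve the total, all
four xy-marginals and the z-marginal exactly (asserted in tests). The
statistic is the log-likelihood ratio
$G = 2\sum \mu_{xyz}\log(\mu_{xyz}/\hat\mu_{xyz})$ with the standard
$0\log 0 = 0$ convention and natural logarithm, referred to $\chi^2_3$.
No continuity correction is applied; at universe sizes in the thousands
the asymptotics are adequate, which the test suite checks by calibration
on 2000 simulated null tables (fraction of p ≤ 0.05 inside the exact
binomial 99% band, plus a uniformity KS test).

One property of hypothesis (c) deserves emphasis: the composite XY can
depend on Z through *either* margin, so a single TF whose targets are
tissue-coupled drags every pair containing it toward significance. True
co-targeting pairs separate by *magnitude* — in planted fixtures the
planted pair's p-value is orders of magnitude below the marginal-coupling
background — which is why the recovery criterion is the per-tissue
arg-min, and why thresholded call sets should be read together with their
p-values rather than as a flat list.

The $\chi^2$ test is omnibus, but an interaction should mean *more* shared
tissue-specific top targets than chance, not fewer. Calls therefore
additionally require the enrichment direction
$\mu_{111} > \hat\mu_{111}$; the direction flag is always reported so
depleted-but-significant tables remain visible. Tissue genes absent from
the promoter universe are dropped with a logged count rather than imputed.
The companion hypotheses on the same table — mutual independence (df 4)
and conditional independence given Z (df 2) — are implemented as
`threeway_alternative_test()` for completeness but excluded from calling.

## Calling, networks, evaluation

Default thresholds are $10^{-20}$ for the global (untissued) scan,
$10^{-6}$ for tissue contexts and $10^{-11}$ for homogeneous cell-line
contexts, whose larger specific-gene sets produce more significant pairs
at any error level; all are configurable per context. Calls are annotated
against a user-supplied known-PPI edge list: `known_ppi` when the pair is
itself a known edge, `trio` when both members share at least one known
partner (all shared co-factors listed). Enrichment of known PPIs among
calls is the fold change of PPI fractions plus a one-sided Fisher exact
test over the full tested-pair universe; whether that universe is all
pairs or only motif-nonsimilar pairs is an explicit parameter, since the
choice is genuinely ambiguous. Hubs — the "one or two central regulators"
pattern — are operationalized as nodes with degree at least a fraction
(default 0.5) of the maximum degree; the notion is not formalized in the
source method, so the rule is configurable.

## What the synthetic generator does and does not emulate

`generate_fixture()` produces a fully self-contained, seeded world: iid
background promoters at a chosen GC content, one random high-information
PWM per TF (multinomial counts around a 0.94-probability consensus,
JASPAR-like sharpness, width 10 by default), planted pairs whose shared
target genes receive one near-consensus site of *both* motifs at
non-overlapping positions (site strength = per-position mutation
probability, default 0.05), tissue sets mixing a `coupling` fraction of
planted shared targets with random genes, and a PPI list containing the
planted pairs plus decoys. The standard benchmark is 5000 genes, 20 TFs,
500 bp promoters, one planted pair with 150 shared targets, and one
250-gene tissue with coupling 0.6 (150 coupled genes; the tissue-set size
sits inside the 58–1409 range typical of EST-derived tissue sets).

A green planted-pair test establishes that the pipeline recovers a strong,
cleanly planted co-targeting signal and stays quiet on unplanted worlds.
It does *not* establish performance on real promoters: the generator has
no CpG islands, no composition heterogeneity, no chromatin, no correlated
motif content beyond what is planted, and its motif information content is
idealized. Real-data behavior additionally depends on the genome build,
motif release and tissue-set derivation, which is why the headline numbers
of any particular study are out of scope for the test suite.

## Degenerate inputs and edge conventions

* Promoters shorter than a motif score 0 with a warning; empty universes,
  duplicated identifiers, malformed motif records and infeasible overlap
  counts are errors that name the offending record.
* Duplicate gene ids in a TSS BED resolve to the first occurrence (logged);
  windows are truncated at contig boundaries with a warning.
* A (near-)deterministic PWM column triggers a warning in the similarity
  module but proceeds.
* `p = 1` is returned exactly when the observed overlap sits at the lower
  feasibility bound; log-space arithmetic keeps `p <= 1e-300` finite.
* Zero expected cells can only co-occur with zero observed cells under the
  partial-independence fit; any other combination raises an internal
  consistency error rather than producing NaN.

## Known limitations

* The affinity scorer is TRAP-*like*, not a numerical reproduction of the
  original TRAP software; the parameterization is documented above and
  pluggable via the affinity TSV input.
* The similarity statistic reproduces the construction, not the exact
  values, of the original S^max implementation.
* The minimum over the cutoff grid is a score; its null distribution is
  not uniform, and no multiplicity correction across pairs is attempted
  (thresholding raw values is the method's own semantics). A seeded
  permutation calibration can be layered on by shuffling one ranked list
  and re-scanning.
* Tissue heterogeneity, open-chromatin restriction and TF expression are
  outside the model; calls are candidates for experimental follow-up, not
  validated interactions.
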