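---
title: "Methods: diversity, endemicity and isolation-by-distance statistics in cryodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, endemicity and isolation-by-distance statistics in cryodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodiv)
```

cryodiv implements the statistical core of a periglacial / glacial
microbiome survey: within-sample (alpha) diversity, between-sample (beta)
phylogenetic diversity with permutation testing, a threshold-rule
classifier separating endemic from cosmopolitan OTUs, and an
isolation-by-distance (IBD) analysis relating genetic divergence of a clade
to the great-circle distance between its sampling sites. This vignette
documents the models, the conventions chosen where the field leaves room,
and what the seeded generators do and do not emulate.

## OTU definition and rarefaction

`cluster_average_neighbor()` performs agglomerative average-linkage
clustering on a pairwise sequence distance matrix: at each step the pair of
clusters with the smallest *mean* inter-cluster distance is merged, while
that mean is at or below the cutoff (0.03 for the conventional 97%
sequence-identity OTU definition). Average linkage is monotone, so the
greedy merge order is equivalent to cutting the UPGMA dendrogram at the
cutoff height; ties are broken toward the lexicographically lowest label
pair so the partition is deterministic. Cluster indices run `1..K`
(the R convention shared by `stats::cutree()`).

Rarefaction (`rarefy_table()`) subsamples every sample *without
replacement* to a common depth — hypergeometric, not multinomial — which is
what makes the analytic curve of `expected_rarefaction_richness()`,

$$E[S_{d}] = \sum_i \left[1 - \binom{N-N_i}{d}\Big/\binom{N}{d}\right],$$

the exact expectation of the subsampled richness. The default depth is the
smallest sample total. Rarefaction is a single seeded draw; averaging over
repeated draws is left to the caller (the analytic curve makes most
repeated-draw uses unnecessary).

## Alpha diversity

Per sample: observed OTUs; Shannon $H=-\sum p_i \ln p_i$ (natural log by
default, base configurable); bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even when no doubletons are
observed; Berger–Parker dominance $N_{max}/N$; Good's coverage $1-F_1/N$;
and Faith's PD, the branch-length sum of the minimal subtree connecting
the present tips *to the root* (the rooted variant; `include_root = FALSE`
restricts to the subtree spanning the tips, since conventions differ
between implementations). `alpha_summary()` reports per-sample values and
unweighted group means (e.g. ice vs soil).

## Beta diversity

Weighted UniFrac between samples $A$ and $B$ is
$\sum_i b_i\,|A_i/A_T - B_i/B_T|$ over all branches $i$, with $b_i$ the
branch length and $A_i$ the reads of sample $A$ descending from the branch.
The **raw** (non-normalized) form is the default: published dissimilarities
in this literature can exceed 1, which only the raw form produces. The
normalized variant divides by $\sum_j d_j (A_j/A_T + B_j/B_T)$ over tips
$j$ ($d_j$ = root-to-tip length) and lies in $[0,1]$.

ANOSIM ranks all $M = n(n-1)/2$ distances (mid-ranks for ties) and
computes $R = (\bar r_B - \bar r_W)/(M/2)$. Significance is by label
permutation with the add-one convention $p = (1+\#\{R_{perm}\ge
R_{obs}\})/(1+n_{perm})$, so $p > 0$ always; `exhaustive = TRUE` enumerates
all label permutations (the identity included) for an exact p at small
$n$. Groups of size 1 are rejected; sizes below 5 trigger a warning because
the permutation distribution is coarse there, a situation that arises
naturally when only two ice cores are available.

PCoA is classical metric scaling (Gower double-centering of $-D^2/2$,
eigendecomposition, coordinates scaled by $\sqrt{\lambda}$), computed with
`stats::cmdscale`. Negative eigenvalues of non-Euclidean dissimilarities
are reported verbatim — no Lingoes/Cailliez correction — and the
proportion explained is taken over the positive eigenvalues only.

## Endemicity classification

`classify_otu()` applies the identity-threshold rule to each OTU's best
database hit: at $\ge 97\%$ identity the OTU is **non-endemic** and is
sub-classified by the environments of all its $\ge 97\%$ hits (all
perennially cold $\to$ cryophilic; all temperate $\to$ non-cryophilic;
both $\to$ polythermal/cosmopolitan — two names for the same category,
stored as `polythermal_cosmopolitan`). Below 97% the OTU is **endemic**:
subnovel in $[95.5, 97)$, novel in $[88.5, 95.5)$. The published rule
leaves the boundary points undefined ("$>97$" vs "$<97$"); cryodiv closes
each interval on the left — 97.0 is non-endemic, 95.5 is subnovel, 88.5 is
novel — so the categories partition the identity line. Identities below
88.5 are reported as `unclassified` with a warning rather than silently
binned. Only OTUs with $\ge 2$ sequences are classified
(`filter_classifiable()`); singletons are too likely to be artifacts. The
classifier consumes a precomputed match table — it never runs a database
search, whose results are database-version dependent.

## Isolation by distance

`genetic_distance_matrix()` computes uncorrected p-distances with
*pairwise deletion*: for each pair, only columns where both sequences
carry an unambiguous base (A/C/G/T, with U read as T) are compared;
`complete_deletion = TRUE` is available. No substitution-model correction
is applied — at the within-clade divergences involved ($\lesssim$ a few
percent) the p-distance is the standard choice.

`geographic_distance_matrix()` uses the haversine great-circle distance
(via geosphere) with a default mean Earth radius of 6371.0088 km;
6378.388 km is offered because older geographic-distance routines used
that convention, and reproducing their printed kilometre values requires
it.

The Mantel test correlates the $n(n-1)/2$ unordered-pair entries of the
two matrices (Pearson $r_M$) and permutes rows and columns of one matrix
simultaneously; the default tail is positive, matching the directional IBD
hypothesis, with the add-one p convention; `exhaustive = TRUE` gives the
exact enumeration at small $n$. 1000 permutations is the classical setting
for a single global test.

The Mantel correlogram partitions geographic distance into
$k = \lceil 1+\log_2 m\rceil$ (Sturge's rule on the $m$ pairs)
equal-width, right-closed classes over $(0, d_{max}]$; same-site pairs
(distance 0) are placed in class 1 so class sizes sum to $m$. For a
96-sequence analysis, $m = 4560$ and $k = 14$. Each class is tested by a
Mantel correlation between the genetic matrix and the binary
class-membership matrix, *sign-flipped* so that a positive class statistic
means pairs within the class are more genetically similar than average
(positive spatial autocorrelation) — the literature rarely states its sign
convention, so cryodiv fixes one. Per-class p-values are one-tailed in the
direction of the observed statistic (the `vegan::mantel.correlog`
convention) and corrected by a *global* Bonferroni factor,
$p_{bonf} = \min(1, k\,p_{raw})$, not the progressive variant. Classes
with no pairs (or all pairs) are retained with `NA` statistics and flagged
non-significant. Note that with $n_{perm}$ permutations the smallest
attainable raw p is $1/(n_{perm}+1)$, so Bonferroni significance at
$\alpha = 0.05$ requires $n_{perm} \ge 20k - 1$; choose permutation counts
accordingly.

One known discrepancy is documented rather than modelled: for a 52-sequence
analysis ($m = 1326$) the ceiling convention gives 12 classes while a
published analysis of that size printed 11; the exact rule used there (or
trailing-class pruning) is unknowable from the text, so cryodiv keeps the
documented ceiling convention. Whether per-class tests should be restricted
to classes below half the maximum distance (a common correlogram default)
is likewise unstated in this literature; cryodiv tests all classes and
leaves truncation to the caller.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth:

* `simulate_otu_table()` — lognormal(0, 1.5) base abundances (a steeply
  uneven, amplicon-like rank curve), a `group_effect` log-fold shift on 20%
  of OTUs in one group, and per-sample multinomial draws of 5000 reads for
  6+6 ice/soil samples. `group_effect = 0` makes groups exchangeable, the
  basis of the ANOSIM size calibration; the default effect of 2 is the
  clearly-detectable regime.
* `simulate_random_tree()` — coalescent topology with exponential times
  (`ape::rcoal`).
* `simulate_ibd_sequences()` — a stepping-stone transect: a master
  sequence accumulates substitutions between consecutive sites at per-site
  probability $1-e^{-\beta d}$, plus independent per-sequence noise
  substitutions at rate `site_noise`. The expected p-distance between
  sites separated by $L$ km is $\approx 1-e^{-\beta L}$ (closed form, the
  oracle for parameter-recovery tests); a saturation guard rejects
  $\beta$ implying expected divergence above 0.75. Defaults — a 25-site,
  750-km-spaced transect, 4 sequences/site, 800 bp, $\beta = 2\times
  10^{-6}$ /site/km (≈3.5% end-to-end divergence), noise 0.002 — give the
  "slight but significant" IBD regime reported for cryosphere taxa at the
  scale of a global survey (a 24-site × 4-sequence configuration
  reproduces the canonical 96-sequence, 4560-pair geometry). An explicit
  stepping-stone scheme was chosen over a coalescent with migration
  because it has a controllable closed-form divergence-vs-distance curve,
  which is exactly what the Mantel machinery must be validated against.
* `simulate_match_table()` — identities drawn uniformly inside each
  category's band with a 0.1 margin from the 97/95.5/88.5 boundaries (so
  recovery is exact; boundary behaviour is unit-tested separately), and a
  default class mix (70% cosmopolitan, 10% cryophilic, 11%
  non-cryophilic, 4.5% subnovel, 4.5% novel) that reflects a
  mostly-cosmopolitan high-altitude bacterial community in which
  cosmopolitan OTUs are 77% of the non-endemic fraction.

What the generators do **not** emulate: sequencing error profiles and
chimeras, compositional overdispersion beyond multinomial noise, back
mutation near saturation, coalescent gene-tree variance, and real spatial
configurations (sites sit on a meridian transect). Passing
parameter-recovery tests therefore demonstrates that the *statistics* are
implemented correctly, not that real communities satisfy their
assumptions.

## Numerical choices and test scales

Ties in ANOSIM use mid-ranks; all sampled permutation p-values use the
add-one convention; comparisons against permuted statistics use a 1e-12
tolerance so exact ties count as exceedances. Distance matrices must be
symmetric within 1e-12 with an exactly zero diagonal. Chao1 uses the
bias-corrected form throughout.

The validation suite runs at deliberately modest sizes chosen to exercise
every code path: exhaustive permutation checks at $n \le 6$; Mantel
type-I calibration on 500 replicates of 10-point random configurations
(99 permutations); ANOSIM size calibration on 200 replicates of 6+6
exchangeable samples; IBD power and null runs on 100 replicates of a
10-site × 3-sequence transect (199–399 permutations, sized so Bonferroni
significance is attainable); classifier recovery on 1000 planted OTUs.
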