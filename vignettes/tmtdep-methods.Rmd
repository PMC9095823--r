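---
title: "Methods: TMT relative quantification, DEP calling and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT relative quantification, DEP calling and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtdep)
```

# Scope and data model

`tmtdep` starts where the spectral search ends: a peptide × channel matrix
of TMT reporter intensities with a group label per channel (here `Wt` vs
`Hom`), a peptide→protein map, and optional annotation sets in GMT format.
It does not parse raw spectra or search-engine output beyond this reduced
schema, and it takes the peptide→protein map as given (no protein-group
inference).

Missing intensities are empty cells; a stored intensity of 0 is converted
to missing on ingest, because a zero reporter signal means "not observed",
not "observed at zero abundance". All means and medians downstream are
taken over observed values only.

# Relative quantification

Three deterministic steps map intensities $I_{ij}$ (channel $i$, peptide
$j$) to protein relative values:

$$U_{ij} = \frac{I_{ij}}{\operatorname{mean}_i I_{ij}}, \qquad
  NR_{ij} = \frac{U_{ij}}{\operatorname{median}_j U_{ij}}, \qquad
  R_{ik} = \operatorname{median}_{j \in k} NR_{ij},$$

where $j \in k$ ranges over the *unique* peptides of protein $k$ — those
mapping to exactly one protein accession. The centralization mean is the
arithmetic mean (no log-space averaging); the median of an even count is
the midpoint of the two central values. Two identities follow exactly and
are asserted to $10^{-12}$ in the tests: every fully observed peptide row
of $U$ has mean 1, and every channel of $NR$ has observed median 1. The
whole map is invariant to rescaling the entire intensity matrix by any
positive constant, and a rank-one matrix ($I_{ij} = a_i b_j$) collapses to
$R \equiv 1$.

A protein is **quantifiable** when at least one of its unique peptides has
observed values in at least two channels of each group; only quantifiable
proteins enter the differential model. This is a package definition — the
term is used loosely in practice and alternatives (e.g. requiring all
channels) would shrink the tested set.

## Why replicate QC runs on the raw scale

Before normalization, each channel is summarized by the median raw
intensity of every protein's unique peptides, and each channel's median
pairwise Spearman correlation (log scale, pairwise-complete) with its
within-group peers is computed; channels below the floor (default 0.8) are
excluded, and normalization is recomputed on the retained channels, so a
corrupted channel cannot distort the others' medians. Groups of fewer than
three channels are skipped with a warning — a single pair cannot attribute
the discrepancy to one member.

The QC deliberately does *not* use the final relative values: relative
quantification removes exactly the cross-protein dynamic range (three
orders of magnitude in typical proteomes) that makes genuine replicates
correlate. On relative values, two ideal replicates differ only by
independent measurement noise and their correlation is near zero — every
channel would look "bad". On the raw rollup, clean simulated channels
correlate at ≈ 0.99 and a fully decorrelated channel at ≈ 0, so the floor
of 0.8 separates them with a wide margin.

# The differential model

Per protein, the fold change is the ratio of group arithmetic means of $R$
(Hom/Wt) — one number per protein, matching the convention of discovery
TMT reports — and the p-value is a two-sided two-sample $t$ on the
per-channel $R$ values, equal-variance by default (`welch` and a `log2`
transform are options; the discovery-stage test is a convention choice, and
the equal-variance default mirrors the targeted-validation stage). No
multiple-testing correction is applied to DEP calls: the thresholds are
raw-p by design, and FDR control enters only in enrichment.

Calls use strict inequalities — Up iff FC > 1.30 and p < 0.05, Down iff
FC < 0.77 and p < 0.05 — so boundary values are not significant. Severity
bins partition the DEPs: Q1 (FC ≤ 0.667), Q2 (0.667 < FC), Q3
(1.3 < FC ≤ 1.5), Q4 (FC > 1.5). The nominal Q2 upper edge (0.769) sits
just below the Down threshold (0.77); Down calls in the sliver
(0.769, 0.77) are assigned Q2 so the bins remain a partition. Degenerate
zero-variance proteins get p = 1 (equal means) or p = 0 (unequal means,
flagged); volcano tables cap $-\log_{10} p$ at 300.

Label symmetry holds exactly: swapping the group labels maps FC to 1/FC,
leaves the Student p unchanged, and swaps Up and Down calls.

# Enrichment

For each annotation category, the universe $N$ is the background proteins
carrying at least one annotation in that category (annotated-quantified
background — the least biased choice when the true analysis background is
unknown), $n$ the foreground members of that universe, and each term
contributes a 2×2 table $(k, n-k, K-k, N-K-n+k)$. The p-value is the
one-sided over-representation (hypergeometric upper-tail) Fisher exact
test; BH correction is applied within each category separately, since
categories (GO namespaces, pathways, domains) are reported separately.
Fold enrichment is $(k/n)/(K/N)$. Top-term selection breaks p-value ties
by larger fold enrichment, then term ID, so output order is deterministic.

The Q-group matrix runs the same test with each severity bin as
foreground, keeps terms BH-significant in at least one bin, and stores
$-\log_{10} p$ capped at 16 (the cap keeps the subsequent z-scores finite
when p underflows). Rows are z-scored (constant rows become zeros, with a
warning), distances are Euclidean and linkage is average — the defaults of
the common heatmap displays of enrichment profiles.

# PRM validation

The packaged 20-protein validation table carries, per protein, the
targeted (PRM) and discovery (TMT) Hom/Wt ratios and the regulation
direction (16 Down, 4 Up); the loader verifies a checksum. Concordance is
sign agreement against 1.0 with strict inequalities (a ratio of exactly 1
is logged and counted for neither side) plus the Spearman correlation of
the log2 ratios. Applying the discovery fold-change bounds to the 20 TMT
ratios reproduces the recorded direction column 20/20, and all 20 pairs
are sign-concordant. Per-protein targeted signal levels are not part of the
table, so the two-group mean ± SEM / Student-t surface (`group_stats()`)
is exercised on synthetic values only.

# The synthetic-data generator

`simulate_dataset()` draws, in one seeded stream and in a fixed order:
per-protein base abundances (log-uniform over $10^4$–$10^7$, three decades
of dynamic range so the median-based normalization is exercised across
scales), planted Hom/Wt ratios for a fraction of proteins (default 0.2,
direction split 50/50, log2 magnitude $|N(1, 0.3)|$ — the packaged
validation table spans ratios 0.25–4.74), per-peptide ionization
efficiencies (lognormal, sdlog 1), multiplicative lognormal measurement
noise (CV 0.1), two-owner shared peptides (fraction 0.05 — the minimal
structure needed to test the unique-peptide rule), and
intensity-dependent missingness (logistic in log intensity, offset
calibrated so the overall blanked fraction matches `missing_rate`,
default 0.05). Channel counts default to 4 Wt vs 5 Hom, the retained
design of the study the pipeline targets.

The generator emulates multiplicative structure, dynamic range, shared
peptides and detection-limit missingness. It does **not** emulate isotopic
impurity, co-isolation interference, retention-time effects, correlated
biological variation between animals, or peptide-specific digestion
variability — so green tests demonstrate algorithmic correctness and
statistical calibration under the stated model, not performance on any
real acquisition.

## Recovery experiments and their design

Two properties of median normalization shape how recovery is measured:

* **Rank recovery** is evaluated on a spike-in design in which *every*
  protein carries a drawn effect (`frac_regulated = 1`): with 80% of true
  ratios exactly tied at 1, rank correlation over all proteins is capped
  near 0.70 for any estimator — the tie block contributes nothing to the
  rank variance — so ties must be absent for the statistic to be
  informative. Observed: Spearman ≈ 0.99 at 500 proteins, 5
  peptides/protein, CV 0.1.
* **Bias** is evaluated at `frac_regulated = 0.2`: median correction
  assumes a majority-unregulated proteome (as in the study, where ~24% of
  quantifiable proteins were DEPs). When every protein is regulated the
  per-channel medians absorb part of the signal and a global log2 offset
  of ≈ 0.06 appears; at 20% regulated the offset is ≈ 0.003, well under
  the 0.05 tolerance.

Null calibration uses `frac_regulated = 0`: the mean fraction of null
proteins with p < 0.05 sits at ≈ 0.050 (100 replicates × 1000 proteins in
the test suite), and the DEP rate after fold-change thresholds is far
below 0.05, since thresholds only remove calls.

# Problem sizes and runtime choices

The shipped tests use 100 seeded 30-protein matrices for the normalization
identities, 20 trials of ≤ 6 × 6 matrices against a brute-force
three-formula oracle, the exhaustive grid of all 2×2 tables with
$N \le 60$ (~635k tables) against tail enumeration, 100 replicates × 1000
proteins for null calibration, and single 500-protein runs for the
recovery experiments — sizes chosen so the full suite completes in about a
minute while each property is measured at a scale where its tolerance is
meaningful.

# Known limitations

* The mapping is taken as given; ambiguous protein groups are not
  resolved, and a peptide shared by two accessions of one biological
  protein group is discarded rather than attributed.
* The discovery-stage test is an ordinary $t$ — no moderated-variance
  (empirical Bayes) shrinkage — by design, to mirror the raw-p threshold
  convention it implements.
* Normalization is computed after QC exclusion; whether the per-peptide
  means should instead be taken over all original channels is not
  determinable from the conventions this pipeline follows, and the
  post-exclusion choice keeps a bad channel from influencing retained
  ones.
* Enrichment results depend entirely on the supplied annotation sets;
  no ontology propagation or live database retrieval is performed.
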