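---
title: "mirhub: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirhub: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhub)
```

## Scope

`mirhub` identifies candidate *regulatory hub* miRNAs from a paired
experiment: a gene-level log2 expression matrix and a miRNA read-count
table over the same samples, plus the sequence resources needed for target
prediction (3'UTRs, mature miRNAs) and, optionally, for upstream-regulator
scanning (TSS annotation, genome, TRANSFAC-format matrices). The package
assumes expression values are already summarized to genes (probe-level
processing is out of scope) and that miRNA counts are already mapped
(alignment is out of scope); its job starts at normalization and ends at a
ranked hub table and promoter-scan hits.

## The hub statistic

For miRNA $m$ and a differentially expressed gene set $G$ the observed
statistic is

$$X = \frac{T}{\bar L}, \qquad
  T = \#\{g \in G: \text{UTR}(g)\ \text{has a qualifying seed site for}\ m\},
  \quad \bar L = \text{mean UTR length of}\ G\ \text{(kb)}.$$

The null distribution draws $N$ gene sets of size $|G|$ uniformly without
replacement from the universe and recomputes $X$ on each draw; the
empirical p-value is the add-one right tail $p = (1 + \#\{X_r \ge X\})/(N+1)$.
Up-regulated miRNAs are tested against the down-regulated gene set and
down-regulated miRNAs against the up-regulated set — the pairing expected
of a repressive regulator. Results are ranked by $p$ ascending, ties by
$X$ descending, then lexicographically, so reports are deterministic.

Decisions taken where the procedure description left room:

* **Length normalization on both sides.** "Normalizing the target count to
  the average 3'UTR length" is read as dividing $T$ by $\bar L$ for the
  observed set *and for every null draw*. This makes the statistic a
  density (targets per kb) and removes the bias of a gene set that happens
  to have long UTRs. The alternative — biasing the null *sampling* toward
  length-matched genes — is available via
  `hub_test_config(length_weighted = TRUE)` but is not the default, since
  both-sides division applies one identical, transparent correction.
* **Universe = expressed genes with a UTR**, not a whole-genome
  annotation: the resampled sets should be exchangeable with the observed
  set, and the observed set can only contain genes that were on the array
  and have a UTR. Configurable via `hub_test_config(universe = ...)`.
* **Add-one empirical p.** Guarantees $p \ge 1/(N+1) > 0$ and an exact
  rational representation; with $N = 10{,}000$ (the default) the floor is
  $\approx 10^{-4}$.
* **$-\log_{10}$** is used for the reported `neg_log10_p` (the log base is
  a labeling choice; base 10 is stated in the column name).

Assumptions worth keeping in mind: resampling treats genes as
exchangeable, so correlated gene families inflate significance slightly;
the test conditions on the DE gene set (uncertainty in the DE call itself
is not propagated); and $N$ bounds the attainable significance.

## Target prediction

Seed matching follows the TargetScan site taxonomy. For a mature miRNA
(RNA or DNA alphabet; everything is canonicalized to DNA internally) the
mRNA-sense words are: 8mer = revcomp(nt 2–8) + A, 7mer-m8 = revcomp(nt
2–8), 7mer-A1 = revcomp(nt 2–7) + A, 6mer = revcomp(nt 2–7). A *locus* is
an occurrence of the 6-nt seed core; its flanking bases decide its single
strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer), so one locus is never
counted as two sites. The default qualifying set {8mer, 7mer-m8, 7mer-A1}
is the canonical high-confidence taxonomy; 6mer can be added
(`site_types`), and adding it can only grow a target set. Matching is
strand-specific — sites exist only on the given 5'→3' mRNA sequence.
Conservation filtering, context scoring and 3'-supplementary pairing are
deliberately not implemented; predicted target sets are therefore more
inclusive than a conservation-filtered tool would give, which is
acceptable because the hub test compares the same predictor against its
own resampled null.

## Differential expression gates

* Genes: quantile normalization, then per-gene two-sample **equal-variance
  t-tests** (the classical choice for small balanced microarray designs;
  Welch via `var_equal = FALSE`), BH-FDR over all genes, gate at
  `q < 0.1` (strict) and linear `|FC| >= 1.5` (inclusive). A one-way
  ANOVA F across all groups is provided (`anova_f_test`) but the
  per-condition sets that feed the hub test come from pairwise
  condition-vs-reference t-tests, matching the per-condition overlap
  accounting.
* miRNAs: retain a miRNA if its **raw** count reaches 25 in at least one
  sample (the "any" rule; a "total" rule is provided). The per-sample rule
  was chosen because a miRNA robustly detected in only one condition —
  e.g. strongly induced — should not be discarded. Normalize to counts
  per million uniquely mapped reads, test on `log2(CPM + 1)` (pseudocount
  1 avoids log of zero; configurable), call significance at raw
  `p < 0.05`. No multiple-testing gate is applied to miRNAs — the panel is
  small and the downstream hub test provides its own null — but a BH
  column is emitted for transparency.
* Degenerate variance conventions (documented and tested): zero pooled
  variance with equal means gives $t = 0,\ p = 1$; zero pooled variance
  with unequal means gives $t = \pm\infty$, $p$ = smallest positive
  double, and a `degenerate` flag.
* Quantile-normalization ties: tied values within a column receive the
  mean of the reference values their rank range spans. This keeps the
  procedure symmetric in tied entries; alternatives differ in the fourth
  decimal. The procedure is idempotent to float round-off on tie-free
  data.

## PWM promoter scanning

Promoters are 1 kb upstream + 500 bp downstream of the TSS, on the
transcribed strand, 0-based half-open internally: plus-strand TSS $t$ →
$[t-1000,\ t+500)$; minus-strand $t$ → $[t-499,\ t+1001)$
reverse-complemented, so the TSS always sits at promoter offset 1000.
Intervals running off a chromosome end are truncated with a warning.

TRANSFAC count matrices become log-odds PWMs (bits):
$\log_2\frac{(c_{bj}+q)/(\sum_b c_{bj}+4q)}{\pi_b}$ with pseudocount
$q = 0.25$ per cell and uniform background $\pi$ by default (a
promoter-composition background can be supplied). Score calibration is
exact: per-column score distributions are discretized to 0.01-bit bins and
convolved, giving the full distribution of a random background word's
score. Windows are scored on the same binned scale, so the p-value lookup
is exact for the binned score; the binning error on any score is at most
`width * 0.01 / 2` bits. Hits are called at tail probability
$< 5\times10^{-6}$ (strict), on both orientations by default (binding-site
orientation is not generally meaningful); minus-orientation hits are
reported at the plus-strand offset of the window. Windows containing N are
skipped and counted. The original tool's internals are not public, so
absolute hit lists are not claimed to match any published table — the
decision rule (exact score p-value, $5\times10^{-6}$) is what is
reproduced.

## The synthetic world

The generator exists so every downstream stage has testable ground truth.
Its defaults are fixed, stated conditions — not knobs:

| parameter | default | why |
|---|---|---|
| genes × miRNAs | 2,000 × 50 | desk-scale universe; large enough for stable resampling, small enough for 100-seed studies |
| UTR length | Normal(800, 200) nt, ≥ 30 | unimodal, realistic mammalian-UTR scale |
| GC fraction | 0.5 | neutral background for seed matching |
| groups | naive, cond1, cond2 × 4 replicates | the three-condition paired design |
| hub 1 / hub 2 | down in cond1 / up in cond2 | targets move opposite their hub |
| target fraction | 0.4 | planted 8mer per target, disjoint target sets |
| target effect | ±1.0 log2 | comfortably above the 1.5-fold gate |
| replicate noise | 0.25 log2 | typical array replicate scatter |
| miRNA counts | NB, dispersion 0.2, lognormal(log 500, 1) baselines | overdispersed counts around realistic abundances |
| hub count shift | 3.5 log2 (~11-fold) | see below |
| library sizes | Uniform(0.8–1.2) × 10⁶ | per-sample totals for CPM |

Two calibration notes. Planted sites *overwrite* bases rather than insert,
so the UTR length distribution is untouched and the length-normalization
contract stays clean. The hub's own count shift is 3.5 log2 units: with
the stated NB dispersion (0.2) and 4 replicates, a Student's t at
p < 0.05 detects a 2–2.5 log2 shift in only ~90% of seeds (occasional
heavy-tailed draws inflate the pooled variance), while the scenario's
planted hub is required to be reliably detectable; 3.5 log2 achieves that
and matches the intuition that a hub worth the name is among the most
strongly regulated miRNAs. Fraction-to-count rounding is
nearest-integer-ties-up throughout.

What the generator does **not** emulate: probe-level artifacts,
between-gene correlation, isomiRs, mapping bias, conservation structure,
and chance seed sites are left unrecorded in the truth table (tests that
need exactness therefore compare against the predictor's output, not the
truth table). A green end-to-end test establishes that the pipeline's
statistics behave correctly under this stated world — not that any
particular biological dataset would yield the same hubs.

## Determinism

Every generator and the resampler are pure functions of (config, seed);
seeds are scoped (the caller's RNG stream is saved and restored).
`identify_hubs` derives one sub-seed per miRNA from the configured seed,
and `run_pipeline` writes a manifest (parameters, seeds, input/output
checksums, stage counts; no timestamps) so identical configurations
produce byte-identical output directories.

## Known limitations

* Observed hub p-values are bounded below by $1/(N+1)$; rankings among
  equally saturated miRNAs then fall back to $X$.
* The miRNA t-test is only approximately calibrated on log-CPM of
  overdispersed counts; the false-positive rate check in the test suite
  allows a small tolerance around the nominal 5%.
* Gene-gene correlation is not modeled in the resampling null; on real
  data, hub p-values are anti-conservative to a degree that depends on
  co-regulation of the target pool.
* Threshold choices upstream (FDR 0.1 vs 0.05, FC gate) change the gene
  set and hence hub ranks; both are exposed as configuration, and the
  per-figure inconsistency in the source material is not adjudicated.
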