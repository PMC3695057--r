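# mirhub

Identification of **regulatory hub miRNAs** from paired mRNA / miRNA
differential-expression data.

## The problem

When a cell population changes state — for example, regulatory T cells
adapting to a type-1 versus a type-2 inflammatory environment — expression
profiling yields two parallel readouts: a gene-level expression matrix and a
small-RNA read-count table. A single miRNA can repress hundreds of
transcripts, so a natural question is whether any differentially expressed
miRNA *coordinates* the observed mRNA program. `mirhub` answers this with a
resampling test: a miRNA is a candidate **regulatory hub** if its predicted
targets are over-represented among the oppositely regulated genes (an
up-regulated miRNA among down-regulated genes, and vice versa) relative to
random gene sets.

## The statistic

For a miRNA *m* and a differentially expressed gene set *G*:

- targets are predicted by seed matching over 3'UTRs using the TargetScan
  site taxonomy (8mer, 7mer-m8, 7mer-A1; 6mer optional):
  *T* = #{g in G : UTR(g) carries a qualifying site for m};
- because longer UTRs accumulate more chance sites, *T* is normalized by
  the mean 3'UTR length of *G* in kilobases: *X = T / L̄*;
- the null distribution resamples *N* = 10,000 gene sets of size |G|
  uniformly without replacement from the expressed-gene universe and
  recomputes *X* on each;
- the empirical p-value is the add-one right tail
  *p = (1 + #{r : X_r ≥ X}) / (N + 1)*.

Upstream gates follow standard practice: quantile normalization, per-gene
two-sample t-tests with Benjamini–Hochberg FDR < 0.1 and linear fold change
≥ 1.5 for genes; a ≥ 25 raw-read filter, counts-per-million normalization
and Student's t at p < 0.05 for miRNAs. A companion module parses
TRANSFAC-format matrices, calibrates exact PWM score p-values by dynamic
programming, and scans promoters (1 kb upstream + 500 bp downstream of the
TSS, hits called at p < 5×10⁻⁶) for transcription factors upstream of a hub
miRNA.

## Worked example

Everything below is runnable as-is: inputs come from the bundled
synthetic-data generator, which plants two ground-truth hubs (one
down-regulated miRNA whose targets go up in condition 1, one up-regulated
miRNA whose targets go down in condition 2).

```r
library(mirhub)

cfg <- pipeline_config(scenario = scenario_config(rng_seed = 42),
                       n_iterations = 1000,
                       outdir = "scratch/demo", rng_seed = 42)
res <- run_pipeline(cfg)
res$truth$hubs
#>       condition mirna_id direction
#> cond1     cond1  mir-001      down
#> cond2     cond2  mir-002        up
head(res$hubs$cond1[, c("mirna", "direction", "T", "L_kb", "X",
                        "null_mean", "empirical_p", "significant")], 3)
#>     mirna direction   T      L_kb         X null_mean empirical_p significant
#> 1 mir-001      down 417 0.7979089 522.61607 233.12466 0.000999001        TRUE
#> 2 mir-040      down  37 0.7979089  46.37121  37.56277 0.072927073       FALSE
```

Reading the top row: all 417 genes up-regulated in condition 1 carry a
predicted site for `mir-001` (the planted targets dominate the gated set);
with a mean UTR length of 0.80 kb that is X = 523 targets/kb against a
null expectation of 233, and none of the 1,000 resampled gene sets reached
the observed value, so p = 1/1001 ≈ 0.001 — the planted hub is recovered
as the top-ranked, significant candidate (dashed-line threshold p < 0.05).
`mir-040`, a background miRNA, sits near its null mean. The same holds for
`mir-002` against the down-regulated genes of condition 2
(X = 506 vs null 226, p ≈ 0.001). Per-stage tables (DE genes, miRNA DE, gene-set
overlap between conditions, a manifest with seeds and checksums) are
written under `outdir`.

The same workflow is scriptable from the shell:

```sh
Rscript inst/cli/mirhub.R simulate --out scratch/sim --seed 42
Rscript inst/cli/mirhub.R report --out scratch/report --seed 42 --iterations 1000
Rscript inst/cli/mirhub.R --help    # lists every default
```

## Vignette

`vignettes/mirhub-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic generator
does and does not emulate, and known limitations.
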