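# spliceRewire

Tools for asking, end to end, what happens when a splicing regulator is
silenced: which isoforms switch, which exons change inclusion, which
RNA-binding proteins plausibly drive the changes, which protein-protein
interactions are rewired as domains are spliced in or out, and how the
affected events behave in a tumor cohort. The motivating setting is the
joint knock-down of the epithelial splicing regulators ESRP1/ESRP2 in a
luminal breast-cancer line, but every component is generic.

## What it computes

- **Isoform fractions and switches.** IF = TPM<sub>iso</sub>/TPM<sub>gene</sub>
  per sample; genes < 1 TPM and isoforms with IF < 0.01 are filtered;
  dIF = mean IF(silencing) − mean IF(control); a switch needs
  |dIF| > 0.1 and BH-adjusted p ≤ 0.05 from a replicate-aware t-test.
- **Differential splicing events.** PSI = (I/eL<sub>I</sub>)/(I/eL<sub>I</sub> + S/eL<sub>S</sub>)
  from inclusion/skipping junction counts; events need ≥ 10 supporting
  reads in ≥ 2 samples per condition, |dPSI| ≥ 0.1 and q ≤ 0.05; tallies
  by event type (ES, MXE, A5SS, A3SS, RI).
- **RBP motif enrichment.** PWM scanning of event regions (±200 nt) at
  match p < 0.001 with exact DP-based p-values; z-score of the regulated
  events' hit frequency against 100 control sets of non-regulated
  events, per motif × region × direction; enriched at z > 1.96.
- **Domain-resolved interaction network.** PPI edges kept only with a
  supporting domain-domain interaction pair; per condition an
  Interaction Score IS = (Σ IF of domain-carrying isoforms of A) ×
  (Σ IF of domain-carrying isoforms of B); rewiring scored as
  dIS = log2((IS<sub>silencing</sub> + ε)/(IS<sub>control</sub> + ε));
  hub ranking, subnetwork extraction, GraphML/SIF/TSV export.
- **Cohort statistics.** Spearman correlation of event inclusion with
  regulator expression, median-split Wilcoxon tests, Kruskal–Wallis and
  chi-square clinical associations, log-rank + hazard-ratio survival
  analysis, pathway-score correlations, tumor-vs-normal dPSI.
- **Synthetic data with planted ground truth** for all of the above
  (`simulate_all()`), and a one-call pipeline (`run_pipeline()`) with a
  reproducibility manifest.

## A worked example

```r
library(spliceRewire)

cfg <- list(simulate = list(n_genes = 120,
                            n_events = c(ES = 100, MXE = 8, A5SS = 8,
                                         A3SS = 8, RI = 4),
                            n_cohort_samples = 120, n_normal = 25),
            seed = 11)
manifest <- run_pipeline(cfg, "run1")
#> [..] stage simulate   done in 17.0s
#> [..] stage quantify   done in 0.0s
#> [..] stage switches   done in 0.6s
#> [..] stage events     done in 0.5s
#> [..] control pool under p < 0.5 criterion too small; falling back to p > 0.5
#> [..] control pool (16) smaller than regulated set (18); using sets of 16
#> [..] stage motifs     done in 8.7s
#> [..] stage network    done in 0.6s
#> [..] stage cohort     done in 4.6s
#> [..] pipeline complete

nodes <- read.delim("run1/nodes.tsv")
head(nodes, 3)
#>   gene_id degree frac_dis_negative rank
#> 1   G0046     12                 1    1
#> 2   G0016      4                 1    2
#> 3   G0032      2                 0    3
```

The top node is the simulation's planted hub: a switch gene whose
domain-carrying isoform collapses upon silencing, so all 12 of its
domain-supported interactions have dIS < 0 (`frac_dis_negative = 1`) —
the qualitative pattern expected of a hub whose interaction domain is
encoded by a skipped exon. `run1/switches.tsv`, `events.tsv`,
`motif_enrichment.tsv`, `edges.tsv`, `correlations.tsv`, `survival.tsv`
and `manifest.json` hold the per-stage results; rerunning with the same
config reproduces identical checksums.

Individual stages are plain functions on plain containers
(`expression_set`, `junction_counts`, event tables as data frames), e.g.

```r
ift <- compute_isoform_fractions(es)        # es: expression_set
sw  <- call_isoform_switches(ift)           # dIF, p, q, significance
ps  <- compute_psi(jc)                      # jc: junction_counts
ev  <- call_differential_events(ps)         # dPSI calls with filters
```

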