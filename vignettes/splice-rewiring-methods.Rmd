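---
title: "Quantifying splicing changes and the interaction rewiring they imply"
author: "spliceRewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing changes and the interaction rewiring they imply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRewire)
```

## The problem

Silencing a splicing regulator (the motivating case is the joint
knock-down of the epithelial splicing regulators ESRP1 and ESRP2 in a
luminal breast-cancer cell line) rewires the transcriptome at several
levels at once: cassette exons change their inclusion, isoform usage
shifts within genes, and — because exons encode protein domains — the
protein-protein interactions mediated by those domains are gained or
lost. This package implements that analysis chain as composable pieces:

1. **Isoform usage.** From an isoform × sample TPM table, the isoform
   fraction IF = TPM~iso~/TPM~gene~ is computed per sample, and
   dIF = mean IF(silencing) − mean IF(control) per isoform. An isoform is
   a *switch* when |dIF| > 0.1 and the BH-adjusted p ≤ 0.05.
2. **Event-level splicing.** From inclusion/skipping junction counts,
   PSI = (I/eL~I~)/(I/eL~I~ + S/eL~S~) per sample (effective lengths
   default to equal), dPSI between condition means, with an expression
   prefilter (≥ 10 supporting reads in ≥ 2 samples of each condition)
   and the same effect/significance rule at |dPSI| ≥ 0.1, q ≤ 0.05.
3. **RBP motif enrichment.** Event regions (cassette exon and both
   flanking introns, each extended ±200 nt) are scanned against a PWM
   library at a match p < 0.001; the hit frequency in the regulated
   events is standardised against 100 control sets drawn from
   non-regulated events, and z > 1.96 flags enrichment, separately per
   direction of splicing change.
4. **Domain-resolved network.** Protein interactions supported by at
   least one domain-domain interaction are scored per condition with an
   Interaction Score — the product over the two partners of the summed
   condition-mean IFs of the isoforms carrying a qualifying domain — and
   compared between conditions as dIS = log2((IS~silencing~ + ε)/(IS~control~ + ε)).
   A lost interaction has dIS < 0.
5. **Cohort statistics.** Event inclusion in a tumor cohort is linked to
   regulator expression (Spearman), median-split strata (Wilcoxon,
   chi-square, Kruskal–Wallis), survival (log-rank plus a two-group
   hazard ratio) and pathway activity scores.

Every step can be exercised on synthetic data with planted ground truth
(`simulate_all()`), which is how the package tests itself.

## Statistical choices

**Replicate test.** Switch and event calls use a two-sided
pooled-variance t-test on per-replicate IF or PSI values. With equal
replicate numbers per condition and a shared noise model, the pooled test
is exact under the null; at n = 3 it is also the difference between a
usable and an unusable test, because the Welch–Satterthwaite
approximation can collapse to ~2 degrees of freedom and cap attainable
p-values near 0.01, which no BH correction can rescue. When both groups
are numerically constant the t statistic is undefined and a strict
separation rule takes over: the call is significant only when every
control value differs from every silencing value (p set to 0), otherwise
p = 1. No variance floor is injected.

**BH families.** One family per run and per item kind: all tested
isoforms in a switch analysis, all tested (expressed) events in an event
analysis, all events per regulator gene in cohort correlations. The
family is recorded in the output attributes.

**Effect-size boundaries.** The usage filter is strict (|dIF| > 0.1) and
the event filter inclusive (|dPSI| ≥ 0.1), following the asymmetric
phrasing of the conventions they come from; both are arguments.

**PSI path lengths.** PSI is defined as a path ratio; effective lengths
default to equal (raw ratio) and can be supplied per event when the
quantifier reports them.

**Missingness.** A gene with zero TPM in a sample yields a missing IF
for that sample (never 0), excluded from condition means. An event with
I + S = 0 in a sample is non-informative there; an event non-informative
everywhere is dropped with a logged reason. An isoform that passes the
IF ≥ 0.01 retention cutoff in only one condition contributes a mean of 0
in the other and is flagged `partial`.

## The motif scan and its null

Motifs are matched on the transcript-sense strand only (RBPs bind RNA),
with U→T; minus-strand event regions are reverse-complemented before
scanning, and their upstream/downstream labels refer to the transcript.
Window scores are background-normalised log2 odds with a small
pseudocount (1% of background) so that consensus-only matrices stay
finite. Match p-values come from the exact null distribution of the
integer-scaled window score, built by dynamic programming over motif
positions under an independent-background null — the same construction
FIMO uses — so the p < 0.001 threshold is exact for the scores actually
scanned, and the unit tests verify the scan against exhaustive
enumeration of all 4^L words for motifs up to length 6. `N` bases
contribute zero log-odds. Overlapping hits all count.

**Frequency unit.** The enrichment "frequency" is hits per kilobase of
scanned sequence per set, which stays exactly size-matched even after
boundary clipping; the proportion of events with ≥ 1 hit is available as
an alternative unit.

**Control sets and calibration.** The 100 control sets are drawn without
replacement (within a set) from the non-regulated pool, implemented
verbatim as |dPSI| < 0.01 with p < 0.5 and switchable to the p > 0.5
reading (`p_greater = TRUE`), since small estimated effects force large
p-values and can leave the printed pool nearly empty at moderate read
depth; the pipeline falls back to the p > 0.5 reading, with a logged
notice, when the printed pool cannot supply the sets. Two caveats the
calibration tests make explicit: the z-score is anti-conservative when
the pool is not much larger than the regulated set (nearly-coincident
control sets underestimate the between-set variance), and when per-set
hit counts are small the Poisson skew inflates the z > 1.96 rate. The
null-calibration test therefore runs in the regime the method assumes —
a pool roughly an order of magnitude larger than the regulated set and
per-set expected counts in the tens — where the observed null rate is
below 5%. On data where those conditions fail, z-scores should be read
as rankings rather than calibrated tail probabilities.

## The interaction score

The IS sentence in the originating method description is compressed; the
reading implemented here is the only one that yields one scalar per edge:
for an edge (A, B), sum the condition-mean IFs of A's isoforms that carry
at least one A-side domain participating in a qualifying domain pair
(each isoform counted once, however many pairs it supports), likewise
for B, and multiply the two sums. Self-interactions square the carrier
sum. Multiple qualifying domain pairs do not weight the score; they are
kept as edge annotation. Under per-gene IF normalisation 0 ≤ IS ≤ 1, and
dIS is antisymmetric under condition swap when ε = 0. The default
pseudocount ε = 1e-3 keeps dIS finite when an interaction is completely
absent in one condition; it is a flag, and all analytic identity tests
run at ε = 0. Self-loops add 2 to a node's degree, the convention used
for the reported degree ranges.

Isoforms enter the network only when their median TPM exceeds 1 in both
conditions, and the IFs entering IS are the condition means from the
isoform-fraction analysis. The regulated subnetwork keeps edges touching
a gene that both harbours a significant exon-skipping event and whose
cohort inclusion correlates (p < 0.05) with the regulators' expression —
with *both* regulators by default, switchable to *either*.

## Cohort conventions

Median stratification puts samples strictly above the median in the
"high" group, ties to "low". Hazard ratios are per-stratum (high vs low
inclusion) from a two-group Cox fit, with the log-rank test for
significance — the minimal model that produces one HR per event; this
choice is recorded in the output rather than assumed per-unit-PSI.
Chi-square tests run without continuity correction and are flagged
unreliable when any expected cell is below 5. The pathway activity score
is a deliberately transparent stand-in for pathway-guided enrichment
tooling: the mean across the gene set of per-gene z-scored log2(x + 1)
expression, restandardised per pathway; it is labelled as such in the
outputs and not claimed equivalent to any external tool. Pathways are
clustered by average linkage on 1 − ρ between their score vectors, and
correlations with |ρ| > 0.3 are reported.

Event matching between a pipeline run and a cohort table requires equal
type, chromosome and strand and ≥ 1 bp overlap of the alternative
regions, resolved one-to-one by maximal overlap (ties: smaller midpoint
distance, then lexicographic ids). Assembly conversion is an input
preparation concern and is out of scope.

## What the generator emulates — and what it does not

`simulate_all()` produces every input the pipeline consumes, under one
master seed (per-stage seeds are derived from it; identical
configurations give byte-identical outputs):

- **Expression**: two conditions × 3 replicates (the standard design for
  this kind of knock-down experiment), gene TPMs drawn mostly above and
  partly below the 1-TPM filter, Dirichlet isoform fractions, and a
  planted switch on a designated isoform pair of a configurable fraction
  of genes — shifted by exactly `planted_dif` (default 0.3, a clearly
  biological but not extreme usage change). Noise is multiplicative
  log-normal on TPM (sd 0.15 by default, a mid-range dispersion for
  bulk RNA-seq replicates; the source data's own dispersion is not
  reported, so this is a free parameter, not an estimate).
- **Junction counts**: Poisson totals around 100 reads per event
  (binomially split by the true PSI), the simplest model matched to the
  estimator under test; a fraction of events is simulated at ~3 reads to
  exercise the read-support filter. Regulated events are planted on
  exon-skipping events of switch genes, consistent with ES dominating
  regulated events in this biology.
- **Interactome**: each switch gene's domain sits on the isoform
  repressed by the silencing (an exon-skipping event removing the
  domain-coding exon), stable genes carry their domain on all isoforms;
  a hub of configurable degree is wired to stable partners so all its
  edges lose interaction upon silencing; decoy PPIs without domain
  support test the network filter; true IS/dIS are stored from the true
  IFs at ε = 0.
- **Sequences and motifs**: i.i.d. uniform background; consensus
  occurrences of the first motif planted into the exon regions of
  up-regulated events so the expected hit rate is `motif_plant_rate`
  times background (rate 1 = no planting).
- **Cohort**: a Gaussian copula plants a target Spearman correlation
  (0.45, the magnitude reported for the strongest event-regulator
  correlations in this setting) between a designated event's PSI and a
  regulator's expression at n = 774; exponential survival with the
  hazard multiplied by `planted_hr` (0.73) above the median PSI;
  a tumor-minus-normal inclusion shift of −0.33 at 773 vs 113 samples;
  two anticorrelated 10-gene pathway modules.

The generator does **not** simulate read-level data, sequencing error,
positional read biases, batch effects, isoform-assignment uncertainty,
or correlated noise across genes. Passing the planted-recovery tests
therefore demonstrates that the estimators and filters do what they
claim under their own assumptions — not that those assumptions hold in
any particular real data set.

## Problem sizes used in the self-tests

The test suite and the acceptance script size their simulations so that
calibration claims rest on enough items: ≥ 500 planted switches and
≥ 500 planted regulated events for sensitivity/FDR (n = 900 genes,
1250 ES events), ≥ 1000 tested items for null calibration, 50 motifs ×
3 regions × 2 directions for motif null calibration with a non-regulated
pool about nine times the regulated set, 20 seeded runs for motif power
and hazard-ratio coverage, and the cohort sizes above for the planted
correlation and group-shift recoveries. Network oracle equivalence is
checked edge-for-edge against a brute-force reimplementation on 20
random fixtures of 10–50 genes.

## A small worked run

```{r example, eval = FALSE}
cfg <- list(simulate = list(n_genes = 120,
                            n_events = c(ES = 100, MXE = 8, A5SS = 8,
                                         A3SS = 8, RI = 4),
                            n_cohort_samples = 120, n_normal = 25),
            seed = 11)
manifest <- run_pipeline(cfg, "run1")
nodes <- read.delim("run1/nodes.tsv")
head(nodes)   # the planted hub tops the degree ranking
```

## Known limitations

- The replicate t-test is a pragmatic substitute for count-aware
  hierarchical models of differential splicing; it ignores the
  mean-variance relation of counts and will be conservative at very low
  depth (where the read filter removes most events anyway).
- The motif z-score caveats above: it is a ranking statistic outside the
  large-pool, moderate-count regime.
- The IS treats all qualifying domain pairs as equivalent and
  unweighted, and interaction loss is inferred purely from isoform
  usage — no structural or affinity information enters.
- Cohort associations are single-covariate; no multivariable survival
  modelling is attempted.
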