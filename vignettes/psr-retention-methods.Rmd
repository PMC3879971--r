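---
title: "Methods: duplicate-gene retention and protein subcellular relocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicate-gene retention and protein subcellular relocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrsurv)
```

## The question and the model

After a gene duplicates, one copy is usually lost. Protein subcellular
relocalization (PSR) — a duplicate pair whose two protein products are
targeted to different compartments — is one proposed route to retention:
a relocalized copy can acquire a new context and therefore new value.
`psrsurv` implements a survival-analysis test of this idea. Each duplicate
pair contributes one observation whose "survival time" is its synonymous
divergence Ks (substitutions per synonymous site), a clock-like proxy for
time since duplication, and whose binary covariate `dp` encodes
relocalization status (`dp = 0` relocalized, `dp = 1` nonrelocalized).
The Cox proportional-hazards model

$$h(t \mid DP) = h_0(t)\, e^{\beta \cdot DP}$$

leaves the baseline hazard $h_0(t)$ — the overall loss process, which need
not be constant — unspecified and estimates only $\beta$ by maximising the
partial likelihood. The hazard ratio $e^\beta$ compares death rates of
nonrelocalized versus relocalized pairs: $e^\beta > 1$ means relocalized
duplicates die more slowly, i.e. relocalization promotes retention. All
records are treated as observed events; no censoring mechanism is
modelled, because the data are the Ks values of pairs that exist.

Upstream of the model sits a pair-detection and annotation pipeline, and
downstream of it a windowed hazard-ratio table: the model is refit on
nested open Ks windows (0, 0.05) … (0, 1) so the effect can be examined
as a function of duplicate age. The ceiling of 1 limits multiple-hit
saturation in Ks; the optional floor of 0.01 (`ks_min`) removes
nearly-identical pairs whose localization predictions are least reliable,
as a sensitivity analysis.

## Pipeline stages and their parameters

**Representative proteome.** One CDS represents each gene: the longest,
with equal lengths broken by the lexicographically smallest transcript ID
so runs are reproducible. Translation uses the standard genetic code by
default (`genetic_code` is configurable per species, since taxa with
nonstandard codes exist); an incomplete trailing codon is trimmed with a
warning, one trailing stop is stripped, and an internal stop excludes the
gene with a warning rather than aborting a whole-genome run.

**Pair detection.** All-vs-all Smith–Waterman local alignment (BLOSUM62,
gap open 11, extend 1 — the conventional protein-search scoring) with
bit scores and e-values from Karlin–Altschul statistics
($\lambda = 0.267$, $K = 0.041$, the gapped BLOSUM62 constants) over a
search space of `len(a) × len(b) × database_count`. Candidate pairs
require e-value ≤ 1e-3 and a BLAST score ratio ≥ 0.33, both inclusive.
The BSR here is `bit(A,B) / max(selfbit(A), selfbit(B))` — symmetric and
the more conservative of the two per-query ratios; requiring both
per-query ratios instead is available via `compute_bsr(convention =
"both")`. The reciprocal filter then demands ≥ 80% coverage of *both*
proteins' full lengths and a length-dependent identity floor: 30% for
alignments of ≥ 150 columns, rising for shorter ones along the
twilight-zone curve $p(L) = n_0 + 480\,L^{-0.32(1+e^{-L/1000})}$ with
$n_0$ calibrated so the curve meets 30% continuously at $L = 150$
(short alignments reach ~30% identity by chance far more easily, so they
need a stricter cut). Pairs used for localization comparison pass a
further ≥ 50% identity gate. When BLAST tabular output is supplied
instead of the internal aligner, its e-values are taken verbatim and the
best-scoring HSP represents each unordered pair.

**Families.** Filtered reciprocal pairs form a graph; stringent double
linkage takes its maximal cliques as clusters (three proteins cluster only
if all three links pass), and clusters sharing members merge by single
linkage into superclusters until each protein sits in exactly one family.
Clique enumeration uses igraph's Bron–Kerbosch with pivoting; a
configurable size cap warns on pathological families. The gene-conversion
exclusion removes every protein with more than five identifying matches —
read as pair-graph degree > 5 on the original graph, single pass, since
"identifying matches" counts a gene's pairings rather than its family's
size. Two-member families are kept: pairs are the analysis unit.

**Divergence.** Each reciprocal pair's proteins are realigned end-to-end,
back-translated to a codon alignment (protein gap → `---`), and Ks/Ka are
estimated with the Nei–Gojobori (1986) method: synonymous site counts
from per-codon mutation fractions averaged over the two sequences,
difference counts averaged with equal weights over minimal mutation
pathways, and the Jukes–Cantor correction applied to the proportions. The
estimator is deliberately the fully specified, desk-checkable one — the
downstream survival analysis consumes only relative Ks — and a reader for
external `yn00` output (`read_yn00()`) lets real-data runs use a
codon-frequency-aware estimator instead. Numerical rules: pathways
passing through stop codons are excluded from averaging (falling back to
unrestricted averaging in the measure-zero case where every pathway does);
substitutions *to* stop codons are excluded from site counting; columns
with gaps, ambiguous bases or stop codons are dropped; a proportion at or
beyond 3/4 makes the log argument nonpositive, so the estimate is flagged
invalid (saturated) rather than returned as a number; `omega = ka/ks` is
undefined (NA) at Ks = 0.

**Localization and relocalization.** Predictions arrive as files (the
predictor itself is never executed): a simple TSV or a MultiLoc2-style
`compartment: score` line format, one top compartment per protein, score
ties broken by vocabulary order with a warning. A pair is RELOCALIZED iff
the two labels differ. Dual targeting is deliberately ignored — only
same-versus-different matters, which also makes pooling across species
with different compartment vocabularies safe, because only statuses are
ever pooled, never labels.

**N-terminal peptide (NTP) mutations.** Targeting peptides are short
(~13–85 residues) N-terminal signals; changes to them are a mechanism for
relocalization. Pairs are re-aligned globally (end gaps penalised —
a local alignment would clip terminal indels, hiding exactly the events
of interest), the leading window covering the first 60 residues of the
longer member is extracted (60 = midpoint of the 13–85 range; per-protein
windows can be supplied), and the window is classified: `COMPLETE` when a
single gap run spans ≥ 30 residues or the whole window (peptide
gain/loss), else `TERMINAL` when a gap run touches column 1, else
`PARTIAL` for any internal indel, else `NONE` (substitutions only). The
30-residue rule is a single maximal run, not a sum of scattered gaps.
Category tables report each class's share of all pairs and *two* PSR
summaries — the relocalization rate within each category and each
category's share of all relocalized pairs — because both denominators are
scientifically meaningful and reports should not have to choose.

**Survival fitting.** The Cox partial likelihood for the single binary
covariate is maximised by Newton–Raphson from $\beta = 0$ (convergence
$|\Delta\beta| < 10^{-9}$, ≤ 100 iterations), with Efron tie handling by
default (Breslow available); the standard error comes from the observed
information and the p-value from the Wald test. Complete separation —
every event of one group strictly preceding the other's — makes the
partial likelihood monotone with no finite maximiser; `cox_fit()` detects
this directly from the group time ranges and raises a nonconvergence
error instead of returning a runaway estimate. Cox–Snell residuals
$\hat\Lambda_0(t_i)e^{\hat\beta\,dp_i}$ (Breslow baseline) should follow a
unit exponential under a well-specified model; the Kolmogorov–Smirnov
distance from Exp(1) is reported as a numeric stand-in for the usual
diagnostic plot, and `autoplot()` draws the plot itself.

## What the synthetic generator emulates — and what it does not

`simulate_retention_dataset()` draws pair lifetimes from group-specific
*exponential* (constant-hazard) death processes — the simplest
realisation of proportional hazards, chosen so the target hazard ratio is
the known rate ratio $\delta_N/\delta_R$ — with Bernoulli relocalization
status, truncated to an open Ks window by rejection sampling (which
matches the analysis-side window filter exactly). Defaults:
`p_relocalized = 0.25`, roughly the relocalized fraction typical of the
species groups analysed; rates 1 and 1.5 per Ks unit, a moderate
retention advantage; window (0, 1), the analysis ceiling.

`simulate_duplicate_sequences()` builds two-member families: a stop-free
random ancestral CDS (ATG start; 120 codons by default, with the first 40
designated the NTP), duplication, independent point substitutions
(default 1% per site — recently diverged paralogs that will pass the
identity filters), and one NTP event per pair drawn from
none/partial/terminal/complete with default probabilities
0.55/0.2/0.15/0.1, mirroring the observed ordering in which substitutions
dominate and complete deletions are rarest. Event-conditional
relocalization probabilities (0.15/0.3/0.4/0.7) encode the observed
gradient that larger NTP disruptions relocalize more often. Compartments
come from a fixed four-label vocabulary for determinism.

The generator does *not* emulate: realistic codon usage or
transition/transversion bias; indel-length distributions beyond short
uniform deletions; families larger than two; birth–death dynamics on a
phylogeny; correlated prediction errors of a real localization predictor.
Consequently, passing tests demonstrate the machinery is correct —
filters, clustering, estimators, classifiers and the solver do what their
definitions say — not that the biological conclusions transfer to any
particular real proteome.

## Numerical choices, problem sizes and known limitations

Tests and examples use deliberately small problem sizes — tens of
families for end-to-end runs, thousands of records for Cox recovery, 100–
200 replicates for coverage — which keep the whole suite fast while
leaving Monte-Carlo error well inside the asserted tolerances. The
oracle-equivalence checks run exhaustively where the space is small (all
graphs on ≤ 5 nodes for clustering) and by fixed-seed random sampling
where it is not (6–7-node graphs; ≤ 12-residue peptides against a
brute-force dynamic-programming aligner; Newton solutions against a
1e-4-step grid search over $\beta \in [-6, 6]$, applicable only when the
maximiser lies inside the grid).

Two limitations deserve emphasis. First, **window truncation is not
innocuous for the hazard ratio.** Conditioning observations on dying
inside a finite Ks window (as both the generator's rejection sampler and
the analysis filter do) changes each group's hazard in a time-dependent
way, so the two groups are no longer exactly proportional and the fitted
hazard ratio is attenuated toward 1 — strongly so when the window is
comparable to the mean lifetime. Parameter-recovery claims in the test
suite therefore use effectively untruncated windows; on tightly truncated
windows the fitted ratio should be read as a *within-window contrast*,
not an estimate of the underlying rate ratio. This caveat applies equally
to windowed hazard tables on real data: ratios are comparable across
windows and species, but are not unbiased rate-ratio estimates. Second,
the NG86 estimator ignores transition/transversion and codon-usage bias;
for absolute Ks values on real genomes, supply `yn00` output via
`read_yn00()`. Smaller notes: identity thresholds, coverage fractions and
the BSR gate are all inclusive at their boundaries, matching their
definitions; Ks windows are open intervals; and every random component
takes an explicit integer seed, so fixtures and simulations are
bit-reproducible.
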