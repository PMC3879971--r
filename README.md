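# psrsurv

Survival analysis of duplicate-gene retention by protein subcellular
relocalization (PSR).

Most duplicated genes are lost; one proposed route to retention is that a
duplicate's protein product moves to a different subcellular compartment,
acquiring new context and value. `psrsurv` is for molecular
evolutionists who want to test that hypothesis on coding-sequence data:
it detects paralogous protein pairs within a genome, clusters them into
gene families, estimates synonymous divergence (Ks) as a proxy for
duplicate age, classifies each pair as relocalized or nonrelocalized from
subcellular-localization predictions, categorises N-terminal targeting
peptide (NTP) mutations, and compares the two groups' death rates with a
Cox proportional-hazards model.

## The model

Each duplicate pair is one observation with survival time `t = Ks` and a
binary covariate `DP` (0 = relocalized, 1 = nonrelocalized). The Cox
model

    h(t | DP) = h0(t) * exp(beta * DP)

leaves the baseline loss process `h0(t)` unspecified and estimates `beta`
by maximising the partial likelihood (Newton–Raphson, Efron ties by
default). The hazard ratio `exp(beta)` compares death rates of
nonrelocalized versus relocalized pairs: values above 1 mean relocalized
duplicates are preferentially retained. A hazard ratio of 1.58 reads as a
58% higher death rate for nonrelocalized pairs. The model is refit over
nested Ks windows, (0, 0.05) up to (0, 1), so the effect can be tracked
across duplicate ages; Cox–Snell residuals provide the goodness-of-fit
diagnostic.

Around the model sits the standard pipeline: all-vs-all Smith–Waterman
alignment filtered by e-value ≤ 1e-3 and BLAST score ratio ≥ 0.33, then
reciprocal coverage (≥ 80% of both proteins) and a length-dependent
identity floor (30% at alignment length ≥ 150, higher below); stringent
double-linkage clustering (maximal cliques) merged into superclusters; an
optional gene-conversion exclusion (degree > 5); Nei–Gojobori (1986)
Ks/Ka from back-translated codon alignments (or external `yn00` output
via `read_yn00()`); and NTP mutation classes NONE / PARTIAL / TERMINAL /
COMPLETE from end-to-end realignments. A synthetic-data module generates
survival records with known hazard structure and duplicated CDS sets with
ground-truth families, statuses and NTP classes, so the whole pipeline is
testable without genome downloads.

## Worked example

Simulate duplicate pairs whose lifetimes follow constant-hazard death
processes with a true nonrelocalized/relocalized rate ratio of 1.6, then
fit the Cox model:

```r
library(psrsurv)

sim <- simulate_retention_dataset(
  n_pairs = 4000, p_relocalized = 0.3,
  death_rate_reloc = 1, death_rate_nonreloc = 1.6,
  ks_window = c(0, 10), seed = 42
)
fit <- cox_fit(sim$records[, c("time", "dp")])
fit
#> Cox proportional-hazards fit (efron ties)
#>   beta = 0.4713 (se 0.0353), HR = 1.602 [1.495, 1.717], p = 1.23e-40
#>   n = 4000 (dp=0: 1238, dp=1: 2762), all events

tidy(fit)
#> # A tibble: 1 x 8
#>   term  estimate std.error statistic  p.value hazard.ratio conf.low conf.high
#> 1 dp       0.471    0.0353      13.3 1.23e-40         1.60     1.49      1.72

round(excess_hazard_percent(fit$hazard_ratio))
#> [1] 60
cox_snell_residuals(fit)$ks_distance
#> [1] 0.0084
```

The fitted hazard ratio 1.60 recovers the simulated ratio 1.6: the
nonrelocalized group dies about 60% faster, and the Cox–Snell residuals
sit within 0.009 of a unit exponential, so the proportional-hazards fit
is adequate. `autoplot(fit)` draws the residual diagnostic;
`ks_window_hazard_table()` plus `plot_hazard_table()` give the
age-windowed view.

For the sequence side, `simulate_duplicate_sequences()` writes a FASTA,
an ID map and a prediction table, and `run_pipeline(pipeline_config(...))`
executes every stage and writes the report tables (`table1.tsv`
duplication proportion, `table2.tsv` relocalization counts and frequency,
`table3.tsv` windowed hazard ratios with significance stars, `fig1.tsv`
NTP category frequencies). A thin command-line wrapper lives at
`inst/cli/psr.R`.

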