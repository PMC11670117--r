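# endolyso

Differential enrichment and sorting-motif analysis for endolysosomal
organelle proteomics.

## The problem

Organelle immunoprecipitation (Endo-IP for EEA1-positive early/sorting
endosomes, Lyso-IP for TMEM192-positive lysosomes) combined with multiplexed
TMT quantification lets you ask which proteins are specifically captured
with an organelle: compare reporter intensities in cells carrying the
endogenous affinity tag against untagged controls. `endolyso` implements the
quantitative stages of such a study for analysts working with protein-level
quant tables:

- **Differential enrichment.** Per-sample median centering in log2 space,
  then a per-protein two-sample contrast with the pooled variance shrunk
  toward the global mean variance (moderated t with fixed prior df, default
  `priorDf = 4`; `priorDf = 0` gives the plain Welch test), Benjamini–
  Hochberg correction across tested proteins, and the volcano-plot call
  `log2FC >= 1`, `q <= 0.01` (configurable). For protein *i* in sample *s*:
  `y_is = mu_i + beta_i·[tagged] + delta_s + e_is`, and the enrichment
  statistic is `t_i = beta_i / (s~_i · sqrt(1/n_A + 1/n_B))` with
  `s~_i² = (d0·s0² + d·s_i²)/(d0 + d)`.
- **Term over-representation** (SynGO-style): upper-tail hypergeometric
  `P[X ≥ overlap]`, BH within each term category.
- **Candidate cargo selection**: enriched proteins with ≥ 1 transmembrane
  segment and a cell-membrane location flag; capture percentages,
  domain/family categorization, cross-reference against external cargo
  lists.
- **Sorting-motif scanning**: SNX27 PDZ-binding C-terminal `[S/T]-x-Φ`
  (with an acidic/phospho context score over positions −4..−8) and SNX17
  FERM-binding `Φ-x-N-x-x-[F/Y]` windows, Φ = {A,V,L,I,M,F,W,Y} by default.
- **Structure-score triage**: strict `ipTM > 0.6` pass/fail on externally
  computed interface confidences, top/bottom selection, and position weight
  matrices with per-position information content (`log2(20) − H`) for motif
  logos.
- **Time-course clustering**: z-scored differentiation profiles, seeded
  multi-restart k-means, adjusted-Rand agreement.
- **A synthetic-data generator** (`simConfig()`/`simExperiment()`) with
  planted ground truth for every stage, so the whole pipeline is testable
  without external data.

## Worked example

```r
library(endolyso)
out <- runPipeline(pipelineConfig(seed = 1,
                                  sim = simConfig(nProteins = 500, seed = 1)))
str(out$report$counts)
#> List of 10
#>  $ n_proteins      : int 500
#>  $ n_tested        : int 500
#>  $ n_enriched      : int 144
#>  $ n_cargo         : int 61
#>  $ n_snx27_proteins: int 9
#>  $ n_snx17_proteins: int 35
#>  $ n_snx17_motifs  : int 58
#>  $ n_candidates    : int 67
#>  $ n_iptm_pass     : int 24
#>  $ cluster_sizes   : int [1:3] 179 164 157
```

Of 500 simulated proteins, 144 pass the enrichment call (tagged vs untagged
IP at log2FC ≥ 1, q ≤ 0.01); 61 of those are transmembrane cell-membrane
proteins (candidate cargo); scanning their sequences finds 9 SNX27 and 35
SNX17 motif-bearing candidates (58 SNX17 windows — a protein can carry
several); 24 of the 67 screening candidates pass the ipTM > 0.6 triage; and
the three planted differentiation patterns are recovered exactly
(`out$report$metrics$cluster_agreement` is 1).

The strongest enrichment calls:

```r
tab <- out$results$enrichment
head(tab[order(tab$q_value),
         c("protein_id", "log2fc", "t_stat", "q_value", "enriched")], 3)
#>    protein_id   log2fc   t_stat    q_value enriched
#> 17     P00017 1.602930 7.772742 0.00159178     TRUE
#> 29     P00029 1.541701 8.495178 0.00159178     TRUE
#> 41     P00041 1.618833 7.330686 0.00159178     TRUE
```

(Estimated log2FC sits below the planted 2.0 because median centering
absorbs part of a large enriched fraction; see the methods vignette.)

## Package layout

- `R/` — S4 classes (`SimConfig`, `PWM`), generators (`sim*`), enrichment
  (`normalizeQuant`, `differential`, `bhAdjust`, `classifyEnriched`,
  `overlapSets`, `compartmentSummary`), annotation statistics
  (`termEnrichment`, `abundanceCategory`), cargo (`selectCandidateCargo`,
  `cargoFraction`, `categorizeCargo`, `crossrefCargo`), motif scanning
  (`scanSNX27`, `scanSNX17`, `ctermPeptide`, `scanProteome`,
  `motifCandidates`), structure-score triage (`triageIptm`,
  `selectExtremes`, `buildPWM`), time course (`zscoreRows`,
  `clusterTimecourse`, `clusterAgreement`, `elbowDiagnostic`), I/O and the
  pipeline (`readFasta`, `readQuant`, `writeSimData`, `runPipeline`).
- `vignettes/endolyso-methods.Rmd` — the model, its assumptions, parameter
  rationale, and what the synthetic benchmarks do and do not show.
- `tests/testthat/` — oracle-based unit and property tests plus end-to-end
  acceptance checks.
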