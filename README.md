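# mirsort

Cells sort their microRNAs: some are preferentially packaged into small
extracellular vesicles (sEVs) and secreted, others are retained in the
cytoplasm, and short RNA-binding-protein (RBP) motifs on the miRNA sequence
appear to drive much of that choice. `mirsort` is an R package for the full
analysis chain behind that question, aimed at anyone with two-compartment
miRNA profiling data (intracellular + sEV, replicated) and a library of RBP
motifs:

1. **Classify** each miRNA as `SEV_ENRICHED`, `CELL_ENRICHED` or `NEUTRAL`
   by comparing its *percentage composition* — signal over the summed
   signal of all reliably detected miRNAs in the same replicate — between
   compartments with a pooled-variance t-test, adjusted by the
   Benjamini–Krieger–Yekutieli two-stage FDR (stage 1: BH at q/(1+q);
   stage 2: BH at q·m/((1+q)·m̂₀)).
2. **Test motif enrichment** of CISBP-RNA-style position weight matrices in
   one class against the other: log₂-odds scanning with pseudocount
   c·bg (c = 0.1), a match threshold optimised on a 90% training split, a
   one-sided Fisher exact test, and an E-value that charges for both the
   number of motifs and the number of candidate thresholds, gated by a 10%
   holdout consistency check.
3. **Predict localization** from the significant motifs' strengths
   (scaled best-match scores, zeroed below each motif's threshold) with
   random forest and Gaussian naive Bayes under stratified 10-fold
   cross-validation, reporting pooled ROC and AUC
   (trapezoid = Mann–Whitney).

Because the profiling data this design models are not publicly deposited,
the package includes a first-class synthetic-data generator
(`simulate_dataset()`) with planted ground truth — composition shifts,
detection structure, motif plantings, GC bias — so the entire pipeline is
exercised and tested end to end without external data. See the methods
vignette (`vignettes/mirna-sorting-methods.Rmd`) for the model details and
design rationale.

## Worked example

Score the miR-2137 sequence against the bundled synthetic CISBP-style motif
set (consensus-built NONO, HNRNPA2B1 and FUS motifs plus random decoys):

```r
library(mirsort)
dir <- system.file("extdata", "cisbp_synthetic", package = "mirsort")
motifs <- read_cisbp_motifs(dir, file.path(dir, "rbp_info.tsv"))
seqs <- sequence_set(c(`mmu-miR-2137` = "GCCGGCGGGAGCCCCAGGGAG"))
rbp <- vapply(motifs, `[[`, "", "rbp_name")
scan_motif(seqs, motifs[[names(which(rbp == "NONO"))]])
#>       mirna_id motif_id best_score best_scaled best_position present
#> 1 mmu-miR-2137 M001_syn   9.490602           1            16    TRUE
```

The NONO motif (consensus `AGGGA`) matches perfectly (`best_scaled = 1`) at
position 16 — the single `AGGGA` window in the sequence; the HNRNPA2B1
motif (`UAGGGA`) finds its best window at position 15, one mismatch short
of perfect.

Run the full pipeline on the default synthetic study (527 miRNAs in the
cell, 129 in sEVs, planted sEV motif `AGGGA` and cell motif `UCCCU`,
20 decoys):

```r
res <- run_pipeline(pipeline_config(seed = 1), "out/")
table(res$localization$call)
#> CELL_ENRICHED       NEUTRAL  SEV_ENRICHED
#>           399            13           115
head(as.data.frame(res$enrich_sev)[, c("motif_id", "fisher_p", "e_value",
                                       "fold_enrichment")], 2)
#>        motif_id     fisher_p      e_value fold_enrichment
#> 1      decoy_09 7.619210e-49 6.084701e-45        8.273579
#> 2 planted_AGGGA 9.253871e-48 7.390141e-44       12.143478
res$cv
#> cv_report: 514 miRNAs, 10 folds
#>   rf: AUC = 0.9466
#>   nb: AUC = 0.9296
```

The classifier recovers the planted structure: the sEV class is dominated
by miRNAs carrying the planted motif (a GC-rich decoy also ranks highly
here because sEV-class sequences are simulated GC-richer, mirroring the
lower AU% of secreted miRNAs), and motif strength alone predicts
localization with AUC ≈ 0.93–0.95 for both models. `out/` contains every
result table (localization, both enrichment directions, features, CV
metrics, ROC points), a run log and an MD5 MANIFEST; reruns with the same
config are byte-identical.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/mirsort.R run --config pipeline.yaml --out out/
Rscript inst/cli/mirsort.R classify --cell cell.tsv --sev sev.tsv --out loc.tsv
```

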