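# trapscreen

Diagnostic DNA metabarcoding of bulk insect trap catches: detect
low-abundance pest species (down to one specimen in a thousand) in mixed
samples, with a curated multi-locus reference database, a naive-Bayes
taxonomic classifier with bootstrap confidence, and a detection threshold
derived from the sequencer's index-switching rate.

## Who this is for

Insect diagnostic and surveillance laboratories screening trap catches for
priority pests (the package's running examples are the tomato potato
psyllid *Bactericera cockerelli* and Russian wheat aphid *Diuraphis noxia*
inside a community of psyllids and aphids), and methodologists who want a
fully simulated, testable version of that workflow.

## What it computes

* **Reference curation** — a four-rule decontamination cascade over
  lineage-annotated FASTA records: (1) length bounds (keep 200–3000 bp) and
  exact duplicates; (2) open-nomenclature labels ("sp.", "nr.", "aff.", …)
  and incomplete binomials; (3) records with > 95% identity to a
  *Wolbachia*-like contaminant panel; (4) minority lineages in mixed 99%
  identity clusters. Then trimming to the primer-bounded region and export
  of classifier training sets.
* **Read QC** — IUPAC-aware primer demultiplexing, expected-error
  filtering (`EE = Σ 10^(-Q/10) ≤ 2`, no `N`, length > 100 bp), and a COI
  pseudogene screen (frame shifts, stop codons under the invertebrate
  mitochondrial code).
* **Classification** — RDP-style 8-mer naive Bayes with word prior
  `(n+0.5)/(N+1)` and genus-conditional probability `(m+P)/(M+1)`,
  bootstrap support over word subsamples, assignment truncated at the
  lowest rank with ≥ 80% support; species by exact sequence matching, with
  slash-joined aggregates for congeners identical at a conserved locus.
* **Contamination threshold** — from the i5 × i7 index-pair grid, the
  single-end switching rate `c = (R_invalid/R_total) · (C_offdiag/C_invalid)`
  and the residual misidentification threshold `t = c²` (for `c = 1.08%`,
  `t` prints as 0.01%); per-library relative abundances strictly below `t`
  are zeroed.
* **Detection evaluation** — per-locus abundances merged as the mean over
  loci with reads, false positives/negatives against mock-community
  designs, locus-overlap counts and group read proportions.
* **Simulation** — every input above can be generated synthetically:
  hierarchical reference sets with planted database defects, mock pools of
  100–1000 specimens with single-specimen targets, biased multinomial read
  counts, and index switching under combinatorial or unique dual indexing.

## Worked example

Simulate the default experiment — twenty mock pools (five compositions ×
sizes 100/250/500/1000) of six Hemiptera species, 5 × 10⁴ reads per library
across COI/12S/18S, unique dual indexing calibrated to a 1% switching
contamination rate — then classify, threshold at `t = c²` and score
detections:

```r
library(trapscreen)

ex <- run_mock_experiment(seed = 11)
ex$stats
#> Index-switching contamination
#>   contamination rate c: 0.9992% (9992 of 1e+06 reads on invalid pairs)
#>   residual threshold t = c^2: 0.009984%
#>   single-switch cells: 380 reachable, 380 invalid

glance(ex$report)
#> # A tibble: 1 × 4
#>   n_pools n_false_positive n_false_negative frac_pools_all_detected
#>     <int>            <int>            <int>                   <dbl>
#> 1      20                0                0                       1

head(tidy(ex$report), 3)
#> # A tibble: 3 × 7
#>   pool_id taxon        expected_abundance observed_abundance status n_loci loci
#> 1 P1_0100 Acizzia alt…              0.6              0.603   detec…      2 12S,…
#> 2 P1_0100 Rhopalosiph…              0.39             0.387   detec…      3 12S,…
#> 3 P1_0100 Bactericera…              0.01             0.00986 detec…      3 12S,…
```

The estimated switching rate recovers the calibrated 1% and squares to a
~0.01% abundance floor; every designed species — including the single
psyllid specimen at 0.1% expected abundance in the 1000-pools — is
detected, with no false positives after thresholding. The two *Acizzia*
congeners are identical at the 18S-like locus and are therefore reported as
the aggregate `Acizzia alternata/solanicola` (2–3 supporting loci per
taxon in the `loci` column). `autoplot(ex$report)`,
`plot_index_pairs(ex$switched$pairs)` and
`plot_abundance_heatmap(ex$combined)` draw the corresponding figures.

Individual steps are ordinary data-frame functions and compose with the
pipe, e.g.

```r
db  <- generate_reference_database(default_community_profiles(),
                                   planting_spec(n_mislabelled = 2), seed = 1)
cur <- curate_references(db$records, db$contaminants)
cur$log          # audit trail: every removal, one rule each
```

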