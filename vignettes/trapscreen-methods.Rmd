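---
title: "Methods: diagnostic metabarcoding of bulk trap catches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic metabarcoding of bulk trap catches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapscreen)
```

## The problem

Plant-health surveillance traps catch hundreds to thousands of small insects
at a time. Screening such bulk catches for a handful of priority pests —
here modelled on the tomato potato psyllid (*Bactericera cockerelli*) and
Russian wheat aphid (*Diuraphis noxia*) — by individual morphological
identification is slow and misses damaged or immature specimens. Multi-locus
DNA metabarcoding (COI, 12S and 18S amplicons sequenced together) can
identify everything in the pool at once, but a diagnostic deployment needs
three guarantees that generic metabarcoding pipelines do not give:

1. a **curated reference database**, because public reference sequences are
   contaminated with misidentified, mislabelled and symbiont-derived records;
2. a **defensible detection threshold**, because index switching on Illumina
   instruments moves a small fraction of reads between samples and a rare
   pest must be distinguished from that cross-talk;
3. a **quantified detection evaluation**, via mock communities of known
   composition with targets spiked down to a single specimen in a thousand.

`trapscreen` implements this workflow end to end and ships a synthetic
simulator that generates all of its inputs with the statistical structure
the analysis assumes, so every rule is exercised by tests rather than
asserted.

## Pipeline components

### Reference curation

Records pass a fixed cascade; the first matching rule removes a record and
is the one logged, giving a reproducible audit trail:

1. **Length and duplicates** — records strictly shorter than 200 or longer
   than 3000 bases are removed (bounds themselves are kept, reading the
   removal rules literally as "smaller/larger than"); exact within-locus
   sequence duplicates keep the first record by ascending id.
2. **Insufficient identification** — labels carrying open-nomenclature
   qualifiers ("sp.", "nr.", "aff.", ...) as delimited tokens, or lacking a
   complete binomial, are removed. The default term list is a superset of
   the usual qualifiers and is configurable.
3. **Symbiont contaminants** — records with more than 95% identity to a
   contaminant panel (*Wolbachia*-like endosymbiont sequences are the
   canonical case) are removed. Identity is matches over alignment columns
   under an end-gap-free pairwise alignment; because an end-gap-free
   alignment of unrelated sequences can degenerate to a short perfect
   overlap, an alignment must also cover at least half of the shorter
   sequence (configurable) before its identity counts.
4. **Cluster misannotations** — greedy centroid clustering at 99% identity
   (end gaps penalised, records processed longest-first with id
   tie-breaks); clusters spanning more than one phylum, class or order are
   mixed, and minority-lineage members are removed. On a tied vote the
   members disagreeing with the cluster centroid's lineage are removed: a
   majority is undefined on ties, and the centroid is the cluster's
   reference by construction. Removed records are also returned separately
   for manual review, since automated majority voting is a deterministic
   surrogate for expert re-examination of mixed clusters.

Records are then trimmed to the primer-bounded region by alignment to seed
amplicons of known coordinates; records covering less than 80% of the
region are dropped (the coverage floor is a package choice — nothing in the
underlying procedure dictates a value — and is configurable). Coordinates
are 0-based half-open internally and 1-based inclusive in logs. Training
sets are exported as a genus-level lineage FASTA for the classifier and a
species FASTA for exact matching.

Deduplication is applied within locus, not globally: the same conserved
gene legitimately recurs across loci only as distinct amplicons, and
cross-locus identity of sequences is not evidence of redundancy.

### Read quality control

Reads are assigned to loci by their forward primer (IUPAC-aware, at most
one mismatch, no indels — a conservative stand-in for adapter-trimming
tools whose exact settings vary), trimmed, and filtered on expected errors
`EE = sum(10^(-Q/10))` with a ceiling of 2, on ambiguous bases, and on a
strict >100 bp length floor applied after primer removal. COI sequences are
screened for pseudogene signatures by end-gap-free alignment to an in-house
amplicon of known reading frame: a net interior indel length not divisible
by three, or a stop codon under the invertebrate mitochondrial code in the
inherited frame, discards the sequence. This pairwise frame check is a
desk-scale simplification of codon-aware multiple alignment; it is applied
to COI only, as rRNA pseudogenes cannot be recognised this way.

### Taxonomic assignment

An 8-mer naive-Bayes classifier in the style of the RDP classifier: word
prior `P_i = (n_i + 0.5)/(N + 1)`, genus-conditional probability
`(m_i + P_i)/(M + 1)`, scored over the query's *distinct* words.
Confidence comes from 100 bootstrap subsamples of one eighth of the word
set; the assignment is truncated at the lowest rank with at least 80%
support, and queries below that support at phylum are excluded (the
training set covers a single phylum, so nothing below the cutoff there is
interpretable). Words are canonicalised against their reverse complement so
classification is strand-independent; argmax ties break alphabetically for
determinism. Species labels come from exact full-sequence matching (forward
or reverse complement) against the species references; when several species
match — congeners identical at a conserved locus — the label is the
alphabetically sorted slash-joined aggregate, and the same aggregation map
is applied to mock designs so expectations and observations stay
comparable.

### Contamination rate and detection threshold

Index pairs are tallied over the full i5 × i7 grid, including undetermined
reads. The single-end switching contamination rate is

```
c = (R_invalid / R_total) * (C_offdiag / C_invalid)
```

where `C_offdiag` counts grid cells reachable from a valid pair by a
single-end switch and `C_invalid` those of them that are invalid. Under
unique dual indexing the factor is 1 and `c` is simply the invalid-read
fraction; under combinatorial indexing some single-switch destinations are
valid pairs, and the factor scales up for that unobservable share under a
uniform-destination assumption (the simplest estimator consistent with a
valid-to-invalid ratio; on a fully saturated combinatorial grid the rate is
declared unidentifiable rather than guessed). A read lands undetectably on
*another sample's valid pair* only when both of its indexes switch, so the
residual misidentification threshold is `t = c²` exactly. With the
illustrative `c = 1.08%`, `t = 0.000117`, i.e. 0.01% at two decimals.
Per-library relative abundances strictly below `t` are zeroed — a taxon at
exactly `t` survives, reading "below this threshold" strictly — and the
table is deliberately not renormalised, so retained abundances remain
interpretable against the original library depth. Abundance is computed per
library over all loci combined by default (a per-locus mode exists), and
thresholding acts on aggregated taxon labels rather than individual ASVs.

### Detection evaluation

Per-locus relative abundances are merged as the arithmetic mean over the
loci that produced reads in a library. A taxon is detected when its
post-threshold combined abundance is strictly positive; no per-locus
minimum count is imposed beyond the threshold itself. An any-single-locus
detection mode is provided for sensitivity analysis, since threshold-based
calls could defensibly be made per locus instead of on the mean. Expected
abundances are specimen counts over pool size — specimens of similar body
size are assumed, so counts proxy biomass. False positives are detections
absent from the design, false negatives are designed species not detected;
the headline summary is the fraction of pools with every designed species
detected.

## The simulator and what it does (not) emulate

The simulator generates species templates on a two-level hierarchy: one
random ancestor per locus, genus templates substituted at the between-genus
divergence, species templates substituted at the within-genus divergence.
Defaults are 300/250/280 bp templates with 2%/2%/0% within-genus and
10%/10%/5% between-genus divergence for COI/12S/18S: the conserved 18S-like
locus leaves congeners identical, reproducing the situation where two
psyllid congeners cannot be separated and must be aggregated. COI templates
are drawn codon-wise without stop codons so clean ASVs pass the pseudogene
screen. Reference databases add planted defects — duplicates, out-of-range
lengths, "sp." labels, cross-phylum mislabels at 99%+ identity to a clean
donor, and records at ~98% identity to generated symbiont-like contaminant
templates (labelled `Contaminant`; no real endosymbiont sequences are
bundled) — together with a manifest used to verify that curation removes
exactly the planted records.

Mock communities mirror the study design: five compositions of three to
five species crossed with pool sizes 100, 250, 500 and 1000, pest targets
present as single specimens in several compositions (expected abundance
down to 0.1%), and each composition omitting at least one species so
cross-sample contamination is observable. Reads are multinomial per locus
with species probability proportional to specimen count × per-species
amplification bias; per-species bias magnitudes are configurable and
default to 1, as only the direction of real amplification bias is known,
not its size. Index switching replaces each read's i5 and i7 independently
with probability `s` by a uniform draw from the in-use pool (a redraw of
the original value is a silent non-event) — the simplest model consistent
with single-end switching and a uniform destination. The helper
`switch_rate_for_contamination()` inverts the estimator's closed-form
expectation (by exact enumeration of switch outcomes and `uniroot`) so
simulations can be calibrated to a stated contamination rate such as 1%.

Deliberately *not* simulated: sequencing error, chimeras, intraspecific
variation (one ASV per species per locus — the pipeline starts
post-denoising), quality-score structure (emitted FASTQ is uniform Q35,
just enough to exercise the QC module), and real taxon sequences. Passing
tests therefore demonstrate the correctness of the rules and estimators on
data satisfying the model's assumptions; they do not demonstrate robustness
to denoising artefacts, primer-binding bias or database gaps in real
surveys.

## Numerical choices and degenerate inputs

* Alignment scoring is unit match/mismatch (+1/−1) with gap open 4 and
  extension 1 throughout; identity is matches over alignment columns with
  gaps counted. End gaps are free for fragment-tolerant steps (contaminant
  screen, seed-amplicon trimming, pseudogene screen) and penalised for
  clustering, where full-length agreement is the point.
* Bootstrap draws use `ceiling(W/8)` words; the draw size never falls to
  zero. Queries shorter than the word size are an error, not a silent skip.
* Multinomial totals: per-locus read totals are themselves a multinomial
  split by locus share, so library depth is exact and locus depths vary
  realistically.
* Libraries with zero reads at every locus are dropped from merging with a
  warning; zero classified reads make a group proportion `NA`, not 0.
* Simulation seeds: library generation, index switching and classification
  consume `seed`, `seed + 1`, `seed + 2`, keeping the streams distinct but
  fully determined by one integer.

## Problem sizes used by the test-suite checks

The statistical checks run at desk scale, chosen so each completes in
seconds to a couple of minutes while keeping Monte-Carlo error far from the
asserted margins: estimator recovery uses 200 replicates of 10⁵ reads over
four libraries (binomial standard error ≈ 0.03 percentage points against a
±0.2 point criterion); the indexing contrast uses 50 replicates of five
250-specimen pools at 5 × 10⁴ reads each; end-to-end recovery uses 20
replicates of the full 20-pool design at 5 × 10⁴ reads per library;
curation completeness uses 50 randomly planted databases of ~12 clean
records; classifier recovery uses 1000 queries at 3% divergence against a
15-sequence, 5-genus training set. The acceptance script recomputes the
same quantities at comparable sizes.

## Known limitations

* The contamination estimator's combinatorial-mode correction assumes
  uniform switch destinations; structured switching (e.g. distance-dependent
  index confusion) would bias it.
* The threshold `t = c²` treats double-end switching as the only route to a
  misassigned valid pair; physical well-to-well contamination is a separate
  process and is not modelled or corrected.
* Minority-vote cluster cleaning can, in principle, remove a correct record
  when wrong records dominate a cluster; the review file exists for exactly
  that audit.
* Exact-match species assignment is brittle to any residual sequencing
  error by construction; that is the intended trade-off for diagnostic
  specificity, with genus-level naive-Bayes assignment as the fallback.
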