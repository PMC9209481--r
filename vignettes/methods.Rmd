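---
title: "Models and methods behind epiclonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiclonal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

epiclonal analyzes somatic mutation calls from deep targeted sequencing of
normal epithelia: positive selection, clone geometry, and UV mutagenesis.
This vignette documents the models, the parameters that matter, the
numerical decisions taken where the design was genuinely open, and what the
synthetic data generator does and does not emulate.

## Data model and coordinates

A gene panel is a set of coding sequences (CDS, including the terminal stop
codon) with single-base flanking context at both edges so that every CDS
position has a trinucleotide context on the coding strand. Mutation
positions are 1-based within the CDS on the coding strand; any genomic BED
interchange would be 0-based half-open. Context is taken on the coding
strand first and only then collapsed onto the pyrimidine-centered strand by
`classify_96()`, because the strand-bias analyses need the orientation
before collapse. When panel metadata supplies no flanks, both default to
`"A"`; the two edge positions per gene contribute negligibly to site counts,
but explicit flanks should be provided when known.

Consequence annotation uses the standard genetic code: synonymous (amino
acid or stop unchanged), nonsense (stop gained), stoploss (stop lost),
missense (otherwise). Stop-loss counts as nonsynonymous in `N_i` but
belongs to neither the missense nor the nonsense submetric — the selection
analyses distinguish only those two named submetrics, and stop-loss sites
are too rare to warrant their own.

Mutations called within 10 bp of each other in the same sample and gene are
flagged (`flag_proximal()`, distance 10 inclusive — the boundary is a
convention and documented as such). Instead of manual read inspection, a
machine-readable `phase_tag` marks mutations observed on the same read;
adjacent same-tag SNVs are merged into DNV/MNV records. The merged VAF is
the arithmetic mean of the members: the members are reads of one allele, so
their VAFs are estimates of the same quantity, and the mean is symmetric and
order-independent. Absent tags mean "not co-read".

## Selection: context-normalized dN/dS

For a scope (gene, gene set, or everything), every possible single-base
substitution is enumerated and classified, giving per-class synonymous
(`S_i`) and nonsynonymous (`N_i`) site counts. With background class
probabilities `P_i`,

$$\mathrm{dN/dS} = \frac{n/s}{\sum_i N_i P_i / \sum_i S_i P_i}$$

where `n`, `s` are observed nonsynonymous and synonymous counts (SNVs only;
DNV/MNV records are excluded from both). The test treats each observed
mutation as an independent draw that is nonsynonymous with probability
$\pi = \sum N_i P_i / (\sum N_i P_i + \sum S_i P_i)$ and computes the
one-sided binomial tail $P[X \ge n]$, $X \sim \mathrm{Bin}(n+s, \pi)$. This
parameterization is the natural reading of "binomial test on dN/dS > 1":
conditioning on the total count removes the unknown mutation rate, exactly
as the conditional binomial test does for two Poisson rates.

Decisions taken where alternatives existed:

- **Per-gene π.** Per-gene tests use gene-specific site counts rather than a
  panel-global π; gene composition varies enough (GC, codon usage) that a
  global π would bias small genes.
- **s = 0.** The dN/dS point estimate is reported as undefined (no
  pseudo-counts — they would bias the statistic), but the binomial test is
  still performed, since it needs only `n`, `s` and π.
- **FDR families.** Benjamini–Hochberg is applied per metric within each
  grouping family (all per-gene dN/dS p-values together, and so on), at a
  10% threshold. The family choice is configurable.
- **Excess fraction.** `(dN/dS − 1)/dN/dS`, clamped at 0 for values below 1.

## Selection: impact scores

Observed functional-impact scores (a supplied `gene_id, pos, alt, score`
table in [0, 1]; PolyPhen-2-like) are compared with a simulated neutral
null: random point mutations in the same gene drawn with probabilities
`P_i`, keeping their scores. Both sides of the comparison are restricted to
*scoreable* substitutions — in practice scores exist for missense changes
only, and mixing scoreless classes into one side would make the null
incomparable. Sampling all point mutations instead is a one-line change and
deliberately not the default. The test is the one-sided Wilcoxon rank-sum
(observed stochastically larger); `wilcox.test()` computes it exactly for
small tie-free samples and by the tie-corrected normal approximation
otherwise, which is the standard choice given null samples of thousands of
draws. The headline effect size is `delta`: median observed minus median
expected. Pooled (gene-set) nulls allocate draws across genes
proportionally to each gene's prior-weighted scoreable mass, so the pooled
null corresponds to random mutagenesis of the whole scope.

Default draws: 1e5 per gene for analyses (`sample_expected_scores()`), 2e4
in `run_study()`; the null median is stable well below 0.01 between these
sizes for genes of realistic length.

## Clone geometry

`clone size (mm²) = 2 × VAF × biopsy area (mm²)` assumes diploid cells
heterozygous for the mutation (the factor 2 is a configurable
`ploidy_factor`). A circular punch biopsy of diameter d covers π(d/2)² mm²:
19.63, 3.14 and 0.79 mm² for 5, 2 and 1 mm punches. Note the common
shorthand that a minimal detectable VAF of 0.005 "implies detectable clones
of 19.6 / 3.1 / 0.79 mm²" equates detectable clone size with the biopsy
area itself; the formula above would give 2 × 0.005 × area ≈ 1% of that.
The package reproduces the biopsy areas and leaves the interpretation to
the user — the two statements differ by the conventional factor linking VAF
to occupied fraction.

Each called mutation in a positively selected gene counts as one clone;
nested or overlapping clones are not resolved. Clone frequency is clones
per cm² of sampled area; occupancy is 100 × Σ clone sizes / Σ area,
equivalently the area-weighted mean of 2×VAF, and can exceed 100% for
pathological inputs — it is reported unclamped with a warning because the
formula has no overlap model. Samples without a known area (no diameter and
no explicit area) are excluded from all area-normalized quantities and
listed in the report.

## UV characterization

- **Dipyrimidine fraction**: a C>T (or G>A, via strand normalization)
  counts as dipyrimidine when either neighbor on the pyrimidine-bearing
  strand is C or T. The either-side convention is used because the
  substrate lesion (a pyrimidine dimer) can involve either neighbor;
  a 5′-only variant would give systematically lower fractions.
- **Strand bias**: counts of C>T with the pyrimidine on the coding vs
  template strand are compared by the exact conditional binomial test
  (the standard exact equivalence for two Poisson counts), two-sided by
  default since transcription-coupled repair could in principle act either
  way. The directional CC>TT coding-strand claim uses the one-sided version.
  Sidedness is an argument in both cases.
- **Signature refitting**: non-negative least squares of the observed
  96-class frequency vector on a fixed signature matrix, exposures
  renormalized to proportions. This is refitting, not de novo extraction
  (no NMF). The packaged `reference_signatures()` matrix is synthetic (a
  UV-like column concentrated on 5′-pyrimidine C>T classes, a flat column,
  a C>A column, a T>C column); real signature matrices are supplied as TSV
  with the 96 class labels in the first column.

## The synthetic generator

`sim_config()` defaults define the simulated study conditions:

| parameter | default | emulates |
|---|---|---|
| `uv_weight` | 0.5 | UV-dominated spectrum: ~58% C>T overall |
| `strand_excess` | 1.24 | 24% coding-strand excess of pyrimidine-site mutations |
| `dnv_rate`, `dnv_coding_frac` | 0.04, 0.824 | CC>TT DNVs, ~82% coding strand |
| `vaf_range` | 0.0023–0.11 | observed VAF range, log-uniform |
| `selection_weight` | 3 | strong positive selection on driver genes |
| `impact_bias` | 4 | driver mutations enriched for damaging scores |
| `n_samples`, `muts_per_sample` | 12, 76 | a ~900-mutation study |
| panel | 10 driver / 4 immune / 4 housekeeping genes, 120–300 codons | scaled-down panel preserving the gene-set structure |

Selection is implemented as acceptance reweighting of nonsynonymous draws
in driver genes, so the neutral limit `selection_weight = 1` is exact.
The reference catalogue for prior estimation is generated by the same
spectrum machinery under an independent seed, decoupling prior estimation
from mutation generation as in a real analysis (external tumor catalogue vs
study mutations). Every output is a pure function of (config, seed).

Two structural caveats. First, the two-component UV/uniform mixture cannot
match an arbitrary pair of (C>T share, dipyrimidine fraction): at
`uv_weight = 0.5` the C>T share is ~58% but ~93–96% of C>T falls at
dipyrimidines, higher than typical observed values near 88%; matching the
dipyrimidine fraction instead would drive the C>T share far too low. The
default prioritizes the overall C>T share. Second, with a scaled-down panel
(~500 C>T per run) the per-run strand excess has a standard error of
roughly ±9 percentage points plus panel-composition variability, so single
runs scatter widely around the configured 24%; the parameter is recovered
when pooling runs. Passing tests on this generator therefore demonstrate
correctness of the statistical machinery under the stated generative model,
not performance on real reads: alignment artifacts, position-dependent
error, copy-number variation and clone overlap are all outside the model.

UMI reads: each barcode family derives from one template molecule, mutant
with probability `true_vaf`; family sizes are Poisson around the configured
mean (or fixed); the error model is per-read — with probability
`error_rate` a read carries one substituted base at a random position.
Consensus rules: families under 10 reads are rejected; 10–20 reads require
unanimity (a single discordant read rejects the family — the strict
reading, and the boundary at exactly 20 belongs to the unanimity rule);
above 20 reads the plurality read must reach 90%, with plurality ties
rejected since no consensus is defensible. The 90% rule applies to
whole-read identity, not per-base voting, matching the rule's phrasing.
The shipped hotspot amplicons are synthetic sequences containing the ETS
CTTCCGG motif and are named after the promoter windows they stand in for;
they are not genomic sequence.

## Problem sizes and tolerances

The test suite and acceptance script use desk-scale sizes chosen to make
the statistical checks decisive while keeping runs short: oracle
equivalence on 20 random genes of up to 30 codons (site enumeration is
combinatorially exhaustive, so small genes already cover every code path);
neutral calibration with 50 replicates of 500 mutations (mean global dN/dS
required in [0.9, 1.1], rejection rate at α = 0.05 at most 10%); power at
`selection_weight = 2` with ~450 driver mutations over 50 replicates
(driver call rate ≥ 90% at 10% FDR); impact-null uniformity over 200
simulated genes (fraction of p < 0.05 within [0.02, 0.09]); signature
mixture recovery within 0.01 at 1e5 counts; consensus VAF recovery within
[0.005, 0.015] at 5000 families of mean size 30. Monte-Carlo consistency
checks use 3 standard errors per class with a multiplicity allowance (at
least 95% of the 96 classes within 3 SE, all within 5 SE).

Numerical details: priors must sum to 1 within 1e-9 (estimation normalizes
exactly); signature columns within 1e-6; zero-count classes get probability
0 with no pseudo-count — a prior that zeroes all synonymous mass of a scope
is an error, not a NaN. All p-values come from exact distributions
(`pbinom`, exact `wilcox.test` where tie-free and small) or the standard
tie-corrected approximation.

## Known limitations

- The mutation table is the entry point: variant calling, alignment and
  indels (beyond the phase-merge rule) are out of scope.
- dN/dS here has no covariate model (dNdScv-style) and no confidence
  intervals; it is the site-normalized ratio with an exact test.
- Occupancy and clone counts ignore clonal nesting and overlap.
- The impact test is only as good as the supplied score table; scores are
  never computed internally.
- Transcription-coupled repair is summarized by one strand-bias test, not
  modelled.
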