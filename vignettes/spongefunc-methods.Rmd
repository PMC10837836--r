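---
title: "Models and methods in spongefunc"
author: "spongefunc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spongefunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongefunc)
```

# Scope and data model

`spongefunc` analyses paired views of a sponge holobiont: the
*composition* of the symbiont community (an ASV-by-sample count matrix
with taxonomic lineages and sample metadata, held in an
`AsvExperiment`, a `SummarizedExperiment` subclass) and its *function*
(transcript expected counts joined to ORF annotations, quantified
through peptide TPM, KO terms and KEGG-style modules). Both arms meet
in shared-feature intersections and differential tests. Everything is
exercised against a synthetic generator with planted, recoverable
ground truth.

# Compositional arm

## Rarefaction and transformation

Rarefaction draws each sample down to a fixed depth once, without
replacement, with a recorded seed. A single draw (rather than averaging
many) keeps the output an integer count table on which downstream
presence thresholds and diversity indices are exact; the cost is a
small extra variance that the seed makes reproducible. Samples under
the target depth are dropped with a warning naming them, never silently.

Beta diversity uses Bray–Curtis dissimilarities on log2-transformed
relative abundances. "log2-transformed" needs a pseudocount convention:
we compute `log2(RA × 10⁶ + 1)`, i.e. proportions are first put on a
per-million scale so the +1 acts like a single-count offset instead of
swamping values below one. The scale factor is an argument of
`log2Abundance()` for users who prefer another convention.

## Shannon index

`shannonIndex()` returns nats (natural logarithm), the default of the
vegan toolchain this arm mirrors. The index is computed on rarefied
counts so that unequal sequencing effort does not masquerade as
diversity.

## PCoA

`pcoaOrdination()` double-centers `-d²/2` and eigendecomposes
(`stats::cmdscale`). Bray–Curtis matrices are generally non-Euclidean,
so negative eigenvalues occur; we report them and drop their axes, with
no Lingoes/Cailliez correction — the simplest choice that keeps the
returned coordinates interpretable, at the price of representing only
the Euclidean part of the dissimilarity structure.

## PERMANOVA

`permanova()` implements the one-factor decomposition
`SS_total = Σ_{i<j} d²_ij / N`, `SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`,
`pseudo-F = (SS_B/(a-1)) / (SS_W/(N-a))`, `R² = SS_B/SS_total`. Sampled
permutation p-values use the +1 correction and can therefore never be
zero. On small designs the test can instead enumerate *all distinct
assignments* of the observed labels (`exhaustive = TRUE`); the identity
assignment is part of the reference set, so the exhaustive p-value is
bounded below by `1/N_distinct`. The unit tests pin the pseudo-F and R²
to `vegan::adonis2` and the exhaustive p to a brute-force oracle.

`dispersionHomogeneity()` is a deliberately plain variant of the
classical multivariate dispersion test: samples are embedded on the
positive-eigenvalue PCoA axes, distances to the own-group centroid are
compared by one-way ANOVA. The imaginary-axis bookkeeping that a full
treatment of negative eigenvalues requires is omitted and documented as
such; for the dissimilarity ranges seen here the positive part carries
almost all structure. `groupVariability()` summarizes each group by its
mean pairwise dissimilarity and, given a group-to-class map (deep vs
shallow habitat), compares the pooled within-group dissimilarities
between classes by ANOVA.

# Functional arm

## From transcripts to peptides to KOs

Bacterial transcripts frequently encode several proteins. To quantify
proteins rather than transcripts, each transcript's expected count is
split over its peptides proportionally to peptide length (amino acids
throughout; TPM is a within-sample proportion, so the amino-acid vs
nucleotide factor of three cancels). The apportioned counts are exact:
they sum back to the transcript count to machine precision, and the
test suite enforces this conservation law.

Peptide TPM divides apportioned counts by peptide length and normalizes
each sample to 10⁶. Transcripts lacking any ORF annotation are excluded
and tallied; peptides lacking a KO are pooled into an explicit
"unannotated" mass so the per-sample TPM budget (KO total plus
unannotated mass = 10⁶) always closes. Whether unannotated peptides
belong in the TPM denominator is genuinely ambiguous in studies of this
kind; we include them — their removal would silently inflate the
annotated fraction — and the tallies make the choice auditable. KO
aggregation is a plain sum over member peptides; aTPM is the unweighted
arithmetic mean across samples.

## KEGG module grammar and completeness

Module definitions are parsed under the standard grammar — `+` binds a
complex (all subunits required), `-` marks an optional subunit (never
required), `,` separates alternatives (any branch suffices), spaces
separate steps (all required), parentheses group; precedence tightest
to loosest is `+`/`-`, `,`, space. A module is *complete* when every
step is satisfied; the reported fraction is satisfied steps over
counted steps, with entirely-optional steps excluded from the count.
This step-satisfaction rule is our documented stand-in for the
curated completeness calls of interactive KEGG tooling, whose internal
rule is not published; the evaluator is verified against exhaustive
subset enumeration on randomly generated definitions.

Rollup choices that matter for interpretation:

- a KO listed several times inside one definition counts once toward
  that module's expression (no double-counting within a module);
- a KO belonging to several modules contributes fully to each, so
  module totals can exceed the sample TPM total — this overestimation
  is inherent to module-level reporting and is quantified by
  `koMultiplicity()`;
- "present" for completeness means TPM above a threshold (default
  strictly above 0) in at least one sample, i.e. completeness is called
  at the dataset level, not per sample; the threshold is an argument;
- pathway-style rollups reuse the same machinery with flat KO lists and
  carry no completeness semantics.

`taxonSplitExpression()` decomposes KO TPM by the taxon of the
contributing peptides *before* module rollup, so per module and sample
the taxon shares sum exactly to the module value (unannotated peptides
appear as "unclassified").

## TMM and CPM

Between-sample normalization delegates to edgeR's TMM (trims 30% on
M-values, 5% on A-values, reference = sample whose upper-quartile count
fraction is closest to the mean, factors re-centred to geometric mean
1). CPM is `count / (library size × factor) × 10⁶`.

# Shared features and differential testing

Presence for shared-set analysis is *strictly greater than* the
threshold in at least one sample of the group, mirroring presence rules
phrased as ">0.01% relative abundance" (ASVs) and ">1 TMM-normalized
abundance" (transcripts). The "TMM unit" for transcripts is read as
TMM-normalized CPM-scale abundance as produced by `cpmMatrix()`; the
threshold is an argument wherever it appears, since the unit convention
differs between pipelines. Exclusive membership patterns partition the
present universe; inclusive (upset-style) intersection sizes are
reported for all 2^k − 1 group combinations; pairwise summaries give
the shared percentage relative to the pair's union and the share of
total abundance the shared features carry.

`differentialFeatures()` filters (ASVs: relative abundance > 0.001% in
≥ 2 samples; transcripts: TMM-CPM > 10 in ≥ 2 samples), computes TMM
log2-CPM with a prior count, and tests the group-mean difference with a
permutation scheme rather than a parametric count model: the statistic
is moderated by the pooled standard error plus a floor `s0` (the median
pooled SE across features), and the null distribution pools the
statistics of *all* features over every distinct unordered relabelling
of the samples. Two consequences drove this design. First, at the
replication level typical of sponge field studies (3 vs 3) there are
only 10 distinct splits, so per-feature permutation p-values bottom out
at 0.1 and could never clear a BH-adjusted 0.01; pooling across
features restores resolution (the identity partition, including its
mirror image in balanced designs, is excluded from the null pool).
Second, the moderation floor keeps low-variance features from
dominating the pooled tails. A feature is called differential only when
both gates hold: BH-adjusted p < 0.01 *and* at least 2-fold change on
normalized abundance (|log2FC| ≥ 1). The fold-change gate does much of
the false-positive control in practice; calibration and recovery are
measured on the generator's planted truth in the test suite.

A structural consequence of the pooled null worth knowing: with F
features and k truly differential ones all achieving the minimal
attainable p-value, the BH-adjusted floor is roughly `1/(9k)` for a
3-vs-3 design, so designs with very few (< ~12) true positives cannot
clear adjusted p < 0.01 at this replication level no matter how strong
the effect. This is a property of permutation resolution, not a bug;
larger designs or more true signals dissolve it.

# The synthetic generator

`simConfig()` fixes the study conditions; the notable defaults and why:

- design 3 species × 1 location × 3 replicates — the core design of the
  kind of field study this package targets (three co-occurring host
  species collected in triplicate at one site);
- 800 ASVs at mean 16S depth 10⁵: the order of magnitude of a filtered
  sponge ASV table and its sequencing effort;
- ASV base abundances log-normal(0, 2) — a standard uneven
  rank-abundance shape; per-sample compositions
  Dirichlet(concentration × base) with total concentration 200, then
  multinomial at Poisson depth. The Dirichlet-multinomial is an
  assumption, not an estimate; no abundance distribution is specified
  by the studies this emulates. The concentration knob maps directly
  onto habitat dispersion (large = tight deep-sea-like communities,
  small = variable shallow-water-like ones), which is how the
  deep/shallow variability contrast is planted;
- group effects multiply the Dirichlet base of a designated 5% ASV
  subset per group by `exp(effect size)`, assigned round-robin and
  recorded in the truth object;
- 2000 transcripts at mean depth 10⁶ expected counts; 36.6% of
  transcripts carry one ORF, the rest uniform on 2–12; peptide lengths
  log-normal(5.2, 0.6) amino acids truncated at ≥ 50 (median ≈ 180 aa,
  a plausible protein-length distribution); per-transcript baselines
  log-normal(0, 1.5);
- KO annotation covers 60% of peptides and taxon annotation 70%,
  drawn from a 150-KO universe and a 12-lineage taxon set typical of
  HMA sponge symbionts (Chloroflexi, Thaumarchaeota, Poribacteria,
  Proteobacteria, ...);
- planted-complete modules have every non-optional leaf KO pinned to a
  peptide of a highly expressed transcript, so completeness recovery is
  deterministic; withheld KOs are never assigned anywhere;
- planted differential transcripts (default 20 at log2FC 2) are chosen
  uniformly and their up-group assigned round-robin.

One master seed expands into fixed per-stage substreams, so the ASV
draw, ORF structure, annotation, baselines and counts can be
regenerated independently; identical configs are bit-identical.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: sequencing error and chimeras, taxonomic
misannotation, compositional correlations between taxa, overdispersion
beyond Dirichlet-multinomial, library-preparation batch effects, and
eukaryotic contamination. Recovery rates measured here are upper bounds
for field data.

# Numerical choices and degenerate inputs

- Apportionment and TPM conservation are enforced to 1e-9 or better;
  TPM columns sum to 10⁶ ± 1e-3 by construction.
- Zero-total samples error with the sample named (relative abundance,
  TPM); all-zero sample pairs make Bray–Curtis undefined and error.
- Permutation p-values are floored at `1/(n+1)` (sampled) or
  `1/N_distinct` (exhaustive); ties on the statistic are counted as
  exceedances with a 1e-12 slack.
- Groups of size one are excluded (with a warning) from dispersion
  testing; single-group inputs error.
- TMM factors are validated positive and finite; a sample sharing no
  expressed features with the reference errors.
- Parsers reject rather than coerce: negative counts, duplicate ids,
  id mismatches and malformed module grammar all raise errors naming
  the offender and, for grammar, the position.

# Problem sizes used in the checks

The verification suite and `scripts/acceptance.R` use: 1000 transcripts
for conservation; 200 random definitions (≤ 10 leaves, all 2^leaves
subsets) for the completeness oracle; 20 six-sample instances for
exhaustive PERMANOVA agreement and 500 null simulations (16 samples,
199 permutations) for its calibration; 50 simulations of 2000
transcripts for differential recovery; 50 simulations for module
completeness recovery; 10000 transcripts for the single-ORF fraction;
and 100 two-habitat simulations (2 × 10 samples, 300 ASVs) for the
dispersion contrast. These sizes give stable rates while keeping the
whole suite comfortably fast on one CPU.

# Known limitations

- Completeness is a structural stand-in; curated KEGG calls may differ
  on modules with unusual definition idioms (`--`, nested optional
  blocks), which the parser does not currently accept.
- The dispersion test ignores imaginary PCoA axes; strongly
  non-Euclidean dissimilarity structures would bias it.
- The differential caller's pooled null trades exactness for
  resolution; on designs with many distinct permutations a per-feature
  null would be preferable and can be approximated by raising
  `n_permutations`.
- `runPipeline()` orchestrates single-machine runs only; no workflow
  engine integration.
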