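---
title: "Locus-level EST analysis with estpipe: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-level EST analysis with estpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estpipe)
```

# Scope

`estpipe` analyses a collection of expressed sequence tags (ESTs) —
single-pass cDNA reads — that have been spliced-aligned to the genome of a
related reference species. Starting from exon-block alignment records it

1. filters alignments by identity and read coverage,
2. clusters alignments (together with reference transcript models) into
   locus-level clusters,
3. detects and classifies local alternative-splicing (AS) events,
4. calls tissue-specific clusters from EST copy numbers,
5. profiles how ESTs cover annotated protein-coding regions, and
6. compares pairwise Ka/Ks distributions between gene sets.

A synthetic genome/EST generator with a machine-readable truth record makes
every stage testable end to end: each planted splicing variant,
tissue-specific gene and substitution-rate target can be scored against what
the pipeline recovers.

# Coordinates and formats

All internal coordinates are 0-based half-open intervals. GTF/GFF input is
converted on read (1-based closed to 0-based half-open) and restored on
write; PSL block starts are already 0-based and are preserved. The native
alignment format is a TSV with one row per EST: `est_id`, `tissue`,
`chrom`, `strand`, `identity`, `est_length`, `blocks`
(`start-end,start-end,...`) and `intron_orientations`
(`forward`/`reverse`/`ambiguous` per inter-block gap). The orientation
column makes the aligner's intron-direction call explicit instead of
re-parsing aligner-specific report text; aligners that mark undetermined
intron direction map those codes to `ambiguous`.

# Alignment filtering

An alignment is kept when its identity exceeds `min_identity` (default
0.85) and its aligned length exceeds `min_coverage` (default 0.5) of the
*EST length* — the read, not the genomic span, since introns inflate the
genomic span arbitrarily. Both thresholds are strict inequalities by
default; published descriptions of such screens often say "higher than
85%" without stating boundary behavior, so `filter_thresholds(strict =
FALSE)` flips both comparisons at once.

Splice sites are extracted per inter-block gap: on forward orientation the
upstream block end is the donor and the downstream block start the
acceptor; on reverse orientation the roles swap. Gaps with an ambiguous
orientation call emit no sites. An EST is "unambiguously spliced" when it
has at least two blocks and all its introns share one non-ambiguous
orientation; only such members enter AS analysis.

# Clustering

Two members are linked when they share an identical splice site (same
chromosome, position, donor/acceptor role and orientation) or when their
genomic projections overlap by strictly more than half of the shorter
projection. Primary clusters are the connected components under this
relation; reference transcripts participate in linkage (they can bridge
ESTs that share no site with each other) but never count as ESTs.
Orientation matters only for the splice-site clause: pure-overlap linkage
is orientation-blind, because unspliced ESTs carry no orientation evidence.

An EST aligned at several loci (e.g. across a duplicated gene pair) sits
in several primary clusters. A primary whose EST-id set is contained in
another's is absorbed into it, iterated to a fixpoint; the primary with
the most ESTs represents the merged unique cluster, with ties broken by
smallest cluster id. The unique cluster's EST count is the number of
*distinct* EST ids over its primaries — summing per-primary counts would
count the very ESTs that caused the merge twice.

# Alternative-splicing classification

Two exon-block structures are compared inside their mutual genomic
overlap. Introns present in exactly one structure form divergent regions,
resolved in priority order:

* **exon skipping** — an intron of one structure spans one or more
  complete exons of the other, with both flanking introns anchored on the
  shared boundaries;
* **intron retention** — a divergent intron lies strictly inside a single
  exon of the other structure;
* **alternative 5'/3' site** — two divergent introns share exactly one
  boundary. The genomic-left boundary is the donor only on forward
  orientation, so the alt-5'/alt-3' label is orientation-aware; mirroring
  a locus to the opposite strand swaps the two labels and preserves
  skipping/retention.

An alternative-site call additionally requires the differing-boundary
region to be free of any other divergent intron; coupled divergences
(e.g. an inserted exon with a shifted flank) are reported as `complex`
and excluded from the four-type counts rather than forced into the
nearest pattern.

Two members are paired for event detection when they share at least one
splice site and their intron sets *within the mutual overlap* differ. The
within-overlap restriction matters for fragment data: a longer EST has
splice sites that a shorter one simply does not reach, and treating those
as "different splice sites" would manufacture events out of read-length
variation. Events are deduplicated per cluster by a canonical coordinate
signature (one skipped exon is one event no matter how many read pairs
witness it) — published event counts rarely state their deduplication
unit, and the signature convention makes ours explicit and testable.
Cluster eligibility defaults to "at least two unambiguously spliced
ESTs"; a `members` rule (more than two usable members, at least one an
EST, reference transcripts allowed as witnesses) is available where
annotation should count as a witness.

`classify_pair()` itself only demands some shared splice structure: the
textbook retention comparison of a two-exon structure against a
single-exon structure has no shared site, yet is perfectly classifiable,
so the shared-site requirement is enforced at the pairing stage and
`classify_pair` errors only when it finds neither a shared site nor a
classifiable divergence.

## Depth normalization

AS detection rates grow with EST depth. Following the standard subsampling
normalization, clusters with at least `n_sample` (default 10)
unambiguously spliced ESTs are selected, `n_sample` ESTs are drawn without
replacement per cluster, events are re-detected, and the summary is
averaged over `reps` (default 100) replicates; Monte-Carlo standard
errors are reported alongside the means. Drawing the whole cluster
reproduces the unsampled summary exactly, which the tests assert.
Cross-species pattern tables are compared with an ordinary contingency
chi-square (no continuity correction) on the r x 4 count table.

# Tissue specificity

EST copy numbers per cluster and tissue approximate expression level. For
each cluster with at least `min_total` (default 10) ESTs and each tissue,
a 2x2 table (this cluster vs all others, this tissue vs all others) is
tested with a two-sided Fisher's exact test under the minimum-likelihood
rule, implemented by direct hypergeometric enumeration (the test suite
checks it against an independent enumeration for every table with total
at most 40, and against `stats::fisher.test`). The reported odds ratio is
the unconditional cross-product `(a*d)/(b*c)` — the quantity screened by
the conventional "odds ratio > 10" rule — not the conditional-MLE
estimate. A cluster is called specific to at most one tissue (highest
odds ratio among passing tissues). No multiple-testing correction is
applied by default, matching the conventional screen this reproduces;
`p.adjust` can be applied to the returned p-value column by callers who
want it.

Cross-species profile correlations convert counts to within-species
tissue proportions first (each tissue column divided by its library
total): raw EST counts across libraries of very different depths
correlate mostly by depth. `normalize = FALSE` restores raw-count
behavior. P-values use the exact t transform of the Pearson correlation,
two-sided, and are omitted below three paired observations.

# CDS coverage

A spliced EST is assigned to a reference transcript when its splice-site
set is *contained* in the transcript's and its blocks are compatible with
the transcript's exons — ESTs are fragments, so demanding set equality
would discard nearly everything (a `strict_equality` flag exists).
Unspliced ESTs match unspliced transcripts by overlap. ESTs matching
transcripts of more than one gene are discarded, as are transcripts
without annotated start and stop codons. EST blocks are projected into
transcript coordinates; coverage is the covered fraction of the CDS, and
ESTs that land entirely in untranslated regions are discarded rather than
scored 0. Relative 5'/3' end positions are reported on the
strand-corrected transcript axis normalized so the CDS spans [0, 1]; the
coverage average is taken per EST (not per transcript). The profile's
center-relative axis puts the CDS midpoint at 0 and its ends at +/- 0.5.

# Pairwise Ka/Ks

The evolution module implements the Nei–Gojobori (1986) counting method
with Jukes–Cantor correction: per-codon synonymous site fractions by
enumerating the three single-base changes at each position (stop-creating
changes count as non-synonymous), differences averaged over all minimal
substitution paths that avoid stop codons, and
`d = -(3/4) ln(1 - 4p/3)`. This is a deliberately deterministic pairwise
estimator: the gene-set comparison it feeds is a claim about the
*distribution* of Ka/Ks between a focal set and the background, for which
a counting estimator is sufficient and exactly reproducible. Codons with
ambiguity characters are excluded; saturation (p at or beyond 3/4) and
internal stop codons are errors, not silent values. Ortholog groups where
more than one pair shows Ka >= 0.25 and/or Ks >= 5 (inclusive bounds) are
discarded as unreliable alignments.

Gene-set comparisons use a Wilcoxon rank-sum test, one-sided (`less`) by
default because the scientific claim is directional (stronger purifying
selection on the focal set). The implementation uses midranks, exact
enumeration up to 12 observations and a tie- and continuity-corrected
normal approximation above; infinite Ka/Ks ratios (Ks = 0 with Ka > 0)
are excluded by default, with an option to rank them above all finite
values.

# The synthetic generator

`simulation_config()` encodes the study conditions: 200 genes tiled over
two chromosomes on alternating strands, 4–8 exons of 90–300 bases,
introns of 200–1500 bases, 5,000 ESTs of 350–900 aligned bases across
five tissue libraries (liver, brain, heart, skeletal muscle, testis),
seed 42. A configured fraction of genes (default 0.3) receives exactly
one alternative isoform of a type drawn from `as_type_weights`; only the
canonical isoform enters the emitted annotation, so planted variants are
observable through ESTs alone, as with a real EST collection read against
a reference annotation. Planted events carry the same canonical signature
strings the classifier emits, so recovery scoring is exact string/region
matching rather than fuzzy interval overlap.

Two generator choices deserve explanation:

* **Retained introns are short.** A planted retention is only observable
  if a single read block can span the intron and still reach another
  splice junction. Real retained introns are strongly length-biased
  short, so retention plants pick the gene's shortest intron and that
  intron is drawn from 80–250 bases. Without this, a fraction of planted
  truth would be unobservable by construction — a generator defect, not a
  detector defect.
* **Tissue tilt parameterizes the expected odds ratio.** A planted
  tissue-specific gene puts weight `p = odds / (odds + T - 1)` on its
  tissue (`p = 5/6` at the default odds of 20 with T = 5 tissues), which
  makes the expected 2x2 cross-product ratio against a uniform background
  equal to `odds`. With ~25 ESTs per gene the *sample* odds ratio then
  fluctuates around 20 with roughly 50% relative spread, so recovery
  against the "OR > 10" screen is high but not certain per gene; that
  variability is a property of the screen at this depth, and is exactly
  what the generator is meant to exercise.

Identity is drawn from a clamped normal (mean 0.93, sd 0.03); the implied
EST read length is the aligned length divided by a uniform 0.45–1
coverage fraction, so a realistic minority of alignments fails the
50%-coverage screen. Fractions of ESTs are emitted unspliced
(single-block, strand unknown; default 0.2) and with one ambiguous intron
orientation (default 0.05), exercising the discard rules. Codon-pair
simulation places synonymous and non-synonymous single-base changes at
per-codon probabilities calibrated through the inverse Jukes–Cantor
transform so the expected counting-method estimates equal the targets; no
stop codon is ever introduced, and targets beyond the per-codon
saturation bound are rejected.

What the generator does **not** emulate: base-level sequencing error
inside blocks (identity is a label, not realized mismatches), alignment
artifacts such as spurious micro-blocks, paralogy beyond exact multi-locus
EST placement, incomplete or wrong reference annotation, and library
normalization chemistry. Passing recovery tests therefore demonstrates
the correctness of the analysis logic under clean geometry, not
robustness to noisy aligners.

# Determinism and problem sizes

Every random stage derives its stream from one seed (locus simulation:
`seed`; EST draw: `seed + 1`; subsampling: `seed + 2`; codon pairs:
`seed + 3`) and restores the caller's RNG state afterwards, so reruns with
one config reproduce byte-identical outputs — `run_pipeline()` writes an
md5 manifest to make that checkable. Defaults (200 genes / 5,000 ESTs for
recovery; 10,000 codons for estimator recovery; 100 subsampling
replicates) were chosen as the smallest sizes at which recovery rates and
estimator errors are stable enough to assert tight bounds in the test
suite; the codon pairs fed through the pipeline itself use 300 codons per
gene, where per-gene sampling error around the targets is expected and
only distribution-level claims are made.

# Known limitations

* Event detection is pairwise and local; mutually exclusive exons and
  other coupled patterns surface as `complex` rather than as named
  events.
* The subset-absorption rule merges paralogous loci through shared EST
  ids only; loci without any shared EST stay separate even if homologous.
* The counting Ka/Ks estimator ignores transition/transversion bias and
  codon frequencies; it is a distribution-level tool, not a substitute
  for likelihood estimation of per-gene rates.
* Fisher-screen recovery is reported against the planted truth of the
  generator's clean geometry; real libraries add dispersion that the
  generator does not model.
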