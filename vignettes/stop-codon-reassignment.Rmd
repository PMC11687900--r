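---
title: "Inferring stop-codon reassignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stop-codon reassignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopscan)
```

`stopscan` decides, from a genome assembly, its gene models and a set of
orthogroup protein alignments, whether a candidate stop codon (UAA, UAG
or UGA) is actually translated as an amino acid. This vignette documents
the statistical procedures, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where reasonable alternatives existed.

## The conserved-site voting model

The core statistic treats every in-frame occurrence of the candidate
codon as a query posed to an orthogroup alignment. Genes are translated
under a base table (default table 1) with the candidate codons rendered
as `X` (`translate_cds(mask_codons = ...)`); codons containing `N` are
also `X` and never enter any denominator. Each masked residue is matched
to its alignment column (`map_codons_to_columns()`; gap characters in
the query row consume no codon). At a column, the non-query rows vote
(`column_conservation()`):

* gaps, `.` and `X` are excluded from both the mode and the identity
  denominator — "percent identity at a column" is read as the modal
  residue's share of scoring residues;
* the query row is excluded: with the query masked, including it could
  only dilute identity, and excluding it keeps the statistic a statement
  about *other* species;
* columns with fewer than `min_depth = 4` scoring background residues
  return nothing — a mode over two or three residues is noise;
* a tied mode discards the site rather than splitting the vote, keeping
  counts integer-valued and the procedure conservative.

A site qualifies when its identity is at or above `threshold = 0.70`
(inclusive: a column at exactly 0.70 counts). `infer_codon_meaning()`
tallies the modal residues of qualifying sites; the codon's meaning is
the most numerous residue and the strength of the call is
`top_fraction`. `scan_all_codons()` wraps the procedure per candidate
codon and applies the calling rule: **sense** when `n_sites >= 20` and
`top_fraction >= 0.5`, otherwise **stop/undetermined**. Both floors are
configurable; the defaults are deliberately permissive because genuine
reassignments in sparse assemblies can rest on a few hundred sites while
true stops produce essentially none — the separation between the two
regimes is large, so the exact floor matters little (on synthetic
genomes under a variant table, `top_fraction` is typically above 0.95,
while a standard-code control yields 0–2 qualifying sites).

`logo_counts()` turns a summary into the normalised residue frequencies
that a sequence-logo renderer consumes; `autoplot()` draws the bar
version.

## The stop-context (C-terminus) test

The voting model depends on gene models. The second line of evidence
does not: protein-to-genome alignments of reference proteins are
filtered to those whose query aligns through its final residue, and the
in-frame trinucleotide immediately 3′ of the aligned block is tallied
(`tally_cterm_codons()`). "The position corresponding to the stop" is
read as the codon immediately after the last aligned residue — the
position a genuine stop codon occupies. On the minus strand the
flanking trinucleotide is reverse-complemented before lookup. Records
whose post-alignment codon would run off the contig are reported in a
separate truncated-at-contig-end bucket so every record lands in exactly
one of contributes / non-C-terminal / truncated.

By default one best alignment per query (longest query span, then most
matches) is tallied; counting all alignments is available via
`best_per_query = FALSE`. `compare_tables()` runs the tally over
alignment sets produced under different translation tables: when a
genome truly translates UAG, aligning under a table that calls UAG a
stop truncates every alignment at the first internal UAG, so the table
matching the genome's true code maximises the number of full-C-terminus
alignments.

## The gene-body profile and depletion test

In genomes where a codon keeps a context-dependent dual meaning, the
sense usage avoids the neighbourhood of the true termination codon. The
profile (`gene_body_profile()`) assigns each internal occurrence at
codon index *p* (0-based) of a gene with *L* internal codons to bin
`floor(n_bins * p / L)` (default `n_bins = 20`), for the target codon
and each synonymous companion; only complete genes contribute and the
terminal stop is excluded from positions.

The depletion statistic is a design of this package — the underlying
comparison is usually presented visually — so it is kept simple and
fully configurable: the ratio of the target codon's relative mass in the
terminal `tail_fraction = 0.1` of bins to the pooled synonymous codons'
mass in the same bins. Genes are resampled with replacement
(`n_boot = 1000`) and the verdict is **depleted** exactly when the 95%
percentile CI's upper bound is below 1. At least 50 target occurrences
are required; below that the verdict is "insufficient data" rather than
a number that would mostly reflect noise. Calibration on the generator
(40 replicates each): a uniform generator is called depleted in ≤ 10%
of runs, a generator that forbids the target codon in the final 10% of
each gene in ≥ 95%.

## Codon-usage statistics

All gene-level statistics are restricted to complete gene models —
predicted start codon, predicted stop under the applied table, length
divisible by three, no internal stop. Genes failing any of these are
flagged and excluded rather than repaired; how a production annotation
pipeline would handle an internal in-frame stop is its own problem, and
silently repairing it here would blur the ground truth. Family
membership for relative synonymous usage follows the applied table: TAG
is the seventh leucine codon under table 16 and the third glutamine
codon under table 15. GC content is computed on the assembly (not the
transcriptome), with `N` excluded from the denominator; comparisons of
assembly GC against transcriptome-derived GC should be made with
caution.

## Suppressor-tRNA analysis

Anticodon screening is a lookup: CTA decodes UAG; TTA decodes UAA and,
by wobble at the third codon position, UAG as well; TCA decodes UGA.

Canonical numbering is derived structurally from the cloverleaf rather
than from a lookup table: the secondary structure is parsed into
acceptor stem, D-arm, anticodon arm, optional variable arm and T-arm
(4 or 5 helices; anything else is an error and element checks are
skipped). Labels are anchored where the biology is anchored: the
anticodon at 34–36, the T-loop start at 54, the D-loop's 3′ end at 21,
the discriminator as the last unpaired 3′ residue before any CCA tail.
Published coordinates for the 3′ half differ by one between numbering
conventions, so acceptor-stem pair elements (A4:U69, G5:C68) are
evaluated at their 5′ position with the partner located *through the
structure*, never by label arithmetic — this makes the check robust to
the convention used to describe the elements.

The leucyl-tRNA synthetase element set checked by
`check_identity_elements()`: discriminator A; pairs A4:U69 (optional by
default — naturally occurring suppressors tolerate the swapped U4:A69)
and G5:C68; a variable region of ≥ 10 nt (the type-II signature of
leucine and serine tRNAs); invariants G18, G19, A21, U33, U54, U55,
C56, A58. Sequences are handled as DNA throughout, so U reads as T.
Unnumberable positions are marked unevaluable and excluded from the
overall verdict instead of failing it.

Pairwise identity uses Needleman–Wunsch global alignment (match 1,
mismatch −1, gap open 2, gap extend 1 as costs, configurable) via
Biostrings; identity is matches over alignment length, and differences
count mismatches plus gapped columns — which reduces to a plain
substitution count when no gap opens, the situation for same-length
tRNA homologs. `nearest_isotype()` takes the arg-max of identity over a
canonical set, breaking ties by score then id, to recover the tRNA a
suppressor most likely evolved from. `telomere_capped()` accepts the
repeat unit, its reverse complement, or any cyclic rotation of either,
because a telomeric tract entered mid-phase matches a rotated unit.

## What the synthetic generator emulates — and what it does not

`synth_config()` fixes the study conditions; every generator is
deterministic given the seed. Defaults: 10 taxa per orthogroup, 200
genes of mean length 300 codons, AT-rich coding sequence
(`gc_bias = 0.35` at degenerate third positions only, so the protein
ground truth is untouched), UAA-dominated stop usage (0.95/0/0.05 under
variant tables; 0.80/0.13/0.07 under the standard code, matching the
usage regime of standard-code relatives), reassigned-codon family usage
0.08, half of alignment columns conserved with per-row identity 0.85,
10% partial gene models, 5% background gap rate. Sample sizes used in
the shipped tests and the acceptance script (200 orthogroups for code
recovery, 40 bootstrap-calibration replicates, 2,000 genes for usage
recovery) were chosen so each statistic's sampling error is small
relative to the effect it measures while a full run stays in the
minutes range on one CPU.

Background residues at non-conserved columns are drawn from a flat
Dirichlet column profile, and at conserved columns each background row
independently carries the query residue or a draw from average
composition. Intergenic spacers are i.i.d. nucleotides; introns (behind
the `introns` flag, off by default) are single GT..AG insertions at
codon boundaries. A 3′-truncated gene model never ends on a reassigned
codon: an annotation pipeline reading that terminal trinucleotide would
call it the model's predicted stop, so emitting one would make the
generator's ground truth inconsistent with any consumer's translation.

Deliberately *not* emulated: phylogenetically realistic substitution
processes (no tree, no rate variation, no correlated columns),
alignment error, assembly artefacts, annotation error beyond simple
truncation, and codon-usage covariates like expression level. Passing
tests therefore demonstrate that the inference machinery recovers known
truth under clean, well-specified conditions — not that it is robust to
every pathology of real metagenome-assembled genomes. On real data the
conserved-site vote in particular inherits whatever biases the
orthology inference and aligner introduce.

## Numerical and interface choices

* Coordinates are 1-based inclusive on disk (GFF3, tRNAscan-SE) and
  0-based half-open internally; tRNAscan's begin > end encodes the minus
  strand and is normalised on parse.
* DNA alphabet (T not U) internally; report renderers may print U.
* GFF3 CDS phase is honoured; absent phase is assumed 0 and logged.
* Candidate-codon masking applies to all three standard stops at once
  during scanning, so an internal occurrence of a *different* stop codon
  cannot truncate the masked translation.
* The depletion bootstrap defaults to seed 0 when none is given, so
  repeated runs of a report are byte-identical; pass `seed` to vary it.
* `run_analysis()` adopts the variant table matching a sense call
  (table 16 for UAG→L, table 15 for UAG→Q) for the usage and gene-body
  sections, mirroring how an annotator would re-annotate after a code
  change; sections with missing optional inputs are marked "not run"
  rather than failing.

## Known limitations

The cloverleaf parser requires strictly stacked helices; bulged stems
fail decomposition (reported, element checks skipped). The identity
threshold of 0.70 and depth floor of 4 are sensible for alignments of
ten-odd taxa; much deeper alignments might warrant a depth-aware
threshold. The depletion test conditions on the annotated stop being
correct; systematic 3′ mis-annotation would bias it toward depletion.
Suppressor detection is anticodon-based and will not find suppressors
acting through modified-base recoding.
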