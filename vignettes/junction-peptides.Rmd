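---
title: "Validating alternative splice forms with MS/MS evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating alternative splice forms with MS/MS evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Deep RNA sequencing reports many exon–exon junctions that are absent from
curated gene models. Whether those novel splice forms are translated into
protein is a separate question, and shotgun proteomics can in principle
answer it: if a tryptic peptide straddling the novel exon–exon boundary is
confidently identified in MS/MS data, the junction has protein-level
support. In practice the yield of such junction peptides is small, for
three compounding reasons that this package makes quantitative:

1. only a minority of junctions have *any* tryptic peptide of
   MS-compatible length straddling the boundary;
2. novel-candidate identifications carry a much higher error rate than
   ordinary ones and need a stricter, class-specific FDR plus a homology
   screen; and
3. detection probability falls steeply with transcript abundance, and
   novel isoforms tend to be lowly expressed.

`jxpepdb` implements each step with explicit, testable rules, and ships a
simulator that plants ground truth for every stage.

# The pipeline

## Coordinates and junction representation

All intervals are 0-based half-open (BED semantics); GTF input is shifted
on read. A splice junction is represented by its **intron** interval:
`start` is the first intronic base and `end` the first base of the
downstream exon. This makes known/novel classification exact: a junction is
*known* iff its intron matches an annotated intron on the same chromosome
and strand at both boundaries. One-sided matches are novel — the pipeline
distinguishes junctions, not exons, and exactness is what a test can pin
down. Unstranded junction input (`.`) is duplicated onto both strands with
a warning, since the correct strand cannot be recovered downstream.

Known/novel status can be assessed at two levels: here at the nucleotide
level against gene models, and again at the peptide level during PSM
novelty calling (a peptide matching any reference protein is *known*,
whatever its junction provenance). Both are reported; they answer different
questions and need not agree for individual junctions.

## Junction windows and translation

For each junction we take `flank_nt = 75` nt (25 codons) from each joined
exon, splice them, and translate all six frames. The 25-residue flank is
the smallest window that still allows a 30-residue open reading frame
spanning the boundary, which is the minimum entry length
(`min_orf_len = 30`) for reliable spectral searching. Junctions whose
available exonic flank is shorter than 75 nt on either side are dropped
rather than truncated: a truncated window could not contain a qualifying
ORF anyway, and keeping the retained windows homogeneous (boundary always
at offset 75) simplifies every downstream boundary computation. Flanks are
clipped at the boundaries of the assigned gene's exons when models are
available; a `genomic_flanks = TRUE` override clips at chromosome bounds
only, for junctions in unannotated regions.

ORFs are stop-delimited, with **no initiator-methionine requirement**: the
windows are internal transcript fragments, and demanding an ATG would
discard nearly everything while adding no specificity. Frames whose length
is not a multiple of three drop the trailing partial codon. Codons
containing `N` translate to `X`; a segment whose junction-straddling
residue is `X` is discarded (its identity at the one position that matters
is unknown), while `X` elsewhere in a segment is tolerated.

The boundary-residue convention: `boundary_aa` is the index of the first
residue whose codon uses any downstream-exon nucleotide, i.e. the
straddling codon belongs to the downstream side. Any single convention
works; this one is recorded in the FASTA headers (`baa=`) so entries are
auditable. An entry *spans* its junction iff `0 < boundary_aa < length`.
Minus-strand windows are built on the plus strand and reverse-complemented,
with the boundary remapped (`L - boundary`); the test suite checks that
mirroring the entire genome and flipping strands reproduces the identical
set of entry sequences.

Entries are deduplicated on exact amino-acid sequence across frames and
junctions (mirroring redundancy removal before a search); the first-seen
entry keeps the provenance, and all contributing junction ids are recorded
so per-junction statistics remain exact after deduplication.

## In-silico identifiability

Digestion is fully tryptic: cleavage C-terminal to K or R, suppressed when
the next residue is proline — the default rule of the common search
engines; a `kp_rule = FALSE` variant is provided. At most one missed
cleavage is considered, matching typical search settings. A junction is
*identifiable* iff some frame's entry yields a junction-spanning peptide of
6–30 residues inclusive — the mass range practical for MS/MS sequencing.
Both bounds are inclusive and configurable; results are reported at zero
missed cleavages and at one, since allowing a missed cleavage enlarges the
identifiable set but such peptides are less likely to be observed.

Per-gene averages are **unweighted means over genes** (each gene counts
once), with "distinct junctions" deduplicated by intron coordinates within
a gene; genes with zero junctions contribute zero to the numerator and one
to the denominator when the full gene universe is supplied. A designated
gene subset (e.g. a mitochondrial gene list) gets a parallel summary. The
identifiable-per-gene column is reported both at zero and at one allowed
missed cleavage, labelled explicitly.

The expected-yield product
`n_genes x junctions_per_gene x class_fraction x identifiable_fraction`
is returned unrounded and rounded; with ~700 genes, ~5 junctions per gene,
a 20% novel share and 5% identifiability it gives 35 expected novel
peptides — the arithmetic that explains why junction-peptide searches
return so little.

## Target-decoy FDR and the novel subset

Decoys are full sequence reversals, one per target, `DECOY_`-prefixed, so
decoy and target length distributions are identical. The estimator is

$$\widehat{FDR}(t) = \frac{N_{decoy}(score \ge t)}{\max(1, N_{target}(score \ge t))}$$

monotonized into q-values by a running minimum from the most permissive
threshold upward. This is the plain concatenated-search convention; the
factor-2 variant `2 N_d / (N_t + N_d)` differs only by a near-constant
factor under the same decoy model and is not used. PeptideProphet-style
probabilities are consumed as the score — any monotone score works with
the decoy machinery — and spectrum-quality scores, when present, are
honoured as a plain numeric cutoff, never recomputed from spectra.

The novel-candidate subset (PSMs mapping exclusively to junction entries)
has a different score-class mixture than the global set, so the global
threshold under-controls it. `subset_fdr_filter()` recomputes the curve
using only junction-exclusive targets and junction-exclusive decoys and
returns the stricter subset threshold. The simulator calibrates the subset
so that its naive false-positive rate at the global threshold is ~0.38,
and the acceptance suite checks that the subset-specific threshold
restores 2% control with true labels. Whether such a subset rate should be
decoy-estimated or mixture-model-derived is ambiguous in general; this
package reports the decoy-based estimate throughout.

The homology screen replaces a heuristic alignment program with an
exhaustive scan: the minimum Hamming distance between the candidate
peptide and every equal-length substring of every reference protein, with
I/L treated as identical by default because they are isobaric and
indistinguishable in standard MS/MS (a flag disables this). For short
ungapped peptides the exhaustive scan is strictly more sensitive than a
heuristic, fully reproducible, and fast (a vectorised sliding comparison).
Candidates with fewer than 3 mismatches to any known sequence are removed;
gapped homology is out of scope.

## Abundance concordance

RPKM is `1e9 * reads / (total_reads * exon_model_length)`. Detection
fractions are tabulated in log10-RPKM bins of width 0.5 (the width is a
display choice, configurable; zero-RPKM genes go to a dedicated bin since
they have no logarithm). Raw counts and fractions are emitted; any
histogram normalisation is left to the caller. The abundance–protein
concordance is the correlation between log10 RPKM and log10 spectral count
over detected genes only — spectral counts are defined only for detected
proteins, and both variables are always log-transformed before
correlating.

# The simulator: what it emulates, and what it does not

The generators are deterministic given `sim_config(seed)`; the defaults
are the study conditions the package validates itself against:

* **Genome/models** (default 80 genes, 5–7 exons of 180–260 nt, introns
  200–600 nt, two chromosomes, both strands). Exon length is bounded below
  by `2 * flank + 9` so the engineered flank regions of distinct splice
  sites can never collide within an exon.
* **Junctions**: all annotated introns not consumed by a novel event are
  emitted as known junctions; a gene hosts a novel event (exon skip or a
  9-nt alternative-acceptor shift) with a per-gene probability solved so
  the expected novel share of emitted junctions is 0.20. Read counts are
  negative-binomial, with novel junctions lower (mean 8 vs 50), echoing
  the lower abundance of novel isoforms.
* **Identifiability planting** is constructive, not rejection-sampled,
  so every junction has an exact truth label. Identifiable junctions
  (probability 0.05) get flanks that are stop-free in the frame aligned to
  the window, with K at residue 20 and R at residue 30, producing a 10-aa
  spanning peptide at zero missed cleavages. Non-identifiable junctions
  get a 12-nt self-reverse-complementary cassette (`TTAATTAATTAA`, a stop
  in every phase of both strands) placed 20–32 nt from the boundary in
  both flanks, so no stop-free stretch spanning the boundary can reach 30
  residues in any frame — such junctions contribute no database entry at
  all.
* **PSMs** (default 10,000; 30% incorrect): correct matches draw real
  tryptic peptides from target entries with Beta(8,1) scores; incorrect
  matches draw uniformly with Beta(1,8) scores and split evenly between
  targets and decoys, which is exactly the regime in which the decoy count
  estimates the incorrect-target count. The allocation of incorrect
  matches to junction targets (mirrored onto junction decoys) is solved in
  closed form from the Beta survival functions so the novel subset's naive
  FP rate at the anticipated global threshold is 0.38.
* **Expression** (default 2,000 genes): log-normal RPKM
  (log10 mean 1, sd 1), 5% zero-RPKM genes that are never detected,
  logistic detection in log10 RPKM (midpoint 0.5, slope 1.5), and spectral
  counts log-linear in RPKM whose noise sd is solved from the realised
  spread of detected log10 RPKM to target a Pearson correlation of 0.53.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: read-level RNA-Seq noise and junction discovery;
spectrum-level effects (peptide flyability, co-elution, modifications);
homologous gene families (the random reference proteome makes accidental
peptide sharing rare, whereas real proteomes are paralog-rich, making the
homology filter bite harder); and realistic score distributions
(PeptideProphet posteriors are bimodal in more complicated ways than a
two-component Beta mixture). The simulator closes the loop on the
*computational* contracts, not on instrument physics.

# Numerical choices and degenerate inputs

* Score ties in the FDR curve are grouped at one threshold (counts taken
  after the last tied observation); q-values are then tie-consistent.
* `threshold_at_fdr()` returns the most permissive threshold with
  q at or below the target, `NA` when unattainable; the subset filter
  returns an empty passing set rather than an error when the subset cannot
  reach the target, and `NA` with a warning when the subset has no decoys.
* Duplicate junction records merge by summed read count (commutative and
  associative, so input order is irrelevant); records with non-positive
  intron length or zero reads are rejected with warnings.
* The mismatch scan masks windows that straddle two reference proteins,
  and returns the peptide length when no window of sufficient length
  exists (every position would be a mismatch).
* Deduplicated database entries keep first-seen provenance; entry ids are
  assigned in first-seen order, so identical inputs produce byte-identical
  FASTA output.

# Problem sizes

The shipped validation runs at sizes chosen to make binomial error bars
informative while keeping a full run on one core in minutes: 80 genes
(~370 junctions) for the database stage, 1,000 random sequences for the
digestion oracle, 10,000 PSMs for FDR control, 500 peptide/database pairs
for the homology oracle, and 2,000 genes for the abundance stage.

# Limitations

Single-junction windows only: multi-junction transcripts and full isoform
reconstruction are out of scope, as are spectral searching itself,
mixture-model rescoring, spectrum quality scoring, protein inference, and
any peptide detectability model beyond length. The known/novel call is
exact-intron-match by design; fuzzy boundary matching (e.g. tolerating a
few nucleotides of slippage) would change the known fraction and is
deliberately not attempted.
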