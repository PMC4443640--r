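---
title: "Methods: mining, classifying and quantifying an SPL gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, classifying and quantifying an SPL gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`splfam` re-implements, as one reproducible pipeline, the computational
workflow used to characterize the SQUAMOSA PROMOTER BINDING PROTEIN-LIKE
(SPL) transcription-factor family in a plant genome: find every gene
carrying the ~76-aa SBP DNA-binding domain, locate miR156 binding sites
on the spliced transcripts, classify members into the family's three
structural subgroups, collect antisense/synteny evidence for ortholog
calls, build an SBP-domain phylogeny, and redo the expression arithmetic
(FPKM, TMM factors, qPCR relative expression with Tukey–Kramer
statistics) used in fruit-load studies of alternate bearing. This
vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data validation
does and does not establish.

## Family mining

Public-database keyword search plus BLAST confirmation is not
reproducible offline, so mining is re-cast as a deterministic two-stage
search with the same intent:

1. **Profile scan.** A position-specific scoring matrix is built from a
   seed alignment of reference SBP domains (`build_profile()`). Per
   column, residue frequencies receive a Laplace pseudocount (default
   1 per residue — appropriate for a small seed set of 16 sequences)
   and are converted to half-bit log-odds against a uniform background.
   Columns with more than 50% gaps are dropped. Every annotated protein
   (conceptual translation of its CDS) is scanned; windows scoring at
   least `min_fraction = 0.6` of the profile's maximum attainable score
   are candidate hits, reported best-first without overlap.
2. **Local-alignment confirmation.** Each candidate window must align
   to some unaligned reference domain with at least 40% identity over
   at least 60 Smith–Waterman columns (affine gaps, BLOSUM62,
   gap open −10, extend −1, half-bit units).

Both thresholds are exposed because the counts printed in genome
surveys depend on them; the defaults recover every planted domain at
70–95% identity to the seed consensus while admitting no random decoy
in the null simulations.

Loci are then collapsed to one representative transcript per gene:
longest CDS, ties broken by longest spliced transcript, then by
lexicographically smallest transcript id. Protein length is derived as
CDS length / 3 − 1; the annotation convention throughout the package
(and its fixture writer) is that a CDS includes its stop codon.

## The miR156 site scanner

The scanner looks for the *binding signature* — the reverse complement
of the 20-nt mature miR156 — on the mRNA-sense spliced transcript. A
window is an accepted site when (i) its mismatches to the signature
number at most `max_mismatches = 2` and (ii) every mismatch falls at an
allowed position, default {1, 7, 9}. Under that rule exactly 37
distinct 20-mers are accepted (1 exact + 9 single- + 27
double-mismatch variants), which the tests verify by exhaustive
enumeration.

Two conventions were genuinely open and are configurable:

* **Position numbering.** Mismatch positions are counted 1-based along
  the mature miRNA from its 5′ end (`position_origin = "mirna5p"`),
  which maps to the 3′ end of the transcript-sense site; published
  figures rarely state the direction, so `"site5p"` is available and
  the choice is recorded in outputs.
* **G:U wobble.** A wobble pair counts as a mismatch by default (the
  source material says only "mismatches"); `wobble_counts_as_match`
  relaxes this.

Windows containing `N` never match. Sites are located in the
5′UTR/CDS/3′UTR partition of the transcript; a site crossing a region
boundary is labelled `SPANNING` with the midpoint region as secondary,
rather than being forced into either region.

## Subgroup classification

The family's three subgroups are defined by strict inequalities:
proteins shorter than 200 aa with a 3′UTR site (`SHORT_3UTR`), longer
than 300 aa with a site inside the ORF (`LONG_ORF`), and members with
no site (`NO_SITE`). Boundary lengths (exactly 200 or 300 aa), 5′UTR
sites, and any other combination map to `UNCLASSIFIED`: the clades are
defined by what is observed, and the classifier does not invent
intermediate classes. A member's summary site is the 5′-most site on
its representative transcript.

Antisense evidence is structural only: every opposite-strand pair of
transcripts whose unspliced genomic spans overlap is reported, with an
`encompasses` flag computed on the spans (locus-level, matching how
such transcripts are described). Ortholog evidence combines four
components — SBP-domain local-alignment identity (scaled to [0, 1]),
protein length-class agreement, site-region agreement, and neighbor
coupling (both genomes carry an antisense/adjacent neighbor within
5 kb whose proteins align at ≥ 50% identity) — as an equally weighted
mean. No quantitative weighting exists in the source material; equal
weights are this package's convention, and the weights are arguments.
When neighbor context is missing in either genome that component is
excluded and the remaining weights renormalized rather than silently
counted as failure.

## Phylogeny

Domain sequences are aligned progressively: pairwise global alignments
(Needleman–Wunsch, affine gaps, deterministic traceback with tie order
diagonal > up > left) give percent-identity distances, an
average-linkage (UPGMA) guide tree orders the merges, and profiles are
merged leaf-to-root with profile–profile alignment whose column score
is the mean pairwise substitution score (gap–residue pairs contribute
0).

Distances are p-distances over co-ungapped columns with a Kimura-style
correction `d = −ln(1 − p − p²/5)` by default (Poisson `−ln(1 − p)`
and raw p available). Values outside the correction's domain are
capped at `d_max = 10` and flagged as saturated.

Tree inference is a from-scratch neighbor-joining implementation
(Saitou–Nei): Q-criterion ties are broken by the smallest index pair,
and a negative branch length at a join is clamped to zero with the
deficit transferred to its sister so path lengths are preserved. Full
maximum-likelihood inference was deliberately not re-implemented: the
downstream claims are clade memberships, which NJ on corrected
distances supports, and the tests verify exact recovery (topology and
branch lengths to 1e-9) on additive matrices plus agreement with an
independent NJ implementation. Trees are `ape::phylo` objects, so
newick round-trips and plotting use the standard toolchain. Midpoint
or outgroup rooting is left to `ape`; `clade_check()` works on
unrooted bipartitions, for which rooting is irrelevant.

## Expression arithmetic

**FPKM** is `count · 1e9 / (length · library size)`.

**TMM factors** follow the trimmed-mean-of-M-values algorithm:
M and A values on features expressed in both samples of a pair,
two-sided trimming (30% per tail on M, 5% per tail on A), inverse
asymptotic-variance weights, factor `2^(weighted mean M)`, recentred to
geometric mean 1. The reference sample defaults to the one whose upper
quartile is closest to the mean upper quartile. One deliberate
definitional choice: M values are computed on **raw counts**, so the
factor captures the full between-sample scaling (sequencing depth ×
composition) — a sample counted exactly twice as deep gets twice the
factor, and planted per-sample scalings in simulations are recovered
directly. The composition-only factor of the edgeR convention equals
this factor divided by relative library size, an identity the test
suite asserts against `edgeR::calcNormFactors` to 1e-9.

**qPCR relative expression** is 2^−ΔΔCt: per sample
ΔCt = Ct(gene) − Ct(reference gene); per group ΔΔCt is the group mean
ΔCt minus the calibrator group's mean. The calibrator is an explicit
argument (defaulting to the first group) because the original
description leaves it implicit; per-replicate RUs are retained for
statistics. Adding a constant to every Ct of a sample cancels in ΔCt,
which the tests check.

**ANOVA / Tukey–Kramer.** The one-way F test uses `stats::aov`.
Pairwise comparisons use the studentized-range distribution
(`stats::ptukey`, numerical — no printed tables) with the unequal-n
Tukey–Kramer standard error. Letters are assigned greedily from the
largest mean; groups sharing a letter are not significantly different.
All-identical data yield p = 1 by convention. The permutation
cross-check in the tests conditions on the observed data and permutes
group labels with a max-|q| family-wise statistic; near the α boundary
the permutation null is known to be slightly more liberal than the
normal-theory criterion at small n, so the tests compare decisions
away from the boundary and p-values quantitatively at it.

## The synthetic study conditions

`fixture_config()` pins the default conditions the whole validation
runs under: 12 family genes (3 short/3′UTR-site at the family's
characteristic 130/143/189 aa, 5 long/ORF-site at 310–450 aa, 4
no-site) and 8 decoys on 2 chromosomes; per-gene domain identity drawn
from 70–95% of a fixed synthetic consensus; a planted mismatch plan
covering the legal space ({}, {9}, {1,7}, {7}, {1}, {1,9}, {7,9}, {})
plus two deliberately illegal sites (position 5; three mismatches); one
PP2C-style antisense transcript encompassing the first short gene; two
extra isoforms exercising the representative-transcript tie rules.
Counts are negative binomial (dispersion 0.1, log-normal baselines)
with known per-sample factors and 10% asymmetrically spiked features;
Ct tables use baseline Ct 24, σ = 0.15, 3 replicates, and planted
folds including a 3-fold effect. All randomness flows from the single
config seed; generation is byte-reproducible, and a self-check pass
verifies the emitted files against the truth tables before anything is
returned.

The packaged seed alignment (`inst/extdata/sbp_seed_synthetic.afa`) is
synthetic: a fixed 76-column consensus with per-sequence mutations and
sparse gaps, standing in for curated reference domains that cannot be
fetched offline. Because the generator plants domains from the same
consensus, planted-truth recovery validates the *machinery* —
coordinate handling, scanning, thresholds, collapse rules — not the
biological sensitivity of the profile on real proteomes. Likewise the
generator does not emulate paralog clusters, pseudogenes, sequencing
error, alternative splicing beyond simple isoforms, or real codon
usage; passing tests therefore demonstrate algorithmic correctness
under controlled truth, and runs on a real genome remain subject to
the threshold caveats above.

Problem sizes used by the test suite and acceptance script — a ~47 kb
genome with 23 transcripts, 200×4 and 2000×4 count matrices, 50
random 5–8-taxon trees, 100,000-resample permutation nulls — were
chosen as the smallest designs at which every check is sharp (exact
structural recovery; Monte-Carlo error well below the asserted
margins).

## Known limitations

* The profile scan has no insert/delete states (not a profile HMM) and
  no iterative refinement; domains with long insertions relative to the
  seed would score poorly.
* The progressive MSA has no iterative polish; its guarantee in tests
  is ≥ 90% recovery of planted homologous column pairs, not optimality.
* Site scanning is positional only — no duplex thermodynamics, no
  cleavage-site inference.
* Ortholog evidence is a per-pair score, not genome-wide orthology
  inference; no reciprocal-best-hit tables or synteny blocks.
* qPCR fold recovery at n = 3 and σ_Ct = 0.15 carries ~12% standard
  error by propagation; single-draw estimates outside 10% are expected
  for some seeds and the acceptance script reports the realized error.
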