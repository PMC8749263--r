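---
title: "Methods: in-silico PCR on circular mitogenomes and mitochondrial-derived peptide prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico PCR on circular mitogenomes and mitochondrial-derived peptide prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoring)
```

## The problem

Sequencing a complete vertebrate mitogenome from total DNA is confounded by
NUMTs — nuclear copies of mitochondrial DNA that can be near-identical to
the organellar genome. One enrichment strategy amplifies the entire
mitochondrial ring as a *single* long-range PCR product using a
**back-to-back primer pair**: two oligonucleotides binding adjacently on
opposite strands with their 3' ends pointing away from each other, so that
extension runs the whole way around the circle. The pair shipped with this
package targets a region of MT-RNR2 (16S rRNA) that is extraordinarily
conserved across bony fishes, amphibians, reptiles, birds and mammals, and
that overlaps the sORF encoding the mitochondrial-derived peptide SHLP6.

`mitoring` models the computational side of this assay end to end:

1. **in-silico PCR** — find primer binding sites on a circular template
   under mismatch/indel tolerance and predict the single near-full-circle
   amplicon (`scan_primer()`, `pair_back_to_back()`, `predict_amplicon()`);
   inversely, derive such a pair from a conserved window of a vertebrate
   alignment (`find_conserved_motifs()`, `design_back_to_back()`);
2. **MDP prediction** — locate the nine mitochondrial-derived peptide
   (MDP) sORF loci (MOTS-c, humanin, SHLP1–6, gau), translate them under
   the rule that mitochondrial transcripts are translated in the cytoplasm
   by the *standard nuclear* genetic code, and classify each locus as
   intact or pseudogenized (`locate_locus()`, `scan_sorfs()`,
   `classify_mdp()`, `build_conservation_matrix()`);
3. **divergence and delimitation** — uncorrected p-distance with
   control-region exclusion and the Genetic Species Concept flag
   (`p_distance()`, `species_flag()`);
4. **candidate-site screening** — calling amino-acid residues at
   cold-adaptation/high-altitude candidate codons across species groups
   (`call_candidate_site()`, `group_contrast()`);
5. **synthetic data** — a seeded generator of annotated circular
   mitogenomes with planted ground truth (`generate_mitogenome()`,
   `mutate_haplotype()`, `plant_pseudogenization()`), so that every stage
   is testable without downloads.

## Coordinates and the circular model

All coordinates are 0-based, half-open and plus-strand oriented. On a
circular sequence (`circ_seq`) position arithmetic wraps modulo the length
`L`; spans crossing the origin are represented with `end > L` and `start`
in `[0, L)`. GenBank's 1-based inclusive spans (including two-part `join()`
locations that meet at the origin) are converted at the I/O boundary only.
Ambiguity codes match by expansion-set intersection everywhere (`N`
matches anything), because cross-species alignments of the primer region
legitimately contain SNPs.

## The primer-binding model

A primer binds where a *semi-global* ("fitting") alignment places it: the
primer is consumed in full, the template locally, under unit-cost edits.
Defaults: `max_edits = 2` and `three_prime_window = 3`. The 3'-window
constraint is structural — polymerase extension requires a paired 3'
terminus, so the terminal three primer bases must match with zero edits and
the edit budget applies only to the remaining prefix. Tolerating up to two
edits including a single-base indel reflects the deviations that still
amplified in practice (cross-species SNPs in the footprint and a
single-base insertion in two of the five target species); both are
exposed as arguments.

Implementation notes:

* the scan runs on the ring extended by `primer length + max_edits` bases
  so origin-spanning sites are found once;
* the fitting dynamic program is vectorized row-wise; the within-row
  dependency introduced by template insertions is closed with a running
  minimum (`cummin`) pass, so no compiled code is needed;
* overlapping alternative placements of one physical site are collapsed to
  the best (fewest edits, then lowest position); ties between footprint
  interpretations prefer the full-length (mismatch) reading over indel
  readings — the traceback prefers diagonal moves;
* the minus strand is scanned by reversing pattern and text and reusing
  the right-anchored machinery, so both strands share one code path.

The scanner is checked against an exhaustive per-offset `adist()` oracle
on planted 2-kb rings (100% site and edit-profile agreement required).

**Amplicon geometry.** For an opposite-strand site pair, the gap is the
circular distance from the minus-strand site's 5' boundary to the
plus-strand site's 5' boundary. Back-to-back geometry means a small gap
(`gap = 0` for adjacent footprints); the product runs the long way round,
so `product_length + gap = L` always. Same-strand pairs are rejected
outright and inward-facing pairs are rejected by the gap bound
(`max_gap = 50` nt by default). Among valid pairings the winner minimizes
total edits, then gap, then position.

**Design.** `design_back_to_back()` splits a conserved window at a
junction (default: `rev_len` bases in, making the two footprints
adjacent): the 5' block reverse-complemented becomes the reverse primer,
the 3' block the forward primer. Splitting the window
`rc(reverse primer) + forward primer` at position 25 reproduces the
published 25-mer/22-mer pair exactly, which is the package's round-trip
test. Window discovery scores sliding alignment windows by mean distinct
symbols per column (gap counts as a variant; fully conserved = 1.0) and
returns non-overlapping windows, ties leftmost — overlap suppression is a
design choice here, since adjacent shifts of one conserved block are not
independent discoveries.

## Genetic codes and the MDP translation rule

Codon tables for the standard nuclear code and the vertebrate
mitochondrial code (NCBI tables 1 and 2) are built in the package from the
TCAG enumeration plus the documented reassignments (ATA Ile→Met, TGA
Stop→Trp, AGA/AGG Arg→Stop); tests verify all 64 codons of both tables
against an independently shipped transcription. Start policy is explicit:
MDP prediction uses the standard code with start set `{ATG}` — the
cytoplasmic translation rule — while the extended mitochondrial start
repertoire `{ATG, ATA, ATT, ATC, GTG}` is available as an override. The
initiator residue is always reported as M. A codon containing an ambiguity
code translates to `X` and is never a terminator.

The gau locus ("gene antisense ubiquitous", antisense within MT-CO1) is
the reason the start policy is a first-class parameter: its sORF opens
with ATA, so under the plain nuclear rule it has *no functional start*
(`absent_no_start`), while `gau_extended_scan()` recovers a 14-residue
dwarf peptide. Both results are meaningful and both are reported.

## Locus anchoring and status classification

`locate_locus()` anchors a catalog reference sORF on a genome by seeded
homology search: 13-mers of the reference (one mismatch tolerated) seed
candidate placements on both strands of the doubled ring; each candidate
is refined by a fitting alignment (reference consumed in full, match 2,
mismatch −2, gap open 10, extend 4); the best placement is padded by a
30-nt flank and reported with percent identity. Below 60% identity the
locus is *not locatable* — deliberately a distinct status from
`absent_no_start`, because "we cannot find the homologous region" and "the
region is there but has lost its start" are different biological claims.
Seeding keeps the matrix construction fast; if no seed hits, the candidate
list is empty and the locus is reported not locatable (at the identity
floor of 60%, some 13-mer seed survives with overwhelming probability).

Classification is **anchored at the aligned reference start** and proceeds
in a fixed order:

1. net indel within the reference footprint not a multiple of three →
   `frameshift`;
2. no listed start codon at the reference start → `absent_no_start`
   (downstream in-frame starts are reported as secondary records, mirroring
   the downstream-AUG variants seen for MOTS-c, but do not rescue the
   primary call);
3. translation from the anchored start: peptide below the 8-residue
   minimum → `premature_stop`; no in-window terminator or peptide above
   the 40-residue maximum → `above_max_length`; otherwise `intact` with
   its observed length.

The 8–40 residue window is the accepted size range of the mitochondrial
sORFome, with eight residues as the minimal credible peptide. A deliberate
design choice sits in step 3: an in-frame stop that still leaves a peptide
of at least eight residues is reported as an **intact size variant**, not
a premature stop. The dwarf forms of SHLP4 (12 aa vs the long 26 aa) and
SHLP6 (9 aa vs 20 aa) are real, repeatedly observed variants across
vertebrates and are exactly this case; conflating them with
pseudogenization would erase the main comparative signal. A stop that
truncates below eight residues is what "no reasonable sORF size" means
here, and that is `premature_stop`.

`conserved_core()` reports the longest run of identical, ungapped columns
across a peptide set (equal-length sets are compared column-wise;
unequal-length sets go through a center-star merge of pairwise global
alignments against the longest peptide — adequate for ≤40-residue
peptides, not a general MSA).

## Divergence

`p_distance()` is the standard uncorrected p-distance: a global pairwise
alignment (Needleman–Wunsch via Biostrings) with substitutions counted
over mutually ungapped columns; gap columns are excluded from numerator
and denominator, and the output records this convention. The major
noncoding region is excluded by default — the control region's repeats and
length polymorphism make it unusable for delimitation — and `exclude =
NULL` restores the full-length comparison, so both values can be reported
side by side. Scoring is match 2 / mismatch −2 / gap open 12 / extend 8:
with these penalties a gap can never buy back a mismatch, so equal-length
substitution-only pairs align gaplessly and a planted divergence is
recovered exactly; tests require recovery within ±0.2 percentage points on
16-kb rings at 1–15% divergence. `species_flag()` applies the Genetic
Species Concept threshold for MT-CYB divergence strictly (> 11%): a
measured 10.3% does *not* flag, and interpretation close to the threshold
is left to the caller.

## Candidate-site screening

Sites are stored as gene-relative 1-based codon indices (with the human
mitogenome position as metadata where the literature reports one), so
non-human genomes are callable. `call_candidate_site()` anchors the gene
by homology, maps the target codon through the alignment columns, requires
all three codon positions to be present and contiguous (otherwise the call
is `uncallable` with the reason recorded), and translates under the
vertebrate mitochondrial code. `group_contrast()` is a descriptive
contingency table — the comparison across torpor-free-cold,
daily-torpor-or-hibernation and warm-habitat species groups (29 species
each) is qualitative by design, and no inferential statistic is attached.

## The synthetic-data generator

`generate_mitogenome()` emulates, per plan and seed (pure function of
both): a 14–20-kb circular genome; the canonical vertebrate gene order as
annotated placeholders with typical lengths scaled to the target size;
base composition skewed as in vertebrate mtDNA (defaults A 0.33, C 0.26,
G 0.13, T 0.28 — the strand-asymmetric, G-poor composition keeps the
spurious-ORF rate realistic); the nine MDP loci planted inside their host
genes, intact (optionally as sequence variants) or pseudogenized via
`plant_pseudogenization()`; the 47-nt primer motif planted so that the
SHLP6 sORF's last 17 coding bases are the motif's first 17 bases — the
published overlap geometry — with the primer plan (exact, k mismatches, a
single insertion, or absent) applied inside the forward-primer footprint
away from the 3' window; and an optional tandem-repeat array inserted in
the NCR. Planted premature stops land before both the half-length point
and the 8-residue minimum, so planted truth and classification agree by
construction rather than by tuning. `mutate_haplotype()` plants exactly
`round(L·d/100)` substitutions (no indels), optionally with per-region
rates, making divergence recovery testable to rounding precision.

What the generator does **not** emulate: real sequence homology between
the placeholder genes and any actual species, tRNA secondary structure,
NUMT backgrounds, heteroplasmy, or read-level errors. Consequently,
passing planted-truth tests demonstrates the correctness of the
algorithms' logic and geometry, not their performance on diverged real
genomes; the locus-anchoring path is additionally exercised at 5%
within-locus divergence and across rotations and strand flips, which is
the regime the anchoring is designed for.

The five-species study conditions (`study_plans()`) fix the qualitative
signatures used throughout the tests: MOTS-c intact in all five synthetic
species as variants sharing exactly one conserved four-residue core; SHLP4
as a 12-residue dwarf in four species and 26 residues in one, identical in
their first twelve residues; SHLP6 in 9- and 20-residue forms; humanin,
SHLP1, SHLP3 and SHLP5 pseudogenized throughout with mixed modes; gau
intact with its ATA start; and a single-base insertion at the forward
primer site in the two dormouse-like species.

## Numerical choices and degenerate inputs

* Anchor rotation (`rotate_to_anchor()`) breaks ties by smallest start
  position; determinism everywhere is preferred over any scoring subtlety.
* Empty slices are legal; wrapping requests on linear molecules are
  errors.
* `scan_primer` with a primer longer than the genome is an error; an
  unpaired scan is an empty table, not an error.
* Zero-length windows, windows longer than the alignment, and empty
  peptides in `conserved_core()` are errors with plain messages.
* Problem sizes in the test suite — 100 two-kb oracle rings, 100
  planted-truth genomes at 15 kb, divergence recovery on 16-kb rings —
  were chosen as the smallest sizes at which the properties are
  non-trivial for a ~16-kb mitogenome method.

## Known limitations

* Primers are plain ACGT in this version; degenerate-base primers are not
  modeled (templates may carry ambiguity codes).
* Indel tolerance is unit-cost; no affine gap model in the scanner —
  single-base events are the documented case.
* No melting-temperature or secondary-structure screening of designed
  primers.
* p-distance only; no Jukes–Cantor or model-based correction.
* The shipped MDP catalog and candidate-site reference residues are
  synthetic constructions with the documented hosts, lengths and
  start-codon behaviour; analyses of real genomes should supply a catalog
  extracted from annotated references.
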