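---
title: "TCR repertoire clonotyping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCR repertoire clonotyping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrclone)
```

## The analysis in one paragraph

`tcrclone` reconstructs T-cell receptor alpha/beta (TRA/TRB) repertoires
from merged amplicon reads.  Each read is assigned its best-matching V
and J gene segment by exhaustive Smith–Waterman local alignment against
an IMGT-style reference; the CDR3 junction is then cut out between two
conserved anchors — the cysteine codon at IMGT position 104 on the V
side and the phenylalanine (or tryptophan) codon at position 118 on the
J side — with the glycine at position 119 confirming the J reading
frame.  Reads sharing the same V gene, J gene and CDR3 amino-acid
sequence form one clonotype; clonotypes are copy-counted, ranked and
expressed as percentage frequencies, summarised as V×J usage matrices,
and compared across samples (tissues, groups, days), including
annotation of the canonical invariant T-cell receptors (iNKT:
TRAV11·TRAJ18; MAIT: TRAV1·TRAJ33).

A ground-truthed V(D)J read simulator accompanies the pipeline.  Every
quantitative claim the test suite makes about the pipeline is made
against this simulator's truth tables, so it is first-class, tested
code rather than a fixture.

## Segment assignment

The aligner scores match +2, mismatch −2, and charges a gap of length
*L* a total of |−4| + *L*·|−1| (affine; the opening base costs 5).  No
aligner or scoring scheme is published for the service pipelines this
package emulates, so these values are an explicit stand-in, exposed in
`assignment_params()`.  A hit is reported when the best local alignment
reaches `min_score_v = 40` / `min_score_j = 24` and at least 85% column
identity; the thresholds separate the bundled reference's segments
cleanly and scale with the +2 match score (40 ≈ a 20-nt exact block).
Equal best scores break deterministically: higher identity, then longer
aligned span, then lexicographically smallest gene name.  Inside the
dynamic program, the best cell is the first maximum in row-major order
and the traceback prefers diagonal over read-gap over segment-gap, so
results are identical across platforms.

Alleles compete as separate sequences and the winning allele is
reported, but clonotype keys use the gene only, matching gene-level
repertoire reporting (e.g. "TRAV12D-1-TRAJ22").  Reads are assumed to
have fixed orientation, as amplicons from 5′-adaptor libraries do;
`both_strands = TRUE` additionally scans the reverse complement and
keeps the orientation with the better V score.

Identical read sequences necessarily receive identical annotations, so
the implementation aligns each distinct sequence once and expands the
result — an exact optimisation, not an approximation.

## Junction extraction

Anchor codon positions are curated metadata carried by the reference
(`anchor_codon_start`, 0-based), never inferred by motif scanning on
the reference.  They are projected onto each read through the alignment
traceback.  The call is conservative in three ways:

* if any anchor base lies outside the aligned block or meets a gap, the
  read fails (`no_anchor_c` / `no_anchor_fg`) — no shifted-anchor
  guessing;
* the projected anchor codons are re-read from the read itself and must
  still translate to Cys and Phe/Trp — a sequencing error inside an
  anchor invalidates the junction rather than producing a malformed
  CDR3;
* the codon following the J anchor must translate to glycine (the
  position-119 check); it validates the frame but is not part of the
  reported junction, which runs anchor-to-anchor inclusive (C…F/W),
  the convention every published CDR3 amino-acid sequence uses.

A junction whose length is not a multiple of three fails
`out_of_frame`; an in-frame junction containing a stop codon is kept,
flagged `stop_codon`, and marked unproductive.

One deliberate deviation from a strict "V before J" rule: junctional
micro-homology (bases shared between the trimmed V 3′ end and the J 5′
start) routinely lets both local alignments extend one or two bases
across the true boundary, so V/J blocks overlapping by up to
`max_vj_overlap = 8` nt are accepted.  On error-free simulated data a
strict rule misclassifies roughly a quarter of perfectly valid reads;
8 nt is far above the micro-homology scale (the chance of an 8-base
coincidental extension is 4^−8) yet far below the overlap of a genuine
chimera, which still fails `vj_overlap`, as do reads whose projected
anchors cross.

## Clonotype statistics

The denominator for every percentage — clonotype frequencies and V/J/
V×J usage alike — is the set of reads that passed V and J assignment
and junction extraction and are productive.  `include_unproductive =
TRUE` additionally counts stop-codon junctions; reads without an
extractable junction never count.  Usage is read-weighted (each
eligible read counts once); a clonotype-weighted variant is available
by passing a clonotype table with modified counts, but read weighting
is the default because abundance, not richness, is what the 3-D usage
surfaces display.  Rank ties break lexicographically by
(v_gene, j_gene, cdr3_aa).  Text outputs print frequencies with two
decimals; full precision is kept in memory.

Cross-sample tables take the union of clonotype keys, one frequency
column per sample, with absences serialised as the literal `N.D.`
("not detected").  Invariant definitions match by V-gene *prefix*
(so `TRAV11` covers the `TRAV11d`/`TRAV11D` spelling variants), exact
J gene, and — only when a definition specifies one — exact CDR3.  The
shipped defaults define iNKT and MAIT by gene pair alone, with the
canonical CDR3s (`CVVGDRGSALGRLHF`, `CAVRDSNYQLIW`) carried as
documentation: the gene segments define these populations, and
requiring the CDR3 would silently drop length variants.

## The simulator: what it emulates, and what it does not

A simulated clone is V(trimmed at the 3′ end) + untemplated insert +
J(trimmed at the 5′ end).  Defaults, all overridable in
`simulation_config()`:

| parameter | default | rationale |
|---|---|---|
| abundance model | lognormal, meanlog 0, sdlog 1.5 | strongly skewed spectra in which a handful of clones dominate the top-30 ranking, the shape real amplicon repertoires show |
| trimming | uniform on 0…6 nt per side | no junction statistics are published for the emulated study; uniform small trims are a neutral choice |
| insert length | geometric, p = 0.4, capped at 12 | short, occasionally empty inserts |
| insert bases | i.i.d. uniform ACGT | neutral |
| sequencing error | i.i.d. substitutions at `error_rate` | substitution-dominated short-read error; no indels |
| quality strings | constant `I` (Q40) | quality modelling out of scope |

Trimming never removes an anchor codon; productivity (for
`productive_only = TRUE`) is achieved by padding the insert length to
restore the reading frame and resampling stop-containing junctions —
documented bias toward productive junctions, which is precisely what a
productive-only repertoire requires.  Spike-in clonotypes are built
deterministically: whole codons are templated greedily from the V
anchor forward and the J anchor backward, and interior residues are
reverse-translated to the lexicographically smallest codon, so a
requested (V, J, CDR3) is reproduced verbatim by error-free reads.
Read counts are multinomial in the true frequencies.  All randomness
flows from the single config seed; identical configuration and seed
give byte-identical clone tables and reads.

The default spike set (`canonical_spike_ins()`) carries the three TRA
clonotypes of interest in murine oral-mucosa metal-allergy work — iNKT
TRAV11-TRAJ18/CVVGDRGSALGRLHF, Cr-associated
TRAV12D-1-TRAJ22/CALSEKSSGSWQLIF, MAIT TRAV1-TRAJ33/CAVRDSNYQLIW — at
frequencies 0.15/0.08/0.04.  No per-sample read depths, clone counts or
clone frequencies are published for the study this mirrors, so these
defaults reproduce the reported *ordering* (iNKT dominant) and are not
calibrated to any measured value; they were chosen once and are stated
here rather than tuned.

What the simulator does **not** model — and therefore what passing
tests do not demonstrate about real data: PCR amplification bias,
UMI structure, indel sequencing errors, quality variation, paired-end
structure (reads are merged amplicons by construction), allelic
variation beyond what the reference contains, and D-segment identity
for TRB (D-derived bases ride inside the untemplated insert, matching
V–J–CDR3-keyed reporting).

## The bundled reference

`toy_reference()` is a synthetic reference — 8 V and 6 J segments per
chain with anchor-valid structure, including genes named TRAV11,
TRAV12D-1, TRAV1, TRAJ18, TRAJ22, TRAJ33 whose anchor-adjacent codons
are compatible with the canonical CDR3s above (TRAJ33's anchor is Trp,
as `…QLIW` requires).  It exists so that every example, test and the
acceptance script run offline and deterministically; it is not IMGT
data.  Real references load through the same `load_reference()` path:
a FASTA with `gene|allele|type|chain` headers plus a TSV of anchor
positions, validated on load (anchor in range and on frame, Cys/Phe/Trp
identity, unique gene-allele pairs) and round-trippable through
`write_reference()`.

## Problem sizes and verification

The test suite validates the pipeline end to end at the scale of one
repertoire sample: 50 random clones plus the three spiked clonotypes
and 10,000 reads per run, with smaller constructed cases for every
failure mode.  At `error_rate = 0` the pipeline recovers exactly the
simulated clonotype set with every junction byte-identical to truth; at
`error_rate = 0.005` V/J assignment stays ≥ 99% accurate and the spiked
clonotypes remain inside the top 30.  Segment assignment is checked
read-by-read against an independent full dynamic-programming
implementation (`Biostrings::pairwiseAlignment`) under the identical
scoring convention, and anchor projection against a column walk of that
oracle's own traceback.  `scripts/acceptance.R` re-runs these
computations from scratch at any seed.

## Known limitations

* Indel sequencing errors shift the junction frame and are reported as
  `out_of_frame` rather than corrected; the aligner tolerates indels,
  the junction logic deliberately does not guess through them.
* The aligner is exhaustive; for references orders of magnitude larger
  than a TRA/TRB segment set a seed-and-extend prescreen would be the
  natural extension (any such accelerator must remain score-equivalent
  to the exhaustive scan).
* Each input file is treated as one sample; pooling replicate animals
  is left to the caller.
* No repertoire-overlap statistics or diversity indices are computed;
  sharing is reported descriptively.
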