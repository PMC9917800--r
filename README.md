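# tcrclone

T-cell receptor (TCR) repertoire clonotyping from amplicon sequencing,
with a ground-truthed V(D)J read simulator.

When T cells infiltrate a tissue — an allergic oral mucosa, a draining
lymph node — the clonal composition of their receptors tells you what
the response looks like: how skewed it is, which V–J gene pairings
dominate, which exact CDR3 junctions are shared between tissues or
animals, and whether innate-like populations (iNKT, MAIT cells) are
involved.  `tcrclone` implements the standard analysis that turns
merged TRA/TRB amplicon reads into those answers, for immunologists who
want every step to be inspectable and testable rather than locked
inside a sequencing service.

## The method

1. **Segment assignment.** Each read is aligned by exhaustive
   Smith–Waterman local alignment (match +2, mismatch −2, gap of
   length *L* costs 4 + *L*) against every V and every J segment of an
   IMGT-style reference; the best hit per segment type is kept, with
   deterministic tie-breaking and score/identity thresholds for
   reporting.
2. **CDR3 extraction.** The junction runs from the conserved Cys104
   codon (V side) to the conserved Phe118/Trp codon (J side),
   inclusive, located by projecting the reference's curated anchor
   positions through the alignments; the following Gly119 codon
   validates the J frame.  The junction is translated and reads are
   called productive when the CDR3 is in frame, stop-free, and
   C…F/W-anchored.
3. **Clonotyping.** Reads with identical (V gene, J gene, CDR3 amino
   acids) form one clonotype; clonotypes are copy-counted, ranked and
   expressed as percentage frequencies, and marginalised into V×J
   usage matrices.
4. **Comparison.** Clonotype tables from multiple samples are crossed
   into shared-clonotype tables (absences marked `N.D.`), tracked over
   time, and annotated with invariant T-cell definitions (iNKT =
   TRAV11*·TRAJ18, MAIT = TRAV1*·TRAJ33).

The package also ships a seeded simulator (`simulate_repertoire()`,
`generate_reads()`) that produces repertoires with lognormal clonal
skew, junctional trimming and N-insertion, substitution sequencing
error, and spike-ins of exact clonotypes — so the whole pipeline can be
validated against known truth.  See the vignette
(`vignettes/repertoire-clonotyping.Rmd`) for the model, assumptions and
every default.

## Worked example

```r
library(tcrclone)

db <- toy_reference()          # bundled synthetic TRA/TRB reference
cfg <- simulation_config(n_clones = 20, read_count = 5000, seed = 7,
                         spike_ins = canonical_spike_ins())
clones <- simulate_repertoire(cfg, db)
reads  <- generate_reads(clones, cfg, db)

ann <- annotate_reads(reads$reads, db)
ct  <- aggregate_clonotypes(ann)
top_clonotypes(ct, 5)
#>    rank v_gene    j_gene cdr3_aa         copy_count frequency_pct
#> 1     1 TRAV11    TRAJ18 CVVGDRGSALGRLHF        773         15.5
#> 2     2 TRAV6     TRAJ33 CVLVSNYQLIW            562         11.2
#> 3     3 TRAV2     TRAJ22 CLPSSGSWQLIF           543         10.9
#> 4     4 TRAV1     TRAJ12 CAVCTGGYKF             462          9.24
#> 5     5 TRAV12D-1 TRAJ22 CALSEKSSGSWQLIF        388          7.76
```

The spiked iNKT clonotype (true frequency 0.15) is recovered at 15.5%
of reads and ranks first; the spiked Cr-associated clonotype (0.08)
ranks fifth at 7.76%.  Invariant annotation labels exactly the
canonical gene pairs:

```r
tab <- annotate_invariants(ct)
tab[!is.na(tab$label), c("rank", "v_gene", "j_gene", "cdr3_aa",
                         "frequency_pct", "label")]
#>    rank v_gene j_gene cdr3_aa         frequency_pct label
#> 1     1 TRAV11 TRAJ18 CVVGDRGSALGRLHF         15.5  iNKT
#> 2    11 TRAV1  TRAJ33 CAVRDSNYQLIW             3.74 MAIT
```

`run_pipeline()` wraps steps 1–3 with AIRR Rearrangement TSV output and
a run manifest (read accounting, config hash), and `exec/tcrclone`
exposes `simulate`, `annotate`, `clonotypes`, `compare` and `run`
subcommands for shell use.

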