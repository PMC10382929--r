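---
title: "Comparative analysis of fragmented mitochondrial minichromosome karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of fragmented mitochondrial minichromosome karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minikaryo)
```

## The biological problem

Most animals carry a single circular mitochondrial (mt) chromosome with
37 genes.  Sucking lice (Anoplura) instead fragment this genome into
9–20 small circular **minichromosomes**, each composed of one short
gene cluster and one large **non-coding region (NCR)** that is highly
conserved across the minichromosomes of a species.  A species'
**mt karyotype** — the number of minichromosomes, their gene content
and gene arrangement — varies between even closely related species,
and recombination *between* minichromosomes (producing gene
translocations, duplications, chromosome mergers and chimeric
molecules) is the leading explanation.

`minikaryo` makes this comparative analysis reproducible end to end:
it models karyotypes, compares them, infers recombination-derived
events against an ancestral karyotype by parsimony, tallies
recombination hotspots, screens sequences for the classical
shared-identical-stretch evidence and for conserved NCR motifs, and —
because the real data live in sequence archives — ships a synthetic
genome/read generator and a toy assembler so every stage is testable
offline.

## The karyotype model and grammar

Each minichromosome is circular with exactly one large NCR, which gives
a natural origin: gene order is read in the majority transcription
direction **starting immediately downstream of the NCR**.  Circular
comparison thereby reduces to plain list comparison.  The text grammar
is one minichromosome per line, genes joined by `-`:

* `~` prefix — reverse orientation (stands in for the underline
  convention of genome diagrams), e.g. `~Q-~nad1-~T-G-nad3`;
* `p` prefix — pseudo gene, e.g. `patp8`;
* `#n` suffix — second and later copies of a duplicated gene; copies
  compare equal by name;
* up to four optional tab-separated size columns (total, cluster, NCR,
  pseudo, in bp).

```{r grammar}
k <- load_fixture("L_vituli")
summarize_karyotype(k)
```

Sizes from published tables are carried **verbatim**: the printed rows
are not always internally additive (e.g. one row prints a 3,052 bp
total against 1,887 + 1,160 = 3,047 bp of parts, presumably gene
overlap accounting), so `total = cluster + NCR` is asserted only for
synthetic genomes.  Missing sizes propagate to absent (`NA`) totals,
never zero.

The four packaged fixtures are the two louse species karyotypes
(transcribed from the published minichromosome tables and genome maps)
and two inferred ancestral karyotypes — of sucking lice as a whole
(11 minichromosomes) and of the *Linognathus* genus (10).  Ancestral
gene orders beyond the portions stated in prose are transcribed from
the published ancestral-karyotype reference; all algorithms treat the
ancestor as a swappable input, never a constant.

## Comparing karyotypes

`chromosomes_equal()` compares the NCR-anchored gene lists by name and
orientation.  **Pseudo genes are ignored by default**: the source
study counts a minichromosome that differs only by a degenerate pseudo
copy as having "the same gene content and gene arrangement" (that is
how both species share 7 of 10 minichromosomes although one of the
shared pairs differs by a pseudo *atp8*).  Strict comparison is a flag
away (`ignore_pseudo = FALSE`).

`compare_karyotypes()` and `match_chromosomes()` pair minichromosomes
greedily by descending shared-full-gene count (duplicates count once
per name, pseudo genes are excluded from the score), breaking ties
lexicographically by label — the study never states a tie rule, so the
lexicographic convention is ours, chosen for determinism.  On random
instances with up to six chromosomes per side the greedy matching
attains the exhaustive optimum (verified against a brute-force oracle
in the test suite).  An unmatched ancestral minichromosome whose full
genes all survive on a single already-matched derived minichromosome is
flagged as a **merger** candidate.

## Event inference and the anchor convention

`infer_events()` classifies every derived gene occurrence and every
ancestral gene exactly once:

| class | meaning |
|---|---|
| retained | present in its matched ancestral context |
| translocation | full gene moved; ancestral copy unaccounted elsewhere |
| duplication_insert | extra full copy; original retained in place |
| partial_duplication | pseudo gene whose full namesake lives elsewhere |
| degeneration_in_place | pseudo gene at the gene's ancestral location |
| deletion | ancestral gene with no derived occurrence |
| merger | two ancestral minichromosomes fused into one |

Maximal adjacent runs with one donor collapse to a single event (a
three-gene run like `R-nad4L-P` rides on one recombination transfer).

The **location anchor** of an event is the nearest *downstream, full,
single-copy, retained* gene.  Skipping pseudo genes, duplicate copies
and co-inserted genes is deliberate: successive insertions at the head
of a cluster then all anchor to the same stable ancestral coordinate,
which is how the source study counts them (a duplicate tRNA inserted
"upstream of *nad2*" still anchors to *nad2* even when an earlier
duplicate insertion lies between).  With the naive
nearest-downstream-gene rule the hotspot ranking would be distorted by
the inserted genes themselves.

`min_recombination_events()` turns the events at one anchor into the
parsimony lower bound: the number of **distinct donor
minichromosomes** (material from one donor can arrive in one event).
When several events share a donor the bound is flagged `ambiguous` and
the event count is reported as `max_events` — reproducing the study's
"at least three, possibly four" reading at the *nad2* hotspot without
silently choosing either.

```{r infer}
mrca <- load_fixture("MRCA_Linognathus")
infer_events(mrca, load_fixture("L_africanus"))[, 1:6]
```

## Sequence-level evidence

* `percent_difference()` — global end-to-end alignment (match +1,
  mismatch −1, gap −2 per column, configurable; Needleman–Wunsch via
  Biostrings); difference = (mismatch + gap columns) / alignment
  length.  The study never defines its per-gene percentages, so the
  convention is declared in the result's attributes and the published
  per-gene values are reported, not asserted.
* `longest_shared_stretch()` — exact longest common substring
  (row-vectorized dynamic programming), optional reverse-complement
  search; ties resolve to the smallest position in the first sequence.
  `stretch_null_quantile()` gives the Monte-Carlo chance null (iid
  multinomial at the stated GC; no Markov-order correction — a declared
  limitation).  Observed stretches above the null quantile are the
  classical recombination signature.
* `find_conserved_motifs()` — maximal exact substrings common to
  *every* supplied NCR, length-ranked, each annotated with AT fraction
  and a position class (NCRs are read from cluster end around to the
  next cluster start, so first-half occurrences are downstream of the
  cluster, second-half upstream; majority vote across NCRs).
  Mismatch-tolerant motifs are out of scope: the emulated genomes carry
  one exactly conserved AT-rich and one GC-rich motif per species.

## The synthetic world

`generate_ancestral_genome()` emulates the architecture the study
describes: 10 minichromosomes by default (valid range 9–20), the
species-table gene partition with 2–8 genes per cluster, one
reverse-oriented run (`~Q-~nad1-~T`), realistic mitochondrial gene
lengths, NCRs of 686–1,296 bp carrying a planted AT-rich motif
(45 bp, 100 % A+T) upstream of the cluster and a GC-rich motif (78 bp,
60 % G+C) downstream of it.  All randomness flows through one integer
seed into R's Mersenne-Twister, so genomes are bit-reproducible across
platforms.

Deliberate simplifications, hence what a green test does *not*
establish:

* **NCRs within a genome are identical by default** — the toy limit of
  the observed high conservation.  Per-minichromosome NCR length
  variation is not modelled.  `ncr_divergence` mutates the non-motif
  background per minichromosome (≈0.1 makes only the motifs exactly
  shared, the regime for the motif-discovery closed loop), but the
  assembler's exact-reconstruction guarantee is established only in the
  identical regime; with divergent NCRs a per-column majority across
  minichromosomes can overrule one minichromosome's own variant — in
  the real study the NCRs were finished by amplicon sequencing for the
  same reason.
* Genes abut without intergenic spacers or overlaps; pseudo genes arise
  only as copied windows (150–450 bp, bracketing the observed pseudo
  sizes) or in-place status flips.
* Reads: uniform circular sampling, FR orientation, 300 bp reads /
  530 bp inserts by default, substitution errors only (no indels, no
  GC-bias, no heteroplasmy), constant Q37 qualities with a
  degraded-tail mode that exists solely to exercise the Q20/50 % filter.

`apply_events()` records every random choice (insertion position,
window coordinates) in its truth log, so replaying a log reproduces the
derived genome byte-identically.  In random mode each sampled event
touches fresh genes and minichromosomes, so the inference closed loop
(`infer_events()` recovering the log) is expected to succeed
essentially always; the acceptance criterion requires ≥95 % over 200
seeded replicates.

## The toy assembler

`filter_reads()` drops a pair when either mate has >10 % `N` or >50 %
of bases at Q ≤ 20 (Phred+33).  `iterative_extend()` is
seed-and-extend with the study's defaults (minimum overlap 200 bp at
99 % identity; overlap identity is exact matches over overlap length —
substitution-only, no gaps): reads whose overlap covers a contig end
are recruited with `Biostrings::vmatchPattern()`, the contig grows by
the per-column consensus, and the contig closes into a circle when its
ends mutually overlap under the same thresholds.

Numerical choices that matter:

* **Supermajority consensus** (`consensus_frac = 0.7`): a column
  extends only when the leading base holds ≥70 % of votes.  At the
  shared-NCR→cluster junctions reads from all minichromosomes are
  recruited and disagree, so extension stalls instead of guessing; a
  bare majority was observed to produce chimeras when one
  minichromosome locally dominated by chance.  Circularization is
  detected *before* any such junction must be resolved, because a
  contig that has traversed its own cluster plus the NCR already
  overlaps itself.
* The study extended ~500 bp into the NCR and then switched strategy;
  the exact stopping rule is unstated, so extension here runs to a
  fixpoint instead (the stall-at-ambiguity rule supplies the stop).
* `derive_ncr_consensus()` anchors on the exact longest common
  substring of the two doubled circles, extends across *isolated*
  mismatches only (a mismatch is absorbed when the next ten columns
  match), and trims `end_trim = 8` bases per end — chance matches
  running past the cluster junction would otherwise poison the bait
  windows.
* `bait_assemble()` groups junction-spanning reads by a 30 bp
  cluster-head flank (small Hamming tolerance, ≥2 supporting reads) and
  seeds one extension per group; the number of distinct circular
  contigs is the minichromosome-count estimate.  Circular contigs are
  canonicalized at the NCR-consensus cut, else at the lexicographically
  minimal rotation.
* Repeats longer than the minimum overlap (e.g. long identical
  duplicate genes) would stall extension, as in any overlap assembler;
  the ancestral generator produces none.

## Pipeline and reproducibility

`run_pipeline()` chains compare → infer → hotspots → stretches →
motifs → simulate → assemble from a flat config
(`pipeline_config()` / `read_run_config()`; CLI flags win over file
values), logs to standard error, and writes TSV/JSON reports whose
bytes are identical across reruns with the same config and seed.
Every protocol default (200 bp, 99 %, 300 bp, 530 bp, 10 %/50 %/Q20)
is visible in the CLI `--help` text.

## Known limitations

* Branch-wise inference only: the ancestor is always supplied;
  reconstructing it from descendants is out of scope.
* No likelihood/DCJ-style rearrangement model — the event taxonomy is
  the study's, counted by parsimony.
* Published per-gene difference percentages and the 133 bp shared
  stretch require the archived sequences, which are deliberately not
  fetched; those values are reported by the tools but asserted nowhere.
* The chance null for stretch lengths is iid by composition only.
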