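# minikaryo

Comparative analysis of fragmented mitochondrial minichromosome
karyotypes, for the molecular-evolution community working on sucking
lice (Anoplura) and other animals with multipartite mitochondrial
genomes.

Sucking lice carry their 37 mitochondrial genes (13 protein-coding, 22
tRNA, 2 rRNA) on 9–20 small circular **minichromosomes**, each with one
gene cluster and one large non-coding region (NCR).  Karyotypes — the
number of minichromosomes, their gene content and arrangement — differ
even between congeneric species, and recombination *between*
minichromosomes is the favoured explanation.  `minikaryo` provides:

* a compact **karyotype grammar** (`E-cytb-S1-S2-R-nad4L-P-atp8`, with
  `~` reverse orientation, `p` pseudo genes, `#2` duplicate tags) with
  parser, serializer, summaries and packaged fixtures for two louse
  species and two inferred ancestral karyotypes;
* pairwise **karyotype comparison** (identical-minichromosome
  detection, ancestral↔derived chromosome matching with merger
  detection);
* **parsimony event inference**: every gene occurrence classified as
  retained / translocation / duplication insert / partial duplication /
  degeneration in place / deletion / merger, with a minimum-event lower
  bound per insertion location — the number of distinct donor
  minichromosomes among events anchored there — and **hotspot tallies**
  across branches;
* sequence evidence: alignment **percent difference** of gene copies,
  **longest shared identical stretch** with a Monte-Carlo chance null,
  and conserved **NCR motif discovery**;
* a seeded **synthetic genome / paired-end read generator** with a
  replayable ground-truth event log, and a toy **iterative
  seed-and-extend assembler** with circularization and NCR-bait
  recovery of whole genomes (filter → two seed assemblies → shared-NCR
  consensus → bait).

## Worked example

```r
library(minikaryo)

kv <- load_fixture("L_vituli")      # cattle louse
ka <- load_fixture("L_africanus")   # goat louse

summarize_karyotype(kv)
#> <karyotype summary> Linognathus vituli
#>   minichromosomes:     10
#>   distinct full genes: 37
#>   duplicate copies:    1
#>   pseudo genes:        4
#>   total / cluster / NCR / pseudo bp: 26,258 / 14,013 / 11,210 / 851
#>   full genes per minichromosome: 2-8

compare_karyotypes(kv, ka)
#> <comparison> Linognathus vituli vs Linognathus africanus
#>   shared: 7, differing: 3, unmatched: 0 + 0
```

Both species have 10 minichromosomes totalling 26,258 and 35,270 bp;
seven of the ten are identical in gene content and arrangement.
Inferring events on the branch from the genus ancestor to the goat
louse:

```r
mrca <- load_fixture("MRCA_Linognathus")
infer_events(mrca, ka)[, c("type", "gene", "donor", "location_anchor")]
#>                    type gene       donor location_anchor
#> 1    duplication_insert    H H-nad5-F-L2            cox3
#> 2    duplication_insert    M M-L1-rrnL-V            nad2
#> 3 degeneration_in_place atp8        <NA>            atp6
```

— a duplicate *trnH* inserted upstream of *cox3*, a duplicate *trnM*
upstream of *nad2*, and the original *atp8* degenerated in place.
Tallying all three branches ranks the recombination hotspots:

```r
anc <- load_fixture("MRCA_Anoplura")
hotspot_tally(list(stem      = infer_events(anc, mrca),
                   vituli    = infer_events(mrca, kv),
                   africanus = infer_events(mrca, ka)))
#>   anchor stem vituli africanus total rank
#> 1   nad2    1      3         1     5    1
#> 2   cox3    0      2         1     3    2
#> 3   atp6    0      1         1     2    3
#> 4      A    1      0         0     1    4
```

The locations upstream of *nad2* and *cox3* collect the most
independent events; the insertions at *cox3* need at least
`min_recombination_events(...) = 3` recombination events because their
donors (*rrnS*, *rrnL*, *trnH*) sat on three different ancestral
minichromosomes.

The synthetic closed loop — generate a genome, apply logged events,
simulate reads, re-assemble, re-infer — runs offline:

```r
g  <- generate_ancestral_genome(seed = 42)        # 10 circles, planted motifs
ae <- apply_events(g, n_events = 3, seed = 7)     # derived genome + truth log
ev <- infer_events(g$karyotype, ae$genome$karyotype)
events_match(ae$truth, ev)
#> [1] TRUE
```

A command-line front end mirrors the stages
(`compare`, `infer-events`, `hotspots`, `stretches`, `motifs`,
`simulate`, `assemble`, `run-all`):

```sh
Rscript -e 'minikaryo::minikaryo_cli()' run-all --out out/ --seed 1
```

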