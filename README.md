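# srnascan

Genome-wide discovery and characterization of bacterial small RNAs (sRNAs)
from differential RNA-Seq (dRNA-Seq) data.

dRNA-Seq sequences two libraries from the same small-RNA fraction: one
treated with a 5′-monophosphate–specific exonuclease so that only primary
transcripts with native 5′-triphosphate ends survive (library 1), and one
untreated library representing the whole small transcriptome (library 2).
`srnascan` turns strand-specific read alignments of such a pair into a
catalogue of promoter-validated sRNA genes:

1. **Profiles** — per-position, per-strand read-start counts and coverage
   depth; library accounting by annotation category (rRNA, tRNA, mRNA sense,
   cis-antisense, unannotated).
2. **TSS calling** — position *i* on a strand is a transcription start site
   candidate when its read-start count *x<sub>i</sub>* exceeds a background
   threshold *T* (default 19, i.e. ≥ 20 starts) and the ratio
   *x<sub>i</sub>*/*x<sub>i−1</sub>* to the transcription-upstream neighbour
   exceeds *R* (default 5); a stack rising from a zero-count neighbour always
   passes.
3. **Promoter validation** — −35/−10 sigma-factor box models
   (position weight matrices, spacer 16–20 bp) trained by a two-box
   expectation–maximization algorithm on published binding-site sets, with
   score thresholds calibrated on shuffled-sequence control runs; SigA
   promoters with a poorly conserved −35 can be rescued by a well-conserved
   extended −10 element. Candidates without promoter evidence are dropped;
   survivors within 3 nt collapse to the strongest stack.
4. **Transcript bounds** — 3′ ends by walking library-2 coverage downstream
   until it falls below a cutoff (default 10); multiple starts within 100 bp
   sharing a 3′ end merge into one region; Rho-independent terminators
   (hairpin + U-rich tail, logistic confidence > 0.75) are detected within
   ±60 nt of the 3′ end.
5. **Classification** — mRNA leader (3′ end < 100 nt before a same-strand
   CDS start), cis-antisense RNA (TSS inside an opposite-strand CDS),
   antisense 5′/3′-UTR (TSS within 100/60 nt of the opposite CDS ends), or
   trans-encoded sRNA; locus tags in the trailing-zero nomenclature
   (`cg0010` → `cgb_00100`; novel features use the freed last digit, e.g.
   `cgb_00105`).
6. **Small ORFs** — 48–249 nt ORFs (≥ 15 aa) with a Shine–Dalgarno match
   (`AGGAG`, ≥ 4/5 identities, 15 nt window) or a leaderless start at the
   TSS; homopolymer residue runs flag attenuator leader peptides.
7. **Conservation & enrichment** — RNAz-style structure-conservation windows
   (p ≥ 0.5, mean pairwise identity > 60%) merge into loci intersected with
   trans-encoded sRNAs; functional-class enrichment of asRNA target genes by
   the fixed <10% / >20% representation rule.

A fully seeded synthetic-data generator (`generate_world()`,
`simulate_libraries()`) plants ground truth for every one of these signals,
so each stage is benchmarked by parameter recovery rather than by eye.

## Worked example

Generate a 60 kb synthetic world with 16 planted sRNA regions, simulate both
dRNA-Seq libraries, and run the pipeline:

```r
library(srnascan)
library(dplyr)

cfg <- synthetic_config(
  genome_length = 60000,
  counts = c(leader = 3, asRNA = 4, as5UTR = 2, as3UTR = 2, trans = 5)
)
world <- generate_world(cfg, seed = 5)
aln <- simulate_libraries(world, seed = 5)

res <- run_pipeline(
  world$genome, world$annotation,
  filter(aln, library == 1), filter(aln, library == 2),
  promoter_models = list(world$promoter_model),
  conservation = world$truth_windows
)
select(res$regions, id, locus_tag, class, strand, tss, three_prime, length)
#> # A tibble: 16 × 7
#>   id          locus_tag class         strand   tss three_prime length
#>   <chr>       <chr>     <chr>         <chr>  <int>       <int>  <int>
#> 1 region_0001 <NA>      mRNA_leader   +       7924        8097    174
#> 2 region_0002 cgb_00105 trans_encoded +      12229       12303     75
#> 3 region_0003 cgb_00125 asRNA         +      15075       15130     56
#> 4 region_0004 cgb_00146 trans_encoded +      17834       17920     87
#> # …
```

The log prints per-stage counts (16 stacks, 16 promoter-validated TSS, class
counts 3/4/2/2/5). Per-class length statistics mirror what the simulation
planted — short cis-antisense RNAs, ~90 nt trans-encoded sRNAs, long
leaders:

```r
length_stats(res$regions)
#> # A tibble: 5 × 6
#>   class             n  mean median   q25   q75
#> 1 mRNA_leader       3 166.   174   152.  183
#> 2 asRNA             4  55.5   54.5  51    59
#> 3 as5UTR            2  79     79    78.5  79.5
#> 4 as3UTR            2  69     69    62    76
#> 5 trans_encoded     5  88.2   86    75    87
```

Scoring the calls against the planted truth:

```r
evaluate_against_truth(res$regions, world)
#> # A tibble: 4 × 4
#>   stage       precision recall     n
#> 1 tss             1          1    16
#> 2 three_prime    NA          1    16
#> 3 class          NA          1    16
#> 4 terminator      0.667      1     2
```

Every planted TSS is recovered at the exact base, every 3′ end within
±10 nt, and every positional class label matches. `tidy()`, `glance()` and
`autoplot()` methods expose profiles and promoter models in tidyverse form;
`inst/scripts/srnascan.R` wraps `synth` and `run` for shell use.

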