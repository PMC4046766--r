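---
title: "Methods: sRNA discovery from dRNA-Seq profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sRNA discovery from dRNA-Seq profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

Differential RNA-Seq pairs two libraries from one small-RNA preparation. In
library 1 a 5′-monophosphate–specific exonuclease removes processed and
degrading transcripts, so read 5′ ends pile up at genuine transcription
start sites; in library 2 (untreated) reads sample the whole small
transcriptome, so coverage depth traces transcript bodies. `srnascan`
exploits exactly this asymmetry: *read starts* of library 1 drive TSS
calling, *coverage depth* of library 2 drives 3′-end calling. All
coordinates are 1-based inclusive (the R/Bioconductor convention); BED input
is converted at the boundary. The chromosome is treated as linear with a
configurable no-call margin at both ends (default 300 nt), since
origin-spanning transcripts are not modelled; the pipeline operates on one
chromosome at a time.

# TSS calling

Position *i* on a strand is a candidate when the read-start count
$x_i$ satisfies $x_i > T$ and either $x_{i-1} = 0$ or $x_i / x_{i-1} > R$,
where $x_{i-1}$ is the transcription-upstream neighbour (strand-aware).
Defaults are $T = 19$ (at least 20 read starts) and $R = 5$; both
inequalities are strict, so a ratio of exactly 5 does not call. A stack
rising from a zero neighbour is treated as passing the ratio condition — it
is the strongest possible 5′ edge, and any other convention would make the
rule undefined there. Candidates inside rRNA/tRNA genes (either strand) or
sense within a CDS are removed before promoter analysis: they reflect
stable-RNA or mRNA signal, not sRNA candidates.

After promoter validation, candidates within 3 nt of each other on a strand
collapse to the one with the largest $x_i$; ties break to the upstream-most
position, which favours the longer transcript. "Strongest" is measured on
the raw count — no normalizer is defined for a single library, so none is
applied.

# Promoter models

Each sigma factor is modelled by −35 and −10 position weight matrices
(widths 6/6), a spacer range of 16–20 bp, and for SigA an extended −10
matrix covering the 8 nt immediately upstream of the −10 box (the classic
TG-containing extension that can compensate for a weak −35).

**Training.** A two-box expectation–maximization algorithm fits both
matrices to equal-length training sites, assuming one occurrence of each box
per sequence with the spacer marginalized over 16–20 bp. Specifics:
pseudocount 0.25 per base; background = 0-order composition of the training
set; at most 200 iterations; convergence when the log-likelihood gain drops
below 1e-6; 4 random restarts (seeded), keeping the best likelihood;
initialization from one random placement per sequence. Non-convergence is an
error that still carries the best-so-far model. The extended −10 matrix is
estimated from the posterior placement distribution after convergence, so it
requires no second EM.

**Thresholds.** Score thresholds come from control runs on shuffled copies
of the training sequences (30 runs, seeded). Every threshold is a statistic
of the *best* score a control run achieves: the per-box and combined
(joint two-box) thresholds are means of the per-run best scores, and the
extended-−10 threshold is the maximum best score over all runs. Using
per-run *best* scores rather than average scores makes the gate demand
box matches that random sequence essentially never produces, which is what
keeps boxes at an invalid spacing (for example 21 bp) from being rescued by
a chance partner box elsewhere in the window.

**Scanning.** The 60 nt window ending 1 nt before the TSS
(strand-aware, reverse-complemented on the minus strand) is scanned over all
(−35 start, spacer) placements. The reported placement maximizes the weaker
of the two box scores — both boxes must be recognized by the sigma factor,
so the weakest-link criterion is the natural ranking — with the joint score
as tie-break. A hit requires both box scores and the joint score to reach
their thresholds. For SigA only, a failed two-box scan can be rescued by the
extended −10: if the 8-mer immediately upstream of a −10 box that itself
passes its threshold scores at or above the maximum control score, the TSS
is accepted regardless of the −35 (the −10 requirement is kept; only the
−35 score is waived). A TSS may carry hits from several models, representing
transcript variants recognized by different sigma factors.

# Transcript 3′ ends and terminators

From each validated TSS the library-2 coverage profile is walked downstream;
the 3′ end is the last position at or above the cutoff (default 10) before
the first position below it. The cutoff phrase "number of reads" is
ambiguous between read starts and depth; depth is the default because a
transcript body is defined by depth, while read starts are 5′-biased.
`use_starts = TRUE` gives the literal read-start walk. Walks shorter than
35 nt (one read length) fall back to a 35 nt region flagged `low_support`:
nothing shorter is resolvable with 35 nt reads. Same-strand regions whose
TSS lie within 100 bp and whose 3′ ends are identical merge into one region
carrying all starts (multiple promoters of one unit); merging is idempotent.

Rho-independent terminators are detected by exhaustive stem-loop
enumeration: stems of 4–15 bp with at most one mismatched pair, loops of
3–10 nt, pair weights G:C = 3, A:T = 2, G:U = 1, followed by a 15 nt tail
whose thymines are counted with linearly decaying positional weights
(a U adjacent to the hairpin contributes 1, the 15th position 1/15).
Confidence is `plogis(0.3·stem + 0.8·tail − 9)`; these repository-defined
constants are calibrated so that a canonical strong terminator (8 bp all-GC
stem, U8 tail; stem score 24, tail score 6.13) scores above 0.9 while random
windows stay below the 0.75 reporting threshold. The detector is *not* a
TransTermHP re-implementation and published terminator counts are not
reproduction targets. The highest-confidence hit whose hairpin ends within
±60 nt of a region 3′ end is attached; the window is read as centred
("around the 3′ end") rather than one-sided. Absence of a terminator is a
normal outcome for bacterial sRNAs.

# Positional classification

Decision order: (1) **mRNA leader** — a same-strand CDS start strictly less
than 100 nt downstream of the region 3′ end, or the region overlaps that
start; (2) **asRNA** — TSS inside an opposite-strand CDS; (3) **as5′-UTR** —
TSS within 100 nt upstream (inclusive, in the opposing gene's orientation)
of an opposite-strand CDS 5′ end; (4) **as3′-UTR** — TSS within 60 nt beyond
an opposite-strand CDS 3′ end (inclusive); (5) otherwise **trans-encoded**.
"Less than" is strict where the source phrasing is "less than", and
inclusive where it is "within"; the boundaries are tested explicitly. A
region qualifying as both asRNA and as5′-UTR is an asRNA (positional
precedence). The two documented dual memberships (as5′-UTR that is also
as3′-UTR; leader that is also as5′-UTR) are recorded as secondary labels;
both the raw per-class counts and their sums are logged so overlapping and
de-duplicated totals can be distinguished.

Locus tags follow the trailing-zero nomenclature: CDS `cg0010` owns
`cgb_00100`, and the freed final digit numbers novel features between
consecutive CDS in genomic order, spread over 1–9 (one feature gets digit 5,
two get 3 and 6, and so on); more than nine features between one CDS pair is
an error demanding manual tags. Only antisense and trans-encoded regions are
tagged.

# Small ORFs, conservation, enrichment

ORFs of 48–249 nt including the stop codon (≥ 15 aa) are scanned on the
region's sense strand in all three frames, with starts ATG/GTG/UUG and stops
TAA/TAG/TGA; the 48 nt minimum equals 15 codons plus stop, which is why the
two statements of the bound (nucleotides vs residues) are consistent. An ORF
is kept as a small mRNA if the 15 nt upstream of its start contains a match
to `AGGAG` with at least 4 of 5 identities (a repository convention;
RBSfinder's internal scoring is not replicated), or if it is leaderless —
the start codon exactly at the TSS by default, relaxable via
`leaderless_slack`. Homopolymer runs of ≥ 3 residues are reported to support
attenuator leader-peptide reading.

Structure-conservation windows (an external screen's output, consumed as a
TSV) are filtered to p ≥ 0.5 and mean pairwise identity > 60 % (strict),
cleared of rRNA/tRNA overlaps, and unioned per strand with the maximum p
recorded. A trans-encoded region matches a locus by ≥ 1 nt same-strand
overlap (strandedness relaxable). Functional enrichment is gene-wise: the
fraction of a class's genes with at least one asRNA, labelled under/over at
the fixed 10 %/20 % cut-offs; a binomial test against the overall fraction
is available but off by default, because the rule is a cut-off, not a
statistic.

# The synthetic-data generator

`generate_world()` plants what the pipeline must find: CDS placed with
generous intergenic margins, sRNA regions of every positional class with
log-normal lengths (means 55 nt for asRNA, 90 nt for trans-encoded, 150 nt
for leaders; sdlog 0.25; minimum 40 nt), promoters sampled from the
scanning model (re-sampled until the scanner recovers them, closing the loop
between planting and detection — and verified at generation time by
re-classifying the planted geometry), canonical terminators after half of
the trans regions, and a conservation-window table with decoys. The default
study conditions are a 200 kb chromosome at GC 0.54 with 50 planted regions,
TSS stack height 30, background rate 1 and body coverage 40.

Library simulation makes two deliberate modelling choices. First, the
background rate is applied literally as a per-position read-start rate in
library 1, where the TSS rule consumes starts; in library 2 the same number
is interpreted as the target background *coverage* (start rate divided by
the read length). With 35 nt reads, a literal per-position start rate of 1
would put genome-wide coverage near 35 — indistinguishable from transcript
bodies at depth 40 and above the 3′-walk cutoff everywhere, which would make
3′-end calling meaningless under the very conditions it is tested in. Each
library's background is therefore expressed in the unit its detection rule
reads. Second, 30 % of a transcript's library-2 reads anchor at the TSS
(untreated libraries retain intact primary transcripts) and the rest start
uniformly within the transcript, with all reads truncated at the transcript
3′ end (the molecule ends there); this keeps coverage above the cutoff at
the 5′ end and makes it fall off sharply at the true 3′ end, as it does in
real dRNA-Seq profiles.

What the generator does **not** emulate: sequencing errors and quality
scores, rRNA-depletion artefacts, a 5′-bias model for degradation products
beyond the two-library contrast, RNA secondary structure of the planted
regions, and origin-spanning transcripts. Passing recovery tests therefore
demonstrates that the detection rules invert the generative model they
assume, not that they are robust to every artefact of real libraries.
Condition-specific transcription is modelled only as on/off flags per truth
region; differential quantification is out of scope.

# Problem sizes and numerical choices

The test suite runs the full pipeline on a 200 kb world (50 regions) and a
60 kb world (16 regions); the TSS rule is checked against a brute-force scan
on 1 000 random 10 kb profiles; the terminator benchmark uses 500 planted
windows against dinucleotide-shuffled (Altschul–Erikson) controls; promoter
training uses 158 sites of 50 nt. These sizes exercise every code path while
keeping a full run in minutes on a single core. Degenerate inputs are
defined rather than left to chance: empty alignment sets give all-zero
profiles, an empty region set gives a valid empty GFF3, walks that reach the
chromosome end are flagged truncated, and a TSS too close to the sequence
end yields a no-call with a warning.

# Known limitations

Promoter validation reduces to PWM matching with control-calibrated
thresholds; it does not model curved spacers, UP elements, or cooperative
binding, and published promoter counts are not reproduction targets because
the original motif-discovery tool's internals differ. The terminator
confidence is a fixed logistic, not a thermodynamic model. Multi-chromosome
genomes are read but analysed one chromosome at a time. Reads are assumed
ungapped (CIGAR M/S), appropriate for 35 nt bacterial mappings.
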