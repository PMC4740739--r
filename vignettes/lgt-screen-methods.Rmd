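---
title: "Screening draft assemblies for bacterial lateral gene transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening draft assemblies for bacterial lateral gene transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtscreen)
```

## The problem

Draft genome assemblies of arthropods and other invertebrates routinely
contain bacterial DNA of two very different kinds. Whole bacterial
scaffolds come from endosymbionts or environmental contaminants that were
co-extracted and co-assembled with the host. Sub-scaffold bacterial
segments embedded in otherwise animal sequence, by contrast, are candidate
*lateral gene transfers* (LGTs): bacterial DNA integrated into the host
nuclear genome, sometimes transcribed and domesticated. Distinguishing the
two, and distinguishing both from chimeric mis-assembly, is a standard
screening task whose pieces — low-complexity masking, nucleotide homology
search with E-value statistics, windowed scanning, interval joining,
mate-pair junction checks, expression classification — this package
implements as one coherent, fully testable pipeline.

## The screen, stage by stage

**Masking.** The bacterial database is masked with the DUST
triplet-composition score before indexing. For a run of $k$ overlapping
triplets with per-triplet counts $c_t$, the score is
$\sum_t c_t (c_t - 1) / 2 / (k-1)$; a stretch is masked when it fits inside
a 64-bp window and scores above `level/10` (default level 20). Masked
(lowercase) positions never seed alignments but remain available to
extension, so simple-sequence runs cannot by themselves create bacterial
hits while genuine homology spanning them is still reported in full. The
production masker is an $O(n \cdot w)$ per-start scan; the test suite holds
it byte-identical to a literal enumerate-every-window-and-sub-window
reference implementation.

**Homology search.** `build_index()` hashes every k-mer (default word size
11) of the database forward strands; `search_homology()` finds exact seed
matches (the reverse strand is searched via the reverse complement of the
query), groups seeds by subject and diagonal, extends them without gaps
under an X-drop rule, and re-aligns surviving segments with banded
affine-gap Smith–Waterman (match +1, mismatch −2, gap open −5, gap extend
−2, band 64). Raw scores are converted to bit scores and E-values with the
Karlin–Altschul formula $E = K m n e^{-\lambda S}$ using the classic
nucleotide parameters $\lambda = 1.28$, $K = 0.46$, with $m$ the query
length and $n$ the total database length. Hits above the E-value cutoff
(default $10^{-5}$) are discarded, and every reported raw score is held
equal, in the tests, to an independent full-matrix Smith–Waterman oracle.

**Scaffold triage.** Before any windowed scanning, whole scaffolds are
classified by `classify_scaffolds()`: a scaffold whose best bacterial bit
score beats its best animal bit score *and* whose bacterial hits cover at
least half its length is called `bacterial` (the co-assembled
endosymbiont/contaminant signature) and excluded from LGT calling;
bacterial-best but low-coverage scaffolds are `ambiguous` — exactly the
LGT-bearing host scaffold case the scanner handles; everything else is
`host`.

**Windowed scan.** `run_scan()` tiles the remaining scaffolds into 1,000-bp
windows, searches each tile against the masked bacterial database, and
counter-screens tiles with bacterial evidence against the animal database:
an interval is vetoed when an overlapping animal hit scores at least as
well as the bacterial evidence. Surviving bacterial-similar intervals less
than 50 bp apart (strictly) are joined, and joined intervals of at least
100 bp (inclusive) become LGT candidates labelled with the genus of their
best bacterial hit. One deliberate refinement over the plain overlap rule:
an animal hit must cover at least `counter_min_overlap` (default 0.5) of
the bacterial interval to veto it. Without this, an animal alignment
stopping exactly at an insertion junction can graze a genuine bacterial
interval by a couple of bases and, carrying the higher bit score of a long
flank alignment, erase a true LGT; setting `counter_min_overlap = 0`
restores the literal any-overlap behaviour.

**Junction validation.** A real insertion should be physically bridged at
both prokaryote–eukaryote junctions. `validate_junctions()` counts, from
mate-pair placements, reads spanning each junction with at least 20 bp of
overhang on both sides, and pairs with one mate wholly inside the candidate
and the other wholly in flanking sequence. A candidate is `supported` when
both junctions are spanned or a bridging pair exists; a candidate covering
its whole scaffold has no junctions and is reported `not_assessable` —
deliberately never `supported`, since nothing ties it to host sequence.

**Expression.** `classify_expression()` computes each candidate's mean
per-base coverage in every RNA-seq condition track and classes it `none`,
`trace`, or `expressed` (thresholds `t0 = 0`, `t1 = 1` fold coverage). A
candidate expressed in exactly one condition and silent in the others is
flagged `differential` — the pattern of a condition-specific, transcribed
LGT.

**Reporting.** `summarize_genera()` tabulates candidates per donor genus
with percentages (one decimal, plus a nearest-integer headline form), and
`length_histogram()` bins candidate lengths into half-open 10-bp bins.
`run_pipeline()` orchestrates every stage on disk with a machine-readable
manifest; no output carries a timestamp, so reruns of the same
configuration are byte-identical.

## The simulator and its scope

Because a genome-scale screen cannot be validated without truth,
`simulate_screen_inputs()` generates a fully truth-tracked synthetic
dataset: i.i.d. random host scaffolds at a configurable GC content; random
bacterial donor "genomes" at host GC + 0.10 (bacterial databases are, on
average, GC-shifted relative to an AT-rich arthropod host); implants cut
from donors, decayed by i.i.d. substitutions at rate `divergence`, and
inserted at spaced positions with exact truth coordinates; whole
contaminant scaffolds appended nearly verbatim; mate pairs drawn as a
Poisson fragment process over every implant junction so `pair_depth` is the
expected physical coverage; and condition-specific coverage tracks over a
configurable fraction of implants. The default configuration — 10 host
scaffolds of 100 kb, 20 implants of 150–2,000 bp at 5% divergence, 3 donor
taxa, 2 contaminant scaffolds, 30× junction depth — is the package's
standing evaluation condition, chosen to be desk-sized yet structurally
faithful; it is deliberately *not* tuned to the screen.

The simulator's limits are worth stating plainly. Decay is
substitution-only (no indels), so simulated alignments stay on-diagonal and
the banded aligner is never stressed by large gaps; sequences are i.i.d.
rather than repeat-structured, so the masker's role in simulation is
prophylactic rather than decisive; and donor taxa are random sequence, not
real bacterial genomes, so genus assignment tests identifiability of the
simulation's own labels, not phylogenetic placement.

## Numerical and interface choices

Coordinates are 0-based half-open everywhere in memory; tabular hit files
use the familiar 1-based inclusive convention with minus-strand subject
coordinates written descending (the BLAST `outfmt 6` dialect), and BED
output is 0-based half-open, so each format means what its ecosystem
expects. All randomness flows through `withr::with_seed()` from a single
configuration seed with fixed per-stage offsets, making every simulation a
pure function of its configuration. E-value statistics are computed in
double precision in R from integer raw scores computed in C++; scores large
enough that $e^{-\lambda S}$ underflows report an E-value of exactly zero.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
sim <- simulate_screen_inputs(cfg)
res <- screen_simulation(sim)
recovery_stats(res$candidates, sim$truth$implants)
#> $n_truth      [1] 20
#> $n_recovered  [1] 20
#> $sensitivity  [1] 1
#> $n_spurious   [1] 0
```

The same computation, end to end on disk, is
`run_pipeline(simulation_config(seed = 1), "out/")`; the command line
equivalent is `lgtscreen run --config cfg.json --outdir out/` using the
script installed under `exec/`.
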