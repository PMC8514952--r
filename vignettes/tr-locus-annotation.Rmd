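---
title: "Annotating T-cell receptor germline loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating T-cell receptor germline loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trlocus)
```

## The problem

T-cell receptor germline genes cannot be annotated with ordinary gene
predictors. V, D and J segments are not spliced into mature transcripts in
the germline; D segments are ~10–15 bp and J segments 40–80 bp; and the
features that define them — recombination signal sequences (RSS), leader
cassettes, conserved framework residues, splice dinucleotides — are motif
anatomy rather than coding statistics. `trlocus` therefore treats annotation
as structure recognition: candidate genes are located by homology to curated
germline references, then each candidate is described feature by feature, and
the recorded evidence drives an explicit functionality call and subgroup
classification.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the tests demonstrate.

## The RSS model

An RSS is modeled as canonical heptamer `CACAGTG` and nonamer `ACAAAAACC`
with a fixed 12-bp or 23-bp spacer. Scoring is substitution counting
(Hamming distance) against these canonical motifs — not a log-odds model —
because conservation in this setting is conventionally reported as the
number of mutations per signal, and because mutation counts compose directly
into the downstream acceptance rules. There are consequently no indels
inside the heptamer or nonamer; a signal that does not fit the frame is a
worse-scoring signal at a neighboring offset, not a gapped alignment.

Orientation is handled by two layouts. A 3′ RSS (V genes, D 3′ side) reads
heptamer–spacer–nonamer on the gene strand; a 5′ RSS (J genes, D 5′ side)
carries the same elements reverse-complemented, nonamer first, so that the
heptamer always abuts the coding edge. `score_rss()` and `scan_rss()` report
element sequences in canonical orientation regardless of layout, which makes
mutation counts and position weight matrices comparable across all four
arrangements.

Key parameters (all in `annotate_params()`):

* `rss_accept_max = 6` mutations — an RSS is "present" only at six or fewer
  total mutations; observed functional signals cluster below this.
* `rss_report_max = 9` — a rejected signal is still reported (as
  *defective*) up to nine mutations, matching the observed upper range of
  degraded but recognizable signals.
* `require_core = TRUE` — the first three heptamer positions must read
  `CAC`; these positions are the mechanistically critical ones and are
  essentially invariant in functional signals. A flag disables this for
  exploratory scans.
* `spacer_tol = 0` — spacers deviating by ±1 bp can be admitted
  (`spacer_tol = 1`) and are then recorded in `spacer_deviation`, never
  silently normalized. The default is strict because the 12/23 rule operates
  on exact spacer classes.

*Missing* versus *defective* RSS is decided positionally: after the coding
boundary of a segment is fixed, a defective call requires a window at the
exact expected junction scoring within `rss_report_max`; anything else is
missing. An earlier design that accepted a "defective" signal anywhere near
the boundary misclassified ablated signals, because in ~130 bp of arbitrary
sequence the best of all windows quite often drifts under nine mismatches by
chance. Both defects demote a gene to ORF, so the call is unaffected; only
the recorded reason differs.

## Detection by homology seeding

`homology_seed()` finds approximate copies of each reference: exact k-mers
(k = 11, subsampled every third position for long references; k shrinks to
8–9 for references under ~22 bp so a single substitution cannot erase every
seed) are matched with Aho–Corasick dictionaries, clustered by implied
reference start, and each anchor window is aligned globally in the reference
and locally in the window. Identity is gap-compressed (an indel run counts
as one aligned column): a V exon carrying one 90-bp structural deletion is
still a near-exact copy of its reference, and compressing the run keeps it
above the seeding floor (`min_identity = 70`%) so the deletion can be
described and flagged rather than silently discarded. At each locus site
references are tried in order of seed support, stopping once one aligns at
≥85% — the remaining references describe the same gene less well.

Overlap resolution, both within seeding and across segment types, is greedy
by (score, length, position), where score is alignment identity for V/C and
RSS quality for D/J. This is deterministic and logs every dropped candidate.

## Structural description

**V genes.** The 3′ boundary is the heptamer start of the best accepted
23-RSS near the candidate end (ties: fewest mutations, then closest to the
coding boundary, then leftmost — the RSS must abut the recombining edge).
The V-exon start comes from end-anchored global–local alignment of the
reference exon. The framework/CDR partition places template positions
26/38/55/65/104 on the translated exon by protein alignment; the germline
CDR3 remainder past position 104 is reported as one `CDR3-GERMLINE` feature
without further subdivision, since germline V genes are open-ended there.
Presence of the four conserved V-domain residues (Cys 23, Trp 41, a
hydrophobic residue at 89 — any of A/V/L/I/M/F/W/Y/C — and Cys 104) is
recorded, never enforced.

The leader is found reference-guided when a leader reference accompanies the
V reference: L-PART1 is aligned upstream, and the init codon (`ATG`), donor
(`GT`), acceptor (`AG` before the fixed 11-bp L-PART2) are then *checked*,
so an ablated site is reported as a defect at the exact planted position.
When the reference finds no credible match (identity below 60% or a
non-positive alignment score) the leader is reported absent rather than
falling through to motif search: in background sequence, a motif-only search
(any `ATG…GT` pair satisfying the frame and stop-free constraints within the
10–60 bp L-PART1 / 60–600 bp intron bounds) can select a spurious cassette
at an appreciable rate, which would mask a genuinely absent leader. The
motif search remains available for reference-free runs.

**D genes.** Every arrangement of accepted 12-RSS, core of 6–25 bp, and
accepted 23-RSS is reported; core G fraction is reported but not filtered by
default (cores are "usually" G-rich, not always; `require_g_rich` makes it a
hard filter). Two decisions tighten precision, because a D call rests
entirely on its two signals with no coding homology to corroborate it:
D RSSs have their own acceptance cutoff (`d_rss_accept_max = 5`), and the
pipeline keeps only D candidates with a J gene at most `d_near_j = 5000` bp
downstream in gene orientation — D genes head D–J–C clusters. Without these
rules, a ~100-kb locus produces chance RSS pairs at a rate that materially
pollutes the D list.

**J genes.** A candidate is an accepted 12-RSS followed by a region ending
at a `GT` donor. Donor choice is the crux: several `GT` dinucleotides
typically fall in the admissible window, so candidates are ranked by
similarity of the following six bases to the `GTAAGT` donor consensus, then
by falling inside the nominal 40–80 bp region bounds, then by shortness. The
donor search deliberately extends ~24 bp beyond the nominal bounds so that
genuinely short or long regions are still anchored on their consensus donor
and can then be flagged `length_out_of_range` (otherwise the flag would be
unreachable). The `[W/F]-[G/A]-X-G` motif is searched in all three frames
and the frame recorded; a region length that is not a codon multiple is
recorded as a frameshift (germline J regions are codon-multiples of 51–66
bp). When no accepted RSS exists near a homology seed, the region is
anchored on the seed and the RSS defect recorded, so RSS-less J genes are
still described.

**C genes.** Each reference exon is located independently and chained in
order, requiring `AG` before every exon and `GT` after every non-terminal
exon; failures are recorded as defects but the chain is still reported. The
terminal untranslated exon (TRA/TRD `EX4UTR`) is exempt from translation.
Very short exons (the 18-bp `EX2` of the TRB scaffold) can lose every exact
seed to one or two substitutions; a chain-based rescue aligns the missing
exon's reference directly in the window after the previous exon and accepts
it at ≥85% identity with the splice checks still applied.

## Functionality

The classifier is a pure function of the recorded defect codes through a
severity table (`default_severity_table()`): stop codon, frameshift, missing
init codon, or a broken splice dinucleotide force P; missing/defective RSS,
missing leader, out-of-range length, missing J motif, or a missing conserved
framework residue demote to ORF; a clean description is F. D genes have no
reading frame, so RSS presence on both sides is their sole requirement. The
table is explicit and replaceable because the boundary between "severe" and
"signal-level" defects is a curation convention rather than a derivable
fact; the default treats a missing conserved residue as ORF, not P — users
who prefer the stricter reading can supply their own table. P calls carry an
`in_frame_pseudo` flag (stop present, frame intact), the subset usable for
phylogenetic trees.

Monotonicity — adding a defect can never improve a call — follows from the
any-P-then-ORF structure and is verified over all defect pairs in the tests.

## Subgroups, trees and names

Pairwise V identity is computed from global alignment as matches over
aligned columns excluding terminal gaps (the representation clips terminal
gaps from its match/indel counts, so the count-based formula implements this
exactly). Subgroups are connected components of the ≥75%-identity graph
under single linkage, since chains of above-threshold pairs belong together.

The tree override mirrors a real curation situation: a pseudogene diverged
below threshold from every member of its subgroup, but sitting on the same
branch of the tree. A below-threshold singleton is merged into its nearest
tree neighbor's group when the supporting node has bootstrap ≥70 (the
literature gives no floor; 70 is the conventional "supported" cutoff and is
configurable). In `annotate_locus()` the override defaults to off because
the default pipeline builds its tree from identity distances without
bootstrap; enabling it without supports would merge every divergent
singleton into its neighbor.

Neighbor joining is implemented directly (Q-criterion minimization,
rate-corrected branch lengths, negative branches clamped to zero with the
deficit moved to the sister so the pair distance is preserved, ties broken
by the lexicographically lowest label pair). The reference implementation in
`ape` serves as an independent cross-check in the tests, never as the
implementation. Distances default to p-distance with pairwise deletion of
gap columns on a shared alignment (`p_distance()`), or `(100 − identity)/100`
inside the pipeline, so identity and tree cannot disagree about the input.
Bootstrap support is column resampling with bipartition counting.

Names follow the IMGT convention: V subgroups inherit the designation of the
nearest named reference clade by mean patristic distance when a tree with
reference leaves is available, otherwise positional subgroup numbers;
multi-member subgroups get `-1, -2, …` in 5′→3′ locus order; D/J/C are
named by D–J–C cluster index and position, hyphenated only when the locus
has several clusters (`TRAJ7` vs `TRBJ1-3`); C genes are numbered by
cluster.

## The synthetic generator

`generate_locus()` plants structurally complete genes in random background
following an architecture spec (`"V(28)-D(1)-J(6)-C(1)-…-Vrev(1)"`).
Templates are neutral scaffolds built in code from seeded stop-free codons
with all anchors imposed — deliberately not copied from any germline
database. Family founders derive from a scaffold at 30% substitution
divergence, members from founders at 5%, J genes at 10%, C genes at 3%;
substitutions avoid anchors and never create in-frame stops, so a zero-defect
gene always satisfies its structural definition. These rates put
within-family identity near 90% and between-family identity near 50%, the
regime the 75% subgroup threshold is designed for. RSS mutation counts are
drawn per signal as a truncated binomial: each of the 13 non-core element
positions mutates at `rss_rate = 0.1`, capped at `rss_max_mismatches = 6` so
intended-functional genes keep acceptable signals. Intergenic spacing is
uniform 300–3000 bp — locus organizations are published with spans, not
spacings, and this range reproduces realistic gene densities while keeping
desk-scale loci around 100 kb.

Defect injection edits the planted sequence (an ablated donor is literally
`GT → AT` at the planted position) and records the code; intended
functionality is derived from the injected codes *through the same severity
table the classifier uses*, which is what makes the recovery tests
meaningful. An ablated ("missing") RSS is redrawn until it scores at least
12 mutations at the junction, so an injected missing signal can never read
as merely defective.

What the generator does **not** emulate: repeats and segmental duplications,
indel divergence between family members (substitution-only), spacer-length
variants, GC heterogeneity, assembly gaps (`N` runs are supported by the
scanners but not planted), pseudogene decay beyond the single injected
defect, and any transcriptional evidence. Perfect recovery on synthetic loci
therefore demonstrates the correctness of the structural logic, not
real-genome performance, where reference divergence and repeat content
dominate the error budget.

## Numerical and engineering choices

* **Coordinates** are 1-based inclusive on the forward strand throughout —
  the native convention of the R/Bioconductor containers used for I/O —
  with GFF3 and BED emitted per their own standards. One convention
  everywhere removes the off-by-one class of bugs entirely.
* **Determinism**: every tie in every stage has a written rule (RSS ties:
  mutations, boundary distance, leftmost; overlap resolution: score, length,
  position; NJ: lowest label pair). Re-running any stage on identical input
  is bit-identical; randomness exists only in the generator and bootstrap,
  both seeded.
* **Degenerate inputs**: windows containing `N` are discarded by scanners
  with an explicit reason; empty loci produce empty (not failing) reports;
  single-V loci skip tree building; matrices are validated for symmetry.
* **Problem sizes in the tests** were chosen to exercise every code path at
  desk scale: scanner-versus-oracle on 10-kb sequences across all four
  layouts and every mutation cutoff 0–9; twenty seeded replicate loci at the
  full published TRB organization (48 genes each) for recovery; 100 random
  5–8-taxon additive matrices for tree exactness; 50 random identity
  matrices for subgroup equivalence; 1000 planted signals for the RSS
  mutation-distribution fit.

## Known limitations

* Leader detection is reference-guided; without a leader reference the
  motif-constrained fallback can select a plausible-looking upstream
  cassette in background sequence.
* The J donor-consensus ranking can, rarely, prefer a chance `GTAAGT` inside
  the admissible window over the true donor, shifting the 3′ boundary by a
  codon multiple.
* C exon chaining assumes collinear, complete exon chains within 5 kb
  introns; a truncated C gene (missing terminal exon) is dropped rather than
  partially reported.
* Subgroup naming against reference clades uses mean patristic distance to
  reference leaves; it does not test monophyly, so a bat subgroup falling
  between two reference subgroups inherits the nearer name.
* The organization string encodes type and orientation only; sub-locus tags
  for nested TRA/TRD loci come from `shared_v_assignment()` and are not
  folded into the string.
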