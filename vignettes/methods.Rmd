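---
title: "Methods: junction annotation, marker filters, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction annotation, marker filters, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomark)
```

`immunomark` measures how well whole-transcriptome sequencing (RNAseq)
recovers the immunoglobulin/T-cell receptor (IG/TR) minimal residual disease
markers found by DNA amplicon sequencing (DNAamp). This vignette documents
the models, conventions and parameter choices behind each stage, in the
order the pipeline runs them.

## The junction-class taxonomy

Rearrangements are typed into 22 junction classes over the seven IG/TR loci,
grouped into four categories:

```{r}
dplyr::count(junction_classes(), locus_group, category)
```

Three conventions resolve ambiguities the class labels leave open:

* **Dd2-Jd1** requires the 3′ gene `TRDJ1` (the label names the J), and the
  simulator draws only that gene for this class; `TRDD2` joined to another
  TRD J is unclassifiable.
* The TRA+D hybrid classes dispatch on the locus of each side, so
  `TRAV + TRDJ` (Va-Jd) and `TRDV + TRAJ` (Vd-(Dd)-Ja) are distinct classes.
* D genes inside complete VDJ junctions are *not* separately identified;
  their contribution is absorbed into the N-(D)-N length. This matches the
  parenthetical notation of the class labels and makes identity keys robust
  to ambiguous D calls.

## Identity keys and the junction window

A rearrangement's identity is the 7-tuple *(class, 5′ gene, 5′ deletions,
N-(D)-N length, 3′ deletions, 3′ gene, junction amino-acid sequence)*.
Abundance is never part of the key. Because the key must reproduce across
platforms, the junction window is fixed: 3 codons upstream of the 5′
segment's last aligned base through 3 codons downstream of the 3′ segment's
first aligned base. For complete VJ classes the window is codon-aligned in
the V reading frame (using the stored frame anchor) and translated in that
frame; for incomplete DJ classes it is translated in the J frame from the
first in-frame codon start inside the window; for incomplete VD, D–D and
the non-coding IGK classes (Vk-Kde, intron-Kde) no frame spans the junction,
so the amino-acid component is empty and productivity is *unknown*. Frame
anchors are stored explicitly in the reference rather than inferred from
conserved residues, because synthetic segments carry no Cys/Trp motifs.

Productivity of a complete VJ junction requires frame preservation between
the V and J anchors (junction span length ≡ 0 mod 3) *and* a stop-free
window translation; germline V and J segments are generated stop-free in
frame, and every junction-spanning codon lies inside the window, so the
window check is equivalent to translating the whole V→J span (the test
suite verifies this against a brute-force oracle). Incomplete DJ junctions
are *potentially productive* when the J-frame translation is stop-free.

## The annotator

Reads are oriented by trying the forward interpretation first and the
reverse complement only when the forward one yields nothing; mates merge
when they overlap by ≥ 15 nt (seeded by an exact 12-mer) with ≤ 10%
mismatches. Segment search is k-mer-seeded (12-mers; 7-mers for the short D
segments), followed by per-diagonal *ungapped* local alignment scored
+1/−2 (match/mismatch), keeping each segment's best diagonal. Gapped
alignment is deliberately omitted: the read model is substitution-only, and
for such reads an ungapped optimum is also the gapped optimum; the scoring
constants are engineering defaults, not biological estimates. Acceptance
minima are per segment type — 20 nt (V), 12 nt (J/Kde/intronRSS), 8 nt (D)
at ≥ 90% identity. An isolated 12 nt J or 8 nt D match carries little
information on its own (a random 150-mer produces one by chance at the
percent level); the discipline comes from pairing.

Candidate (5′, 3′) pairs are enumerated over classifiable segment
combinations in read order, and the winner is the pair with the highest
total alignment score. Two refinements matter:

* **Covered-pair preference within an identity.** Among candidates with the
  *same class and genes* as the score-best pair, a variant that fully covers
  the junction window is preferred over a higher-scoring variant that does
  not (e.g. the full V alignment sits on mate 1 but a shorter V alignment on
  mate 2 resolves the junction). The preference is deliberately *not*
  applied across classes: an unconditional covered-first rule lets spurious
  low-score D–D or D–J pairs outrank the true V–J evidence.
* **Terminal-stub rescue.** When the best pair spans both mates, the
  junction may still be confined to one mate with only a short terminus of
  the partner gene on it. A boundary-anchored, exact-match run of ≥ 9 nt of
  that gene (corroborated by its full-length alignment on the other mate)
  re-anchors the pair on one mate. Requiring exactness keeps the
  wrong-placement rate of rescues negligible; with sequencing errors a
  rescue simply fails and the record stays damaged (conservative).

Junctional micro-homology — overlapping 5′ and 3′ alignments — is
canonicalized by clamping the N-(D)-N length to 0 and shifting the overlap
into the 3′ gene's deletions. The same canonicalization defines the
simulator's ground truth (below), so keys match across platforms by
construction. Segmentation statistics a damaged record's coverage cannot
determine are `NA` and render as `?` in its (partial) key. Records whose
implied deletions or insertions exceed `max_region` (60 nt) are rejected as
spurious pairings.

## Ground truth is canonical

`simulate_rearrangement()` draws genes uniformly from the class's eligible
pool, deletions uniform on 0..`deletion_max` (default 10, clamped so at
least 30/10/14 nt of V/D/J remain alignable), and a geometric N-(D)-N length
(mean 8, filled uniformly over ACGT) — then annotates the assembled sequence
with the package's own aligner and stores *that* record as the truth. Keys
are therefore canonical: maximal alignment extension may absorb an N base
identical to the germline continuation, and truth and read annotation agree
on the result by construction. Raw draws whose assembled sequence does not
annotate back to the intended class (rare junction coincidences) are
redrawn.

## The synthetic cohort

Defaults encode the study conditions: 20 cases, each with the clonal plan
(two complete IGH alleles, each unproductive with probability 0.7 — the
typical fraction in ALL — plus one IGH DJ, IGK VJ, IGK Kde, TRB, TRG and TRD
complete rearrangement) and 80 polyclonal background rearrangements whose
complete-VJ draws are productive with probability 0.98. Background classes
are drawn with weight 3 for complete-VJ classes and 1 otherwise — a
plausible lymphocyte repertoire profile, configurable, not a cohort
estimate.

**DNAamp** reads are sampled per primer tube (1500 reads/tube default):
within a tube, the clone's rearrangements jointly take `blast_fraction`
(default 0.9) of expected reads, background the rest. Amplicon reads are the
full rearranged sequence, so their junctions are never damaged. The eight
tubes cover 14 of the 22 classes; IGL and TRA-5′ classes have no primer set,
and the TRB/TRD classes without a primer pair (Vb-Db, Db-Db, Dd3-Jd,
Dd3-Dd2) are likewise RNAseq-only.

**RNAseq** fragments (2500/case default) are sampled proportional to
cellular abundance (clonal = blast fraction; background = the remaining
fraction split equally) times a three-tier transcription rate: productive
complete 1.0, unproductive complete `sterile_rate` = 0.01, incomplete/other
`incomplete_rate` = 0.001. The direction (non-transcribed unproductive and
incomplete rearrangements are hardly detectable by RNAseq) is established
biology; the magnitudes are this package's choice, set once so the
transcriptome qualitatively under-represents sterile and incomplete classes
without making them strictly impossible to see. Fragments are placed
uniformly in a junction-centered 600 nt transcript context (random flanks
stand in for leader/constant-region sequence — only junction-spanning reads
matter downstream), with normal lengths (250 ± 50, truncated at 150) and
2×75 bp reads off the fragment ends.

A fragment's truth `damaged` flag records whether the junction window is
**reconstructable** from its reads: inside a single mate, or inside the
fragment when the mates overlap by at least the merge threshold. A fragment
of exactly twice the read length has abutting mates whose union covers the
window but cannot be stitched by any overlap-based merger, so it counts as
damaged; this definition is what the ≥ 99% annotator/truth agreement is
measured against.

What the simulator does *not* emulate: somatic hypermutation, primer bias
and PCR chimeras, sequencing error profiles (substitution errors are
available but off by default), UMI structure, allele-level gene nomenclature
and real IG/TR germline homology (toy segments are random, hence easier to
distinguish than real V families). Passing tests therefore demonstrate the
pipeline's logic — key reproducibility, filter semantics, transcription-
driven recovery patterns — not clinical-grade gene assignment on real reads.

## Marker filters and cross-platform matching

The **uniqueness filter** removes any complete identity key observed in more
than one case, from every case, regardless of platform; recurrence across
patients signals contamination or artefacts rather than clone-specific
biology. Damaged partial keys are exempt — they are not comparable
identities and would collide across cases spuriously.

**DNAamp markers** need ≥ 10 de-duplicated reads *and* ≥ 5% of the
uniqueness-surviving reads in their primer tube; both bounds are inclusive
("minimum 10" admits 10), the thresholds apply jointly per tube, and the
tube total is the denominator choice (stated here because "5% of reads" does
not define one). **RNAseq** rearrangements are searched at any abundance by
default; `apply_to_rnaseq = TRUE` imposes the same thresholds with per-locus
denominators (RNAseq has no tubes), which is only used for the per-case
marker-count comparison.

Abundance is platform-aware: DNAamp counts reads, RNAseq counts distinct
fragments (de-duplicated), mirroring fragment-level counting in capture
assays.

**Matching** is exact-key by default: a DNAamp marker is recovered iff an
undamaged RNAseq record of the same case has an equal key, at any count.
The permissive `allow_damaged_partial` mode additionally accepts a damaged
record agreeing on class, genes and every segmentation statistic its
coverage determined; it exists to *quantify* how much damaged evidence could
add, not as a claim about how re-identification ought to work, and
permissive recovery is provably a superset of exact recovery.

## Problem sizes and numerical notes

The test suite exercises two-case cohorts for unit behavior and a 20-case
default-parameter cohort (≈ 240k amplicon reads, 50k fragment pairs) for the
end-to-end properties; the acceptance script re-runs the 20-case study from
scratch. The damaged-fraction calibration check uses a single productive TRG
rearrangement in an 800 nt context with fixed 400 nt fragments, where the
coverage probability has the closed form `2(r − w + 1)/(L − F + 1)` for read
length `r`, window width `w`, context `L` and fragment `F`, cross-checked by
enumerating all fragment placements. Alignment ties break to the longer
alignment, then the lexicographically smaller gene name; candidate-pair ties
keep the first in registry order. Degenerate inputs are defined: zero
deletion/insertion draws reproduce the germline abutment exactly; zero tube
depth or all-zero transcription rates yield empty (warned) read sets; empty
tables flow through every stage.

## Known limitations

* Gene assignment is exact-match-oriented; somatically hypermutated V genes
  would need higher mismatch tolerance and gapped alignment.
* The N-(D)-N canonicalization is a declared convention, not a reproduction
  of any published pipeline's internal segmentation; keys are comparable
  within this package but not byte-for-byte with other tools.
* Short D-only evidence (8 nt minimum) is intentionally permissive and only
  trusted inside classifiable, geometry-checked pairs.
* Per-case marker counts at RNAseq thresholds depend on the per-locus
  denominator choice; with primer tubes absent from RNAseq there is no
  unambiguous analogue of the tube fraction.
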