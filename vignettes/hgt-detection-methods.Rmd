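---
title: "Detecting endosymbiont-to-host horizontal gene transfer: methods and design"
author: "hgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endosymbiont-to-host horizontal gene transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscan)
```

## The problem

Intracellular endosymbionts such as *Wolbachia* live inside the germ-line
cells of their arthropod and nematode hosts, and fragments of their genomes
are repeatedly found integrated into host chromosomes. When a host genome is
shotgun-sequenced from whole animals, both genomes are sequenced at once, and
a draft assembly mixes three kinds of scaffolds: host scaffolds, scaffolds of
the live (cytoplasmic) endosymbiont, and — the interesting case — host
scaffolds that carry integrated (chromosomal) endosymbiont fragments.
A fourth kind is the dangerous look-alike: a *chimeric* scaffold, an assembly
artifact that fuses host and symbiont molecules that were never joined in
vivo.

`hgtscan` implements the evidence chain that separates these cases:

1. **TAGC screening** (`classifyAssembly()`). Every scaffold is annotated
   with the taxon composition of its similarity hits and its mean read
   depth. Scaffolds matched (nearly) end-to-end by symbiont hits are the
   symbiont genome; scaffolds carrying *both* substantial symbiont and host
   blocks are HGT candidates. Read depth is attached as supporting evidence:
   an intracellular symbiont is typically present in many copies per host
   cell, so its scaffolds sit in a different coverage regime, and a genuine
   insertion rides at *host* coverage. GC content is computed for the
   classic blob plot (`plotTagc()`) but deliberately is not a decision
   criterion — a host at 36% GC and a symbiont at 35% GC are inseparable on
   that axis.
2. **Block finding** (`anchorChainAlign()`). On candidate scaffolds, host-
   and symbiont-derived blocks are located with a light k-mer
   anchor-chaining aligner: exact shared k-mers (21-mers by default) are
   collapsed into exact diagonal segments and chained when collinear within
   `maxGap` on both sequences. Block identity is anchored bases over block
   span. The aligner is deliberately simple — at the scale of candidate
   scaffolds versus two reference genomes it replaces an external
   whole-genome aligner, and its exactness makes it testable against a
   brute-force maximal-exact-match oracle.
3. **Segmentation** (`segmentCandidate()`). Maximal runs of symbiont blocks
   flanked by host blocks become candidate insertions; the host/symbiont
   boundaries are the junctions.
4. **Junction depth continuity** (`junctionDepthTest()`). The decisive test
   against the chimera hypothesis: across a genuine insertion the sequencing
   depth does not change, whereas a chimeric join fuses molecules from
   different coverage regimes and shows a depth step at the junction. Mean
   depth is compared in a window on each side of the junction and the
   junction is *continuous* iff `|log2(left/right)| <= log2(tauJunction)`.
5. **Cross-assembly corroboration** (`corroborateJunction()`). Independent
   assemblies of the same reads (different algorithms make different
   errors) are searched for a single contig that aligns contiguously across
   the junction.
6. **Annotation and verdict** (`detectHgt()`, `callHgt()`). Calls are
   annotated with transposase proximity (integration sites are expected in
   or near transposase regions), overlapping genes and their transcription
   (FPKM), and receive a verdict: `chimera_suspect` iff any junction shows a
   depth step; `hgt` iff every testable junction is continuous and at least
   `cMin` assemblies corroborate; `unresolved` otherwise.

Two companion modules reproduce the bookkeeping that surrounds such a study:
multi-strain evidence for the symbiont assembly (`strainReport()`) and
assembly statistics (`assemblyStats()`, `nxx()`, `libraryAccounting()`).

## Parameters

All detection tunables live in `hgtParams()`; each is a config key of the
file front end. Units are base pairs unless noted.

| key | default | rationale |
|---|---|---|
| `k` | 21 | anchor word long enough that random 21-mer collisions are negligible at genome scale, short enough to survive ~1% divergence (survival \(0.99^{21} \approx 0.81\)) |
| `mRep` | 10 | k-mers more frequent than this in the reference are repeats, not anchors |
| `maxGap` | 500 | chain/merge distance; bridges anchor dropouts without merging distinct inserts |
| `minBlock` | 300 | below the smallest insert worth calling, with margin for boundary fraying |
| `window` | 500 | junction depth window; at ~47x coverage the window mean has a CV of a few percent, far inside the test band |
| `guard` | 50 | keeps reads overlapping the junction itself out of both windows |
| `tauJunction` | 1.5 | a genuine junction shows ratio ~1; host/symbiont regimes differing by >= 1.5x are flagged. The published evidence is qualitative ("no change in depth"); this threshold is our formalisation |
| `flank`, `flankCovered` | 500, 200 | a corroborating contig must align 200 bp on each side of the junction within the 1 kb window |
| `cMin` | 1 | one independent assembly suffices to corroborate |
| `maxDist` | 2000 | transposase proximity horizon |
| `minFpkm` | 0.01 | transcription call threshold; published HGT-gene FPKMs run 0.04–1.6 |
| `fPure` | 0.90 | operationalises "matched completely" for pure-symbiont scaffolds while tolerating unaligned scaffold ends |
| `tauDepth` | 1.5 | log2 band for the TAGC depth clusters |
| `edgeTol` | 100 | a symbiont run within this distance of a scaffold end is an edge insert with one testable junction |

## Coordinates

Internally every interval is 1-based and closed — the native
IRanges/GRanges convention — and every dialect conversion happens once, at
the I/O boundary: BLAST tabular and GFF3 are natively 1-based inclusive
(reversed subject coordinates are normalised to forward with strand
recorded); BED is 0-based half-open and converted by rtracklayer on read and
write. Published interval strings like `"scaffold83: 2271642-2,272,117"`
follow a printing convention in which the quoted length equals
`end - start`; `parsePrintedInterval()` fixes that length (all five published
insert lengths are consistent with it) and maps the interval to
`[start + 1, end]`. Whether the printed start itself is 0- or 1-based is not
recoverable from the lengths alone; only the length convention is relied
upon.

## The synthetic experiment

`simulateHgtExperiment()` generates the full input bundle with known truth.
Its defaults are the validation conditions used by the test suite and the
acceptance script: a 1 Mb host genome at GC 0.36 in five scaffolds sequenced
to 47.37x; a 300 kb symbiont at GC 0.3513 in three scaffolds at 120x; three
planted insertions of 0.5–20 kb, each accompanied by a transposase feature
and (for inserts over 2 kb) gene features with a sparse low-FPKM expression
table; one chimeric scaffold fusing a 20 kb host fragment with a 20 kb
symbiont fragment; 100 bp reads; and one alternative assembly shredded at a
mean contig length of 50 kb (the contig scale a second short-read assembler
would plausibly produce). These sizes are a deliberate scale model: genome
proportions, depth regimes, GC values, read length and the insert length
range mirror an ant/*Wolbachia*-like study, at a size where a full 20-seed
sweep of the pipeline completes in minutes.

Design choices of the generator:

* **Reads are placed, not mapped.** Depth tracks are computed exactly from
  recorded read placements. The detection evidence is depth, not per-read
  alignment, so a mapping step would add nothing but noise and runtime.
* **Uniform read starts, error-free reads.** Neither GC bias nor sequencing
  error enters any implemented statistic; an error-rate knob exists but
  defaults to 0.
* **The hit table is emitted from truth.** In a real study the taxon
  annotation comes from a database search; the module boundary treats the
  hit table as an input, so the simulator writes the table its truth
  implies.
* **Transposases are annotations, not sequences.** The detector consumes
  features, so the simulator plants features; inserts under 2 kb carry a
  transposase annotation spanning the whole insert (the degenerate-
  transposase pattern of the smallest published inserts).
* **Strain mixtures** (`simulateStrainEvidence()`) emulate the *assembly
  outcome* of co-infection: a fraction of single-copy genes (and all marker
  genes) have their second-strain copy resolved as a separate contig
  (duplicated loci), the rest collapse so that pooled reads pile up as
  polymorphic sites at the planted variant positions, with per-site read
  support computed from placed reads of each strain.

What the simulation does *not* emulate — and hence what passing tests do not
show about real data: repeat-rich genomes (random sequence is essentially
repeat-free, so the TAGC bins are cleaner than in any real assembly),
alignment noise from a heuristic aligner, GC-coverage bias, indel
divergence between strains, and contamination from taxa other than the one
symbiont. The pipeline's thresholds are therefore validated for their logic,
not tuned to any real genome's noise floor.

## Numerical and procedural choices

* **Junction placement.** A junction sits at the midpoint of the gap between
  the symbiont run and the flanking host block. Anchors fray where edits
  cluster at a boundary, and the midpoint minimises the worst-case boundary
  error; with exact simulated copies the blocks abut and the error is 0–2
  bp.
* **Boundary sharing.** The few bases adjacent to an insertion point can
  genuinely match both references (the insertion landed next to sequence
  that happens to continue identically for a few bases), producing small
  host/symbiont block overlaps with tied identity. Overlaps up to
  `overlapTol` (50 bp) are split at their midpoint; only larger tied
  overlaps are marked ambiguous and excluded from junction testing.
  Substantive overlaps are resolved in favour of the higher identity.
* **Corroboration counts positive evidence only.** An assembly corroborates
  a call when one contig spans at least one of its junctions contiguously.
  A junction that no contig spans — because the alternative assembly
  happens to break elsewhere nearby — is uninformative, not contradictory;
  demanding every junction of every call be spanned would let random contig
  ends veto true calls.
* **Edge inserts.** An insertion truncated by a scaffold end has one
  testable junction; the missing junction counts as indeterminate and does
  not block an `hgt` verdict. Junction windows that would extend past the
  scaffold end likewise return `indeterminate` rather than a fabricated
  ratio.
* **Pseudo-depth.** The log2 depth ratio uses a pseudo-count of 0.5 on both
  windows, so dropout windows cannot divide by zero.
* **The depth-equality confound.** If host and symbiont happen to be
  sequenced to indistinguishable depths (within `tauJunction`), a chimera
  cannot be separated from an insertion by depth at all. The call set then
  carries an explicit note instead of silently passing.
* **Truncation, not rounding.** Gene-set recovery percentages are truncated
  to two decimals (80/84 prints as 95.23, not 95.24); library yields are
  summed in two-decimal fixed point so printed per-library yields reproduce
  their printed total exactly.
* **Nxx ties.** The qualifying contig's own length is reported even when
  several contigs share it, and Lxx counts through the first qualifying
  contig (the QUAST-style definition).
* **Forward strand only.** The anchor aligner does not reverse-complement:
  hits arrive normalised to forward intervals with strand recorded, the
  simulator plants forward copies, and none of the downstream evidence uses
  orientation. Real inverted insertions would need a reverse-complement
  pass of the same machinery.

## Validation

The test suite validates each operation against an independent oracle where
one exists: the aligner against a brute-force \(O(nm)\) maximal-exact-match
scan on sequences up to 2 kb; Nxx/Lxx against a brute-force cumulative walk
on random length multisets; taxon coverage against a per-base union count;
junction verdicts against closed-form log ratios on constructed tracks. The
end-to-end property — every planted insertion called `hgt` with junction
boundary error at most 50 bp, every constructed chimera called
`chimera_suspect`, and no `hgt` call on insertion-free scaffolds — is swept
over 20 seeds at the full study conditions, and `scripts/acceptance.R`
recomputes the same recovery rates from scratch for any seed.

## Limitations

Beyond the generator's simplifications listed above: the aligner is exact
(substitution divergence thins anchors; indel-rich divergence would break
chains that a banded aligner would bridge); depth evidence cannot separate a
chimera whose two sides happen to share coverage; corroboration presumes the
alternative assemblies derive from the same reads; and the package detects
transfers only from the configured symbiont bin — transfers from taxa not in
the taxon map are invisible. Presence/absence of candidate genes in the
symbiont assembly is reported as observed and never interpreted as gene
loss, which short-read draft assemblies cannot establish.
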