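---
title: "Correcting draft assemblies with linked-read molecule coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting draft assemblies with linked-read molecule coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkcut)
```

## The model

Linked-read sequencing (e.g. 10x Genomics Chromium) partitions large DNA
molecules -- typically around 100 kbp -- into droplets and tags all reads
from one droplet with a shared barcode. Aligned back to a draft assembly,
the reads carrying one barcode delimit the extent of the molecule(s) they
came from. This gives access to *physical molecule coverage*: the number of
molecules whose extent contains a position, as opposed to read-level depth.

The key observation is that a correctly assembled locus is spanned
end-to-end by many molecules, while a misassembled join -- a junction
between sequences that are not adjacent in the genome -- is spanned by
none, because no physical molecule exists across it. Read-level and even
point-wise molecule coverage can look perfectly smooth across such a
junction (molecules run *into* a repeat from the left, and *out of* it to
the right); what vanishes is the count of molecules containing a whole
window around the junction. `linkcut` therefore:

1. filters alignments (keep edit distance NM $< 5$ and alignment score
   AS $\ge 0.65\,l$ for read length $l$, both defaults);
2. chains same-barcode reads on one contig into molecules while consecutive
   read starts are within 50 kbp (default), records each molecule's extent
   and read count, and drops molecules shorter than 2 kbp or with fewer
   than 4 reads (defaults);
3. slides a $w$-bp window ($w = 1000$ by default) along each contig with a
   step of 1 bp and labels a window *well-covered* when at least $s$
   molecules ($s = 20$ by default) contain it entirely;
4. for every maximal run of poorly-covered windows flanked by well-covered
   windows on both sides, cuts the contig after the last base of the
   preceding well-covered window and before the first base of the
   following one;
5. splits the draft FASTA at the cut positions.

## Spanning as window containment

A molecule "spans a point" when it has reads on both sides of it. Molecule
extents are delimited by read alignments, so we implement spanning of a
window as interval containment: molecule $[m_s, m_e)$ spans window
$[a, a+w)$ iff $m_s \le a$ and $m_e \ge a+w$, both boundaries inclusive. A
containing molecule necessarily has a read at or left of $a$ and a read at
or right of $a + w$. Containment is evaluated two ways: per-query through
an `IRanges`-backed interval index (`count_spanning()`), and for whole
contigs through a difference vector over window starts -- molecule
$[m_s, m_e)$ contains exactly the windows starting in
$[\max(m_s, 0),\, m_e - w]$ -- followed by a cumulative sum
(`compute_support_profile()`, $O(n + L)$ per contig). The test suite
requires both routes to agree with an $O(nL)$ brute force on random
instances.

## Cut-point arithmetic

Window starts are indexed $0 \dots L - w$. For a maximal poorly-covered run
occupying window starts $p \dots q$ with well-covered windows at $p - 1$
and $q + 1$, the two cuts are placed at $(p-1) + w$ (after the last base of
the preceding well-covered window) and at $q + 1$ (before the first base of
the following one). Three regimes follow from this arithmetic:

* run longer than $w - 1$ windows: $(p-1)+w < q+1$, an ordinary excised
  middle region;
* run of exactly $w - 1$ windows -- the signature of a sharp junction,
  where precisely the windows overlapping the junction point fail -- both
  formulas give the *same* position, which is the junction estimate; the
  pair collapses to a single cut;
* shorter runs: the two positions invert; both are still emitted (sorted),
  matching the stated rule, and the region record keeps their span.

Runs touching a contig end produce no cuts: molecule coverage necessarily
decays toward sequence ends (no molecule can extend past them), so a
leading or trailing poor run carries no evidence of misassembly, and an
entirely poor contig passes through uncut. The poorly-supported middle
piece between a cut pair is retained as its own output segment rather than
discarded: the method's mandate is to split at unsupported joins, not to
drop sequence. Cut segments are named `<parent>-<ordinal>` with the parent
coordinates in the description, uncut contigs keep their names, and
concatenating a parent's segments reproduces it byte-for-byte (softmasked
lowercase included; sequences are handled as `BStringSet` to guarantee
verbatim fidelity).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `max_mismatches` | 5 | reject reads with NM $\ge$ 5 (strict) |
| `min_score_ratio` | 0.65 | keep reads with AS $\ge 0.65\,l$ (inclusive; a $10^{-6}$ epsilon guards the binary representation of the product) |
| `min_mapq` | 0 | no mapping-quality filter unless requested |
| `max_read_gap` | 50 kbp | adjacent same-barcode read start distance within a molecule; values between 20 and 100 kbp behave similarly on real data, below 20 kbp molecules start to fragment |
| `min_molecule_size` | 2 kbp | molecules shorter than this are noise |
| `min_reads_per_molecule` | 4 | near-singleton molecules are alignment noise |
| `window` | 1000 bp | scan window; 2000 also works well on human-scale data, at the cost of more (less precise) cuts |
| `min_spanning` | 20 | well-covered threshold; results are insensitive up to about 50 on deep data |

The chaining rule measures the distance between the *start* coordinates of
consecutive same-barcode reads. Whether starts, ends or inter-read gaps are
used is immaterial at read-length scale relative to a 50 kbp threshold;
starts are simple and deterministic after sorting, and the choice is
documented rather than asserted as canonical. Mate-pair relationships are
ignored (each alignment record is an independent read observation), and
only primary, non-duplicate alignments are used, so no read can contribute
to two molecules. Reads without a barcode cannot inform molecule extents
and are dropped by default. A missing NM or AS tag fails the corresponding
filter: a read whose quality cannot be assessed is not trusted to delimit
a molecule.

## The synthetic scenario generator

`simulate_scenario()` builds a desk-scale analogue of a misassembled
assembly: a random genome (1 Mbp by default) is partitioned into segments
(at least 55 kbp each by default), and the segments are dealt into draft
contigs in a permuted order, so that every internal boundary of a draft
contig joins sequences that are not adjacent in the genome -- a recorded,
ground-truth misassembly junction. `simulate_molecule_alignments()` places
molecules uniformly on the circularised genome (so interior coverage is
uniform at the calibrated `molecule_coverage`, 100 by default), with
lengths 2 kbp plus an exponential with mean 58 kbp (mean 60 kbp overall),
unique barcodes, and a Poisson number of uniformly placed 150 bp reads at
about one read per kbp of molecule. Reads are mapped through the segment
map onto the draft, so a molecule crossing a segment boundary yields reads
at discontiguous draft loci and can never span a junction on the draft.
All-match SAM records with NM/AS/BX tags are emitted, so the real parser
and filters are exercised; a 5% fraction of noise reads (NM = 7,
AS $= 0.3\,l$) stands in for poorly aligned reads, exercising the filters
without a full error model.

Two generator constraints keep the injected junctions detectable *in
principle*, which is what the recovery tests measure:

* **Segments are longer than the chaining distance.** If a segment shorter
  than `max_read_gap` separated the two pieces of a split molecule on a
  draft contig, the pieces would re-chain into a spurious molecule
  spanning both flanking junctions.
* **Joined segments are distant in (circular) true-genome space** -- at
  least 3 mean molecule lengths apart. A molecule whose true extent
  reaches from inside one joined segment to inside the other produces read
  pieces that abut the junction from both sides of the draft and re-chain
  regardless of the gap threshold. At 3 mean lengths the expected number
  of such bridging molecules is roughly
  $\mathrm{coverage} \cdot e^{-3} \approx 5$, far below the spanning
  threshold of 20. Real misassemblies overwhelmingly join distant loci
  (distinct repeat copies), so this constraint mirrors the phenomenon the
  method targets.

The partition (segment lengths, contig composition and permutation) is
rejection-sampled until both constraints hold; parameter sets for which no
placement exists raise an error rather than silently degrade.

What the generator does *not* emulate: sequencing errors and soft-clipped
or split alignments (reads straddling a segment boundary are dropped, as a
real aligner would clip them), barcode collisions between distinct
molecules sharing a droplet, GC- or mappability-dependent coverage, and
heterozygosity. Passing the recovery tests therefore demonstrates the
correctness of the inference chain under clean conditions, not performance
on real libraries, where precision is limited by coverage fluctuations and
true structural variation.

`evaluate_cuts()` scores detected cuts against the injected junctions:
each cut matches at most its nearest junction within a tolerance (the
window size by default, since cut placement is resolved no finer than the
window); precision is matched cuts over all cuts -- both members of a cut
pair flanking one junction count as matched -- and recall is recovered
junctions over all junctions. With zero detected cuts precision is
reported as 1.0 (with a warning), the convention for "no false
positives".

## Worked example

```{r example, eval = FALSE}
params <- sim_params(seed = 42L)
scenario <- simulate_scenario(params)
dir <- tempfile(); dir.create(dir)
sam <- file.path(dir, "reads.sam")
simulate_molecule_alignments(scenario, sam_path = sam)
write_scenario(scenario, dir)

cfg <- pipeline_config()
run_molecule(sam, file.path(dir, "molecule.bed"), cfg)
plans <- run_cut(file.path(dir, "draft.fa"), file.path(dir, "molecule.bed"),
                 file.path(dir, "corrected.fa"),
                 file.path(dir, "breakpoints.bed"), cfg)
evaluate_cuts(plans, scenario$truth, tolerance = cfg$scan$window)
```

On this seed the pipeline retains 95,169 of 100,274 simulated reads,
infers 2,646 filtered molecules, makes 20 cuts (two flanking each of the
10 injected junctions, every cut within 255 bp of the true position), and
scores precision 1.0 and recall 1.0 at tolerance 1000 bp.

## Numerical and degenerate-input conventions

All coordinates are 0-based half-open internally and in all BED output;
SAM's 1-based positions are converted once at the parse boundary. Contigs
shorter than the window yield an empty profile and are never cut. Unknown
contigs in a spanning query return 0 with a warning (contigs without
molecules are legal); a molecule BED naming a contig absent from the FASTA
is an error. Ties in molecule grouping (same-barcode reads at identical
positions) chain normally. Outputs are byte-deterministic: records are
emitted in sorted order, FASTA is wrapped at 60 columns, and the only
header metadata is the package version and the parameter set -- no
timestamps. Scenario generation and read placement derive all randomness
from `params$seed` (the alignment stage uses `seed + 1` so the two stages
draw from independent streams).

## Problem sizes used in the checks

The bundled tests run the full pipeline -- SAM on disk, parsing, filtering,
grouping, scanning, cutting, FASTA splitting -- on 1 Mbp scenarios with 10
junctions at 100x molecule coverage (about 100,000 reads), repeated over
20 seeds for the recovery average, plus a junction-free null scenario that
must produce zero interior cuts. Scan correctness is checked against an
$O(nL)$ brute force on instances up to 50 kbp and 500 molecules. These
sizes were chosen so the whole suite exercises every stage at realistic
coverage while remaining a desk-scale computation.

## Limitations

Only misassemblies that interrupt molecule spanning are detectable:
collapsed repeats, and relocations or inversions smaller than a typical
molecule, do not produce a spanning dropout and pass unnoticed. Cut
placement is resolved to roughly the window scale, not base-pair
precision. Contig ends are never trimmed, so a misassembly within a window
of a contig end is not called. The package consumes alignments; producing
them (e.g. with `bwa mem` on barcoded FASTQ) and downstream scaffolding of
the corrected assembly are out of scope, though `run_all()` exposes a
post-hook for chaining a scaffolder.
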