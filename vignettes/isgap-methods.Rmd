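---
title: "Evidence-based gene annotation on assembled transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based gene annotation on assembled transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A de novo transcriptome assembly is the only gene catalogue available for
most non-model organisms, and it is a structurally messy one: transcripts
retain introns, carry UTRs, and sometimes represent non-coding RNA
altogether. The classical annotation route — six-frame translation,
keeping long ORFs — implicitly assumes each transcript is a clean spliced
CDS. A single retained intron breaks that assumption: it interrupts the
reading frame (and, in this package's generator, always carries stop
codons), so the true protein can only be recovered by *removing* the
intron, which a frame scanner cannot do. `isgapr` builds gene structures
from spliced protein alignments instead, uses ab initio models where no
protein evidence exists, and keeps six-frame translation only as the
baseline it is.

This vignette is the package's own account of the method: the model, the
parameters that matter, what the synthetic fixtures do and do not
emulate, and the design decisions taken where the procedure was genuinely
underdetermined.

# Data model

All coordinates are 0-based, half-open, on the transcript's forward
strand, whatever the gene's strand; GFF I/O converts to 1-based inclusive
at the boundary. A gene model is an ordered list of disjoint exon blocks;
the gaps between consecutive blocks are introns, described by their
(donor, acceptor) boundary pairs. Minus-strand models store exons in
forward ascending order; the spliced CDS is the reverse complement of the
concatenated blocks, and `phase` (0–2) is the offset of the first
complete codon of that strand-corrected CDS. Completeness flags
(`has_start`, `has_stop`) are always derived from, and validated against,
CDS content: a start means phase 0 and an `ATG` prefix, a stop means an
in-frame terminal `TAA`/`TAG`/`TGA`.

Translation uses the standard genetic code only (the package targets
nuclear mRNA). Codons containing `N` translate to `X`; `X` is never a
stop and never blocks frame extension — treating assembly `N`s as stops
would truncate genes for no biological reason.

# The pipeline, step by step

## Step 1: evidence structures

Each retained spliced protein alignment (percent score ≥ `min_percent`,
default 30; implied introns ≤ `max_intron`, default 50,000 nt — both the
conventional settings for protein-to-transcript alignment screening)
yields one candidate structure. Structures with the identical junction
set on one transcript and strand are the same gene seen through different
homologs, so they merge into a consensus model.

*Consensus* here can only concern boundaries: the nucleotides always come
from the transcript itself. Internal boundaries are fixed by the shared
junctions; each terminal boundary is chosen by majority vote over the
contributing alignments, ties going to the outermost (longer) boundary,
because terminal disagreement is nearly always inward truncation of the
weaker alignment. The merged phase is taken from the contributors that
own the winning 5' boundary. Support counts distinct evidence proteins;
score sums the contributing alignment scores.

Single-exon structures have no junctions, so junction identity is
undefined for them; the natural analogue used here is same-frame span
overlap on one transcript and strand (the frame tag is added to the
grouping key, and overlap clusters are transitive).

Models are then removed when their spliced CDS translates with a stop
before its final codon, or when their block pattern implies a frameshift.
Exonerate's text output does not mark frameshifts explicitly; the
operational definition used here is an inter-block gap too short to be a
plausible intron (< 20 nt) whose length is not a multiple of 3, plus the
consistency requirement that a complete model's CDS be a whole number of
codons. The 20 nt floor is far below any credible spliceosomal intron
and far above any alignment indel of interest; it is configurable.

Finally, same-strand models overlapping by at least one nucleotide
(transitive closure) compete, and only the best-supported one survives:
ranked by support, then score, then CDS length, then id. Support
dominates score deliberately — many homologs agreeing on a structure is
stronger evidence than one homolog aligning well. Overlap resolution is
per-strand by default (`strandless` switches this off) since opposite
strands can legitimately host overlapping ORFs on a transcript.

## Step 2: fixed-frame extension

Protein alignments stop at the protein's ends, so evidence models
typically lack the stop codon and may miss the start. Extension walks
codon-by-codon outward in the established frame, never touching a
junction. On the 3' side the first in-frame stop is included and ends the
gene; reaching the transcript end first leaves a flagged partial, trimmed
to the last full codon. On the 5' side an in-frame `ATG` found before any
stop becomes the start. What to do when a stop is hit first is genuinely
underdetermined; this implementation refuses to extend past evidence —
the boundary stays where the alignment put it (unless the codon
immediately downstream of that stop is itself an `ATG`, which is then
accepted). An upstream stop means the true start, if any, lies beyond a
frame disruption the model cannot see across.

Extension is idempotent, and the original translation is always a
substring of the extended one.

## Step 3: ab initio integration

A training set of complete genes (default 2,000, the conventional size
for training an ab initio predictor) is exported for an external trainer;
running the trainer is out of scope by design. Sampling is deterministic
given a seed and weighted toward multi-exon and longer-CDS models, which
carry the most information about splice and length distributions.

Incoming ab initio models are screened for abnormality. The term is
defined operationally here: internal in-frame stops, CDS < 150 nt (half
the conventional 100-residue ORF floor — short enough to keep real short
genes, long enough to drop ORF noise), exons out of transcript bounds, or
declared phase/completeness inconsistent with the CDS. All thresholds are
arguments.

Integration treats evidence as the backbone: an ab initio model may
*extend* an evidence model (identical junctions in the shared span and a
compatible reading frame — checked per shared coding position), in which
case the result is the interval union of both exon sets with the evidence
frame preserved; a conflicting ab initio model is discarded; one
overlapping no evidence is added unchanged. An ab initio model spanning
two evidence models is discarded rather than allowed to bridge them —
bridging would let the statistically weaker predictor overrule two
independent pieces of evidence. A final overlap-resolution pass restores
the same-strand non-overlap invariant (evidence wins via its support).

## Step 4: final filter and representatives

The external homology screen (e.g. against a protein database) is a
pluggable predicate: accept-all by default, or a hit-list of model ids.
Per locus — a transitive same-transcript/strand overlap cluster — exactly
one representative is kept: the longest complete model, else the longest
partial; ties break by support, then id, so output is reproducible.

# Validation metric

A predicted gene *represents* a reference-protein alignment region when
the matched region, strand and frame all agree. The metric is codon-level
deliberately: frame agreement is only meaningful per codon, so a query
codon counts as covered when all three of its nucleotides land in the
gene's CDS and form one whole gene codon. A region is represented at
coverage ≥ 0.99 (the conventional strict threshold). Query regions come
from strict alignments (percent ≥ 70, coverage ≥ 90%, no frameshift or
premature stop), and redundant regions are evaluated independently and
never deduplicated — one protein mapping to three transcripts is three
annotation opportunities, not one.

# Variant confirmation

Variants called on assembly A are classified against the final gene
models with precedence exon > intron > others, so an InDel straddling a
boundary gets a single deterministic label matching a mutually exclusive
summary table. Flank confirmation extracts the k-mers (default k = 50)
immediately 5' and 3' of the REF span and requires both to occur, in
order and exactly once, within a single transcript of assembly B,
separated by a gap equal to the ALT allele. Exact matching is the
strictest reproducible reading of "flanks detected" and is what a marker
assay needs; `max_mismatch` relaxes it, `require_alt = FALSE` drops the
allele check. Multi-hit flank pairs are flagged ambiguous and not
confirmed — a marker that maps twice is unusable. Variants within k nt of
a transcript end are unconfirmable and flagged as such rather than
silently failed.

# The synthetic fixture generator

`simulate_truth()` generates the structures the pipeline is built to
handle: transcripts carrying one true gene each (random ATG…stop CDS, no
internal stops, flanked by UTRs), retained GT..AG introns in a
configurable fraction of genes, 5'/3'-truncated partials, non-coding
decoy transcripts, evidence proteins (mutated translations of the true
CDS with inward, frame-preserving boundary jitter), perturbed ab initio
models, strict evaluation queries, and a paired assembly with planted
SNPs/InDels, half of them inside deliberately diverged flank zones.

Generator design choices worth knowing:

* **Introns carry stops in every frame.** Each intron embeds
  `TTAATTAATTAA` (its own reverse complement), placing a stop codon in
  all six frames. Real introns almost always contain stops; making it
  certain means no ORF can ever read through a retained intron, so the
  six-frame baseline's failure on multi-exon genes is structural, not a
  sampling accident. Intron insertion points fall in the central 80% of
  the CDS, at codon boundaries or mid-codon (both occur, to exercise
  phase handling across splices).
* **Jitter is inward and frame-preserving.** An aligner cannot extend an
  alignment past the protein's ends, so boundary error is modelled as
  truncation by 0/3/6 nt (biased toward 0), up to
  `alignment_boundary_jitter`. Fixed-frame extension is what recovers the
  lost codons, and to keep that recovery landing on the true start, the
  generator avoids `ATG` in CDS codons 2–5.
* **One variant per transcript.** InDels shift coordinates; planting at
  most one variant per transcript keeps every flank window exact without
  coordinate bookkeeping. Diverged zones substitute ~10% of each flank
  and force at least one substitution per flank, so the
  conserved/diverged separation is guaranteed by construction.
* **Defaults.** CDS 300–1500 nt, introns 60–500 nt (mean ≈ 300 bp, the
  order observed in plant transcriptome gene sets), UTRs 100–300 nt, 30%
  intron retention, 2–4 evidence proteins per gene at 3% residue
  mutation, 10% evidence dropout, ab initio miss/shift/spurious rates
  10%/5%/10%. Presets: `noise-free` (200 transcripts, exact inputs),
  `default` (500 transcripts, the rates above), `hard` (high jitter and
  error rates), `variants` (300 transcripts, one variant each, half
  diverged). Identical parameters and seed regenerate byte-identical
  fixtures.

What the generator does *not* emulate: assembly chimeras and
fragmentation beyond simple truncation, sequencing error in the
transcripts themselves, alternative splicing (one isoform per locus),
paralogous cross-mapping of evidence proteins, and genome-scale intron
lengths. Passing tests on these fixtures therefore demonstrates the
pipeline's structural logic — junction consensus, frame arithmetic,
extension, integration, flank matching — not robustness to every artifact
of real assemblies.

# Numerical and degenerate-input choices

* Ties are always broken deterministically (outermost boundary; support,
  then score, then length, then id), so identical inputs give identical
  output.
* Empty inputs return empty outputs (or zero-filled tables), not errors;
  genuinely malformed records fail loudly with line numbers, while
  records that are merely inconsistent (unsorted blocks, mixed strands)
  are dropped with warnings so one bad alignment cannot kill a run.
* A training request larger than the number of complete models returns
  all of them with a warning; zero complete models is an error.
* Mean intron length of an intron-free gene set is reported as 0 with an
  explicit `no_introns` flag rather than NA.
* Sub-codon sequences translate to the empty string; ORF scanning of
  transcripts shorter than 3 nt returns nothing.

The six-frame ORF definition had to be fixed where convention varies: a
complete ORF runs from the first in-frame `ATG` after the previous stop
through the stop codon (the stop is inside the reported span; `aa_length`
excludes it, matching GFF3 CDS convention); a frame with no complete ORF
contributes its trailing open stretch as a partial ORF. Defaults are the
conventional `min_aa = 100` with the single longest ORF per transcript;
`mode = "all"` and `require_start`/`require_stop` expose the stricter and
looser variants.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path while staying fast: 500–1,000 random 500-mers
for the ORF-enumeration cross-check against an independent brute-force
enumerator, 200-transcript noise-free and 500-transcript noisy fixtures
for end-to-end recovery, 300 planted variants for flank confirmation, and
100 randomized model sets for format round-trips. The pipeline itself is
linear in transcripts and alignments and runs comfortably on far larger
inputs.

# Known limitations

* One gene model per locus: overlapping isoforms are resolved away, by
  design, to yield a non-redundant reference set.
* The integration step never lets ab initio models bridge or shorten
  evidence models; where an ab initio predictor is genuinely right and
  the evidence wrong, the evidence wins anyway.
* Frameshift detection in evidence alignments is heuristic (short
  non-codon gaps); an in-frame compensated double frameshift is
  invisible to it.
* The representation metric requires exact frame agreement per codon;
  alignments with residue-level slippage score as unrepresented even
  when the protein is substantially recovered.
* Flank confirmation is exact-match by default; highly polymorphic
  regions will under-confirm unless `max_mismatch` is raised.
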