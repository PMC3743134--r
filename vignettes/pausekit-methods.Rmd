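---
title: "Quantifying Pol II pausing across the midblastula transition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II pausing across the midblastula transition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausekit)
```

# The scientific problem

During the *Drosophila* midblastula transition (MBT, nuclear cycles 13–14)
the zygotic genome is activated en masse: RNA polymerase II (Pol II) is
recruited de novo to thousands of promoters, and at most of them it pauses
30–50 bp downstream of the transcription start site (TSS) before productive
elongation. A much smaller set of genes is already transcribed before the
MBT (nuclear cycles 8–12), under severe time pressure from 8–13 minute
nuclear cycles, and these early genes are largely *not* paused. pausekit
implements the staged ChIP-seq analysis that quantifies this contrast:
per-transcript Pol II enrichment over a whole-cell-extract (WCE) control, a
pausing index, multi-criteria identification and classification of the gene
groups, core-promoter element statistics, profile summaries, and
gene-structure statistics — together with a synthetic-data generator so the
entire pipeline can be exercised and validated without external data.

# From aligned reads to coverage

Inputs are aligned-read interval tables (BED6; 0-based half-open
coordinates, a convention kept throughout the package).

1. **Duplicate-stack filtering** (`remove_duplicate_stacks()`). Reads
   sharing (chromosome, start, strand) form a stack; stacks of more than 10
   reads are PCR/alignment artifacts and are removed *unless* a
   corresponding number of reads sit on the opposite strand approximately
   one fragment length away in the stack's 3' direction — the two-strand
   signature of a genuine protein-binding pileup. Two conventions are
   quantified as parameters because they are not measurements:
   "approximately" is ±20% of the fragment length
   (`tolerance_fraction = 0.2`) and "a corresponding number" is at least
   half the stack size (`partner_fraction = 0.5`). Support is evaluated
   against *retained* reads and iterated to a fixed point; this makes the
   filter idempotent (a stack propped up only by another removed artifact
   stack is itself removed), which a single pass over the raw reads would
   not guarantee.
2. **Fragment extension** (`extend_reads()`). Single-end reads are extended
   to the library insert size (default 200 bp) from their 5' end in the
   strand direction, clipped at chromosome bounds.
3. **Coverage** (`compute_coverage()`). Each genomic coordinate scores the
   number of extended reads overlapping it, stored as run-length-encoded
   vectors (IRanges/S4Vectors `Rle`), which keeps multi-megabase tracks
   small and makes region sums cheap (`Views`/`viewSums`).

# Enrichment and the pausing index

For every transcript three regions are defined in transcript orientation
(`define_regions()`): the **TSS region** (first 200 bp), the **downstream
region** (+201 to +400 bp) and the **TU region** (+401 bp to the transcript
end). Transcripts shorter than 600 bp use the whole transcript as TU region.
Corners the definition leaves open are resolved as follows: below 400 bp the
downstream region is truncated at the transcript end, and at 200 bp or less
it is empty — the pausing index is then undefined, and the record is flagged
and excluded from group summaries.

Region enrichment normalizes both libraries for fragment length and total
read count:

$$\mathrm{Enrichment} = \frac{\mathrm{IP\ signal} / (\mathrm{IP\ reads} \times \mathrm{IP\ fragment})}{\mathrm{WCE\ signal} / (\mathrm{WCE\ reads} \times \mathrm{WCE\ fragment})}$$

where "signal" is the coverage sum over the region. A WCE region signal of
exactly zero (possible at desk-scale depths) is floored at one
fragment-equivalent (fragment length × 1 read) and the record is flagged;
this keeps the ratio finite without inventing signal.

The **pausing index** (also called stalling index) is
`log2(max(TSS, 1)) − log2(max(downstream, 1))`: both enrichments are floored
at 1 (background) so that a gene with no signal scores 0 rather than a noise
ratio. Per-gene indexes are the mean across replicates.

# Gene identification and classification

**Pre-MBT genes** (4 replicates, pre-MBT stage). A transcript qualifies when
(a) TSS enrichment is at least twofold over WCE in *every* replicate, (b)
its IP-normalized TSS signal (the numerator of the enrichment formula) is in
the top 1% of all transcripts in every replicate — high ratios must be
backed by high absolute signal — and (c) a TBP peak lies within 500 bp of
its TSS. Criterion (c) operationalizes as an automatic filter what was
originally a manual read-through screen: promoters without TBP occupancy
most likely receive Pol II signal running through from a neighboring gene.
"Twofold above" is interpreted as ≥ 2.0 (boundary inclusive) for consistency
with the "at least twofold" wording of the MBT criterion; the percentile is
computed with linear interpolation (`stats::quantile`, type 7). Peak sets
are inputs (e.g. from MACS); genes with un-annotated start sites can be
rescued via `assign_custom_tss()`, which places a TSS 19 bp downstream of
the TBP coverage maximum inside a peak (plateau maxima resolve to the
5'-most position in transcript orientation) and re-scores it with the
standard criteria.

Qualifying genes are classified (`classify_pre_mbt()`): **paused** if the
replicate-mean TU enrichment is below 1 (no gene-body signal); otherwise
**dual** if the gene's TSS enrichment is in the top 20% of an external
late-embryo reference ranking (these genes are non-paused early but pause
later); otherwise **not-paused**.

**MBT genes** (3 replicates, MBT stage). A transcript qualifies at TSS
enrichment ≥ 2 in all replicates; per gene the representative is the
qualifying transcript with the highest TSS signal, ties broken by the mean
TU enrichment (and then lexicographically, for determinism). Genes already
identified as pre-MBT are reported separately, not re-classified. MBT genes
are split by expression (`classify_mbt()`): **maternal** at nc10 RPKM ≥ 1
(transcripts already present before zygotic transcription), else **active**
at nc14D RPKM ≥ 5, else **poised**. Both cutoffs are boundary-inclusive.
For time-course analyses, `maternal_timecourse_filter()` removes genes with
nc10 RPKM > 16 or maternal expression at least twofold above zygotic at
nc10.

# Promoter elements

`motif_catalog()` carries the eleven core-promoter elements with their IUPAC
consensus, directionality and TSS-relative search window. Scanning
(`scan_motif()`) is exact IUPAC matching (Biostrings, `fixed = "subject"`,
so `N` in the promoter sequence never matches); directional motifs are
scanned on the sense strand only, non-directional motifs (GAGA, Zelda) on
both strands. An occurrence counts when its 5'-most matched base *in the
scanned orientation* falls inside the window — chosen over whole-motif
containment because windows like TATA's `[-100, 0]` are anchored on where
the element starts; the convention is configurable in spirit by editing the
catalog windows. Two deliberate choices: the GAGA match string defaults to
`GAGAG` (the canonical GAGA-factor element; the four-letter variant can be
restored via `motif_catalog(gaga_consensus = "GAGA")`), and occurrences
present on both strands at one position count once per strand-occurrence
while the presence flag is unaffected.

Group enrichment (`element_enrichment()`) is Observed/Expected on presence
fractions, reported as the negative reciprocal when below 1 (so a value of
−2 means twofold depletion; |signed value| ≥ 1 always), with two-sided
Fisher exact p-values and Benjamini–Hochberg correction across motifs at
q ≤ 0.05. Zelda, which occurs multiply per promoter, uses counts instead of
presence: `zelda_sampling_test()` compares the group's mean count per
transcript with the genome mean and computes an empirical p-value as the
fraction of 10,000 random equal-size transcript samples with strictly
higher enrichment. Pairwise co-occurrence (`motif_cooccurrence()`) compares
joint presence with the product of marginals, tests each pair with Fisher's
exact test, and orders the display by hierarchical clustering of the
enrichment matrix with Euclidean distance; complete linkage is used (the
clustering tool's distance was specified, the linkage was not, and complete
linkage gives compact, order-stable groups).

# Profiles

`metapeak()` averages read-count-normalized IP/WCE per-base enrichment
across anchor-centered windows (intervals reduce to midpoints; oriented
anchors are flipped so offsets run 5'→3'). Per-base zero WCE positions are
floored at one tenth of the genome-wide mean WCE coverage and flagged.
Profiles are per-base for flanks up to 5 kb and averaged into 100 bp bins
for larger flanks (the 80 kb default), purely to keep output desk-scale.

`heatmap_normalize()` implements the display normalization: enrichment in a
centered 100 bp sliding window (truncated at chromosome edges), replicates
combined by the per-base *minimum* (a conservative consensus that suppresses
single-replicate noise), then a linear rescale mapping enrichment 1
(background) to 0 and the 99th-percentile displayed value to 1, clipped to
[0, 1]. A sample with no enrichment above background (99th percentile ≤ 1)
must be normalized against the maximum of a comparable enriched sample
(`reference_max`) rather than amplifying its own noise.

`group_average_profile()` averages strand-aware TSS-anchored windows
(−200..+800 bp by default) within gene groups and scales all displayed
groups by their common maximum.

# Gene-structure, conservation and expression-pattern statistics

`structure_summary()` reproduces the group table: gene count, median
transcript width (annotated span of the representative transcript), genes
with multiple distinct TSSs, shortest-transcript usage, and intron content.
Percentages are rounded to one decimal. Two denominators matter:
shortest-transcript usage is computed *among genes with ≥ 2 distinct TSSs*
(the representative transcript must be the gene's shortest), and intron
content *among protein-coding genes* (a gene is intronless when its
representative transcript has a single exon). Contrasts between pre-MBT and
MBT-zygotic genes use a two-sided Mann–Whitney test on widths and two-sided
Fisher exact tests on the 2×2 count tables; sidedness is not stated in the
source convention, and two-sided is the conservative default.

`conservation_summary()` scores each transcript as the mean of a per-base
conservation track over its annotated span (gaps skipped, covered fraction
reported, fully uncovered transcripts excluded and counted) and summarizes
groups as quartiles. `first_expression_enrichment()` removes 'maternal' and
'no staining' annotations, keeps each gene's earliest remaining (stage,
term) annotation, and tests per-category group enrichment with exactly the
promoter-element machinery.

# The synthetic study

`simulation_plan()` + `simulate_study()` generate every input the pipeline
consumes. What the generator emulates, and the defaults:

* **Gene groups.** 0.5/0.3/0.2% pre-MBT (not-paused/dual/paused), 30%
  maternal, 10% active, 15% poised, 44% unbound. These keep the ordering of
  the real study (pre-MBT genes rare, roughly a third of genes maternal, a
  quarter zygotic) while keeping every group populated at the default
  n = 1000. The pre-MBT fraction must stay below 1% of transcripts for the
  identification filter to be satisfiable at all — the 99th-percentile
  signal criterion caps how many genes can qualify, exactly as in the real
  study where ~100 genes are far less than 1% of transcripts.
* **Gene structure.** Log-normal widths (median 1200 bp for pre-MBT genes
  vs 6000 bp otherwise, sdlog 0.4), a third of genes with 2–4 alternative
  TSSs, intronless probability 0.55 (pre-MBT) vs 0.07–0.09 (others),
  pre-MBT genes more often using the TSS yielding the shortest transcript
  (0.63 vs 0.31). Two chromosomes are auto-sized to the total gene span
  with ~60% intergenic headroom; fixed 1 Mb chromosomes cannot host 1000+
  genes at these widths without overlap, and overlapping genes would
  contaminate each other's TSS regions.
* **Reads.** WCE is uniform. 10% of IP depth is uniform nonspecific
  background; the rest is split across the stage's bound genes (log-normal
  occupancy spread, sdlog 0.2) and divided per gene between a TSS-proximal
  pause-site component — fragment centers from a discretized normal at
  +40 bp, sd 50 bp, in transcript orientation — and a gene-body-uniform
  component, with weights per group and stage
  (`default_mixture_weights()`): paused groups are pure pause-site signal
  (their TU regions carry background only, hence TU enrichment < 1), the
  dual group switches from 0.5 to 0.85 at the MBT. The pause-site sd is a
  modelling choice: the source describes the pause position (+30–50 bp) but
  not the signal width. Each IP read set also carries planted PCR duplicate
  stacks (5 stacks of 15 reads) at coordinates recorded in the ground
  truth.
* **Companion tables.** RPKM tables with maternal/zygotic structure
  (log-normal noise, sd 0.25, with the defining thresholds enforced so
  planted labels stay consistent); promoters (−2000..+99, 40% GC) with
  motifs planted at per-group rates inside their catalog windows; a
  conservation track elevated over pre-MBT gene spans; expression-pattern
  annotations with active genes first detected at stages 4–6 and poised
  genes at 9–10; a reference ranking placing dual genes in the top 20%; and
  TBP peaks at bound-gene TSSs with summits 20 bp upstream.

Everything is a pure function of (plan, seed): sub-seeds are derived per
generator, stage and replicate, so any single piece can be regenerated
independently and byte-identically.

**What the generator does not emulate** — and what passing tests therefore
do not demonstrate about real data: sequencing error and mappability bias,
chromatin-dependent WCE structure (real input is not uniform), realistic
fragment-size distributions, overlapping and nested gene models, and
realistic enrichment magnitudes at the pre-MBT stage (with only ~10 bound
genes sharing 90% of the depth, synthetic pre-MBT enrichments reach the
hundreds; the real study's are far smaller, and the classification criteria
are threshold-based precisely so magnitudes do not matter). One realistic
artifact *does* appear: genes immediately adjacent to strongly bound genes
can pick up read-through enrichment and classify as false MBT positives at
a low rate — the same failure mode the TBP-proximity screen addresses for
pre-MBT calls.

# Problem sizes and determinism

The default synthetic study is 1000 genes, 2×10⁶ reads per library, four
pre-MBT and three MBT replicate pairs; the test suite exercises the full
pipeline at this size once and uses 60–150-gene studies elsewhere. The
planted-label recovery requirement is ≥ 95% of bound-gene labels recovered
end-to-end. Statistical machinery is validated against independent oracles:
the motif scanner against brute-force regex expansion of the IUPAC codes,
Fisher p-values against exhaustive hypergeometric summation, BH against a
hand-written step-up, coverage against per-base overlap counting, and the
resampling test against its null calibration (random groups should yield
p < 0.05 about 5% of the time; the discreteness of an empirical p-value on
a 200-sample grid makes the observed rate slightly anti-conservative, which
the tests bound at ±1.5 percentage points).

# Known limitations

* The percentile criterion couples the pre-MBT candidate count to the
  transcript universe: analyses on sub-genomes should rescale `percentile`.
* `identify_mbt()` has no read-through screen (following the source
  procedure), so adjacent-gene false positives are possible in dense
  regions.
* Paired-end handling is reduced to fragment intervals with insert-size
  bounds applied as a filter; no fragment-size modelling.
* The co-occurrence clustering order depends on the linkage choice
  (complete); the enrichment and p-value matrices do not.
* `zelda_sampling_test()` p-values have resolution 1/n_samples; at the
  default 10,000 samples the smallest reportable non-zero p is 10⁻⁴.
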