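---
title: "Calling large deletions from exome-capture read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling large deletions from exome-capture read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delscan)
```

## The model

`delscan` detects multi-megabase deletions in a mutagenized line by
comparing its binned exome-capture read depth to a wild-type line of
the same background captured with the same probe set. The coverage
model assumes that each 1 Mb bin has an unknown capture efficiency
shared between the two lines (probe density, GC, mappability), that
read counts are approximately Poisson around that expectation, and
that a homozygous deletion suppresses coverage to a small residual
(off-target and misaligned reads) rather than exactly zero. Under that
model the two-step normalization

\[
v_i=\frac{m_i/M}{w_i/W}
\]

(bin count over line total, divided by the same ratio in the wild
type) cancels both the per-bin efficiency and the depth difference
between libraries, leaving \(v_i \approx 1\) in diploid regions and
\(v_i \approx r \ll 1\) inside homozygous deletions. Bins where the
wild type has no reads carry no information and are masked rather than
treated as zero, so probe deserts cannot masquerade as deletions.

Deletions are then runs of low bins: a call opens at the first bin of
a run of at least `min_low_run` (default 4) adjacent bins with
\(v \le\) `low_fraction` (default 0.1) and is considered finished only
once at least `min_high_run` (default 4) adjacent bins exceed the
threshold. Interior high runs shorter than that are absorbed into the
call; this is the direct reading of the stopping rule, and the
alternative (splitting at any high bin) would shatter real deletions
on single noisy bins. The reported interval runs from the first to the
last low bin; masked bins count toward neither run and are spanned
when flanked by low bins. All calling uses raw bin values; the
window-4 moving average exists for plotting only.

Why 4 bins and 10%? A 4 Mb minimum focuses the screen on the large
terminal and interstitial deletions that gamma irradiation produces
and that these thresholds were designed around, and 10% separates the
residual-coverage regime (about 2% of normal in our simulations) from
heterozygous loss (about 50%) with a wide margin on both sides at
depth ~100 reads per bin.

## Coordinates

Everything internal is 0-based half-open, so a deletion's size is
exactly `end - start`. Reference "parts" pseudomolecules are lifted to
full chromosomes by shifting part-2 coordinates by the part-1 length;
because the terminal part-1 bin is usually shorter than 1 Mb, lifted
bin boundaries on the second half of a chromosome are offset from
whole megabases. The lift is a bijection (`lift_full_to_parts()` is
its inverse), which the tests exercise as a round-trip property. GFF3
input is converted at the boundary; no internal operation sees 1-based
coordinates.

## Border refinement against gene models

Bin-resolution borders are refined by scanning gene models that show
capture coverage in the wild type. Genes whose normalized mutant
coverage is at or below `low_fraction` are treated as deleted; the
refined interval extends from the *end of the last covered gene
upstream* of the deleted block to the *start of the first covered gene
downstream* (chromosome ends when no such gene exists). The manual
procedure this automates inspected alignments at each border and
reported the nearest flanking genes; placing the refined border at the
flanking covered genes is the only rule consistent with refined
intervals that exceed the bin-method extent where annotated genes are
sparse near a border — the refined interval brackets the true deletion
and deliberately errs outward. A call containing no low-coverage gene
is returned unchanged with a notice rather than refined.

Shared low-coverage regions deserve suspicion rather than deletion
status: independent mutants should not share breakpoints, so any call
overlapping a call in another line is flagged
`background_polymorphism_suspect` (read misalignment over a
background/reference polymorphism produces exactly this signature).
Flagged calls are annotated, never removed — the analyst decides.

## Dominant markers and segregation

The PCR markers are dominant: a product is amplified from wild-type
and heterozygous plants alike, so only homozygous deletions are
identifiable, and "absent or faint" is read as a putative deletion
(faint bands arise from trace amplification in deletion homozygotes;
calls resting only on faint evidence are marked low-confidence).
Extent inference assumes a single contiguous deletion per arm and
classifies the deleted block relative to an anchor marker
(`spans_all_markers`, `distal_not_including_anchor`, `anchor_only`,
`interstitial`), with non-contiguous patterns surfacing as
`inconsistent` instead of being forced into a class. Not-determined
entries are excluded from inference rather than erroring, since real
screening tables contain them.

Genotype classes for segregation are therefore defined over
homozygous-deletion status only. With per-gamete transmission
probability \(p\) (0.5 when unbiased), a locus is homozygous deleted
with probability \(p^2\) and independent loci multiply: 1/16 double
homozygotes for two unlinked loci. The transmission-bias test uses the
Pearson chi-square statistic when every expected count is at least 5
and an exact binomial tail otherwise; because the natural question for
a rare class is one-sided ("are double mutants under-represented?"),
naming a focal class always adds the exact lower-tail probability for
that class regardless of branch.

## Granule morphometry

Micrographs are binarized with Otsu's global threshold (the method is
a stated default — no particular rule is prescribed by the original
procedure), touching granules are separated by a distance-transform
watershed, and particle areas are pixel counts times the squared
pixel size, excluding border-touching particles whose visible area
underestimates the granule. The two-pass analysis counts particles
with area ≥ 0.785 µm² (circles of diameter ≥ 1 µm: A- plus
B-granules) and particles in [0.785, 78.5] µm² (1–10 µm diameter:
the small-granule class); both cutoffs are inclusive, matching the
particle-analysis convention the procedure invokes, and
`pct_small` is the per-image percentage averaged over images. The
"large" class used for its mean area is everything above 78.5 µm².
Swelling power is the swollen-pellet to dry weight ratio.

## What the simulators emulate — and what they do not

* `simulate_coverage_pair()` draws one lognormal capture-efficiency
  factor per bin (σ = 0.3), shared between lines, then Poisson counts
  at mean depth 100 per full bin, with 2% residual coverage inside
  planted deletions. The 2% default keeps the 10% threshold doing real
  work (a residual of exactly 0 would make the caller trivially
  right). It does not model mappability structure, GC waves along
  chromosomes, or heterozygous deletions (a residual near 0.5 is
  available as a parameter but unused by default, since the sequenced
  lines were homozygous).
* The built-in `paragon_layout()` plants the ten published bin-method
  deletion intervals of lines A1 and D4. Chromosome lengths for 1B and
  4B are pinned by deletions that run to the chromosome end; the other
  lengths and all part-split points are synthetic, chosen so every
  published interval is representable as whole bins after the lift
  (the split point must be congruent to the interval boundaries modulo
  1 Mb when a deletion sits on part 2).
* `simulate_gene_models()` places non-overlapping genes that never
  straddle a planted breakpoint (breakpoints fall between genes), so
  planted shared-homoeologue counts are exact truth. Real annotation
  is denser, unevenly spaced, includes genes without wild-type capture
  coverage, and crosses breakpoints.
* `simulate_granule_image()` renders filled discs with lognormal
  diameters (small class mean area ≈ 25 µm², large ≈ 300 µm²,
  matching typical control starch), limited overlap, and mild Gaussian
  noise. It does not model optics, illumination gradients, staining
  variability, or strongly clumped granules.

Passing tests on these simulations show that the algorithms implement
their stated rules and recover planted truth under the assumed noise
model; they do not show robustness to artefacts the generators omit
(alignment waves, annotation error, imaging conditions).

## Numerical and design choices

* Bin membership is by alignment start position in half-open bins, so
  every read counts exactly once; `total_reads` counts retained
  (MAPQ-filtered, proper-pair) reads so normalization and filtering
  share one universe.
* The moving average is window-start aligned and masked-aware (masked
  bins drop out of the window mean; an all-masked window is masked).
* Degenerate inputs: empty profiles yield empty call sets, not errors;
  blank images yield empty masks with a notice; zero-qualifying-
  particle images are excluded from the sample mean with a notice.
* Homoeologue intersection is greedy in coordinate order with each
  gene used at most once, making the reported pair count
  deterministic.
* Problem sizes in the test-suite simulations (a ~6.3 Gb ten-
  chromosome layout at 1 Mb bins, 20 replicate seeds for noisy
  recovery, 220-granule micrographs, exhaustive rule-equivalence up to
  length-20 profiles) were chosen to exercise every rule at full scale
  while keeping a complete run in minutes on one core.

## Known limitations

Breakpoints are resolved to bin or gene granularity only; small
indels, SNPs and copy-number gains are out of scope. The caller's
thresholds are tuned for homozygous deletions at moderate depth —
heterozygous calling would need a second threshold band around 0.5.
Refined borders depend on annotation density and inherit its gaps, and
real gene-model sets will not reproduce synthetic refinement results
exactly. Multiplex peak interpretation applies a relative-height rule
(< 0.2 of the median positive peak is "very small") because no
numeric rule is prescribed; the ratio is configurable.
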