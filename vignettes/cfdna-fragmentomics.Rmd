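---
title: "Methods: orientation-aware cfDNA fragmentomics and the E-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation-aware cfDNA fragmentomics and the E-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragaxis)
```

## The model

Plasma cell-free DNA (cfDNA) is the debris of programmed cell death:
nucleases digest chromatin down to nucleosome-protected fragments that
circulate until cleared. Where a nuclease can cut is governed by chromatin
structure — linker DNA between nucleosomes is exposed, core-wrapped DNA is
protected, and within the core the helical twist exposes one face of the
duplex every ~10 bp. DNA methylation stabilizes the nucleosome; losing it
(as tumor and placental genomes do globally) opens the core to intra-nucleosomal
cutting. The observable consequences in sequencing data are:

1. a modal fragment size of 166 bp (one core plus linker),
2. a 10-bp periodic ladder below 147 bp,
3. fragment *ends* that pile up at preferred positions relative to
   nucleosome centers, different for the upstream (U) and downstream (D)
   end of each fragment,
4. hypo-methylated reads running shorter than hyper-methylated reads, and
5. per-sample end-position usage that is highly reproducible in healthy
   plasma and perturbed in cancer.

`fragaxis` implements the measurement side of this picture (end profiling,
periodicity, methylation partition, end motifs, E-index) and a generative
simulator whose only mechanisms are the geometry and the
methylation-accessibility coupling above, so that every measured phenomenon
is *emergent* from the generator rather than painted into it.

## Coordinate conventions

All intervals are 0-based half-open `[start, end)`. The U end is `start`,
the D end is `end - 1` (the last covered base), hence
`size = end - start = D - U + 1`. This inclusive convention is what makes
the classic worked example exact: a U cut at −68 bp and a D cut at +74 bp
relative to a nucleosome center delimit a fragment of
`74 − (−68) + 1 = 143` bp. Note that under the same arithmetic the pair
(−59, +63) gives 123 bp, not the ~122 sometimes quoted for it; one of the
two published figures is internally off by one, and this package fixes the
convention rather than guessing per case. Strand is ignored throughout:
U/D are defined purely by coordinate order.

## The synthetic generator

The generator defines the study conditions for all tests; its defaults are
fixed once and not tuned per analysis.

**Nucleosome array** — `make_nucleosome_array(400, spacing = 185)` emulates
a region of constitutively well-positioned nucleosomes of the chr12p11.1
type used as a model locus for end profiling: ~400 centers at a 185-bp
repeat, optional Gaussian jitter, re-sorted. Spacing below 147 bp is
rejected (cores would overlap). Core geometry is carried by the track:
±73 bp core half-width (147 bp of wrapped DNA), ±90 bp spacing half-width.

**Cut model** — `cut_model()` holds the nuclease preferences:

| parameter | default | meaning |
|---|---|---|
| `u_core_offsets` | −68, −58, …, −8 bp | intra-core preferred U cut sites, a 10-bp lattice anchored at −68 |
| `d_core_offsets` | +63, +74 bp | intra-core preferred D cut sites (outermost at +74) |
| `u_linker_offset`, `d_linker_offset` | −83, +82 bp | linker cuts; the linker pair spans 82 − (−83) + 1 = 166 bp |
| `peak_sd` | 1.5 bp | Gaussian positional noise around any preferred site |
| `w_linker` | 3.0 | linker cut weight (never methylation-modulated) |
| `w_core_unmeth`, `w_core_meth` | 1.0, 0.25 | intra-core weight at local methylation 0 and 1 |
| `meth_sensitivity` | 1 | exponent `s` in `w(m) = w_meth + (w_unmeth − w_meth)(1 − m)^s`; `s = 0` switches the coupling off |

The U-side lattice ends at −68 and the D side at +63/+74 because those are
the reported landmark peaks; placing the U lattice upstream and the D sites
downstream of the center makes the U/D orientation asymmetry emergent. The
quantitative form of the methylation-to-cutting map is not known; the
interpolating-exponent form above is an explicit assumption, kept separable
(`meth_sensitivity = 0` disables it) so sensitivity analyses and null tests
can switch it off.

**Methylation landscape** — `make_methylation_landscape()` places CpG sites
every 25 bp (dense enough that a mono-nucleosomal read covers ~6–7 sites and
is classifiable under the ≥2-CpG rule) and draws per-site methylation
probabilities hierarchically: a Beta-distributed domain mean (2-kb domains,
concentration 8) plus tight site-level Beta noise (concentration 50). The
domain layer supplies the nucleosome-scale heterogeneity that couples a
read's *drawn* methylation states to the cut weights of its source
nucleosome — without it the per-read states and the cutting behavior would
be independent and the size-methylation analyses would have no signal to
recover. The `"tumor"` profile has mean 0.4 and a fraction (default 0.3) of
domains forced to 0.05, emulating global tumor hypomethylation; `"blood"`
has mean 0.8. Degenerate means (0 or 1) pass through exactly.

**Sampling** — `sample_fragments()` picks a nucleosome uniformly per
fragment, computes the local core methylation for the fragment's tissue
profile, samples U among {intra-core lattice, linker} and D likewise with
the weights above, adds positional noise, and redraws the rare D ≤ U
violations. Per-CpG binary states are Bernoulli draws from the site
probabilities. A tumor fraction mixes in fragments generated under the
`"tumor"` profile (per-fragment Bernoulli); `mix_samples()` additionally
mixes pre-generated pools with provenance tracking.

**Reference and motifs** — `make_reference()` emits a uniform-random A/C/G/T
sequence and seeds the CCCA end motif at preferred cut sites (probability
0.7 per site): forward CCCA at a seeded U site, TGGG (reverse-complementing
to CCCA) at a seeded D site. By default the *linker* sites are seeded: in
this generator methylated, nucleosome-stabilized DNA is cut in linkers, so
tagging linker cuts with CCCA reproduces the observed association between
methylated-DNA cleavage and CCCA usage — a MeDIP-enriched (methylated)
pool then shows elevated CCCA usage relative to its parent pool, which is
the direction the motif analyses test. Positional noise means only exact
on-site cuts read the full motif, which keeps usage realistically far from 1.

**MeDIP capture** — `simulate_medip_capture()` retains a fragment with
probability `min(1, w·m)` for `m` methylated CpGs (default `w = 0.25`), the
simplest retention curve that is monotone in methylated-CpG count and
reaches certainty.

**What the simulator does not emulate** — real sequencing noise (base
errors, bisulfite conversion failure, alignment artifacts), single-strand
library chemistry, genome-wide nucleosome irregularity, CpG clustering into
islands, di- and oligo-nucleosomal fragments (the >170 bp tail here comes
only from positional noise on linker-to-linker cuts, not from spanning two
cores), or inter-individual variation. Passing tests therefore demonstrate
that the *measurement code* recovers the structure a generative model puts
in; they are not evidence about any particular cohort.

## Analysis-side choices

**End assignment** — each end is assigned independently to its nearest
center within a window of W = 93 bp (covering the ±90 spacing boundary with
margin); equidistant ends go to the left center; farther ends are counted
as unassigned. Assignment conservation (assigned + unassigned = 2 ×
fragments) is tested.

**Peak calling** — the per-position frequency series is smoothed with a
3-bp centered moving average (computed on integer counts and normalized
afterwards, so plateau ties are exact), local maxima are scored by
topographic prominence — which is invariant to an additive uniform
background — and kept if prominence exceeds 1.5 × the median smoothed
frequency; peaks closer than 5 bp (half the lattice period) are pruned
keeping the more prominent. Plateaus resolve to their center; all remaining
ties break toward the smaller |position|. The smoothing window, threshold
and separation must jointly resolve 10-bp-spaced peaks of unequal height;
these defaults do so with margin on the pooled-scale fixtures.

**Periodicity** — profiles are detrended with a degree-1 loess (span 0.3 of
the window; the smoother's envelope removes the broad nucleosomal shape
while leaving the 10-bp oscillation), residuals are centered, and a plain
FFT periodogram `|X(f)|²/n` is taken at the Fourier frequencies. No taper
or padding by default — with a 187-point window the Fourier grid puts the
dominant period of a 10-bp lattice at 187/18 ≈ 10.39 bp; the optional
`pad_to` argument refines the grid (padding to 1870 points yields 10.0).
The band for `dominant_period` defaults to 5–20 bp. The full ±W window is
analyzed (not core-only); this is configurable by profiling a subset.

**Methylation classes** — reads with ≥2 CpGs (alternative: 5) are hyper if
average methylation > 0.80, hypo if < 0.20, strictly; boundary values are
unclassified. The hypo-vs-hyper size comparison uses a paired t test across
matched 1-bp size bins of the *cumulative* frequency curves: per-bin
density differences sum to zero identically (both densities are
normalized), so the cumulative curves — which carry the stochastic ordering
"hypo runs shorter" — are the per-distribution quantity a bin-paired test
can meaningfully compare. The genomewide curve averages per-fragment mean
methylation within 1-bp size bins over 50–400 bp and fits count-weighted
least squares; per-fragment-then-per-size averaging was chosen over
per-CpG averaging so that deeply covered fragments do not dominate.

**E-index** — the pooled-control model counts, per locus, appearances as U
and as D end; counts stay raw (one model, applied everywhere, needs no
normalization — and doubling the pool doubles every score, which is tested).
A sample's E-index is the mean of `M_U + M_D` over its deduplicated
fragments; loci absent from the model contribute 0 with no pseudocount, as
the score is a plain sum of counts. Samples scored against the model are
held out from it (the pipeline's `holdout_controls` parameter). ROC
analysis negates scores so that the cancer-low convention yields AUC > 0.5,
uses the Hanley–McNeil normal approximation for the Z test against 0.5,
and a Mann–Whitney U test between groups. `combine_features` fits a
two-feature logistic model scored by leave-one-out; the single-feature AUCs
it reports use the same leave-one-out protocol, because comparing
out-of-sample combined scores against in-sample raw-feature AUCs would bias
the comparison against the combination by construction.

**Deduplication** — PCR duplicates are fragments with identical
(chromosome, start, end); the first occurrence is kept. The operation is
idempotent and applied before model building and scoring.

## Numerical and degenerate-input behavior

Empty fragment sets, empty size ranges, all-unclassified samples, constant
score vectors, flat profiles and missing model loci all signal explicitly
(error, `NA` with warning, or an `insufficient` flag) rather than returning
silent zeros; the degenerate paired-t cases (identical distributions → P =
1; constant nonzero shift → P → 0) are special-cased because the t
statistic itself degenerates. All generator operations are bit-reproducible
under a fixed seed, restore the caller's RNG state, and derive nothing from
global state.

## Problem sizes used by the test suite

The pooled-scale fixtures use one 200,000-fragment control sample on the
400-nucleosome array (the generator's per-sample default); direction and
power checks use 10,000–60,000-fragment samples, 20–25 seeded replicates
for the motif and slope power analyses, and 50 replicate 12-vs-12 panels of
4,000-fragment samples for the AUC property. These sizes were chosen so
each stochastic check has comfortable statistical margin while the whole
suite stays quick to run; all of them are parameters, not constants, and
scale up freely.

## Known limitations

- The generator is mono-nucleosomal and single-chromosome by construction;
  genome-scale heterogeneity, oligo-nucleosomal fragments and coverage
  biases are out of scope.
- The methylation-to-cut-weight map is an assumed functional form; only its
  direction and its off switch are load-bearing in the analyses.
- E-index behavior under cross-platform protocol shifts (a key strength
  claimed for the real-data metric) cannot be probed with a single
  generative process.
- The paired WGS/MeDIP motif comparison assumes both assays sample the same
  fragment population up to the capture weighting; real immunoprecipitation
  has sequence- and length-dependent efficiencies not modeled here.
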