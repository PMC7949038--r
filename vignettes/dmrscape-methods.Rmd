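---
title: "Calling, classifying and interpreting differentially methylated regions with dmrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, classifying and interpreting differentially methylated regions with dmrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscape)
```

# The model

dmrscape works at the level of per-CpG bisulfite calls: for CpG $i$ and
sample $s$, a methylated read count and an unmethylated read count whose
sum is the coverage $c_{is}$ and whose ratio estimates the methylation
fraction $m_{is} \in [0,1]$. Fractions are always recomputed from the
counts; the percentage column of the input bedGraph is ignored so that
no upstream rounding propagates. CpGs are keyed by position on one
strand; merging of the symmetric CpG is assumed done upstream.

Three ideas carry the whole analysis:

1. **All-sample filtering.** Only CpGs with $c_{is} \ge 5$ in *every*
   sample enter the matrix. This makes every downstream count refer to
   one fixed, comparable site universe, at the price of discarding sites
   that are deep in most but not all samples.
2. **Thresholded group differences.** With control group $A$ and tumor
   group $B$, $\bar m_i^{G}$ is the unweighted mean over the samples of
   $G$. A differentially methylated cytosine (DMC) satisfies
   $|\bar m_i^{B}-\bar m_i^{A}| \ge \delta$ with $\delta = 0.30$; the
   comparison is inclusive because the definition is printed as
   "$\ge 30\%$". Unweighted (rather than coverage-weighted) means keep
   each sample's methylome equally influential regardless of depth.
3. **Chaining plus a regional rank test.** DMCs sorted by position chain
   while the next DMC has the same direction and lies within 50 bp; a
   maximal chain of at least 3 DMCs is a candidate region and is kept
   iff a two-sided Mann--Whitney U (MWU) test on the member CpGs'
   methylation values gives $p < 0.05$ (strict). Chains are maximal
   runs; adjacent regions are never post-merged, and no multiple-testing
   correction is applied — the output mirrors the stated definition, not
   an FDR-controlled call set.

## What the Mann--Whitney test compares

The regional test needs two samples of values. By default dmrscape
pools, for each group, every sample's methylation fraction at every
member CpG (`mwuValues = "pooled"`, giving $n_{\mathrm{CpG}} \times
n_{\mathrm{samples}}$ values per side; with a single control sample this
still works). The alternative of testing the two per-CpG group-mean
vectors (`mwuValues = "group_means"`) looks natural but has a hard
statistical defect: an exact two-sided rank test on two 3-vectors can
never go below $p = 2/\binom{6}{3} = 0.1$, so the minimal 3-CpG region
permitted by the chaining definition could never pass $p < 0.05$ and
the region definition would be internally inconsistent. Pooling keeps
3-CpG regions reachable ($2/\binom{12}{6} \approx 0.002$ at complete
separation with two replicates per side) and is the default; the
group-means variant remains available for sensitivity analyses.

The test itself enumerates all group reassignments exactly (with
midranks, so ties are handled without approximation) whenever the
pooled size is at most 12, and above that uses the normal approximation
with tie-corrected variance and a 0.5 continuity correction. The exact
path is validated against an independent pairwise-counting enumeration
to $10^{-12}$; the approximate path against the standard corrected
formula.

## Reading "consecutive"

The definition constrains the distance between consecutive *DMCs*, not
between consecutive retained CpGs. dmrscape therefore lets a retained
non-DMC CpG sit inside a chain (a site that just misses the 30-point
cut does not erase an otherwise coherent region), while
`strictConsecutive = TRUE` gives the other reading, where any
intervening retained CpG breaks the chain. Only distance, direction and
chromosome break chains by default.

# Annotation, set logic, integration

**Element annotation.** Promoter windows are strand-aware: long
promoter TSS $-1500/+500$ bp, core promoter $-300/+150$ bp, the minus
strand mirrored around the TSS point and windows clipped at the
chromosome start. A DMR is assigned to an element class when the
class's intervals jointly cover at least half of the DMR's length. The
*union* of per-class overlaps is used (splitting an element into
abutting pieces can never change a decision), and classes are
independent — one DMR may be, say, promoter and exon at once; no
precedence hierarchy is imposed.

**Genotype set logic.** Two DMRs from different comparisons are "the
same region" when they overlap by at least 1 bp with the same
direction — the bedtools-intersect default, chosen because no overlap
fraction is part of the published procedure; `reciprocalFrac` exposes
stricter matching. Regions matched across all three tumor-vs-control
comparisons (`WT`, `KO`, `CI`) are attributed to transformation and
removed everywhere before classification. The remaining membership
profiles map to mechanisms: hypomethylated in `KO` only → accessory
function (AF) target; in `KO` and `CI` → catalytic activity (CA)
target; hypermethylated in `CI` but not `KO` → AF target; only in `WT`
→ CA target; everything else is `unassigned`, so the four labels
partition every region entering the classifier. Summary counts are
reported on the knockout list's units for the hypomethylated classes
(the reference set of the AF/CA accounting), on `CI`/`WT` units for the
hypermethylated ones.

**Integration.** Genes whose long-promoter window received a
hypomethylated DMR under the same 50% rule (the long window, not the
core, is the default linkage window; `window = "core"` switches) are
split into G1 (fold change $\ge 2$ and $p < 0.05$; upregulation only,
so a significantly *down*-regulated gene is not G1), else G2 when the
control FPKM is at least 0.2, else G3. The published boundary is
written both as ">0.2" and "<0.2", leaving FPKM $= 0.2$ undefined; the
tie goes to G2 here. When several DMRs hit one promoter the one with
the largest $|$mean difference$|$ represents the gene.

**Signal profiling.** Region bodies are rescaled to 200 bp in 10-bp
bins by mapping bin boundaries linearly onto the native region and
taking the coverage-weighted mean of the per-base signal over each
mapped span (regions shorter than the bin count are handled by
fractional mapping, never an error); 100-bp flanks are binned natively.
TSS windows ($\pm 2000$ bp) are unscaled, oriented 5'→3', zero-padded
and flagged when they run off the chromosome. DMR profiles are
unstranded (DMRs carry no strand). Per-bin curves report mean $\pm$
SEM (sd with $n-1$, divided by $\sqrt{n}$); group comparisons offer
Student's and Welch's two-sided t-tests both per bin and on per-region
mean signal, since it is ambiguous which of the two a per-bin asterisk
convention tests — both are exposed, neither asserted as canonical.

# The synthetic methylome

The generator emulates exactly the structure the caller assumes, with a
planted truth table for scoring:

* CpG positions with geometric-like spacing (mean 100 bp) on one
  synthetic chromosome; planted regions are CpG-dense (uniform 5–15 bp
  spacing, the density of CpG-island-like regulatory loci where such
  regions live) and separated by at least 150 bp of guard gap (3x the
  50-bp chain limit) so two truths can never chain together.
* A bimodal baseline: 70% of CpGs from Beta(9,1), 30% from Beta(1,9) —
  the genome-wide high/low methylation bimodality; these are defaults,
  not claims about any particular genome. Regions destined for
  hypomethylation draw their baseline from the high mode (methylation
  must exist before it can be lost) and hypermethylation targets from
  the low mode, so shifts are realizable without clipping.
* Planted categories wire the set logic: hypo AF targets shift only
  `KO`, hypo CA targets `KO`+`CI`, transformation regions all three,
  hyper AF only `CI`, hyper CA only `WT`, `specific_A`/`specific_B`
  only one of two comparisons, `none` nothing. Default: 60 regions of 5
  CpGs with shifts of $\pm 0.4$.
* Reads: coverage $\sim$ Poisson(30) per sample, methylated count
  $\sim$ Binomial(coverage, true fraction) — a beta-binomial in effect,
  with the beta variability carried by the per-CpG truth rather than an
  extra dispersion parameter. Each (group, replicate) pair has its own
  deterministic RNG substream derived from the one global seed, so the
  whole pipeline is byte-reproducible and replicates still differ.
* Matched expression (G1 genes constructed to pass FC $\ge 2$,
  $p < 0.05$; G2/G3 split by FPKM around 0.2 with lognormal noise) and
  per-base signal tracks (background with mean-corrected lognormal
  noise, enrichment multipliers applying fully inside a region and
  decaying linearly over 50 bp).

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: spatial correlation of methylation
beyond the planted regions, bisulfite-conversion error, copy-number and
purity effects, read-level biases, overdispersion beyond binomial, and
real genome annotation geometry. Recovery rates here certify the
algorithmic chain, not field performance.

# Numerical choices and degenerate inputs

* Threshold comparisons mirror the printed definitions: $|\Delta| \ge
  0.30$ inclusive (with a $10^{-12}$ guard against representation
  error), $p < 0.05$ strict.
* A pooled MWU sample with all values identical returns $p = 1$; a
  zero-variance bin comparison returns $p = 1$ when the means agree and
  0 otherwise.
* Zero-coverage CpG records are legal input (fraction undefined) and
  fall to the coverage filter.
* Profile bins are integrated via cumulative sums with linear
  interpolation at fractional boundaries; the oracle tests reproduce
  them with explicit per-base weights to $10^{-9}$.
* The group swap is an exact symmetry: swapping the groups flips every
  DMC/DMR direction, negates differences and leaves p-values unchanged.

# Problem sizes

The shipped test and scoring configurations use a 200-CpG tiny fixture
(3 planted regions) for exhaustive definition checks and a 50,000-CpG
default fixture (60 regions, 8 samples) for recovery scoring — sizes
chosen so the full suite exercises every stage in a couple of minutes
on one core while keeping, at $\ge 14$ retained CpG observations per
planted region per sample, enough signal that recovery failures mean
defects rather than noise.

# Known limitations

* The caller implements the stated chaining definition, not the
  circular-binary-segmentation internals of the historical tool that
  produced the published counts; on identical inputs the two can
  differ at region boundaries.
* "Present in a genotype" is membership in that genotype's
  tumor-vs-control DMR list after the transformation filter; whether
  the filter should apply before or after per-genotype counting is
  ambiguous in the source procedure, and dmrscape filters before
  mechanism classification only.
* No FDR control, no smoothing, no non-CpG methylation, no gene-body
  methylation model.
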