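---
title: "Survival-index analysis of simulated Tn-seq selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-index analysis of simulated Tn-seq selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The screen this package models

A mariner-class transposon (such as magellan6x) inserts exclusively at TA
dinucleotides, so the candidate insertion sites of a genome are enumerable
from its sequence alone. A saturated insertion library -- on the order of
10^5 unique clones, covering well over half of all TA sites -- is exposed
for a fixed time to a bactericidal agent alongside an untreated (carrier
protein) control. Clones whose disrupted gene normally *contributes to*
killing survive the treatment disproportionately and are enriched; clones
whose disrupted gene *protects* the cell are depleted. Sequencing the
transposon--chromosome junctions before aggregating read counts by gene
turns that enrichment into a per-gene statistic:

* **Dval** -- the feature's actual read count divided by its
  length-expected read count (`total reads x feature length / genome
  length`). Dval = 1 means the feature holds exactly its
  length-proportional share of the library.
* **SI (survival index)** -- Dval in the treated library divided by Dval
  in the control library. SI = 1 is neutral; SI > 1 marks a resistant
  mutant (the gene product enhances killing); SI < 1 marks a sensitive
  mutant (the gene product protects).

`tnscreen` implements the full desk-scale loop: a genome coordinate frame
(TA sites plus a tiling catalog of genes and constructed intergenic
regions), a generative simulator of the library and the selection
experiment with known ground truth, read processing from FASTQ back to
per-site counts, and the Dval/SI statistics with replicate significance
testing.

## The generative model

The simulator is a standard hierarchical counting model; the experiment
itself specifies only the marginal rates (survival fractions, growth, and
colony numbers), so the noise model is this package's choice:

1. **Library** (`simulateLibrary`): each TA site independently carries a
   clone with probability `saturation` (default 0.63); orientation is
   uniform over the two transposon directions; initial abundances are
   log-normal with sigma = 0.5 on the natural log around a common mean
   (default 200 cells per clone -- dense enough that selection noise, not
   inoculum sampling, dominates).
2. **Selection** (`simulateSelection`): clone i's expected abundance is
   multiplied by the arm's factor -- x20 growth for the control, or
   baseline survival (0.17 sub-bactericidal, 0.005 bactericidal) times the
   clone's feature-level resistance multiplier for treated arms -- and the
   realized abundance is an independent Poisson draw. A multiplier that
   would push survival above certainty is clipped to 1 with a warning.
3. **Bottleneck** (`simulateBottleneck`): plating and scraping a limited
   number of colonies (defaults 100,000 / 8,000 / 230 for control /
   sub-bactericidal / bactericidal) is a multinomial sample over clones;
   clones drawn zero times are lost. This is the dominant noise source in
   the bactericidal arm.
4. **Sequencing** (`generateReads`): reads are multinomial over clones in
   proportion to abundance. Each read is a fixed-length group barcode
   followed by a genomic tag anchored at the insertion's TA: for a (+)
   clone at TA position p the tag is `genome[p, p + tagLength)`; for a (-)
   clone it is the reverse complement of `genome[p + 2 - tagLength, p + 2)`.
   Every tag therefore begins with TA. The default tag length of 16 bp
   reflects the short genomic fragments that type-IIS (MmeI-class)
   junction chemistry yields; the chemistry itself (digestion, adaptors,
   gel band) is deliberately not modeled, because the tag already carries
   all the information the protocol recovers: the site and the
   orientation. Per-base substitution errors are available
   (`readErrorRate`, default 0); indels, PCR duplicates and insertion-site
   bias beyond the TA requirement are not modeled.

All coordinates are 0-based and half-open; a TA site is identified by the
position of its T, and an insertion belongs to the feature containing that
T (a single-base rule that avoids double assignment at feature
boundaries). One barcode identifies each experimental group, as in
group-pooled sequencing designs; biological replicates live in separate
FASTQ files.

## Read processing

Demultiplexing (`demultiplex`) assigns a read to the unique barcode within
`maxMismatches` (default 1) Hamming distance; the bundled barcodes are at
pairwise distance 6, so assignment is unambiguous. Tag mapping
(`mapTags`) is an exact lookup against a precomputed index of every
TA-anchored tag in the genome (`buildTagIndex`), in both orientations.
This replaces seed-and-extend alignment deliberately: at desk scale an
exact TA-anchored search is complete (a 16-bp tag over a 10^5-bp genome
collides with probability ~10^-2 per library, and collisions are flagged,
never silently resolved). The cost of exactness is that an erroneous read
is discarded rather than rescued -- a documented divergence from aligner
behavior; ambiguous and unmapped reads are always reported in the stage
log, and conservation (assigned + rejected = total; unique + ambiguous +
unmapped = assigned) is asserted by the pipeline.

## Statistics

For each replicate pair, per-feature Dvals are formed in both samples and
divided (treated / control) to give one SI per replicate. Choices the
experiment's description leaves open, and how this package resolves them:

* **Pseudocount (default 0.5 reads)**, added to both actual and predicted
  reads in the Dval used for SI: the bactericidal bottleneck (230
  colonies) routinely empties features in the treated sample, and the
  pseudocount keeps their SI defined (near 0, classified sensitive)
  instead of undefined. Raw Dvals (pseudocount 0) are reported alongside.
  With pseudocount 0 the length-weighted mean Dval is exactly 1 on every
  sample -- an identity the test suite asserts to 1e-9 -- and Dvals are
  invariant to uniform depth scaling.
* **Replicate combination**: SI is computed per replicate and combined as
  the geometric mean. Significance is a two-tailed one-sample t-test of
  ln(SI) against 0 across replicates -- the paired-test equivalent on the
  log scale, which symmetrizes the ratio. Zero-variance cases are flagged
  degenerate (p below machine resolution with a nonzero mean; p = 1
  otherwise) rather than erroring.
* **Minimum-site filter**: features need at least 3 distinct insertion
  sites for a reliable frequency-change call. n_sites is the union of
  positions observed in any sample of the comparison -- the control arm,
  with its generous bottleneck, is the closest observable to the library
  itself.
* **Multiple testing**: the hit call uses the raw P <= 0.05 cut, matching
  the screen design this models; BH q-values are reported alongside for
  modern practice but do not gate the call.
* **Overlapping gene annotations** (annotation dialects disagree here):
  the later-starting gene is truncated to begin at the earlier gene's
  end, and genes fully contained in another are dropped with a warning.
  This preserves the tiling partition on which the conservation of total
  predicted reads -- and hence the Dval identities above -- depends.

## What the simulator establishes (and what it cannot)

Because ground truth is known, the test suite can close loops that real
data cannot: error-free reads round-trip *exactly* to the simulator's
per-clone draws; a neutral feature has SI = 1 identically; across 500
all-neutral screens 3-7% of features reach p <= 0.05 (the t-test is
calibrated); five planted resistant features (multiplier 30) in a
300-feature screen under bactericidal conditions are recovered in the
ranked hit list in >= 95% of seeded runs; and the Monte-Carlo mean SI of a
rare resistant class matches the closed form m / (1 + f (m - 1)).

Problem sizes are the package's own desk-scale choices: 100-kb random
genomes (~6,250 TA sites) for saturation recovery, 30-kb / 50-feature
screens at 30,000 reads per sample for null calibration, and 200-kb /
300-feature screens for planted-hit recovery. Null calibration runs the
sub-bactericidal arm (survival 0.17, bottleneck 8,000) against the
control, where per-feature counts are large enough for the log-ratio
t-test's normality assumption; the bactericidal arm's 230-colony
bottleneck is exercised by the recovery property instead, where the
planted effect dwarfs the extra noise.

Passing these tests shows the pipeline is a faithful implementation of
the model above -- it does not show that real libraries obey the model.
Real data add insertion-site bias, PCR duplication, hot spots and gaps,
operon polarity, and reference/strain mismatches, none of which the
generator emulates. Results on real screens should therefore lean on the
reported diagnostics (ambiguous/unmapped fractions, n_sites, per-sample
Dval distributions) rather than on the simulator's guarantees.

## A worked toy screen

```{r toy}
library(tnscreen)
dir <- tempfile("toy")
toy <- makeToyScreen(dir, seed = 1)
toy$planted
```

```{r run, warning = FALSE, message = FALSE}
res <- runScreenPipeline(toy$config, file.path(dir, "out"))
head(res$hits$bactericidal[, c("feature_id", "n_sites", "mean_si", "p_value")])
```

The three planted resistant genes surface as the top-ranked SI hits; the
run directory contains the per-replicate FASTQ files, site-count tables,
fitness tables, hit lists, a JSON-lines event log with per-stage read
conservation counts, and a manifest that reproduces the run byte-for-byte
under the same seed.

## Limitations

Single circularity-free chromosome; no per-site (sub-gene) fitness
estimation or essentiality HMM; single-endpoint selection only; exact tag
matching tolerates no sequencing error in the tag itself. The survival
fractions act at the feature level -- intergenic insertions default to
neutral -- so polar effects on downstream genes are out of scope.
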