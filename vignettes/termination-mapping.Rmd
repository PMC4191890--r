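---
title: "Mapping Pol II termination regions from depletion occupancy tracks"
author: "termscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Pol II termination regions from depletion occupancy tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termscan)
```

## The problem

Budding-yeast RNA polymerase II terminates coding transcripts through the
cleavage-and-polyadenylation (pA) pathway and non-coding transcripts
(snoRNAs, CUTs) through the Nrd1–Nab3–Sen1 (NNS) pathway. Where exactly
polymerase leaves the template is hard to see in steady-state RNA because
turnover erases the evidence. Strand-specific maps of polymerase occupancy
itself (e.g. PAR-CLIP of a Pol II subunit), measured with and without
acute nuclear depletion of a termination factor, make termination visible:
at a functional terminator, depletion shifts occupancy from upstream of
the release point to downstream of it.

`termscan` implements that comparison as a reproducible pipeline:

1. **Coverage**: per-base, strand-specific occupancy tracks, normalized to
   $10^7$ aligned reads (`build_track()`), with bedGraph/fixed-step wiggle
   I/O.
2. **Readthrough Index scan**: at every genomic position $p$ on each
   strand, occupancy is summed in 500-bp windows upstream ($U$) and
   downstream ($D$) of $p$ and the readthrough fraction $f = D/(U+D)$
   computed per condition. The Readthrough Index is
   $\mathrm{RI}(p) = f_\text{depleted}(p) - f_\text{control}(p)$.
   Positions pass when $\mathrm{RI} > 0.10$, at least 1000 summed units
   fall in either sample, and the depleted total exceeds the control
   total (`global_scan()`); passing points are thinned to non-overlapping
   candidates 1 kb apart (`select_candidates()`).
3. **Termination point**: around each candidate, the per-base difference
   $\Delta(x) = \text{control} - \text{depleted}$ over ±1 kb is smoothed
   with a 25-nt moving average, fitted with a cubic smoothing spline, and
   the positive-to-negative zero crossing with the largest flanking
   amplitude (mean of $\Delta$ over 100 nt upstream minus 100 nt
   downstream) is reported as the termination point — the center of a
   ~50-nt release region (`locate_termination()`, `refine_all()`).
4. **pA anchors**: polyadenylation sites with ≥ 200 raw reads are
   clustered at 200 bp (same strand only); a cluster with a clear
   dominant site (second/first read ratio < 0.4) contributes its dominant
   site, an ambiguous cluster is discarded; the top 500 survivors by read
   count are the metagene anchors (`select_top_pa()`).
5. **Metagenes and rankings**: anchor-centered occupancy averaged in
   10-bp bins, transcription-oriented (`anchor_matrix()`), and
   per-terminator percent readthrough
   $100 \times \mathrm{RI}$ ranked descending
   (`percent_readthrough_ranking()`).
6. **Terminator sequence**: RNA-sense 150-nt windows 5′ of each
   termination point, scanned for NNS-pathway motifs (Nrd1 site
   `GUA[AG]`, Nab3 site `UCUU(G)`) with overlapping matches counted,
   maximal U-run statistics in ±50 nt of the termination point, and
   empirical enrichment against dinucleotide-preserving shuffles
   (`motif_enrichment()`).

## Sign and coordinate conventions

Public coordinates are 0-based; intervals are half-open as in BED.
Wiggle I/O converts to that format's 1-based convention. On the plus
strand the downstream window includes the focal position
(`[p, p+500)` vs `[p-500, p)`); minus-strand windows are the exact
mirror, so mirroring the genome maps every readthrough point onto its
mirror image with an identical index.

The difference profile is fixed as **control minus depleted**, so a
terminator shows positive differences upstream (the pause that depletion
eliminates) and negative differences downstream (the readthrough that
depletion creates); the termination point is the downward zero crossing.
Sub-nucleotide crossings are rounded to the nearest base, ties toward the
upstream side. Candidates with no qualifying crossing (positive upstream
mean and negative downstream mean) are dropped and logged, never
force-assigned.

## The synthetic study and what it emulates

Real depletion libraries are not available at desk scale, so the package
ships a generator that emulates the occupancy structure the analysis
assumes, with known ground truth. Expected occupancy at a transcription
unit is:

* a uniform gene-body plateau of `body_rate` events/base on
  `[tss, term_point]` (default 5, chosen so a 500-bp window sums to
  ~2500 units and the 1000-unit filter is a real filter);
* a Gaussian **pause bump** (amplitude `pause_amp` × body, default 2;
  σ = 25 nt) centered `pause_offset = 3σ` nt upstream of the termination
  point. Polymerase pauses before it releases, so the bump belongs
  upstream of the release point; centering it exactly at the release
  point would smear pause mass into the downstream windows and bias the
  zero crossing downstream;
* a short exponential release tail past the termination point
  (`decay_tau_control` = 15 nt) in the control;
* under depletion of a factor targeting the locus class, a fraction
  `readthrough_alpha` (default 0.5) of polymerases fails to terminate
  and sustains the body rate over `readthrough_len`, while the remaining
  `1 − alpha` still terminate with the control tail:
  $r_\text{depl}(d) = \alpha\,\lambda + (1-\alpha)\,\lambda e^{-d/\tau}$
  for $0 < d \le \mathrm{RL}$. This mixture (rather than a flat
  $\alpha\lambda$) keeps the depleted-minus-control metagene
  non-negative at every downstream distance, which is the observable the
  real experiment shows: depletion adds polymerase downstream, it does
  not remove it.

Per-base counts are independent Poisson draws from this rate; one seeded
generator per call makes every simulator byte-reproducible. No
autocorrelated noise, crosslinking biochemistry (T→C conversions),
exosome dynamics or replicate structure is modeled — passing tests
demonstrate that the algorithms recover planted structure under Poisson
sampling noise, not that they are robust to every artifact of real
libraries.

Factor classes differ only in which loci respond and how far:

| preset | targets | readthrough_len | pause bump under depletion |
|--------|---------|-----------------|----------------------------|
| Nrd1 | snoRNA, CUT, antisense CUT | 1500 nt (processive) | eliminated |
| Sen1 | snoRNA, CUT, antisense CUT | 250 nt (short) | eliminated |
| Ysh1 | mRNA (pA sites) | 150 nt (confined) | retained, plus a pileup bump 50 nt downstream of the pA site |

The default study design is 12 chromosomes × 100 kb carrying 32 loci
(12 mRNA, 10 snoRNA, 8 CUT, 2 antisense CUT — 20 non-pA terminators),
same-strand loci ≥ 2 kb apart so 500-bp windows of distinct terminators
never mix, and every locus ≥ 1 kb from a chromosome end. Simulated
genomes are AT-rich intergenically (GC 0.32 vs 0.40 genic) with planted
`GUAA`/`UCUUG` motifs in the 150 nt upstream of NNS termination points
and 5-nt U-runs within ±50 nt of them.

## Numerical choices

* **Spline refinement**: the "spline over a 25-bp window" is
  operationalized as 25-nt moving-average pre-smoothing followed by
  `stats::smooth.spline()` with generalized cross-validation. On a
  noiseless antisymmetric ramp the crossing is recovered exactly; under
  the default Poisson noise, 20 planted Nrd1-type terminators are
  recovered within ±25 nt in ≥ 90% of seeds (the test suite runs 30
  seeds of the full scan→select→refine path).
* **Window boundary**: downstream includes the focal base, upstream
  excludes it, so the two windows partition a 1-kb span.
* **1000-unit filter**: applied to the summed *normalized* track values
  by default (the tracks this scan consumes are normalized); raw-count
  behavior is obtained by building tracks with `normalization factor 1`.
* **Ambiguous pA clusters**: ratio ≥ 0.4 drops the cluster (no
  unambiguous 3′ end to anchor on); `ambiguous_action = "keep_dominant"`
  selects the opposite reading. Note the selector is deliberately *not*
  monotone in `min_reads`: raising the cutoff can remove a competitor
  and rescue a previously ambiguous cluster — a property of the
  clustering rule itself.
* **Shuffle null**: motif enrichment uses the Altschul–Erickson
  Eulerian-path shuffle, preserving dinucleotide counts exactly, because
  terminator-proximal sequence is AT-rich and a mononucleotide null
  would overstate U-containing motifs.
* **Degenerate inputs**: all-zero windows give missing fractions, never
  0/0; flat difference profiles give no termination site; empty
  candidate lists propagate as empty outputs.

## Scale of the shipped checks

The test suite and acceptance checks run the full default design
(12 × 100 kb, 30 seeds for recovery, 50 seeds for the rate-integral
check, 5 seeds × 3 factor classes for the metagene phenomenology); the
whole pipeline completes in seconds per seed on one CPU, well inside the
five-minute envelope the design targets.

## Worked example

```{r example}
cfg <- run_config(out_dir = file.path(tempdir(), "demo"), seed = 1,
                  simulate = list(n_chrom = 3L),
                  motifs = list(n_shuffles = 100L))
res <- run_pipeline(cfg, quiet = TRUE)
head(res$sites)
res$enrichment
```

`res$sites$pos` are the refined termination points;
`crossing_amplitude` is the pause-minus-readthrough contrast each one is
supported by. `res$enrichment` gives the shuffle-based p-values for the
Nrd1 and Nab3 motifs in the 150-nt upstream windows.

## Limitations

* The generator's independence assumption understates the local
  autocorrelation of real crosslinking libraries; recovery tolerances on
  real data will be wider.
* The scan reports *depletion-responsive* terminators only; a terminator
  fully redundant between pathways never passes the index filter.
* De novo motif discovery is out of scope; the sequence module scans
  known NNS motifs and quantifies them against a shuffle null.
* Multi-crossing segmentation of polycistronic difference profiles is
  not attempted: each candidate yields at most one termination point.
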