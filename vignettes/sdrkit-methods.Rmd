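---
title: "sdrkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sdrkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrkit)
```

This vignette is the package's own account of the methods it implements:
what each stage computes, what it assumes, which tunable parameters matter,
what the synthetic-data generators do and do not emulate, and where the
design was genuinely open.

## 1. Self-coverage multiplicity and allele divergence

### Model

When an assembly is aligned against itself, every base is covered at least
once by the trivial full-length self-hit. In an assembly where a region's
two haplotypes were kept as separate contigs, each haplotype copy addition-
ally receives an alignment from its partner, so its bases are covered twice.
The diagnostic statistic is the multiplicity profile: the fraction
$f_k$ of bases covered exactly $k$ times by filtered hits, with $k \ge 5$
pooled into one class. If a fraction $d$ of the haploid sequence is present
in two copies, the emitted assembly has size $(1+d)G$ and

$$f_2 = \frac{2d}{1+d}, \qquad f_1 = \frac{1-d}{1+d}$$

(for $d = 0.45$: $f_2 \approx 0.62$ of emitted bases). Internal repeats
push mass into $f_{3+}$; real genomes also have $f_{5+}$ mass from
high-copy families.

### Decisions

* **The diagonal self-hit is counted.** Unique sequence therefore has
  multiplicity 1, which is the convention under which a haplotype-merged
  genome is reported as mostly "covered once". A hit is diagonal iff query
  and subject ids, intervals and orientation all coincide.
* **Query-side counting only.** All-vs-all self-alignment emits both
  directions of every pair, so subject-side coverage of one record is the
  query-side coverage of its reciprocal; counting query intervals once
  avoids double-counting.
* **Filters are strict inequalities** (length > 300 bp, identity > 75%,
  bitscore > 1000), applied before any counting.
* **Divergence over off-diagonal records.** Mismatches/kb and gaps/kb are
  ratios of summed counts to summed alignment length, and identity is
  length-weighted; each reciprocal direction is a distinct record and
  counts once — consistent numerator and denominator. When the input
  table lacks a total-gaps column (the standard 12-column dialect), gap
  opens are used as a lower bound and a warning is raised; exact gaps/kb
  needs the 13-column dialect.
* **Implementation.** Multiplicity is computed by an endpoint sweep over
  interval breakpoints (piecewise-constant multiplicity between
  breakpoints), not per-base arrays; the test suite proves exact agreement
  with per-base counting on random instances.

## 2. SDR haplotyping

### Procedure

Marker sequences are aligned to the assembly and the hit table is chained:
hits of one marker on the same contig and strand are merged while the
contig-coordinate gap stays within `chain_gap`. A contig is an SDR carrier
when its best `SDR` cluster covers at least `min_query_fraction` of the
reference SDR query. A located SDR is **Y** iff at least one
`ARR17_repeat` cluster overlaps the SDR interval extended by `flank`;
**X** iff none does. Inverted repeats are pairs of opposite-strand repeat
clusters within `max_span` whose spacer contains a `HEMA` cluster; MSL is
complete/partial/absent by query coverage.

### Parameters

| parameter | default | why |
|---|---|---|
| `chain_gap` | 20 kb | the SDR is ~120 kb with long variable intergenic stretches; chaining must jump them |
| `min_query_fraction` | 0.5 | half the reference SDR query must be accounted for before a contig is called a carrier |
| `flank` | 50 kb | repeat clusters can sit at the edge of, or just outside, the aligned SDR interval |
| `max_span` | 10 kb | inverted-repeat arms plus spacer span a few kb in poplars |
| `complete_fraction` | 0.9 | an MSL call is "complete" only with ≥ 90% query coverage |

None of these thresholds has a canonical published value; all are exposed
in the configuration. Enlarging `flank` is monotone: it can only add Y
evidence, never turn Y into X (a property the tests assert). A contig with
two separated SDR clusters is emitted as two flagged calls rather than
merged, so putative chimeras stay visible.

## 3. VAF clustering

### Model

For a panel of samples jointly called over a region at ploidy 4, the
variant allele fraction $v = AO/DP$ at a site concentrates near the dosage
states $\{0, \tfrac14, \tfrac12, \tfrac34, 1\}$. Samples sharing ancestry
over the region share VAF profiles; the analysis is purely geometric:
Euclidean distances over shared well-covered sites, Ward.D2 agglomeration,
classical MDS for visualisation.

### Decisions

* **Masking, not imputation.** Entries with depth < `min_depth` (default
  5 reads) or a missing genotype are excluded; a site contributes to a
  pair's distance only when unmasked in both samples (pairwise deletion).
  Distances are *not* rescaled by shared-site counts by default — the raw
  Euclidean distance is the quantity of record — but
  `pairwise_distance(..., rescale = TRUE)` multiplies by
  $\sqrt{n_{\text{total}}/n_{\text{shared}}}$ for severely unequal panels.
  A pair with zero shared sites is an error by default (`on_empty = "na"`
  propagates NA instead).
* **One row per (site, alt allele).** Multi-allelic records contribute one
  VAF row per alternate allele rather than being collapsed.
* **Ward.D2 via `stats::hclust`.** The linkage the package exposes is
  exactly R's `ward.D2`: Lance–Williams updates on squared distances with
  heights reported on the distance scale, hence nondecreasing. The test
  suite verifies every merge against an exhaustive minimum-variance oracle
  computed from raw coordinates for $n \le 7$. Tie-breaking on exactly
  equal merge costs follows `hclust`; partitions on generic (continuous)
  data are unaffected.
* **Classical (Torgerson) MDS via `stats::cmdscale`**, i.e.
  double-centring of the squared distances and eigendecomposition.
  Masked distance matrices are generally non-Euclidean; negative
  eigenvalues are dropped with a warning, eigenvalues that are zero up to
  round-off ($\le 10^{-12}$ of the spectral radius) have their coordinate
  columns truncated to exact zeros, and coordinates are zero-padded when
  fewer than `k` positive eigenvalues exist.
* **Newick export** writes branch lengths as merge-height differences, so
  leaves sit at the height of their first merge — the usual dendrogram
  geometry; two leaves merged at height 3 export as `(a:3,b:3);`.

## 4. Depth-anomaly repeat discovery

Reads from a multi-copy family mapped to a single-copy reference pile up
on the one represented copy. Detection tiles non-overlapping `window`
(100 bp) windows, flags window means at or above
`fold_threshold` (10) × background, merges flagged runs separated by at
most `merge_gap` (500 bp), and drops loci under `min_locus_len` (1 kb).
The background is the **median** depth of the analysed track — robust to
the loci themselves provided they cover well under half the track (a
documented limitation: on a track dominated by one huge locus the median
inflates and detection weakens). Segmentation relabels windows inside a
locus as `low` below `low_fold` (3) × background and merges same-label
runs, giving the uniformly-high vs mosaic decomposition; boundaries are
accurate to one window by construction. Copy counting merges genuinely
overlapping (≥ 1 bp) subject intervals per subject sequence — abutting
intervals stay separate — making the count invariant to hit order and to
splitting a hit into overlapping sub-hits.

The ORF scanner reports, in each of six frames, the most-upstream ATG to
the next in-frame stop (one ORF per stop), at or above `min_aa` (100);
codons containing N never match ATG or a stop, and reverse-strand ORFs are
mapped back to forward coordinates. Requiring ATG means 5'-partial ORFs
are not reported, so counts can differ from annotation tools that emit
partial ORFs. "Upstream" in the proximity annotation is 5' of the gene
start on the gene's strand, with the gap measured between interval ends;
the default window is 15–40 kb and repeat adjacency uses a 10 kb gap.

## 5. The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed, not tuned.

* **Diploid assembly** (`gen_diploid_assembly`): `dup_fraction = 0.45` of
  the haploid sequence re-emitted as second-haplotype contigs carrying
  `mismatch_rate = 130` substitutions and `indel_rate = 31` gap columns
  per kb (geometric indel lengths, mean 3 bp) — the observed degree of
  haplotype separation and allele divergence in the motivating assemblies.
  The desk-scale default genome is 1 Mb in 20 contigs; that size keeps the
  full validation suite in minutes while leaving per-seed sampling error
  of the divergence rates under ~5%.
* **Self-alignment tables are generated from the planted truth**, not by
  running an aligner: the downstream modules are thereby tested for
  interval arithmetic and accounting, not for alignment heuristics. A
  naive exact-substring verifier (`verify_exact_hits`) checks the
  zero-divergence corner on small fixtures.
* **SDR contigs** (`gen_sdr_contig` / `gen_sdr_panel`): an ordered
  LRR–MET1–CLC–TCP block shared by Y and X; Y additionally carries ARR17
  partial repeats (including one inverted pair around a HEMA block), a PSR
  copy and a partial MSL block. Marker hits again derive from truth.
* **VAF panels** (`gen_vaf_vcf`): group profiles drawn on the quarter
  states; a planted fraction of sites is redrawn independently per group
  so that the expected per-site state difference equals
  `group_divergence` (two independent uniform draws over the five states
  differ by 0.4 on average, so the divergent-site fraction is
  `group_divergence / 0.4`). Depths are Poisson(`mean_depth`) with
  probability `dropout_prob` of being redrawn below the 5-read mask;
  allele observations are Binomial(depth, state). Defaults (3 groups × 23
  samples, 300 sites, depth 30, dropout 0.1) emulate a ~70-sample
  resequencing panel of mixed coverage. With noise disabled, depths are
  rounded up to multiples of 4 so quarter states yield exact VAFs.
* **Depth tracks** (`gen_depth_track`): background plus planted
  `fold`-scaled loci, Gaussian noise everywhere, clipped at zero and
  rounded.
* **ORF loci** (`gen_orf_locus`): planted ORFs on alternating strands
  separated by filler interleaved with a 12-mer carrying stop codons in
  all six frames, which bounds any unplanned ORF well below the 100-aa
  threshold in the filler; reverse-frame accidents inside planted ORFs are
  removed by bounded rejection, so the construction is validated to
  contain exactly the planted set. The planted coordinates remain an
  independent check on the scanner.

What the generators do **not** emulate: sequencing-error models and read
mapping (depth and VAF are drawn directly), repeat-family sequence
structure (hits derive from truth), reference bias, linked selection or
recombination gradients along the SDR. Passing the synthetic recovery
tests therefore demonstrates the correctness of the implemented
procedures under their stated models, not robustness to every artefact of
real resequencing data.

## 6. Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout; BED output is the only
  0-based half-open surface, and bedgraph input is converted on read.
  Minus strand in hit tables is encoded by swapped subject coordinates and
  normalised on parse.
* Multiplicity fractions partition to 1 within $10^{-9}$ per sequence and
  genome-wide; genome-wide fractions are length-weighted means.
* A divergence summary with no off-diagonal records reports zero total
  length and NA rates with a `rates_defined = FALSE` flag rather than
  silently returning 0/0.
* All generator randomness flows through one seeded RNG per call (the
  caller's RNG state is restored), so equal seeds give byte-identical
  artifacts; the pipeline writers use fixed field formatting for the same
  reason.
* Validation problem sizes: 1 Mb assemblies, 100-contig SDR panels across
  20 seeds, 15–69-sample VAF panels over 200–300 sites, 30–120 kb depth
  tracks. These sizes were chosen so the complete suite runs on a laptop
  in a few minutes while keeping every stochastic recovery criterion
  comfortably inside its tolerance.

## 7. Known limitations

* Divergence statistics are computed over all off-diagonal filtered hits;
  whether to restrict to 2×-covered regions or to inter-contig hits
  (`inter_contig_only = TRUE`) is left to the caller, and the two choices
  differ on assemblies with abundant internal repeats.
* The multiplicity convention counts query bases only; a symmetrised
  variant would differ on asymmetric hit tables (e.g. truncated aligner
  output).
* `detect_high_coverage_loci` assumes the track is mostly background (see
  the median caveat above) and has no notion of statistical significance —
  thresholding stands in for an enrichment test, which the motivating
  analysis did not specify either.
* The ORF scanner's ATG requirement undercounts relative to tools that
  report 5'-partial ORFs.
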