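---
title: "Testing R-loop / ORC1 / origin co-localization at CpG island promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing R-loop / ORC1 / origin co-localization at CpG island promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopcoloc)
```

## The question and the counting unit

CpG island promoters are the most efficient and most conserved replication
initiation sites in mammalian genomes. Many of them are also prone to
co-transcriptional R-loop formation: when the non-template strand carries
an excess of G over C (positive GC skew), the nascent G-rich transcript can
re-anneal to the template and displace the non-template strand. The
displaced single strand can fold G-quadruplexes (G4), and ORC1 — the
largest subunit of the origin recognition complex — binds G4 structures on
single-stranded nucleic acids far better than on duplex DNA. If that chain
of events operates in vivo, R-loop-forming islands should carry ORC1
binding and origin activity more often than chance predicts, in the same
sub-island position as the G4/skew signal.

`rloopcoloc` makes that test concrete. The counting unit everywhere is the
**promoter/CpG-island**, not the peak: a promoter is "DRIP-positive" if at
least one (fold-enrichment-filtered) DRIP peak intersects its island,
however many peaks land there. This avoids double-counting islands that are
fragmented into several peaks by the restriction digest that DRIP-seq
resolution depends on. Two association geometries are exposed and reported:
`cgi_overlap` (≥ 1 bp overlap with the island; the default, since overlap
claims are naturally made at island resolution) and `upstream_window`
(overlap with the oriented `[TSS − u, TSS)` window, default `u` = 1000 bp,
for "binding just upstream of the TSS").

## The statistic and its null models

For a query set $Q$ of promoters (say, the $n_q$ DRIP-positive islands) and
a target indicator $T$ (say, ORC1 positivity), the observed statistic is
the fraction $\hat f = |Q \cap T| / n_q$. "Expected by chance" is only
meaningful relative to a declared null, and published overlap statements
frequently leave the null implicit. This package makes it explicit and
dual:

* **Label permutation** (primary): each of $N$ permutations draws $n_q$
  promoters uniformly without replacement from the universe and records
  their target-positive fraction. The expectation is the marginal
  target-positive rate; the null conditions on the *realized* target
  labels, so systematic enrichment of the target at promoters as a class
  does not inflate significance.
* **Genomic shuffling** (sensitivity): each round re-places every target
  peak uniformly at random on its own chromosome (length-preserving,
  avoiding optional excluded regions, rejection sampling) and re-runs the
  association. This null only preserves peak number and lengths; the gap
  between the two nulls measures how much of the target's promoter
  affinity the permutation null absorbs.

The empirical p-value uses the add-one estimator
$p = (1 + \#\{f^{null} \ge \hat f\})/(N + 1)$, which is never 0, is valid
(slightly conservative) under the null, and has floor $1/(N+1)$ — at the
default $N = 1000$, "p ≤ 0.001" is the strongest attainable statement.
Fold enrichment $\hat f / \bar f^{null}$ is reported as missing when the
null mean is 0 rather than as infinity. The acceptance suite verifies
calibration directly: under a no-association world (universe 1000, target
rate 0.20, query 100, $N = 2000$), p-values over 200 replicates are
uniform by Kolmogorov–Smirnov and type-I error at $\alpha = 0.05$ sits in
the binomial band $[0.02, 0.09]$.

## Sequence signals

**G4 motifs.** The scanner implements the classical Quadparser pattern
literally: `n_tracts` = 4 tracts of exactly `tract_len` = 3 guanines with
loops of `loop_min` = 1 to `loop_max` = 7 nt between consecutive tracts.
Quadparser variants differ in how they treat runs of ≥ 4 Gs; here a tract
is an exactly-3 window that may sit inside a longer run, with the leftmost
feasible placement chosen — the choice is explicit and configurable rather
than buried in a regex. Loops are length-only constraints (any base,
including N; N never matches a tract). Two reporting policies exist:
`greedy_nonoverlapping` (leftmost-first, each motif starting after the
previous one's end — the common Quadparser behaviour, and the default) and
`all` (every admissible tract combination; the form the brute-force test
oracle enumerates). Minus-strand motifs (`CCC` tracts on the forward
strand) are found by scanning the reverse complement and mapping
coordinates back. For the greedy policy this is *not* the same as scanning
`CCC` left-to-right on the forward strand; the reverse-complement
definition was chosen because it is the one under which
reverse-complementing a sequence exactly swaps + and − motifs — an
invariant the test suite checks on every random instance.

**GC skew.** Skew is $(G - C)/(G + C)$ on the forward strand of sliding
windows (default 100 bp window, 50 bp step — ≥ 10 windows across the ~1 kb
promoter footprint of interest), missing where $G + C = 0$. Region calling
is a deliberately simple thresholded run-length rule (≥ `min_run`
consecutive windows at skew ≥ `threshold`), replacing HMM-based skew
segmentation: in this pipeline skew is an annotation on promoters, not an
inference target, and the simple rule is transparent and testable (a
planted 1 kb G-biased segment must be recovered at Jaccard ≥ 0.5).
Promoter flagging (`flag_gc_skew`) measures the mean windowed skew of the
non-template strand over the 1 kb *downstream* of the TSS — forward strand
for `+` genes, reverse complement for `-` genes — with a default threshold
of 0.1.

## Composite profiles

Profiles answer "where, relative to the TSS, does the signal sit?". For
each anchor (oriented TSS), every base covered by a hit within ±3000 bp
(the conventional 6 kb span) increments the count at its offset;
minus-strand windows are reflected so upstream is always leftward. Counts
are divided by the number of anchors actually covering each offset
(windows truncated at chromosome ends contribute to neither numerator nor
denominator there) and then by the genome-wide hit density, so a uniformly
scattered hit set has expected value 1 at every offset. "Hits per base"
is interpreted as per-base coverage, counted with multiplicity, and the
normalizer is hit-covered bases per genome base — the numerator and
denominator use the same convention, which is what makes the uniform
expectation exactly 1; a midpoint-counting mode (one base per hit,
normalized by hits per genome base) is provided as an alternative. For G4
profiles, `strand_mode` selects motifs on the anchor gene's own strand
(`nontemplate` — the displaced strand where single-stranded G4s would
form), the opposite strand (`template`), or `both`; under strand filtering
each anchor-strand group is normalized by its own strand's motif density
and combined, so uniformity still profiles at 1. No smoothing is applied
by default; a centered odd-width moving average is available for plotting.

## The synthetic world

The generator emits the world this analysis assumes, with every planted
element recorded: background sequence (GC ≈ 41%), genes placed in evenly
spaced slots on 3 × 2 Mb chromosomes (300 genes), a 1.2 kb CpG island
(GC = 65%, extra CpG dinucleotides) centered on each TSS, and — for the
75% of promoters drawn as skewed — a 1 kb G-biased footprint on the
non-template strand downstream of the TSS (G = 0.34 vs C = 0.14, skew
≈ +0.42). G4 motifs are planted at Poisson rate 2 per promoter at oriented
offsets $\mathcal N(-500, 100)$ bp (clamped into the upstream kb, A/T
loops, non-G flanks, no mutual overlap — so planted coordinates are exact
scanner truth) plus a background rate of 5 motifs/Mb.

Peak labels are drawn per promoter in a chain that preserves configured
marginals: DRIP ~ Bernoulli(0.16), ORC1 with P(ORC1 | DRIP) = 0.30 and a
complementary-stratum rate chosen so the ORC1 marginal is 0.06, SNS with
P(SNS | ORC1) = 0.85 against a 0.35 marginal. Infeasible
conditional/marginal combinations are rejected at configuration time.
Positive labels generate one peak in oriented coordinates upstream of the
TSS (DRIP centered −450 ± 100, length 600; ORC1 −350 ± 80, length 300;
SNS −300 ± 100, length 400) with lognormal fold enrichment (DRIP median
12, so almost all true peaks survive the strict > 5 filter); 150 decoy
peaks per label (25/Mb) with median fold 2.5 are scattered uniformly, of
which ~8% leak through the filter — deliberate, realistic noise. With
`restriction_site` set (e.g. `GATC`), DRIP boundaries snap outward to the
nearest flanking site, emulating restriction-fragment resolution.

Defaults were fixed once from the structure of the emulated analysis:
0.16 ≈ 1571/9864 R-loop-positive islands, 6% as the chance baseline, 30%
as the conditional, 75% skewed. Those published joint counts cannot all be
satisfied simultaneously (an SNS∧ORC1 rate of 1661/9864 ≈ 0.17 is
incompatible with a 6% ORC1 marginal), so the generator prioritizes the
30%-vs-6% contrast; the origin-set size that falls out (~8% of promoters)
is smaller than the published one. What a green test establishes is that
the *procedure* recovers planted structure at realistic scales — not that
real HeLa/Ntera2 data would reproduce any particular number: the generator
has no repeats, no copy-number structure, no mappability artifacts, one
TSS per gene, independent promoters, and uniform decoys.

## Numerical and design choices

* Coordinates are BED-convention 0-based half-open everywhere; book-ended
  intervals (`[0,10)`, `[10,20)`) merge, and share no base in
  intersection. Sorting ties break by `(chrom, start, end, name)`.
* "Greater than fivefold enrichment" is read literally as strictly `> 5`;
  a peak with no score is an error, not a silent pass.
* Unstranded (`.`) peaks match either strand; genes must be stranded and
  unstranded gene records are dropped with a warning.
* TSS–island association: distance 0 means TSS inside the island (the
  conventional "CpG island promoter"); `max_distance` loosens it. Nearest
  island wins; ties go to the leftmost. Merge-then-intersect order for
  peak sets is the caller's choice; readers do not merge implicitly.
* All randomness flows from a single integer seed through derived child
  seeds (kept below $2^{31}$); library code saves and restores the
  caller's RNG state. Identical config + seed reproduces every output
  byte; the run report isolates the timestamp in one field so the rest is
  byte-comparable.
* Degenerate cases: empty peak set filters to empty; a window larger than
  the sequence yields an empty skew track; a saturated target gives p = 1;
  an all-negative target reports expected 0 with missing fold; an
  infeasible shuffle placement errors after bounded retries.

## Limitations

Peak calling, read alignment and HMM skew segmentation are out of scope by
design — the pipeline consumes called peaks. The island-granularity count
discards within-island peak multiplicity. The permutation null treats
promoters as exchangeable (no matching on GC content, island length or
expression), so on real data the reported "expected by chance" should be
read alongside the shuffle null, which makes the opposite trade-off. The
published counts the package is structured around derive from datasets in
two different cell types; nothing here corrects for that, and the package
does not attempt to reproduce them.
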