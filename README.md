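# rloopcoloc

Do R-loops mark replication origins? CpG island promoters are the most
efficient replication initiation sites in mammalian genomes, and many of
them form stable RNA:DNA hybrids (R-loops) when transcribed. `rloopcoloc`
is an R package for asking, quantitatively, whether R-loop-forming regions
(DRIP-seq peaks) co-localize with ORC1 binding sites and short-nascent-
strand (SNS) replication origins at CpG island promoters — and whether
G-quadruplex (G4) motifs and GC skew mark the same ~1 kb footprint around
the transcription start site (TSS).

The package is aimed at regulatory/replication genomicists who have
already-called peak sets in BED format (it does no alignment or peak
calling) and at method developers who want a fully seeded synthetic genome
with recorded ground truth to validate this class of analysis.

## What it computes

* **Interval engine** — BED3–BED6 and FASTA I/O, 0-based half-open
  coordinates throughout, merging, intersection, and a strict `> 5`
  fold-enrichment peak filter.
* **Sequence signals** — Quadparser-style G4 scanning (4 tracts of
  `GGG`/`CCC`, loops of 1–7 nt, greedy non-overlapping or exhaustive
  reporting, exactly strand-symmetric) and windowed GC skew
  `(G − C)/(G + C)` with run-length region calling.
* **Promoter universe** — TSS-associated CpG island promoters (TSS = 5′
  gene end; nearest island wins) with strand-aware GC-skew flagging of the
  1 kb footprint downstream of the TSS.
* **Co-localization statistics** — island-level co-occurrence of a query
  set (e.g. DRIP-positive islands) with a target (e.g. ORC1), with an
  explicit "expected by chance": the primary null permutes promoter labels
  (drawing equal-sized random promoter sets), a sensitivity null re-places
  the target peaks uniformly on the genome (bedtools-shuffle-like). The
  empirical p-value is the add-one estimator
  `(1 + #{null ≥ observed}) / (n_perm + 1)`; fold enrichment is
  observed/expected.
* **Composite profiles** — per-base hit density over a 6 kb TSS-centered,
  strand-oriented window, normalized by genome-wide hit density so a
  uniform hit set profiles at 1.
* **Synthetic data** — a seeded generator producing a toy genome whose CpG
  island promoters carry a G-biased non-template-strand footprint, planted
  upstream G4 motifs, three peak sets with configurable marginal and
  conditional co-positivity probabilities, optional restriction-fragment
  quantization of DRIP peak boundaries, and truth tables for everything.

## Worked example

```r
library(rloopcoloc)

report <- run_all(sim_config(seed = 1), out_dir = "demo",
                  n_perm = 1000, n_shuffle = 100)
```

With the default synthetic world (3 chromosomes x 2 Mb, 300 genes, 16% of
promoters DRIP-positive, ORC1 marginal 6%, P(ORC1 | DRIP) = 30%, 75% of
promoters GC-skewed, 150 decoy peaks per set) this prints, via the report:

```
universe: 300 promoters (237 GC-skewed)
origin set: 24 SNS+ORC1 positive of 300
DRIP-positive islands: 44; ORC1 co-positive: 18 (40.9%)
expected by chance (permutation): 11.6%; fold 3.5; p = 0.000999
expected by chance (shuffle): 4.5%; p = 0.0099
G4 motifs: 649; profile argmax (bp rel. TSS): ORC1 -412, DRIP -557, G4 -620
```

Reading: 18 of the 44 R-loop-positive islands also bind ORC1 — about 3.5×
more than random promoter sets of the same size (11.6%), and far more than
randomly re-placed ORC1 peaks would give (4.5%); at 1000 permutations the
smallest attainable p is 1/1001 ≈ 0.001, which the contrast reaches. All
three composite profiles (ORC1 peaks, DRIP peaks, G4 motifs) peak a few
hundred bp upstream of the TSS, inside the 1 kb skewed-footprint region
where they were planted. The observed 40.9% exceeds the configured 30%
because decoy peaks also hit islands; the permutation "expected" (11.6%)
correspondingly exceeds the 6% configured marginal. The two nulls answer
different questions: label permutation conditions on the realized set of
ORC1-positive promoters, peak shuffling only preserves peak number and
lengths.

Every run writes `report.json` (all parameters, seeds, checksums and
numbers; the timestamp is a single isolated field), the promoter universe,
the origin-set BED and the three profiles into `out_dir`, and identical
config + seed reproduces every byte.

## Command line

An `Rscript` front end is installed under `exec/`:

```sh
rloopcoloc simulate --out-dir sim --seed 1
rloopcoloc annotate --genes sim/genes.bed --cgis sim/cgis.bed --fasta sim/genome.fa --out universe.tsv
rloopcoloc scan-g4  --fasta sim/genome.fa --out g4.bed
rloopcoloc gc-skew  --fasta sim/genome.fa --out-track skew.bedgraph --out-regions skewed.bed
rloopcoloc coloc    --universe universe.tsv --drip sim/drip_peaks.bed \
                    --orc1 sim/orc1_peaks.bed --sns sim/sns_peaks.bed \
                    --fasta sim/genome.fa --null both --seed 1 --out coloc.json
rloopcoloc profile  --hits sim/orc1_peaks.bed --anchors universe.tsv \
                    --fasta sim/genome.fa --out profile.tsv
rloopcoloc run-all  --out-dir run --seed 1
```

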