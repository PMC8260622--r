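---
title: "Methods: 5' UTR design, surrogate modeling and sort-seq screen analysis"
author: "utrdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5' UTR design, surrogate modeling and sort-seq screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`utrdesign` covers the computational arc of a 5' UTR engineering
campaign in mammalian cells: quantify translation efficiency (TE) of
natural transcripts from paired ribosome-profiling (Ribo-seq) and
RNA-seq counts, assemble a fixed-length screening library of natural
and computationally designed 5' UTRs, train a sequence-feature
surrogate that predicts TE and mRNA level, evolve synthetic 5' UTRs
with a genetic algorithm against the surrogate, and analyze a
FACS-bin sort-seq screen of the library down to called hits. A
synthetic-data module generates every input with recorded ground
truth so that each stage, and the pipeline end to end, is testable
without any external data.

# Translation efficiency

TE is defined per transcript as the ratio of ribosome-footprint
abundance to mRNA abundance,

$$\mathrm{TE} = \frac{\mathrm{RPKM}_{\text{Ribo-seq}}}{\mathrm{RPKM}_{\text{RNA-seq}}},
\qquad \mathrm{RPKM} = \frac{\text{count}}{(\text{length}/10^3)\,(\text{library size}/10^6)} .$$

RPKM uses the transcript length (not the UTR length), matching the
per-transcript definition. TE is undefined (`NA`), never 0 or
infinity, when the RNA denominator is zero; no pseudocount enters the
ratio. Instead, transcripts with insufficient coverage in either
assay are discarded before ranking. Published Ribo-seq processing
pipelines rarely state a numeric coverage rule, so the default filter
requires at least 10 raw reads in each assay — a conservative, depth-robust
choice (raw counts rather than RPKM, so shallow libraries do not pass
noise through the filter); both thresholds are configurable.

# Library standardization

The screening library uses a fixed 100-bp diversity region
(compatible with array oligo synthesis; two 20-nt priming/homology
flanks complete a 140-mer oligo). Natural UTRs are standardized as
follows:

* longer than 100 nt: two variants, the 5'-end prefix and the 3'-end
  suffix of length 100;
* shorter than 100 nt: two variants padded at the 5' end with repeats
  of the unstructured CAA motif, the second pad phase-shifted by one
  nucleotide. Padding is placed 5' so the native sequence stays
  adjacent to the Kozak/CDS junction, where its regulatory context
  matters most; both phase variants are emitted and the caller may
  filter. Sequences under 3 nt are rejected rather than padded.

Start codons are removed to avoid creating upstream ORFs: the
sequence is scanned left to right and at each ATG one of its three
nucleotides is mutated to a random different base; a draw that leaves
or re-creates an ATG overlapping the repaired window is rejected and
re-drawn. Each accepted repair removes the leftmost ATG without
introducing one in its window, so the scan terminates with an
ATG-free sequence of unchanged length.

Natural panels are selected by rank: top/bottom TE panels per cell
context (defaults 1505/937 for HEK 293T, 1692/756 for PC3, 1831
top-TE for muscle) and a top-mRNA panel (1693) for muscle tissue,
with ties broken by transcript id for reproducibility. Validated
members can be combined pairwise into 206-nt combinatorial UTRs with
a CAACAA linker; the operation is order-sensitive.

# Sequence features

Features are computed on the UTR concatenated with the first 15 nt of
the CDS (the sequence context around the main start codon), except
`utr_length` and the upstream-ORF counts, which describe the UTR
alone — the CDS context begins with the main ORF's ATG, which is not
an upstream ATG. The feature set:

* **k-mer frequencies** for k in {1, 2, 3} by default (84 features;
  configurable up to k = 6). Frequencies, not counts, so the scale is
  length-invariant; all `4^k` words are present so the schema has
  fixed dimension, and a schema hash guards model/feature
  compatibility.
* **Folding energy**: by default a self-contained maximum-pairing
  interval dynamic program (Watson-Crick plus G-U wobble, minimum
  hairpin loop of 3 unpaired nucleotides) scaled by -1 kcal/mol per
  pair. This is a structure proxy with the right ordering (more
  negative = more structure), not a thermodynamic free energy; a
  thermodynamic engine (`RNAfold`) can be plugged in behind the same
  signature when available. The default keeps the package free of
  mandatory external dependencies and is verified against exhaustive
  structure enumeration for short sequences.
* **Upstream ORFs**: `n_uaug` counts ATG occurrences; `n_uorf` counts
  those followed by an in-frame stop codon entirely inside the
  sequence. The stricter uORF definition (start plus complete stop)
  was chosen because an ATG without an in-frame stop acts as an
  alternative initiation site rather than a complete repressive uORF.

# Surrogate models

Regressors map feature vectors to TE or mRNA level. Four model
classes are supported — random forest, elastic net, a single
regression tree, and an SVM — through the standard R packages for
each. Evaluation is 5-fold cross-validation: rows are shuffled by a
seeded permutation into five non-overlapping test folds, and the
metric is the Spearman correlation (average ranks) between predicted
and actual targets; the reported model is refit on all rows. The
random forest uses 500 trees for deterministic, stable fits.
Targets are log-transformed (`log2(y + 1e-3)`) before regression
because TE and RPKM are strongly right-skewed; predictions are
back-transformed (toggleable). Predicted protein expression is the
product `predict(mRNA) * predict(TE)`.

`compare_models()` shares one fold assignment across model classes so
the comparison reflects the models, not fold luck.

# Genetic-algorithm design

Each design run starts from a seeded sample of 100 standardized
natural 5' UTRs and runs at most 50 generations. Per run the top 5
sequences are kept subject to (i) pairwise Hamming distance of at
least 5 and (ii) fitness at least 0.05 — on the fitness scale used
for that run, predicted TE or predicted expression after any
transform — above the best sequence in the run's initial population.
These population/selection/diversity rules are fixed by the screening
design; the variation operators are not specified there, and were
chosen as follows:

* **Parent selection**: uniform from the 5 fittest individuals
  (truncation selection).
* **Offspring**: 150 per generation; single-point crossover with
  probability 0.5 (a start codon can form at the junction, so repair
  follows), point mutation at 0.01 per nucleotide, and a
  Poisson(0.5) number of segment-shift mutations — remove a base at
  one random position, reinsert it at another, shifting the
  intervening segment. Every offspring ends with AUG repair.
* **Survivor selection**: the fittest 100 distinct sequences among
  parents and offspring (elitist plus-selection), so the
  best-fitness trajectory is non-decreasing by construction.

The segment-shift operator deserves a note. Fitness landscapes over
fixed-length sequences with periodic motif structure have plateau
defects (phase boundaries) that no single point mutation can fix —
any single change breaks as much as it repairs. A shift moves an
entire register by one position and resolves such defects in one
step. On a periodic toy objective (the count of GC/CG dinucleotide
steps, analytic maximum 99 for an alternating 100-mer), selection
schemes without the shift operator stall around 85–90% of the
optimum within the 50-generation budget, while the configuration
above reliably exceeds 90% across seeds; these defaults were fixed by
benchmarking the optimizer on that toy landscape. All operator
settings are configurable.

Fitness values are memoized by sequence, so duplicated offspring cost
nothing to evaluate (important when the fitness function is a model
prediction). A "two-generation" mode — `max_generations = 2`, shift
mutations disabled, relaxed improvement threshold — generates
model-test variants that stay within a small Hamming distance of
their natural seed, mirroring the design of validation sets that
probe a model with near-natural variants.

A run with a constant fitness function keeps nothing: no candidate
can clear the +0.05 improvement rule, which is the intended behavior.

# Screen analysis

Screen reads carry the library's two 20-nt flanks around the 100-nt
insert. Assignment is flank-anchored dictionary matching: locate the
exact left flank, extract the insert, require the right flank, then
match the insert exactly (or, with `max_mismatch = 1`, to the unique
member within Hamming distance 1; ambiguous reads stay unassigned).
For a designed fixed-length library this is exact and self-contained,
replacing a general-purpose aligner; every read is assigned to
exactly one member or counted unassigned.

Counts are normalized by median-of-ratios size factors: the reference
for each member is its geometric mean across samples (members with
any zero count are excluded from the reference set) and a sample's
factor is the median ratio to the reference. Raw counts are never
overwritten; normalized values live in separate tables. Per-bin
enrichment is summarized two ways: a descriptive mean
`log2((n_bin + 0.5) / (n_unsorted + 0.5))` across replicates, and an
inferential negative-binomial Wald test per member:

* per-member dispersion by method of moments on normalized counts,
  `(s^2 - mu)/mu^2` within condition, averaged over the two
  conditions. Raw estimates are kept unfloored at this stage —
  negative values are sampling noise around a small true dispersion,
  and discarding them would bias the next step upward (about 2-fold
  in our calibration runs);
* a parametric mean-dispersion trend `a0 + a1/mu` fit across members
  (falling back to the flat mean when the fitted coefficients are
  negative, which happens when the mean range is too narrow to
  identify a slope);
* shrinkage of each member's dispersion toward the trend with prior
  weight 10 against the residual degrees of freedom (2 with two
  replicates per condition), flooring the result at `1e-8` — a
  simplified trend-shrink, not full empirical-Bayes machinery;
* a NB GLM with log link, size-factor offsets and a bin-vs-unsorted
  coefficient; the Wald z of that coefficient gives the p-value, and
  the coefficient over `log 2` is the reported `log2fc`.

Members with zero counts in every sample are reported as `NA` rows
and excluded from testing and from Benjamini-Hochberg adjustment
(which is applied per bin, within tested members). With two
replicates per condition this estimator is deliberately
heavily-moderated: simulated null screens put its type-I error at
about 0.04–0.06 at nominal 0.05.

A member is a **hit** when its fold change is at least 1.5
(`log2fc >= log2 1.5`) and its adjusted p-value is below 0.05 in all
three top-expressing bins (top 2.5%, 2.5–5%, 5–10%) against the
unsorted control. The joint all-three-bins rule is the hit
definition; the mean-log2-ratio threshold of 0.52 used in visual
ranking is reported alongside as a diagnostic, not folded into the
rule. Replicate agreement is the Pearson correlation of
`log2(normalized + 0.5)` between the two replicate libraries of a
bin, and category enrichment of hits is
`100 * (hits_in/size_in) / (hits_out/size_out)`.

# Synthetic data

`simulate_transcriptome` draws UTRs with i.i.d. uniform bases,
lengths uniform on 30–300 nt (the bulk of mammalian 5' UTR lengths),
and CDSs beginning with ATG. `simulate_ribo_rna` plants a linear
k-mer signal: true log-TE is a weight vector over 3-mer features
rescaled to a signal SD of 0.7, plus Gaussian noise; the
signal-to-noise argument is interpreted as the ratio of signal SD to
noise SD (SNR 2 gives noise SD 0.35). mRNA levels are lognormal, and
both count tables are negative binomial with means proportional to
`mRNA x length x depth` (RPF means additionally proportional to TE)
and a common dispersion (default 0.05).

`simulate_screen` models recombinase-style single-copy integration:
each cell carries exactly one member, drawn uniformly; fluorescence
is lognormal around the member's strength with cell SD 0.5 (a
realistic cell-to-cell expression CV of roughly 50%); cells are
ranked and the top 2.5% / 2.5–5% / 5–10% define the sorted bins
(`floor(fraction x n_cells)` cells each, a stated rounding rule that
makes cell conservation testable), while the unsorted control is all
cells. Reads are drawn multinomially per (bin, replicate) from the
bin's member composition; replicates are independent cell
populations, which is exactly the reproducibility a landing-pad
design buys. Defaults are 500,000 cells per replicate (the scale of a
typical integrated screen, far above the 25-fold-coverage floor at
which a warning fires), 200,000 reads per bin and two replicates.
Optionally the reads are emitted as flanked FASTQ to exercise the
matching stage.

What the simulators do *not* model: PCR amplification bias and
duplicates, sequencing errors (off by default; a per-base error rate
can be enabled through read-level simulation), position effects,
integration efficiency, selection dynamics, and multi-copy
insertions. Passing tests on this generator therefore demonstrates
the statistical machinery under its stated model, not robustness to
every artifact of real screens.

# Problem sizes and numerical choices

The bundled checks run at: TE recovery n = 500 transcripts at 1e6
reads; surrogate training n = 2000 at SNR 2; GA runs with population
100 for 50 generations; screens with a 1000-member library, 50
planted 2-fold enhancers, two replicates and 2e5 reads per bin —
sizes chosen so every stage runs at full statistical fidelity on a
single CPU in minutes. Other numerics: Spearman ties use average
ranks; panel and diverse-subset ties break lexicographically;
p-values are floored at the smallest positive double before BH; the
dispersion floor is 1e-8; all randomness flows from explicit seeds
and reruns are byte-identical.

# Known limitations

* The default folding score is a pairing-count proxy; absolute
  energies are not comparable to thermodynamic MFE values.
* The NB test's moderation is tuned for very small replicate numbers;
  with many replicates a per-member estimator would be less biased.
* The uORF definition ignores near-cognate starts and Kozak context.
* The GA optimizes a surrogate; nothing guards against surrogate
  pathologies outside its training distribution beyond the AUG and
  length constraints.
* Real screening data (fluorescence validation, ELISA fold changes,
  published hit lists) are out of scope; the package reproduces the
  computational method, and its tests quantify recovery on synthetic
  ground truth only.
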