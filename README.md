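# utrdesign

Engineering 5′ untranslated regions (5′ UTRs) for enhanced protein
expression in mammalian cells — for synthetic biologists and gene
therapy developers who want to squeeze more protein out of a fixed
promoter/payload by optimizing the sequence between the cap and the
Kozak, and for computational biologists analyzing the sort-seq
screens that test such libraries.

The package implements the full computational loop of a 5′ UTR
engineering campaign:

1. **TE quantification** — per-transcript translation efficiency from
   paired ribosome-profiling and RNA-seq count tables,
   `TE = RPKM_Ribo / RPKM_RNA`, with raw-count coverage filtering.
2. **Library preparation** — standardize natural 5′ UTRs to a fixed
   100-bp diversity region (prefix/suffix extraction for long UTRs,
   phase-shifted CAA padding for short ones), remove AUGs by random
   point repair, select top/bottom TE and top-mRNA panels, assemble
   140-mer synthesis oligos (20-nt flank + 100-bp UTR + 20-nt flank),
   and build 206-nt combinatorial UTRs joined by a CAACAA linker.
3. **Featurization** — k-mer frequencies (k = 1–3 by default), an RNA
   folding-energy proxy (maximum base pairing by dynamic programming,
   in C++; ViennaRNA pluggable), UTR length and upstream-ORF counts,
   computed on the UTR plus 15 bp of CDS context.
4. **Surrogate models** — random forest (default), elastic net,
   regression tree and SVM regressors mapping features to TE or mRNA
   level, evaluated by 5-fold cross-validated Spearman correlation;
   predicted protein expression = predicted mRNA × predicted TE.
5. **GA design** — evolve 100-bp AUG-free synthetic UTRs against the
   surrogate: populations of 100 natural seeds, at most 50
   generations, keeping per run the top 5 designs that are ≥ 5
   mismatches apart and ≥ 0.05 fitter than the best natural seed.
6. **Screen analysis** — flank-anchored read counting,
   median-of-ratios size factors, per-bin log2 enrichment against the
   unsorted control, a moderated negative-binomial Wald test, BH
   adjustment, and hit calling requiring ≥ 50% fold change with
   adjusted p < 0.05 in all three top-expressing bins (top 2.5%,
   2.5–5%, 5–10%).
7. **Synthetic data** — generators with recorded ground truth for
   transcriptomes, Ribo/RNA-seq counts with planted k-mer signal, and
   FACS-bin screens with planted enhancer strengths.

See `vignettes/utrdesign-methods.Rmd` for the models, assumptions and
design choices in detail.

## Worked example: analyze a simulated screen

Simulate a 200-member library in which 20 members (10 synthetic, 10
natural) carry a true 2-fold expression advantage, then run the full
analysis:

```r
library(utrdesign)
set.seed(1)
members <- vapply(1:200, function(i)
  strip_augs(paste(sample(c("A","C","G","T"), 100, TRUE), collapse = "")),
  character(1))
lib <- utr_manifest(data.frame(
  id = sprintf("utr%03d", 1:200),
  source = rep(c("synthetic_high_te", "natural"), c(40, 160)),
  origin_context = "designed", sequence = members))
strengths <- setNames(rep(1, 200), lib$records$id)
strengths[sprintf("utr%03d", c(1:10, 101:110))] <- 2

screen <- simulate_screen(lib, strengths = strengths,
                          n_cells = 2e5, depth = 1e5, seed = 1)
sf   <- size_factors(screen$counts)
bins <- c("top2.5", "top2.5_5", "top5_10")
res  <- lapply(bins, function(b)
  nb_test(screen$counts, screen$metadata, b, factors = sf))
names(res) <- bins
hits <- select_hits(res)

head(hits[hits$hit, c("id", "min_log2fc", "max_padj", "mean_log2fc")], 4)
#>       id min_log2fc max_padj mean_log2fc
#> 1 utr001       2.10 3.51e-28        3.01
#> 2 utr002       2.21 8.43e-28        3.07
#> 3 utr003       2.22 5.77e-25        3.02
#> 4 utr004       2.33 7.26e-26        3.00
sum(hits$hit)
#> [1] 20

norm <- normalize_counts(screen$counts, sf)
replicate_correlation(norm, screen$metadata, "top2.5")
#> [1] 0.88
category_enrichment(hits$id[hits$hit], lib)
#> [1] 400
```

All 20 planted enhancers are recovered with no false positives:
`min_log2fc` is the weakest of a member's three per-bin enrichments
(each ≥ log2 1.5 for a hit), `max_padj` the largest of its three
adjusted p-values (each < 0.05), and `mean_log2fc` the descriptive
mean log2 ratio used for ranking. The replicate Pearson r of 0.88
reflects the single-copy integration model's reproducibility, and the
category enrichment of 400% says synthetic members are 4× as frequent
among hits as natural ones relative to their library shares (100% =
parity).

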