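# Sort-seq screen analysis: assign reads to library members by
# flank-anchored dictionary matching, normalize counts by
# median-of-ratios size factors, compute per-bin log2 enrichments
# against the unsorted control, test differential enrichment with a
# negative-binomial Wald test, and call hits that are enriched and
# significant in all three top-expressing bins.

SCREEN_BINS <- c("top2.5", "top2.5_5", "top5_10", "unsorted")

#' Assign screen reads to library members
#'
#' Each read is scanned for the manifest's exact 20-nt left flank; the
#' insert of the library length is extracted after it and the right
#' flank must follow. The insert is then matched against the manifest
#' dictionary exactly, or (with `max_mismatch = 1`) to the unique
#' member within Hamming distance 1; ambiguous or unmatched reads are
#' unassigned. Every read lands in exactly one of {one member,
#' unassigned}.
#'
#' @param reads Character vector of read sequences, or a data.frame
#'   from [read_fastq()].
#' @param manifest A [utr_manifest()] whose members share one length.
#' @param max_mismatch 0 (exact) or 1 insert mismatch tolerated.
#' @return List: `counts` (named integer vector over manifest ids) and
#'   `unassigned` (count); `counts` sum + unassigned equals the number
#'   of reads.
#' @export
match_reads <- function(reads, manifest, max_mismatch = 0L) {
  stopifnot(inherits(manifest, "utr_manifest"), max_mismatch %in% c(0L, 1L))
  if (is.data.frame(reads)) reads <- reads$sequence
  recs <- manifest$records
  if (nrow(recs) == 0L) stop("empty manifest", call. = FALSE)
  L <- unique(nchar(recs$sequence))
  if (length(L) != 1L) {
    stop("match_reads requires a single-length library", call. = FALSE)
  }
  lookup <- setNames(seq_len(nrow(recs)), recs$sequence)
  counts <- setNames(integer(nrow(recs)), recs$id)
  unassigned <- 0L
  lf <- manifest$left_flank
  rf <- manifest$right_flank
  for (rd in toupper(reads)) {
    pos <- regexpr(lf, rd, fixed = TRUE)[1]
    hit <- NA_integer_
    if (pos > 0L) {
      s <- pos + 20L
      e <- s + L - 1L
      rstart <- e + 1L
      rend <- min(nchar(rd), rstart + 19L)
      right_ok <- rstart <= nchar(rd) &&
        substr(rd, rstart, rend) == substr(rf, 1L, rend - rstart + 1L)
      if (e <= nchar(rd) && right_ok) {
        insert <- substr(rd, s, e)
        hit <- lookup[insert]
        if (is.na(hit) && max_mismatch == 1L) {
          d <- vapply(recs$sequence, function(m) hamming(insert, m),
                      integer(1), USE.NAMES = FALSE)
          near <- which(d <= 1L)
          if (length(near) == 1L) hit <- near
        }
      }
    }
    if (is.na(hit)) unassigned <- unassigned + 1L
    else counts[hit] <- counts[hit] + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

#' Median-of-ratios size factors
#'
#' For each member the reference is its geometric mean across samples
#' (rows containing any zero are excluded from the reference set); a
#' sample's size factor is the median across members of
#' `count / reference`. Normalized counts (`count / factor`) are then
#' comparable across sequencing libraries.
#'
#' @param counts Integer matrix, members x samples.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) {
    stop("no member has nonzero counts in all samples; consider adding a ",
         "pseudocount before normalization", call. = FALSE)
  }
  logc <- log(counts[ok, , drop = FALSE])
  ref <- exp(rowMeans(logc))
  apply(counts[ok, , drop = FALSE], 2, function(col) median(col / ref))
}

#' Normalize a count matrix by size factors
#'
#' @param counts Integer matrix.
#' @param factors Optional precomputed [size_factors()].
#' @return Numeric matrix of normalized counts (raw counts are not
#'   modified).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  sweep(counts, 2, factors, "/")
}

#' Per-member log2 enrichment of a bin over the unsorted control
#'
#' `log2((n_bin + pc) / (n_ref + pc))` on normalized counts, computed
#' per replicate and averaged across replicates.
#'
#' @param norm Normalized count matrix (members x samples).
#' @param metadata data.frame with columns `sample`, `bin`,
#'   `replicate` covering every column of `norm`.
#' @param bin Bin label to contrast.
#' @param reference_bin Control bin (default `"unsorted"`).
#' @param pseudocount Added to both numerator and denominator
#'   (default 0.5).
#' @return Named numeric vector of per-member mean log2 ratios.
#' @export
log2_enrichment <- function(norm, metadata, bin,
                            reference_bin = "unsorted",
                            pseudocount = 0.5) {
  if (identical(bin, reference_bin)) {
    stop("bin must differ from reference_bin", call. = FALSE)
  }
  for (b in c(bin, reference_bin)) {
    if (!b %in% metadata$bin) stop("bin '", b, "' not in metadata",
                                   call. = FALSE)
  }
  reps <- intersect(metadata$replicate[metadata$bin == bin],
                    metadata$replicate[metadata$bin == reference_bin])
  per_rep <- vapply(reps, function(r) {
    sb <- metadata$sample[metadata$bin == bin & metadata$replicate == r]
    sr <- metadata$sample[metadata$bin == reference_bin &
                            metadata$replicate == r]
    log2((norm[, sb] + pseudocount) / (norm[, sr] + pseudocount))
  }, numeric(nrow(norm)))
  rowMeans(per_rep)
}

# Per-member method-of-moments dispersion from normalized counts:
# within-condition (var - mu) / mu^2 averaged over conditions. Raw
# estimates are returned unfloored: negative values are sampling noise
# around a small true dispersion and must enter the trend fit, or the
# trend is biased upward.
mom_dispersion <- function(norm_sub, cond) {
  vapply(rownames(norm_sub), function(u) {
    per_cond <- vapply(unique(cond), function(cc) {
      x <- norm_sub[u, cond == cc]
      mu <- mean(x)
      if (mu <= 0) return(NA_real_)
      (var(x) - mu) / mu^2
    }, numeric(1))
    if (all(is.na(per_cond))) NA_real_ else mean(per_cond, na.rm = TRUE)
  }, numeric(1))
}

#' Negative-binomial differential enrichment test for one bin
#'
#' Re-implemented NB analysis: per-member dispersion is estimated by
#' method of moments on normalized counts (floored at 1e-8) and shrunk
#' toward a parametric mean-dispersion trend
#' (`a0 + a1 / baseMean`) with prior weight `prior_df`; a NB GLM with
#' log link, size-factor offsets and a bin-vs-control coefficient is
#' then fit per member, and a Wald test of that coefficient gives the
#' p-value. Members with all-zero counts are reported as `NA` rows and
#' excluded from testing and adjustment.
#'
#' @param counts Raw integer count matrix (members x samples).
#' @param metadata data.frame (`sample`, `bin`, `replicate`).
#' @param bin Bin to contrast against `reference_bin`.
#' @param reference_bin Control bin (default `"unsorted"`).
#' @param factors Size factors for all columns of `counts` (computed
#'   if missing).
#' @param prior_df Prior degrees of freedom pulling per-member
#'   dispersions toward the trend (default 10).
#' @return data.frame: `id`, `base_mean`, `log2fc`, `se`, `p`, `padj`
#'   (BH within the tested members), `dispersion`.
#' @export
nb_test <- function(counts, metadata, bin, reference_bin = "unsorted",
                    factors = NULL, prior_df = 10) {
  stopifnot(is.matrix(counts))
  md <- metadata[metadata$bin %in% c(bin, reference_bin), , drop = FALSE]
  for (b in c(bin, reference_bin)) {
    if (sum(md$bin == b) < 2L) {
      stop("need >= 2 replicates per condition to estimate dispersion (bin '",
           b, "')", call. = FALSE)
    }
  }
  if (is.null(factors)) factors <- size_factors(counts)
  sub <- counts[, md$sample, drop = FALSE]
  sf <- factors[md$sample]
  cond <- ifelse(md$bin == bin, 1L, 0L)
  norm_sub <- sweep(sub, 2, sf, "/")

  testable <- rowSums(sub) > 0L
  disp_gene <- mom_dispersion(norm_sub[testable, , drop = FALSE], cond)
  base_mean <- rowMeans(norm_sub)
  bm <- base_mean[testable]

  # parametric trend a0 + a1/mu, fit on all raw MoM estimates
  # (including negative ones, which keep the trend unbiased)
  informative <- !is.na(disp_gene) & bm > 0
  trend_at <- function(mu) rep(max(mean(disp_gene, na.rm = TRUE), 1e-8),
                               length(mu))
  if (sum(informative) >= 10L) {
    fit <- tryCatch(lm(disp_gene[informative] ~ I(1 / bm[informative])),
                    error = function(e) NULL)
    # a noisy negative slope or intercept would distort the trend;
    # fall back to the flat mean-dispersion trend in that case
    if (!is.null(fit) && all(coef(fit) >= 0)) {
      a <- coef(fit)
      trend_at <- function(mu) pmax(a[1] + a[2] / mu, 1e-8)
    }
  }
  disp_trend <- trend_at(bm)
  resid_df <- length(cond) - 2L
  disp <- pmax((prior_df * disp_trend + resid_df *
                  ifelse(is.na(disp_gene), disp_trend,
                         pmax(disp_gene, 1e-8))) /
                 (prior_df + resid_df), 1e-8)

  res <- data.frame(id = rownames(counts), base_mean = base_mean,
                    log2fc = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, dispersion = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  ti <- which(testable)
  log_sf <- log(sf)
  for (k in seq_along(ti)) {
    i <- ti[k]
    y <- sub[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp[k])
    fit <- tryCatch(
      suppressWarnings(glm(y ~ cond + offset(log_sf), family = fam)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- suppressWarnings(summary(fit, dispersion = 1))
    if (!"cond" %in% rownames(sm$coefficients)) next
    beta <- sm$coefficients["cond", "Estimate"]
    se <- sm$coefficients["cond", "Std. Error"]
    res$log2fc[i] <- beta / log(2)
    res$se[i] <- se / log(2)
    res$p[i] <- max(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
    res$dispersion[i] <- disp[k]
  }
  tested <- !is.na(res$p)
  res$padj[tested] <- bh_adjust(res$p[tested])
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement (wraps [stats::p.adjust()]); validates that p-values
#' lie in (0, 1].
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, `padj >= p` elementwise.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Call screen hits across the three top-expressing bins
#'
#' A member is a hit iff its fold change is at least `min_fold`
#' (`log2fc >= log2(min_fold)`) and its adjusted p-value is below
#' `alpha` in all three bins. The mean-log2-ratio diagnostic threshold
#' (`log2_line`, default 0.52) is reported alongside, not combined
#' into the hit rule.
#'
#' @param results Named list of three [nb_test()] result data.frames
#'   (one per top bin) over the same member universe.
#' @param min_fold Minimum fold change (default 1.5, i.e. 50%
#'   increase).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param log2_line Diagnostic mean log2-ratio line (default 0.52).
#' @return data.frame per member: `id`, `hit`, per-bin `log2fc_*` and
#'   `padj_*`, `min_log2fc`, `max_padj`, `mean_log2fc`,
#'   `above_log2_line`, and a human-readable `rationale`.
#' @export
select_hits <- function(results, min_fold = 1.5, alpha = 0.05,
                        log2_line = 0.52) {
  if (length(results) != 3L) stop("expected results for exactly 3 bins",
                                  call. = FALSE)
  bins <- names(results)
  ids <- results[[1]]$id
  for (r in results) {
    if (!identical(sort(r$id), sort(ids))) {
      stop("all bins must cover the same member universe", call. = FALSE)
    }
  }
  lfc <- sapply(results, function(r) r$log2fc[match(ids, r$id)])
  padj <- sapply(results, function(r) r$padj[match(ids, r$id)])
  colnames(lfc) <- paste0("log2fc_", bins)
  colnames(padj) <- paste0("padj_", bins)
  enriched <- rowSums(lfc >= log2(min_fold), na.rm = TRUE) == 3L &
    rowSums(is.na(lfc)) == 0L
  signif <- rowSums(padj < alpha, na.rm = TRUE) == 3L &
    rowSums(is.na(padj)) == 0L
  hit <- enriched & signif
  mean_lfc <- rowMeans(lfc)
  out <- data.frame(id = ids, hit = hit, lfc, padj,
                    min_log2fc = apply(lfc, 1, min),
                    max_padj = apply(padj, 1, max),
                    mean_log2fc = mean_lfc,
                    above_log2_line = !is.na(mean_lfc) & mean_lfc > log2_line,
                    rationale = ifelse(hit,
                      sprintf("fold >= %.2f and padj < %.2g in all 3 bins",
                              min_fold, alpha),
                      ifelse(!enriched, "fold-change criterion not met in all bins",
                             "adjusted p-value criterion not met in all bins")),
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out
}

#' Replicate reproducibility for one bin
#'
#' Pearson correlation of `log2(normalized count + pseudocount)`
#' between the two replicates of a bin.
#'
#' @param norm Normalized count matrix.
#' @param metadata data.frame (`sample`, `bin`, `replicate`).
#' @param bin Bin label.
#' @param pseudocount Added before the log (default 0.5).
#' @return Pearson r in \[-1, 1\].
#' @export
replicate_correlation <- function(norm, metadata, bin, pseudocount = 0.5) {
  sm <- metadata$sample[metadata$bin == bin]
  if (length(sm) != 2L) {
    stop("replicate_correlation expects exactly 2 replicates for bin '",
         bin, "'", call. = FALSE)
  }
  x <- log2(norm[, sm[1]] + pseudocount)
  y <- log2(norm[, sm[2]] + pseudocount)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero-variance replicate vector in bin '", bin, "'", call. = FALSE)
  }
  cor(x, y)
}

#' Fold enrichment of a source category among hits
#'
#' `100 * (hits_in_category / category_size) /
#' (hits_outside / outside_size)`, the percentage enrichment of a
#' library category (e.g. GA-designed synthetic members) among called
#' hits relative to the rest of the library.
#'
#' @param hit_ids Character vector of hit member ids.
#' @param records Manifest records data.frame (`id`, `source`), or a
#'   [utr_manifest()].
#' @param category Source category of interest (default
#'   `"synthetic_high_te"`).
#' @return Enrichment percentage (100 = parity), or `NA_real_` when a
#'   denominator is zero.
#' @export
category_enrichment <- function(hit_ids, records,
                                category = "synthetic_high_te") {
  if (inherits(records, "utr_manifest")) records <- records$records
  if (!all(hit_ids %in% records$id)) {
    stop("hit ids not all present in manifest", call. = FALSE)
  }
  in_cat <- records$source == category
  n_in <- sum(in_cat)
  n_out <- sum(!in_cat)
  h_in <- sum(hit_ids %in% records$id[in_cat])
  h_out <- sum(hit_ids %in% records$id[!in_cat])
  if (n_in == 0L || n_out == 0L || h_out == 0L) return(NA_real_)
  100 * (h_in / n_in) / (h_out / n_out)
}
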