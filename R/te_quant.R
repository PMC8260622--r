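# Translation-efficiency quantification from paired Ribo-seq and
# RNA-seq count tables. TE = Ribo-seq RPKM / RNA-seq RPKM; inputs are
# pre-tabulated per-transcript counts (alignment, P-site offsetting and
# periodicity QC are upstream of this toolkit).

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count Non-negative read count(s).
#' @param length_nt Transcript length(s) in nucleotides (> 0).
#' @param total_mapped Library size: total mapped reads (> 0).
#' @return `count / (length_nt/1000) / (total_mapped/1e6)`.
#' @export
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be > 0", call. = FALSE)
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count / (length_nt / 1000) / (total_mapped / 1e6)
}

#' Translation efficiency
#'
#' TE is the ratio of ribosome-footprint (RPF) abundance to mRNA
#' abundance: Ribo-seq RPKM / RNA-seq RPKM. It is scale-invariant:
#' multiplying both RPKMs by a constant leaves TE unchanged. A zero
#' RNA denominator yields `NA` (undefined), never 0 or Inf.
#'
#' @param rpf_rpkm,rna_rpkm Non-negative RPKM values (vectorized).
#' @return TE values; `NA_real_` where `rna_rpkm == 0`.
#' @export
translation_efficiency <- function(rpf_rpkm, rna_rpkm) {
  if (any(rpf_rpkm < 0, na.rm = TRUE) || any(rna_rpkm < 0, na.rm = TRUE)) {
    stop("RPKM values must be >= 0", call. = FALSE)
  }
  te <- rpf_rpkm / rna_rpkm
  te[rna_rpkm == 0] <- NA_real_
  te
}

#' Filter transcripts on raw-count coverage
#'
#' Transcripts with insufficient coverage in either assay are
#' discarded: a transcript is retained iff `rna_count >= min_rna_count`
#' and `rpf_count >= min_rpf_count`.
#'
#' @param quants data.frame with columns `rna_count` and `rpf_count`.
#' @param min_rna_count,min_rpf_count Raw-count thresholds (>= 0,
#'   default 10 each).
#' @return The filtered data.frame, with attributes `n_in` and `n_out`.
#' @export
filter_coverage <- function(quants, min_rna_count = 10L, min_rpf_count = 10L) {
  stopifnot(min_rna_count >= 0, min_rpf_count >= 0,
            all(c("rna_count", "rpf_count") %in% names(quants)))
  keep <- quants$rna_count >= min_rna_count & quants$rpf_count >= min_rpf_count
  out <- quants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- nrow(quants)
  attr(out, "n_out") <- nrow(out)
  out
}

#' Quantify translation efficiency for a count table
#'
#' Combines paired RNA-seq and Ribo-seq counts with transcript lengths
#' into per-transcript RPKMs and TE, and flags the coverage filter.
#' Library sizes are the column totals of the supplied tables.
#'
#' @param rna_counts,rpf_counts Named integer vectors (or single-column
#'   matrices) of per-transcript counts over the same transcripts.
#' @param lengths Named vector of transcript lengths (nt).
#' @param min_rna_count,min_rpf_count Coverage thresholds, see
#'   [filter_coverage()].
#' @return data.frame with columns `transcript_id`, `length_nt`,
#'   `rna_count`, `rpf_count`, `rna_rpkm`, `rpf_rpkm`, `te`,
#'   `pass_filter`.
#' @export
quantify_te <- function(rna_counts, rpf_counts, lengths,
                        min_rna_count = 10L, min_rpf_count = 10L) {
  if (is.matrix(rna_counts)) rna_counts <- rowSums(rna_counts)
  if (is.matrix(rpf_counts)) rpf_counts <- rowSums(rpf_counts)
  ids <- names(rna_counts)
  if (is.null(ids)) stop("rna_counts must be named by transcript id")
  if (!setequal(ids, names(rpf_counts)) || !all(ids %in% names(lengths))) {
    stop("rna_counts, rpf_counts and lengths must cover the same transcripts",
         call. = FALSE)
  }
  rpf_counts <- rpf_counts[ids]
  lengths <- lengths[ids]
  rna_rpkm <- rpkm(rna_counts, lengths, sum(rna_counts))
  rpf_rpkm <- rpkm(rpf_counts, lengths, sum(rpf_counts))
  out <- data.frame(
    transcript_id = ids,
    length_nt = as.integer(lengths),
    rna_count = as.integer(rna_counts),
    rpf_count = as.integer(rpf_counts),
    rna_rpkm = unname(rna_rpkm),
    rpf_rpkm = unname(rpf_rpkm),
    te = unname(translation_efficiency(rpf_rpkm, rna_rpkm)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$pass_filter <- out$rna_count >= min_rna_count &
    out$rpf_count >= min_rpf_count
  out
}
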