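# Synthetic-data generators with recorded ground truth. They emulate
# the three inputs the toolkit consumes: a transcriptome with 5' UTR
# and CDS sequences, paired Ribo-seq/RNA-seq count tables whose true
# TE is a planted function of k-mer features, and a FACS-bin sort-seq
# screen in which each cell carries a single integrated library member
# and fluorescence is lognormal around the member's true strength.
# Every generator is a pure function of (arguments, seed).

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome of 5' UTRs with CDS context
#'
#' UTR lengths are uniform on `utr_len_dist`; bases are i.i.d.
#' uniform. Each CDS begins with ATG (the main start codon) followed
#' by random sequence, long enough to provide the 15-nt featurization
#' context.
#'
#' @param n Number of transcripts.
#' @param utr_len_dist `(min, max)` UTR length bounds (default
#'   `c(30, 300)`).
#' @param cds_len CDS length (default 30, >= 15).
#' @param seed Integer seed.
#' @return data.frame: `transcript_id`, `utr_seq`, `cds_seq`.
#' @export
simulate_transcriptome <- function(n, utr_len_dist = c(30L, 300L),
                                   cds_len = 30L, seed = 1L) {
  stopifnot(n >= 1L, cds_len >= 15L)
  if (utr_len_dist[1] > utr_len_dist[2]) {
    stop("utr_len_dist min exceeds max", call. = FALSE)
  }
  withr::with_seed(seed, {
    lens <- sample(seq(utr_len_dist[1], utr_len_dist[2]), n, replace = TRUE)
    data.frame(
      transcript_id = sprintf("tx%04d", seq_len(n)),
      utr_seq = vapply(lens, random_dna, character(1)),
      cds_seq = vapply(rep(cds_len - 3L, n), function(k)
        paste0("ATG", random_dna(k)), character(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
}

#' Draw a planted k-mer weight vector
#'
#' @param n_active Number of 3-mer features with nonzero weight.
#' @param seed Integer seed.
#' @return Named numeric weight vector over `k3_*` features.
#' @export
planted_weights <- function(n_active = 20L, seed = 1L) {
  feats <- grep("^k3_", feature_schema(c(1L, 2L, 3L)), value = TRUE)
  withr::with_seed(seed, {
    w <- rnorm(n_active)
    setNames(w, sample(feats, n_active))
  })
}

#' Simulate paired Ribo-seq and RNA-seq counts with known TE
#'
#' True log-TE is a planted linear function of k-mer features of the
#' UTR (+ CDS context) plus Gaussian noise; the weights are rescaled
#' so the signal standard deviation is `signal_sd`, and the noise SD
#' is `signal_sd / snr` unless `noise_sd` is given directly. mRNA
#' levels are lognormal. RNA counts are negative binomial with mean
#' proportional to `mRNA * length * depth` (column total ~ depth);
#' RPF counts likewise with mean proportional to
#' `mRNA * TE * length * depth`.
#'
#' @param transcripts From [simulate_transcriptome()].
#' @param weights Planted k-mer weights (default [planted_weights()]).
#' @param snr Signal-to-noise ratio `sd(signal) / sd(noise)`
#'   (default 2).
#' @param noise_sd Overrides `snr` when supplied.
#' @param signal_sd Standard deviation of the planted log-TE signal
#'   (default 0.7, natural-log scale).
#' @param depth Target reads per assay (default 1e6).
#' @param dispersion NB dispersion of counts (default 0.05; must be
#'   non-negative, 0 giving Poisson).
#' @param seed Integer seed.
#' @return List: `rna_counts`, `rpf_counts` (named integer vectors),
#'   `lengths` (UTR + CDS length proxy for the transcript), `truth`
#'   (data.frame `transcript_id`, `true_te`, `mrna`), `features` (the
#'   [featurize_matrix()] output used to plant the signal, reusable
#'   for surrogate training), `weights`, `noise_sd`, `seed`.
#' @export
simulate_ribo_rna <- function(transcripts, weights = NULL, snr = 2,
                              noise_sd = NULL, signal_sd = 0.7,
                              depth = 1e6, dispersion = 0.05, seed = 1L) {
  stopifnot(depth > 0)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (is.null(weights)) weights <- planted_weights(seed = seed)
  X <- featurize_matrix(setNames(transcripts$utr_seq,
                                 transcripts$transcript_id),
                        substr(transcripts$cds_seq, 1L, 15L))
  stopifnot(all(names(weights) %in% colnames(X)))
  raw_signal <- as.numeric(X[, names(weights), drop = FALSE] %*% weights)
  s <- sd(raw_signal)
  signal <- if (s > 0) (raw_signal - mean(raw_signal)) / s * signal_sd else
    rep(0, length(raw_signal))
  if (is.null(noise_sd)) noise_sd <- signal_sd / snr
  withr::with_seed(seed + 1L, {
    log_te <- signal + rnorm(nrow(X), 0, noise_sd)
    true_te <- exp(log_te)
    mrna <- rlnorm(nrow(X), meanlog = 2, sdlog = 1)
    len <- nchar(transcripts$utr_seq) + nchar(transcripts$cds_seq)
    mu_rna <- mrna * len
    mu_rna <- mu_rna / sum(mu_rna) * depth
    mu_rpf <- mrna * true_te * len
    mu_rpf <- mu_rpf / sum(mu_rpf) * depth
    draw <- function(mu) {
      if (dispersion == 0) as.integer(stats::rpois(length(mu), mu)) else
        as.integer(rnbinom(length(mu), mu = mu, size = 1 / dispersion))
    }
    rna <- draw(mu_rna)
    rpf <- draw(mu_rpf)
    ids <- transcripts$transcript_id
    list(rna_counts = setNames(rna, ids), rpf_counts = setNames(rpf, ids),
         lengths = setNames(len, ids),
         truth = data.frame(transcript_id = ids, true_te = true_te,
                            mrna = mrna, row.names = NULL,
                            stringsAsFactors = FALSE),
         features = X, weights = weights, noise_sd = noise_sd,
         seed = seed)
  })
}

#' Simulate a FACS-bin sort-seq screen
#'
#' Each of `n_cells` cells carries exactly one library member
#' (single-copy integration), drawn uniformly. Cell fluorescence is
#' lognormal around the member's true strength
#' (`log-fluor ~ Normal(log strength, cell_noise_sd)`). Cells are
#' ranked and the top fractions define the sorted bins
#' (`floor(fraction * n_cells)` cells each); the unsorted control is
#' all cells. Per (bin, replicate), `depth` reads are drawn
#' multinomially from the bin's member composition. Replicates are
#' independent cell populations.
#'
#' @param manifest A [utr_manifest()].
#' @param strengths Named positive vector of true expression
#'   strengths per member (default all 1).
#' @param bin_fractions Sorted-bin fractions, top first (default
#'   `c(0.025, 0.025, 0.05)` for top 2.5%, 2.5-5%, 5-10%).
#' @param n_cells Integrated cells per replicate (default 5e5; a
#'   warning is raised below 25x library coverage).
#' @param depth Reads per (bin, replicate) (default 2e5).
#' @param replicates Number of independent replicates (default 2).
#' @param cell_noise_sd Lognormal cell-to-cell noise SD (natural log;
#'   default 0.5).
#' @param seed Integer seed.
#' @param output `"counts"` (default) or `"fastq"`; with `"fastq"`,
#'   flanked reads are written to `dir` as
#'   `<bin>_rep<r>.fastq` and file paths are returned.
#' @param dir Output directory for `output = "fastq"`.
#' @return List: `counts` (members x samples integer matrix),
#'   `metadata` (`sample`, `bin`, `replicate`), `truth` (strengths,
#'   per-replicate bin cell counts), `seed`; plus `fastq_files` when
#'   requested.
#' @export
simulate_screen <- function(manifest, strengths = NULL,
                            bin_fractions = c(0.025, 0.025, 0.05),
                            n_cells = 5e5, depth = 2e5, replicates = 2L,
                            cell_noise_sd = 0.5, seed = 1L,
                            output = c("counts", "fastq"), dir = NULL) {
  output <- match.arg(output)
  stopifnot(inherits(manifest, "utr_manifest"), sum(bin_fractions) <= 1)
  recs <- manifest$records
  m <- nrow(recs)
  if (is.null(strengths)) strengths <- setNames(rep(1, m), recs$id)
  stopifnot(all(recs$id %in% names(strengths)), all(strengths > 0))
  strengths <- strengths[recs$id]
  if (n_cells < 25 * m) {
    warning("n_cells below 25-fold library coverage; screen estimates ",
            "will be noisy", call. = FALSE)
  }
  bins <- SCREEN_BINS
  stopifnot(length(bin_fractions) == length(bins) - 1L)

  withr::with_seed(seed, {
    counts <- matrix(0L, nrow = m, ncol = 0L,
                     dimnames = list(recs$id, NULL))
    meta <- list()
    bin_cells <- list()
    for (r in seq_len(replicates)) {
      member <- sample.int(m, n_cells, replace = TRUE)
      logf <- log(strengths[member]) + rnorm(n_cells, 0, cell_noise_sd)
      ord <- order(logf, decreasing = TRUE)
      sizes <- floor(bin_fractions * n_cells)
      offsets <- c(0L, cumsum(sizes))
      comp <- matrix(0, nrow = m, ncol = length(bins),
                     dimnames = list(recs$id, bins))
      for (b in seq_along(sizes)) {
        idx <- ord[(offsets[b] + 1L):offsets[b + 1L]]
        comp[, b] <- tabulate(member[idx], nbins = m)
      }
      comp[, "unsorted"] <- tabulate(member, nbins = m)
      bin_cells[[r]] <- comp
      for (b in bins) {
        cc <- comp[, b]
        reads <- if (sum(cc) > 0) {
          as.integer(rmultinom(1L, size = depth, prob = cc / sum(cc)))
        } else rep(0L, m)
        counts <- cbind(counts, reads)
        meta[[length(meta) + 1L]] <- data.frame(
          sample = paste0(b, "_rep", r), bin = b, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
    metadata <- do.call(rbind, meta)
    colnames(counts) <- metadata$sample
    out <- list(counts = counts, metadata = metadata,
                truth = list(strengths = strengths, bin_cells = bin_cells),
                seed = seed)
    if (output == "fastq") {
      if (is.null(dir)) stop("output = 'fastq' requires dir", call. = FALSE)
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- character(0)
      for (s in metadata$sample) {
        cc <- counts[, s]
        seqs <- rep(paste0(manifest$left_flank, recs$sequence,
                           manifest$right_flank), times = cc)
        reads <- data.frame(
          id = sprintf("%s_read%07d", s, seq_along(seqs)),
          sequence = seqs, stringsAsFactors = FALSE)
        f <- file.path(dir, paste0(s, ".fastq"))
        write_fastq(reads, f)
        files <- c(files, f)
      }
      out$fastq_files <- files
    }
    out
  })
}
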