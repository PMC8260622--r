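# Shared fixtures: everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# A random AUG-free standardized library member.
rand_member <- function(len = 100L) strip_augs(rand_seq(len))

# Small manifest of AUG-free members with deterministic ids.
make_manifest <- function(n = 20L, len = 100L,
                          source = "natural") {
  recs <- data.frame(
    id = sprintf("u%04d", seq_len(n)),
    source = rep_len(source, n),
    origin_context = "designed",
    sequence = vapply(seq_len(n), function(i) rand_member(len),
                      character(1)),
    stringsAsFactors = FALSE
  )
  utr_manifest(recs)
}

# Toy GA objective: number of GC or CG dinucleotide windows.
gc_dinucleotide_fitness <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sum((ch[-length(ch)] == "G" & ch[-1] == "C") |
        (ch[-length(ch)] == "C" & ch[-1] == "G"))
}

# Independent maximum-pairing oracle: exhaustive recursion over all
# nested structures (first-position decomposition, no memoization).
# Only usable for short sequences.
brute_force_max_pairs <- function(seq, min_loop = 3L) {
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq(i, j)) {
      if (k - i > min_loop && pairs_ok(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Independent median-of-ratios implementation (loop-based).
brute_force_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[keep, , drop = FALSE]
  ref <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) ref[i] <- prod(sub[i, ])^(1 / ncol(sub))
  out <- numeric(ncol(sub))
  for (j in seq_len(ncol(sub))) out[j] <- median(sub[, j] / ref)
  setNames(out, colnames(counts))
}

# Independent step-up BH implementation.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Independent sliding-window k-mer frequency computation.
brute_force_kmers <- function(seq, k) {
  words <- sort(apply(expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE],
                      1, paste, collapse = ""))
  counts <- setNames(numeric(length(words)), words)
  nwin <- nchar(seq) - k + 1L
  for (i in seq_len(nwin)) {
    w <- substr(seq, i, i + k - 1L)
    counts[w] <- counts[w] + 1
  }
  counts / nwin
}

# Independent greedy diverse-subset selection with an explicit
# distance matrix.
brute_force_diverse <- function(seqs, fits, k, min_dist) {
  n <- length(seqs)
  keep1 <- !duplicated(seqs)
  seqs <- seqs[keep1]; fits <- fits[keep1]; n <- length(seqs)
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  dist <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dist[i, j] <- sum(mats[[i]] != mats[[j]])
  }
  ord <- order(-fits, seqs)
  acc <- integer(0)
  for (i in ord) {
    if (length(acc) >= k) break
    if (all(dist[i, acc] >= min_dist) || length(acc) == 0L) {
      acc <- c(acc, i)
    }
  }
  seqs[acc]
}
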