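# Sequence featurization: k-mer frequencies, RNA folding energy,
# length and upstream-ORF counts. Features are computed on the 5' UTR
# concatenated with 15 bp of downstream CDS context (the nucleotides
# surrounding the main AUG), except for utr_length and the uORF counts
# which describe the UTR itself.

#' k-mer frequency features
#'
#' Overlapping-window k-mer frequencies for each k in `k_set`:
#' `f_k(w) = count(w) / (|seq| - k + 1)`. All `4^k` words are present
#' (zeros included) so the feature schema has fixed dimension; for each
#' k with at least one window the frequencies sum to 1. Counting is
#' done with [Biostrings::oligonucleotideFrequency()].
#'
#' @param seq DNA string.
#' @param k_set Integer k values (default `c(1, 2, 3)`).
#' @return Named numeric vector, names `k<k>_<word>` in lexicographic
#'   word order within each k.
#' @export
#' @examples
#' kmer_frequencies("ACGA", k_set = 2)  # AC, CG, GA each 1/3
kmer_frequencies <- function(seq, k_set = c(1L, 2L, 3L)) {
  assert_dna(seq)
  dna <- Biostrings::DNAString(seq)
  out <- lapply(sort(as.integer(k_set)), function(k) {
    nwin <- nchar(seq) - k + 1L
    if (nwin < 1L) {
      warning("k = ", k, " exceeds sequence length ", nchar(seq),
              "; returning zeros", call. = FALSE)
      words <- Biostrings::mkAllStrings(DNA_BASES, k)
      freq <- setNames(numeric(length(words)), words)
    } else {
      freq <- Biostrings::oligonucleotideFrequency(dna, width = k) / nwin
    }
    names(freq) <- paste0("k", k, "_", names(freq))
    freq
  })
  unlist(out)
}

#' Count upstream AUGs and upstream ORFs
#'
#' `n_uaug` is the number of ATG occurrences in the sequence.
#' `n_uorf` is the number of those ATGs that are followed by an
#' in-frame stop codon (TAA, TAG or TGA) lying entirely within the
#' sequence, i.e. complete upstream open reading frames.
#'
#' @param seq DNA string.
#' @return Named integer vector `c(n_uaug = , n_uorf = )`.
#' @export
count_uorfs <- function(seq) {
  assert_dna(seq)
  starts <- atg_positions(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  has_stop <- vapply(starts, function(i) {
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% stops) return(TRUE)
      j <- j + 3L
    }
    FALSE
  }, logical(1))
  c(n_uaug = length(starts), n_uorf = sum(has_stop))
}

#' RNA folding energy of a sequence
#'
#' With the default `nussinov_default` engine, returns -1.0 kcal/mol
#' per base pair in the maximum nested pairing (Watson-Crick plus G-U
#' wobble, minimum hairpin loop of 3 unpaired nucleotides), computed by
#' an interval dynamic program in C++. More negative means more
#' predicted structure; the score is a structure proxy, not a
#' thermodynamic free energy. The `external` engine shells out to
#' ViennaRNA's `RNAfold` when available, behind the same signature.
#'
#' @param seq DNA string (transcribed T -> U internally).
#' @param engine `"nussinov_default"` or `"external"`.
#' @return Folding energy in kcal/mol, always `<= 0`.
#' @export
#' @examples
#' folding_energy("GGGGAAAACCCC")  # -4
folding_energy <- function(seq, engine = "nussinov_default") {
  assert_dna(seq)
  if (identical(engine, "nussinov_default")) {
    return(-1.0 * nussinov_max_pairs(seq, min_loop = 3L))
  }
  if (identical(engine, "external")) {
    if (Sys.which("RNAfold") == "") {
      stop("external folding engine requested but RNAfold not on PATH",
           call. = FALSE)
    }
    rna <- chartr("T", "U", seq)
    out <- system2("RNAfold", args = c("--noPS"), input = rna, stdout = TRUE)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1",
                          out[length(out)]))
    return(min(mfe, 0))
  }
  stop("unknown folding engine: '", engine, "'", call. = FALSE)
}

#' Feature schema for a configuration
#'
#' @param k_set k-mer sizes.
#' @return Character vector of feature names in canonical order, with
#'   attribute `hash` (used to guard model/feature compatibility).
#' @export
feature_schema <- function(k_set = c(1L, 2L, 3L)) {
  k_set <- sort(as.integer(k_set))
  kn <- unlist(lapply(k_set, function(k)
    paste0("k", k, "_", Biostrings::mkAllStrings(DNA_BASES, k))))
  nm <- c(kn, "mfe", "utr_length", "n_uaug", "n_uorf")
  attr(nm, "hash") <- rlang::hash(nm)
  nm
}

#' Featurize one 5' UTR with its CDS context
#'
#' k-mer frequencies and folding energy are computed on the
#' concatenation `utr + cds_context`; `utr_length` and the uORF counts
#' are computed on the UTR alone (the CDS context starts with the main
#' ORF's AUG, which is not an upstream AUG). Pure function: repeated
#' calls give identical output.
#'
#' @param utr 5' UTR DNA string.
#' @param cds_context First 15 nt of the downstream CDS.
#' @param k_set k-mer sizes (default `c(1, 2, 3)`).
#' @param engine Folding engine, see [folding_energy()].
#' @return Named numeric vector following [feature_schema()] order,
#'   with attribute `schema_hash`.
#' @export
featurize <- function(utr, cds_context, k_set = c(1L, 2L, 3L),
                      engine = "nussinov_default") {
  assert_dna(utr, "utr")
  assert_dna(cds_context, "cds_context")
  if (nchar(cds_context) != 15L) {
    stop("cds_context must be exactly 15 nt, got ", nchar(cds_context),
         call. = FALSE)
  }
  full <- paste0(utr, cds_context)
  uorf <- count_uorfs(utr)
  fv <- c(kmer_frequencies(full, k_set),
          mfe = folding_energy(full, engine),
          utr_length = nchar(utr),
          n_uaug = unname(uorf["n_uaug"]),
          n_uorf = unname(uorf["n_uorf"]))
  schema <- feature_schema(k_set)
  stopifnot(identical(names(fv), as.character(schema)))
  attr(fv, "schema_hash") <- attr(schema, "hash")
  fv
}

#' Featurize many sequences into a matrix
#'
#' Vectorized version of [featurize()]; k-mer counting runs on a
#' `DNAStringSet` in one pass.
#'
#' @param utrs Named character vector of UTR sequences.
#' @param cds_contexts Character vector of 15-nt contexts (recycled if
#'   length 1).
#' @inheritParams featurize
#' @return Numeric matrix, rows = sequence ids, columns =
#'   [feature_schema()]; attribute `schema_hash`.
#' @export
featurize_matrix <- function(utrs, cds_contexts, k_set = c(1L, 2L, 3L),
                             engine = "nussinov_default") {
  n <- length(utrs)
  if (length(cds_contexts) == 1L) cds_contexts <- rep(cds_contexts, n)
  stopifnot(length(cds_contexts) == n)
  if (any(nchar(cds_contexts) != 15L)) {
    stop("all cds_contexts must be exactly 15 nt", call. = FALSE)
  }
  full <- paste0(utrs, cds_contexts)
  set <- Biostrings::DNAStringSet(full)
  k_set <- sort(as.integer(k_set))
  kmers <- do.call(cbind, lapply(k_set, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    freq <- counts / (nchar(full) - k + 1L)
    colnames(freq) <- paste0("k", k, "_", colnames(freq))
    freq
  }))
  mfe <- vapply(full, folding_energy, numeric(1), engine = engine,
                USE.NAMES = FALSE)
  uorfs <- t(vapply(utrs, count_uorfs, c(n_uaug = 0L, n_uorf = 0L),
                    USE.NAMES = FALSE))
  colnames(uorfs) <- c("n_uaug", "n_uorf")
  X <- cbind(kmers, mfe = mfe, utr_length = nchar(utrs),
             n_uaug = uorfs[, "n_uaug"], n_uorf = uorfs[, "n_uorf"])
  rownames(X) <- if (is.null(names(utrs))) paste0("seq", seq_len(n)) else
    names(utrs)
  schema <- feature_schema(k_set)
  stopifnot(identical(colnames(X), as.character(schema)))
  attr(X, "schema_hash") <- attr(schema, "hash")
  X
}
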