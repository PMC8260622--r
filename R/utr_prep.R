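# Library preparation: standardize raw 5' UTRs to a fixed length,
# remove start codons, select natural panels by TE / mRNA rank,
# assemble synthesis oligos and build combinatorial members.

#' Standardize a 5' UTR to a fixed library length
#'
#' The screening library uses a fixed diversity-region length (100 bp
#' by default, compatible with array oligo synthesis). Sequences longer
#' than `target_len` yield two variants: the 5'-end prefix and the
#' 3'-end suffix of length `target_len`. Shorter sequences are padded
#' at the 5' end with repeats of the unstructured CAA motif, in two
#' versions whose pad is phase-shifted by one nucleotide; the native
#' sequence stays adjacent to the downstream Kozak/CDS junction.
#'
#' @param seq DNA string ({A,C,G,T}, length >= 3).
#' @param target_len Library length (default 100).
#' @return Character vector of 1 (already at length) or 2 variants,
#'   each exactly `target_len` nt.
#' @export
#' @examples
#' standardize_utr(strrep("ACGT", 24), target_len = 100)
standardize_utr <- function(seq, target_len = 100L) {
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than 3 nt cannot be standardized",
                   call. = FALSE)
  if (n == target_len) return(seq)
  if (n > target_len) {
    return(c(substr(seq, 1L, target_len),
             substr(seq, n - target_len + 1L, n)))
  }
  d <- target_len - n
  caa <- strrep("CAA", ceiling((d + 1L) / 3L) + 1L)
  c(paste0(substr(caa, 1L, d), seq),
    paste0(substr(caa, 2L, d + 1L), seq))
}

#' Remove start codons by random point mutation
#'
#' Scans left to right for ATG occurrences; at each one, a single
#' nucleotide among the three is mutated to a random different base.
#' Draws that leave or create an ATG overlapping the repaired window
#' are rejected and re-drawn, so the procedure terminates with an
#' ATG-free sequence of unchanged length. Deterministic under a fixed
#' seed.
#'
#' @param seq DNA string.
#' @param seed Optional integer seed; if `NULL`, the current RNG
#'   stream is used (callers inside larger seeded procedures).
#' @return ATG-free DNA string, same length as `seq`.
#' @export
strip_augs <- function(seq, seed = NULL) {
  assert_dna(seq)
  if (!is.null(seed)) return(withr::with_seed(seed, strip_augs(seq)))
  chars <- seq_chars(seq)
  n <- length(chars)
  repeat {
    s <- paste(chars, collapse = "")
    pos <- atg_positions(s)
    if (length(pos) == 0L) return(s)
    i <- pos[1]
    # window that any ATG overlapping the mutated codon could span
    lo <- max(1L, i - 2L)
    hi <- min(n, i + 4L)
    repeat {
      p <- i + sample.int(3L, 1L) - 1L
      old <- chars[p]
      chars[p] <- sample(setdiff(DNA_BASES, old), 1L)
      win <- paste(chars[lo:hi], collapse = "")
      if (length(atg_positions(win)) == 0L) break
      chars[p] <- old
    }
  }
}

#' Panel sizes for natural 5' UTR selection
#'
#' Defaults reproduce the published library composition: top/bottom TE
#' panels from HEK 293T (1505/937) and PC3 (1692/756), a top-TE panel
#' from human muscle (1831) and a top-mRNA-expression panel from
#' muscle tissue (1693).
#'
#' @param hek293t,pc3 Length-2 integer vectors `(n_top, n_bottom)`.
#' @param muscle_te,muscle_mrna Top-n panel sizes.
#' @return Named list with class `panel_spec`.
#' @export
panel_spec <- function(hek293t = c(1505L, 937L), pc3 = c(1692L, 756L),
                       muscle_te = 1831L, muscle_mrna = 1693L) {
  stopifnot(length(hek293t) == 2L, length(pc3) == 2L,
            all(c(hek293t, pc3, muscle_te, muscle_mrna) >= 0))
  structure(list(HEK293T = as.integer(hek293t), PC3 = as.integer(pc3),
                 muscle_te = as.integer(muscle_te),
                 muscle_mrna = as.integer(muscle_mrna)),
            class = "panel_spec")
}

#' Library composition implied by a panel specification
#'
#' Sums the natural panel sizes and the synthetic design-set sizes into
#' the overall library composition.
#'
#' @param spec A [panel_spec()].
#' @param n_high_te_designs Number of GA-designed high-TE synthetic
#'   members (default 2388).
#' @param n_test_designs Number of two-generation model-test designs
#'   (default 1198).
#' @return Named list: `n_natural`, `n_synthetic`, `n_total`.
#' @export
library_composition <- function(spec = panel_spec(),
                                n_high_te_designs = 2388L,
                                n_test_designs = 1198L) {
  n_nat <- sum(spec$HEK293T) + sum(spec$PC3) + spec$muscle_te +
    spec$muscle_mrna
  n_syn <- n_high_te_designs + n_test_designs
  list(n_natural = as.integer(n_nat), n_synthetic = as.integer(n_syn),
       n_total = as.integer(n_nat + n_syn))
}

# Rank a quant table by a column, descending, ties broken by id.
rank_order <- function(tab, col, decreasing = TRUE) {
  order(if (decreasing) -tab[[col]] else tab[[col]], tab$transcript_id)
}

#' Select natural 5' UTR panels by TE and mRNA rank
#'
#' Per cellular context, takes the top-n transcripts by TE (descending)
#' and, where the panel specification requests it, the bottom-n by TE
#' (ascending);
#' the muscle mRNA panel takes the top-n by mRNA expression. Ties are
#' broken by lexicographic transcript id so output is deterministic.
#' Top and bottom panels within a context never overlap.
#'
#' @param quant_tables Named list with elements `HEK293T`, `PC3`,
#'   `muscle_te`: data.frames with columns `transcript_id`, `te`,
#'   `utr_seq` (coverage-filtered).
#' @param mrna_table data.frame with `transcript_id`, `mrna`, `utr_seq`
#'   for the muscle mRNA panel.
#' @param spec A [panel_spec()].
#' @return data.frame of records: `id`, `source` ("natural"),
#'   `origin_context`, `panel` ("top"/"bottom"), `sequence`.
#' @export
select_natural_panels <- function(quant_tables, mrna_table,
                                  spec = panel_spec()) {
  take <- function(tab, n, decreasing, context, panel, value_col) {
    if (n > nrow(tab)) {
      stop("requested ", n, " transcripts from context '", context,
           "' but only ", nrow(tab), " available", call. = FALSE)
    }
    if (n == 0L) return(NULL)
    idx <- rank_order(tab, value_col, decreasing)[seq_len(n)]
    data.frame(id = tab$transcript_id[idx], source = "natural",
               origin_context = context, panel = panel,
               sequence = toupper(tab$utr_seq[idx]),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (ctx in c("HEK293T", "PC3")) {
    tab <- quant_tables[[ctx]]
    if (is.null(tab)) stop("quant_tables missing context '", ctx, "'")
    if (sum(spec[[ctx]]) > nrow(tab)) {
      stop("context '", ctx, "': top+bottom (", sum(spec[[ctx]]),
           ") exceeds available transcripts (", nrow(tab), ")",
           call. = FALSE)
    }
    out[[paste0(ctx, "_top")]] <-
      take(tab, spec[[ctx]][1], TRUE, ctx, "top", "te")
    out[[paste0(ctx, "_bot")]] <-
      take(tab, spec[[ctx]][2], FALSE, ctx, "bottom", "te")
    both <- intersect(out[[paste0(ctx, "_top")]]$id,
                      out[[paste0(ctx, "_bot")]]$id)
    if (length(both) > 0L) {
      stop("context '", ctx, "': top and bottom panels overlap (",
           both[1], "); reduce panel sizes", call. = FALSE)
    }
  }
  out$muscle_te <- take(quant_tables$muscle_te, spec$muscle_te, TRUE,
                        "muscle_te", "top", "te")
  out$muscle_mrna <- take(mrna_table, spec$muscle_mrna, TRUE,
                          "muscle_mrna", "top", "mrna")
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id = character(0), source = character(0),
                      origin_context = character(0), panel = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Assemble a synthesis oligo from a library member
#'
#' A synthesis oligo is `left_flank + sequence + right_flank`: two
#' 20-nt homology/priming arms around the 100-nt diversity region,
#' 140 nt in total.
#'
#' @param sequence 100-nt standardized member sequence.
#' @param left_flank,right_flank 20-nt flanks.
#' @return 140-nt oligo string.
#' @export
build_oligo <- function(sequence, left_flank, right_flank) {
  assert_dna(sequence); assert_dna(left_flank); assert_dna(right_flank)
  if (nchar(left_flank) != 20L || nchar(right_flank) != 20L) {
    stop("flanks must be exactly 20 nt", call. = FALSE)
  }
  if (nchar(sequence) != 100L) {
    stop("library member must be exactly 100 nt, got ", nchar(sequence),
         call. = FALSE)
  }
  paste0(left_flank, sequence, right_flank)
}

#' @rdname build_oligo
#' @param oligo 140-nt oligo.
#' @return For `extract_insert`, the 100-nt insert.
#' @export
extract_insert <- function(oligo, left_flank, right_flank) {
  assert_dna(oligo)
  if (nchar(oligo) != 140L) stop("oligo must be 140 nt", call. = FALSE)
  if (substr(oligo, 1L, 20L) != left_flank ||
      substr(oligo, 121L, 140L) != right_flank) {
    stop("oligo flanks do not match manifest flanks", call. = FALSE)
  }
  substr(oligo, 21L, 120L)
}

#' Join two standardized members into a combinatorial 5' UTR
#'
#' Combinatorial members place two validated 100-nt UTRs in series
#' with a short unstructured linker (CAACAA by default), giving a
#' 206-nt element. The operation is order-sensitive; downstream
#' position (3' end, adjacent to the Kozak sequence) matters.
#'
#' @param a,b One-row record data.frames (see [utr_record()]) with
#'   100-nt sequences; `a` is placed 5' of `b`.
#' @param linker DNA linker (default "CAACAA"; "" allowed).
#' @return One-row combinatorial record with id `"<a>-<b>"`.
#' @export
combine_utrs <- function(a, b, linker = "CAACAA") {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (nchar(a$sequence) != 100L || nchar(b$sequence) != 100L) {
    stop("combinatorial building blocks must be standardized 100-nt members",
         call. = FALSE)
  }
  if (nchar(linker) > 0L) assert_dna(linker, "linker")
  utr_record(id = paste0(a$id, "-", b$id),
             sequence = paste0(a$sequence, linker, b$sequence),
             source = "combinatorial", origin_context = "designed",
             notes = paste0("5p=", a$id, ";3p=", b$id))
}
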