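# Readers and writers for the plain-text formats the toolkit touches:
# FASTA, FASTQ, count tables, library manifests and flat key=value
# configuration files. Parsing of FASTA/FASTQ is delegated to
# Biostrings; the wrappers add the error contracts the toolkit relies
# on (line-numbered parse errors, integer-count enforcement, unique
# ids) and return plain R structures.

#' Read a FASTA file
#'
#' Sequences are uppercased on read so that all downstream code can
#' assume a normalized {A,C,G,T} alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  in_record <- FALSE
  n_seq_lines <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(sub("^>", "", ln))) == 0L) {
        stop("FASTA parse error at line ", i, ": empty header", call. = FALSE)
      }
      if (in_record && n_seq_lines == 0L) {
        stop("FASTA parse error at line ", i, ": record with empty sequence",
             call. = FALSE)
      }
      in_record <- TRUE
      n_seq_lines <- 0L
    } else if (nchar(trimws(ln)) > 0L) {
      if (!in_record) {
        stop("FASTA parse error at line ", i,
             ": sequence data before first header", call. = FALSE)
      }
      n_seq_lines <- n_seq_lines + 1L
    }
  }
  if (in_record && n_seq_lines == 0L) {
    stop("FASTA parse error at line ", length(lines),
         ": record with empty sequence", call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  data.frame(
    id = names(ss),
    sequence = toupper(as.character(ss)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write records to a FASTA file
#'
#' @param records A data.frame with columns `id` and `sequence` (or a
#'   named character vector of sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  ss <- Biostrings::BStringSet(toupper(records$sequence))
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: truncated record near line ", length(lines),
         " (line count not a multiple of 4)", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  for (i in idx) {
    if (!startsWith(lines[[i]], "@")) {
      stop("FASTQ parse error at line ", i, ": expected '@' header",
           call. = FALSE)
    }
    if (!startsWith(lines[[i + 2L]], "+")) {
      stop("FASTQ parse error at line ", i + 2L, ": expected '+' separator",
           call. = FALSE)
    }
    if (nchar(lines[[i + 1L]]) != nchar(lines[[i + 3L]])) {
      stop("FASTQ parse error at line ", i + 3L,
           ": quality length differs from sequence length", call. = FALSE)
    }
  }
  data.frame(
    id = sub("^@", "", vapply(lines[idx], function(x)
      strsplit(x, "[\t ]")[[1]][1], character(1))),
    sequence = toupper(lines[idx + 1L]),
    quality = lines[idx + 3L],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `sequence` and optionally
#'   `quality` (defaults to constant "I").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$sequence
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a count table (TSV)
#'
#' First column holds UTR/transcript ids, remaining columns are one
#' integer count column per sample. Non-integer or missing cells are
#' an error, never silently coerced.
#'
#' @param path Path to a tab-separated count table with a header row.
#' @return Integer matrix with ids as rownames, samples as colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count table needs an id column plus >= 1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate id in count table: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m == "")) stop("missing cell in count table",
                                          call. = FALSE)
  num <- suppressWarnings(as.numeric(m))
  if (any(is.na(num)) || any(num != floor(num)) || any(num < 0)) {
    bad <- m[is.na(num) | suppressWarnings(as.numeric(m)) %% 1 != 0][1]
    stop("non-integer count in table: '", bad, "'", call. = FALSE)
  }
  counts <- matrix(as.integer(num), nrow = nrow(m),
                   dimnames = list(ids, colnames(df)[-1]))
  counts
}

#' Write a count (or numeric) matrix as TSV
#'
#' @param mat Matrix with rownames (ids) and colnames (samples).
#' @param path Output path.
#' @param id_col Name of the id column in the output header.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Library manifests ------------------------------------------------------

UTR_SOURCES <- c("natural", "synthetic_high_te", "synthetic_test",
                 "combinatorial")
UTR_CONTEXTS <- c("HEK293T", "PC3", "muscle_te", "muscle_mrna", "designed")

#' Construct a 5' UTR library record
#'
#' @param id Unique member id.
#' @param sequence Uppercase DNA sequence.
#' @param source One of `r paste(UTR_SOURCES, collapse = ", ")`.
#' @param origin_context One of `r paste(UTR_CONTEXTS, collapse = ", ")`.
#' @param notes Free text.
#' @return One-row data.frame.
#' @export
utr_record <- function(id, sequence, source = "natural",
                       origin_context = "designed", notes = "") {
  source <- match.arg(source, UTR_SOURCES)
  origin_context <- match.arg(origin_context, UTR_CONTEXTS)
  sequence <- toupper(sequence)
  assert_dna(sequence, paste0("record '", id, "'"))
  data.frame(id = id, source = source, origin_context = origin_context,
             sequence = sequence, notes = notes, stringsAsFactors = FALSE)
}

#' Assemble a library manifest
#'
#' A manifest bundles the member records with the two 20-nt PCR-priming
#' flanks used to assemble 140-mer synthesis oligos and to anchor read
#' matching in screen analysis.
#'
#' @param records data.frame of records (`id`, `source`,
#'   `origin_context`, `sequence`; `notes` optional).
#' @param left_flank,right_flank 20-nt DNA flanks.
#' @return An object of class `utr_manifest`.
#' @export
utr_manifest <- function(records,
                         left_flank  = "GGGACACGCGTACGTAACGA",
                         right_flank = "TCGTAGCATCGCTACGGATC") {
  stopifnot(is.data.frame(records),
            all(c("id", "source", "origin_context", "sequence") %in%
                  names(records)))
  if (anyDuplicated(records$id)) {
    stop("manifest ids not unique: ", records$id[duplicated(records$id)][1],
         call. = FALSE)
  }
  for (fl in c(left_flank, right_flank)) {
    assert_dna(fl, "flank")
    if (nchar(fl) != 20L) stop("flanks must be exactly 20 nt", call. = FALSE)
  }
  records$sequence <- toupper(records$sequence)
  bad <- !records$source %in% UTR_SOURCES
  if (any(bad)) stop("unknown source: ", records$source[bad][1], call. = FALSE)
  structure(list(records = records, left_flank = left_flank,
                 right_flank = right_flank),
            class = "utr_manifest")
}

#' @export
print.utr_manifest <- function(x, ...) {
  cat("utr_manifest:", nrow(x$records), "members\n")
  print(table(x$records$source))
  cat("flanks:", x$left_flank, "...", x$right_flank, "\n")
  invisible(x)
}

#' Read / write a library manifest TSV
#'
#' The TSV carries one row per member (id, source, origin_context,
#' sequence, notes); the flanks are stored in `#left_flank=` /
#' `#right_flank=` comment lines at the top of the file.
#'
#' @param path Manifest TSV path.
#' @return For `read_manifest`, a `utr_manifest`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_flag <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) != 1L) stop("manifest missing #", key, "= line",
                                call. = FALSE)
    sub(paste0("^#", key, "="), "", hit)
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE)
  utr_manifest(df, left_flank = get_flag("left_flank"),
               right_flank = get_flag("right_flank"))
}

#' @rdname read_manifest
#' @param manifest A `utr_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "utr_manifest"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#left_flank=", manifest$left_flank),
               paste0("#right_flank=", manifest$right_flank)), con)
  write.table(manifest$records, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Flat key=value configuration -------------------------------------------

#' Default run configuration
#'
#' All tunable parameters of the toolkit in one flat named list; every
#' stochastic operation draws its randomness from `seed`. The list is
#' serializable to a `key=value` text file.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    target_len = 100L,
    kmer_k = "1,2,3",
    cds_context_len = 15L,
    folding_engine = "nussinov_default",
    min_rna_count = 10L,
    min_rpf_count = 10L,
    n_folds = 5L,
    n_trees = 500L,
    ga_pop_size = 100L,
    ga_max_generations = 50L,
    ga_n_keep = 5L,
    ga_min_hamming = 5L,
    ga_min_improvement = 0.05,
    ga_mutation_rate = 0.01,
    ga_crossover_rate = 0.5,
    ga_shift_rate = 0.5,
    ga_parent_pool = 5L,
    ga_n_offspring = 150L,
    screen_pseudocount = 0.5,
    hit_min_fold = 1.5,
    hit_alpha = 0.05,
    hit_log2_line = 0.52
  )
}

#' Read / write a flat key=value config file
#'
#' @param path Config file path (one `key=value` per line, `#` comments
#'   allowed). Values that parse as numbers are returned numeric.
#' @return For `read_config`, a named list merged over
#'   [default_config()].
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("bad config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=",
                    vapply(config, as.character, character(1))), path)
  invisible(path)
}
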