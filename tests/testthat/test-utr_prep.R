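test_that("standardization truncates from both ends or pads with CAA", {
  s100 <- strrep("ACGC", 25)
  expect_equal(standardize_utr(s100), s100)

  s150 <- paste0(strrep("A", 50), strrep("C", 50), strrep("G", 50))
  out <- standardize_utr(s150)
  expect_equal(out, c(paste0(strrep("A", 50), strrep("C", 50)),
                      paste0(strrep("C", 50), strrep("G", 50))))

  s96 <- strrep("ACGC", 24)
  out <- standardize_utr(s96)
  expect_equal(out, c(paste0("CAAC", s96), paste0("AACA", s96)))

  # oracle over pad phases for every deficit 1..99
  caa <- strrep("CAA", 50)
  for (len in c(3, 10, 57, 99)) {
    s <- strrep("G", len)
    d <- 100 - len
    expected <- c(paste0(substr(caa, 1, d), s),
                  paste0(substr(caa, 2, d + 1), s))
    expect_equal(standardize_utr(s), expected)
  }
  expect_error(standardize_utr("AC"), "shorter than 3")
})

test_that("standardized outputs always contain the input or a full-length slice", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(c(3:99, 101:300), 1)
    s <- rand_seq(n)
    out <- standardize_utr(s)
    expect_length(out, 2L)
    expect_true(all(nchar(out) == 100))
    if (n < 100) {
      expect_true(all(substr(out, 101 - n, 100) == s))
    } else {
      expect_true(all(vapply(out, function(o) grepl(o, s, fixed = TRUE),
                             logical(1))))
    }
  }
})

test_that("AUG repair draws only safe single substitutions", {
  expect_equal(strip_augs("CCCACC"), "CCCACC")

  # enumerate the 9 single-substitution variants of the ATG in CCATGC
  # and keep those free of any ATG; strip_augs must land in that set
  base <- "CCATGC"
  variants <- character(0)
  for (p in 3:5) for (b in setdiff(BASES, substr(base, p, p))) {
    v <- base
    substr(v, p, p) <- b
    if (!grepl("ATG", v)) variants <- c(variants, v)
  }
  for (seed in 1:25) {
    out <- strip_augs(base, seed = seed)
    expect_true(out %in% variants)
  }

  out <- strip_augs("ATGATG", seed = 7)
  expect_equal(nchar(out), 6L)
  expect_false(grepl("ATG", out))

  # repair that could re-create an overlapping ATG must be rejected
  set.seed(11)
  for (i in 1:50) {
    s <- rand_seq(60)
    out <- strip_augs(s)
    expect_false(grepl("ATG", out))
    expect_equal(nchar(out), 60L)
  }
  expect_equal(strip_augs("ATGCCC", seed = 5), strip_augs("ATGCCC", seed = 5))
})

test_that("panel selection matches brute-force full-sort selection", {
  tab <- data.frame(transcript_id = paste0("t", 1:5),
                    te = c(5, 4, 3, 2, 1),
                    utr_seq = replicate(5, rand_seq(50)),
                    stringsAsFactors = FALSE)
  qt <- list(HEK293T = tab, PC3 = tab, muscle_te = tab)
  mr <- data.frame(transcript_id = paste0("t", 1:5), mrna = 1:5,
                   utr_seq = tab$utr_seq, stringsAsFactors = FALSE)
  spec <- panel_spec(hek293t = c(2L, 1L), pc3 = c(1L, 1L),
                     muscle_te = 2L, muscle_mrna = 1L)
  out <- select_natural_panels(qt, mr, spec)
  hek_top <- out[out$origin_context == "HEK293T" & out$panel == "top", ]
  expect_equal(hek_top$id, c("t1", "t2"))
  hek_bot <- out[out$origin_context == "HEK293T" & out$panel == "bottom", ]
  expect_equal(hek_bot$id, "t5")
  expect_equal(out[out$origin_context == "muscle_mrna", "id"], "t5")

  # zero-size panels are empty; oversize requests error with context
  empty <- select_natural_panels(
    qt, mr, panel_spec(c(0L, 0L), c(0L, 0L), 0L, 0L))
  expect_equal(nrow(empty), 0L)
  expect_error(select_natural_panels(
    qt, mr, panel_spec(c(9L, 0L), c(1L, 1L), 1L, 1L)), "HEK293T")

  # random tables: equals an independently coded full sort (with ties)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    tab <- data.frame(transcript_id = sprintf("t%02d", 1:n),
                      te = sample(1:8, n, replace = TRUE),
                      utr_seq = replicate(n, rand_seq(30)),
                      stringsAsFactors = FALSE)
    n_top <- sample(0:4, 1); n_bot <- sample(0:4, 1)
    out <- select_natural_panels(
      list(HEK293T = tab, PC3 = tab[1, ], muscle_te = tab[1, ]),
      data.frame(transcript_id = "x", mrna = 1, utr_seq = rand_seq(30)),
      panel_spec(c(n_top, n_bot), c(0L, 0L), 0L, 0L))
    srt <- tab[order(-tab$te, tab$transcript_id), ]
    expect_equal(out$id[out$panel == "top"],
                 head(srt$transcript_id, n_top))
    srt2 <- tab[order(tab$te, tab$transcript_id), ]
    expect_equal(out$id[out$panel == "bottom"],
                 head(srt2$transcript_id, n_bot))
  }
})

test_that("oligo assembly is a 140-nt round trip", {
  set.seed(6)
  man <- make_manifest(3)
  u <- man$records$sequence[1]
  oligo <- build_oligo(u, man$left_flank, man$right_flank)
  expect_equal(nchar(oligo), 140L)
  expect_equal(extract_insert(oligo, man$left_flank, man$right_flank), u)
  expect_error(build_oligo(substr(u, 1, 99), man$left_flank,
                           man$right_flank), "100 nt")
  expect_error(build_oligo(u, "ACGT", man$right_flank), "20 nt")
})

test_that("combinatorial members join two 100-mers with the linker", {
  set.seed(7)
  a <- utr_record("NeoUTR1", rand_member())
  b <- utr_record("NeoUTR2", rand_member())
  ab <- combine_utrs(a, b)
  expect_equal(nchar(ab$sequence), 206L)
  expect_equal(substr(ab$sequence, 1, 100), a$sequence)
  expect_equal(substr(ab$sequence, 107, 206), b$sequence)
  expect_equal(ab$source, "combinatorial")
  ba <- combine_utrs(b, a)
  expect_false(ab$sequence == ba$sequence)
  aa <- combine_utrs(a, a)
  expect_equal(substr(aa$sequence, 1, 100), substr(aa$sequence, 107, 206))
  expect_equal(nchar(combine_utrs(a, b, linker = "")$sequence), 200L)
  short <- utr_record("x", rand_member(99))
  expect_error(combine_utrs(a, short), "100-nt")
})

test_that("library composition sums panels and design sets", {
  comp <- library_composition()
  expect_equal(comp$n_natural, 8414L)
  expect_equal(comp$n_synthetic, 3586L)
  expect_equal(comp$n_total, 12000L)
})
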