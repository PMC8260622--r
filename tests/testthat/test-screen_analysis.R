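test_that("reads are assigned by flank-anchored exact matching", {
  set.seed(22)
  man <- make_manifest(3)
  mult <- c(50L, 30L, 20L)
  reads <- rep(paste0(man$left_flank, man$records$sequence,
                      man$right_flank), times = mult)
  mr <- match_reads(reads, man)
  expect_equal(unname(mr$counts), mult)
  expect_equal(mr$unassigned, 0L)
  expect_equal(sum(mr$counts) + mr$unassigned, length(reads))

  corrupt <- paste0("TTTTTTTTTTTTTTTTTTTT", man$records$sequence[1],
                    man$right_flank)
  mr2 <- match_reads(c(reads[1], corrupt), man)
  expect_equal(mr2$unassigned, 1L)
  expect_error(match_reads(reads, utr_manifest(man$records[0, ])))
})

test_that("one insert mismatch is tolerated only when unambiguous", {
  base <- strrep("ACGC", 25)
  near <- base
  substr(near, 50, 50) <- "T"   # distance 1 from base
  far <- strip_augs(strrep("GGCA", 25), seed = 1)
  man <- utr_manifest(data.frame(
    id = c("m1", "m2"), source = "natural", origin_context = "designed",
    sequence = c(base, far), stringsAsFactors = FALSE))
  read_near <- paste0(man$left_flank, near, man$right_flank)
  expect_equal(match_reads(read_near, man, max_mismatch = 0)$unassigned, 1L)
  mr <- match_reads(read_near, man, max_mismatch = 1)
  expect_equal(unname(mr$counts), c(1L, 0L))

  # ambiguous within distance 1 of two members -> unassigned
  twin <- base
  substr(twin, 50, 50) <- "G"   # base and twin are distance 1 apart
  man2 <- utr_manifest(data.frame(
    id = c("m1", "m3"), source = "natural", origin_context = "designed",
    sequence = c(base, twin), stringsAsFactors = FALSE))
  probe <- base
  substr(probe, 50, 50) <- "T"  # distance 1 from both base and twin
  mr2 <- match_reads(paste0(man2$left_flank, probe, man2$right_flank),
                     man2, max_mismatch = 1)
  expect_equal(mr2$unassigned, 1L)
})

test_that("size factors follow median-of-ratios with geometric reference", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 40), s2 = c(30, 60, 120))
  rownames(m2) <- c("a", "b", "c")
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(3), sqrt(3)))

  # homogeneity: a global rescaling cancels between counts and the
  # geometric-mean reference, so the factors are unchanged and the
  # relative normalized profile is preserved
  sf <- size_factors(m2)
  sf4 <- size_factors(m2 * 4)
  expect_equal(sf4, sf)
  expect_equal(normalize_counts(m2 * 4, sf4), 4 * normalize_counts(m2, sf))

  zeros <- matrix(c(0L, 0L, 1L, 0L), 2)
  expect_error(size_factors(zeros), "pseudocount")

  set.seed(23)
  for (i in 1:25) {
    mm <- matrix(rpois(40, 50), ncol = 4,
                 dimnames = list(paste0("u", 1:10), paste0("s", 1:4)))
    expect_equal(size_factors(mm), brute_force_size_factors(mm))
  }
})

test_that("log2 enrichment averages replicate ratios", {
  counts <- matrix(
    c(8, 8, 8, 8,
      32, 8, 8, 8), nrow = 2, byrow = TRUE,
    dimnames = list(c("u1", "u2"),
                    c("top2.5_rep1", "unsorted_rep1",
                      "top2.5_rep2", "unsorted_rep2")))
  md <- data.frame(sample = colnames(counts),
                   bin = c("top2.5", "unsorted", "top2.5", "unsorted"),
                   replicate = c(1, 1, 2, 2), stringsAsFactors = FALSE)
  lfc <- log2_enrichment(counts, md, "top2.5", pseudocount = 0)
  expect_equal(unname(lfc["u1"]), 0)
  expect_equal(unname(lfc["u2"]), 1)   # mean(log2(4), log2(1)) = 1
  expect_error(log2_enrichment(counts, md, "unsorted"), "differ")

  set.seed(24)
  norm <- matrix(runif(80, 1, 100), ncol = 4,
                 dimnames = list(paste0("u", 1:20), md$sample))
  got <- log2_enrichment(norm, md, "top2.5", pseudocount = 0.5)
  manual <- (log2((norm[, 1] + 0.5) / (norm[, 2] + 0.5)) +
               log2((norm[, 3] + 0.5) / (norm[, 4] + 0.5))) / 2
  expect_equal(got, manual)
})

test_that("NB Wald test recovers a planted four-fold enrichment", {
  set.seed(25)
  n <- 300
  mu <- 333   # depth 1e5 spread over the library
  counts <- cbind(
    b1 = rnbinom(n, mu = mu, size = 100),
    b2 = rnbinom(n, mu = mu, size = 100),
    u1 = rnbinom(n, mu = mu, size = 100),
    u2 = rnbinom(n, mu = mu, size = 100))
  counts[1:20, c("b1", "b2")] <-
    rnbinom(40, mu = 4 * mu, size = 100)
  rownames(counts) <- paste0("u", seq_len(n))
  counts[n, ] <- 0L
  md <- data.frame(sample = colnames(counts),
                   bin = c("top2.5", "top2.5", "unsorted", "unsorted"),
                   replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  res <- nb_test(counts, md, "top2.5")
  planted <- res[1:20, ]
  expect_lt(abs(mean(planted$log2fc) - 2), 0.3)
  expect_true(all(abs(planted$log2fc - 2) < 0.3 + 3 * planted$se))
  expect_gte(mean(abs(planted$log2fc - 2) < 0.3), 0.75)
  expect_true(all(planted$p < 0.01))
  expect_true(all(is.na(res[res$id == paste0("u", n),
                            c("log2fc", "p", "padj")])))
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
  expect_error(nb_test(counts[, c(1, 3)],
                       md[c(1, 3), ], "top2.5"), "2 replicates")
})

test_that("BH adjustment matches a hand-built step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(26)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p))
  }
})

test_that("hits require enrichment and significance in all three bins", {
  mk <- function(lfc, padj) {
    data.frame(id = paste0("u", seq_along(lfc)), base_mean = 100,
               log2fc = lfc, se = 0.1, p = padj / 2, padj = padj,
               stringsAsFactors = FALSE)
  }
  res <- list(
    top2.5   = mk(c(2.0, 1.5, 0.2, 1.0, -1.0), c(.001, .001, .001, .2, .001)),
    top2.5_5 = mk(c(1.8, 1.2, 0.1, 1.0, -0.5), c(.001, .01, .001, .2, .001)),
    top5_10  = mk(c(1.2, 0.9, 0.3, 1.0, -0.2), c(.001, .04, .001, .2, .001)))
  hits <- select_hits(res)
  expect_equal(hits$id[hits$hit], c("u1", "u2"))
  # u4 is enriched everywhere but significant nowhere
  expect_false(hits$hit[hits$id == "u4"])
  # degenerate thresholds: every non-negatively enriched member passes
  all_in <- select_hits(res, min_fold = 1, alpha = 1)
  expect_setequal(all_in$id[all_in$hit], c("u1", "u2", "u3", "u4"))
  expect_true(all(c("rationale", "above_log2_line") %in% names(hits)))
})

test_that("replicate correlation behaves on identical and scaled replicates", {
  set.seed(27)
  norm <- matrix(runif(40, 1, 100), ncol = 2,
                 dimnames = list(paste0("u", 1:20),
                                 c("top2.5_rep1", "top2.5_rep2")))
  md <- data.frame(sample = colnames(norm), bin = "top2.5",
                   replicate = 1:2, stringsAsFactors = FALSE)
  norm[, 2] <- norm[, 1]
  expect_equal(replicate_correlation(norm, md, "top2.5"), 1)
  # independent replicates decorrelate
  set.seed(28)
  big <- matrix(rpois(2000, 50), ncol = 2,
                dimnames = list(paste0("u", 1:1000),
                                c("top2.5_rep1", "top2.5_rep2")))
  mdb <- data.frame(sample = colnames(big), bin = "top2.5",
                    replicate = 1:2, stringsAsFactors = FALSE)
  expect_lt(abs(replicate_correlation(big, mdb, "top2.5")), 0.1)
  flat <- norm; flat[, 1] <- 5
  expect_error(replicate_correlation(flat, md, "top2.5"), "zero-variance")
})

test_that("category enrichment reproduces the contingency computation", {
  recs <- data.frame(
    id = c(paste0("syn", 1:2388), paste0("nat", 1:8414)),
    source = rep(c("synthetic_high_te", "natural"), c(2388, 8414)),
    stringsAsFactors = FALSE)
  hits <- c(paste0("syn", 1:6), paste0("nat", 1:7))
  enr <- category_enrichment(hits, recs)
  expect_equal(enr, 100 * (6 / 2388) / (7 / 8414))
  expect_equal(round(enr, 1), 302)
  expect_equal(round(enr, -2), 300)

  # equal hit rates give parity
  recs2 <- data.frame(id = paste0("u", 1:40),
                      source = rep(c("synthetic_high_te", "natural"),
                                   each = 20), stringsAsFactors = FALSE)
  expect_equal(category_enrichment(paste0("u", c(1:2, 21:22)), recs2), 100)
  expect_true(is.na(category_enrichment(paste0("u", 1:2), recs2)))

  set.seed(29)
  for (i in 1:20) {
    n <- 60
    recs3 <- data.frame(id = paste0("u", 1:n),
                        source = sample(c("synthetic_high_te", "natural"),
                                        n, replace = TRUE),
                        stringsAsFactors = FALSE)
    if (length(unique(recs3$source)) < 2) next
    hits3 <- sample(recs3$id, 20)
    h_in <- sum(hits3 %in% recs3$id[recs3$source == "synthetic_high_te"])
    n_in <- sum(recs3$source == "synthetic_high_te")
    h_out <- 20 - h_in
    n_out <- n - n_in
    want <- if (h_out == 0) NA_real_ else
      100 * (h_in / n_in) / (h_out / n_out)
    expect_equal(category_enrichment(hits3, recs3), want)
  }
})

test_that("normalization and NB results agree with DESeq2 as reference", {
  set.seed(34)
  counts <- matrix(rnbinom(200 * 4, mu = rep(c(60, 300), 400),
                           size = 20), ncol = 4,
                   dimnames = list(paste0("u", 1:200),
                                   c("b1", "b2", "c1", "c2")))
  counts[3, ] <- 0L
  sf <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)

  counts[4:18, 1:2] <- matrix(rnbinom(30, mu = 4 * 180, size = 20), 15)
  md <- data.frame(sample = colnames(counts),
                   bin = c("top2.5", "top2.5", "unsorted", "unsorted"),
                   replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  mine <- nb_test(counts, md, "top2.5")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(condition = factor(c("bin", "bin", "ctl", "ctl"),
                                          levels = c("ctl", "bin"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- as.data.frame(DESeq2::results(dds))
  ok <- !is.na(mine$log2fc) & !is.na(dres$log2FoldChange)
  expect_gt(cor(mine$log2fc[ok], dres$log2FoldChange[ok]), 0.95)
  # both pipelines flag the planted block as the strongest enrichments
  expect_true(all(order(-mine$log2fc)[1:10] %in%
                    c(4:18, order(-dres$log2FoldChange)[1:15])))
})
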