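toy_catalog <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r[[1]], gene_id = sub("^t", "g", r[[1]]),
               chrom = "chr1", start = 1000, end = 1000 + as.integer(r[[2]]),
               strand = r[[3]], exon_count = 1L,
               spliced_length = as.integer(r[[2]]), class_code = r[[4]],
               sequence = NA_character_, stringsAsFactors = FALSE)
  }))
}

test_that("basic filter applies the length, strand and class-code rules", {
  cat1 <- toy_catalog(list("t1", 150, "+", "u"),   # too short
                      list("t2", 500, "+", "j"),   # wrong class code
                      list("t3", 200, "+", "x"),   # boundary: 200 bp retained
                      list("t4", 500, ".", "u"),   # unstranded
                      list("t5", 300, "-", "i"))
  kept <- basic_filter(cat1)
  expect_setequal(kept$transcript_id, c("t3", "t5"))
  # raising the length threshold never adds candidates
  expect_true(all(basic_filter(cat1, min_length = 400)$transcript_id %in%
                  kept$transcript_id))
})

test_that("known-set matching is exact by default and strict on mismatches", {
  cand <- toy_catalog(list("t1", 8, "+", "u"), list("t2", 8, "+", "u"),
                      list("t3", 8, "+", "u"))
  cand$sequence <- c("ACGTACGT", "ACGTACGA", NA)
  ref <- Biostrings::DNAStringSet(c(k1 = "ACGTACGT"))
  expect_warning(m <- match_known(cand, ref), "without sequence")
  expect_identical(m$known$transcript_id, "t1")     # byte-identical
  expect_true("t2" %in% m$remainder$transcript_id)  # one mismatched base
  # relaxed identity admits the near-match
  expect_warning(m2 <- match_known(cand, ref, identity_min = 0.8))
  expect_setequal(m2$known$transcript_id, c("t1", "t2"))
  # empty reference: everything stays in the remainder
  m3 <- match_known(cand[1:2, ], Biostrings::DNAStringSet())
  expect_identical(nrow(m3$known), 0L)
})

test_that("coding consensus honours strict inequalities and both Pfam modes", {
  cand <- toy_catalog(list("t1", 300, "+", "u"), list("t2", 300, "+", "u"),
                      list("t3", 300, "+", "u"), list("t4", 300, "+", "u"))
  scores <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    cnci = c(-0.5, 0, -1, -1), cpc = c(-1.2, -1, -1, -1),
    plek = c(-0.1, -1, -1, -1), pfam_evalue = c(1e-7, 1e-7, 0.5, 1e-5),
    stringsAsFactors = FALSE)
  printed <- coding_consensus(cand, scores, pfam_logic = "as_printed")
  expect_identical(printed$transcript_id, "t1")     # t2: cnci = 0 excluded;
  # t3: large E-value fails the literal rule; t4: 1e-5 fails "< 1e-5"
  nohit <- coding_consensus(cand, scores, pfam_logic = "no_hit_required")
  expect_setequal(nohit$transcript_id, c("t3", "t4"))
  # a transcript missing a required score is excluded
  scores$plek[1] <- NA
  expect_identical(nrow(coding_consensus(cand[1, ], scores)), 0L)
})

test_that("the cascade is a refinement chain with disjoint known/putative sets", {
  ts <- simulate_transcript_set(n = 400, seed = 11)
  cat1 <- build_lncrna_catalog(ts$catalog, ts$reference, ts$scores,
                               pfam_logic = "no_hit_required")
  survivors <- basic_filter(ts$catalog)$transcript_id
  expect_true(all(cat1$transcript_id %in% survivors))
  expect_identical(anyDuplicated(cat1$transcript_id), 0L)
  expect_true(all(cat1$spliced_length >= 200))
  expect_true(all(cat1$strand %in% c("+", "-")))
  expect_true(all(cat1$class_code %in% c("i", "u", "x")))
  expect_identical(
    length(intersect(cat1$transcript_id[cat1$status == "known"],
                     cat1$transcript_id[cat1$status == "putative"])), 0L)
})

test_that("well-separated score distributions are recovered almost perfectly", {
  ts <- simulate_transcript_set(n = 600, seed = 12, score_separation = 4)
  cand <- basic_filter(ts$catalog)
  rem <- match_known(cand, ts$reference)$remainder
  put <- coding_consensus(rem, ts$scores, pfam_logic = "no_hit_required")
  truth <- ts$truth
  truly_nc <- truth$transcript_id[!truth$coding & !truth$known &
                                  truth$passes_basic]
  tp <- length(intersect(put$transcript_id, truly_nc))
  precision <- tp / nrow(put)
  recall <- tp / length(truly_nc)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("positional classes map from codes with a coordinate fallback", {
  cat1 <- toy_catalog(list("t1", 300, "+", "u"), list("t2", 300, "+", "i"),
                      list("t3", 300, "+", "x"))
  expect_identical(positional_class(cat1), c("intergenic", "intronic", "antisense"))

  # fallback for "." codes against an annotation: gene g spans 1..10000 with
  # exons 1..1000 and 9000..10000 on "+"
  genes <- data.frame(gene_id = c("g", "g", "g"), chrom = "chr1",
                      start = c(1, 1, 9000), end = c(10000, 1000, 10000),
                      strand = "+", is_exon = c(FALSE, TRUE, TRUE))
  fb <- data.frame(transcript_id = c("n1", "n2", "n3"), gene_id = NA,
                   chrom = "chr1", start = c(2000, 500, 20000),
                   end = c(3000, 1500, 21000), strand = c("+", "-", "+"),
                   exon_count = 1L, spliced_length = 1000L, class_code = ".",
                   sequence = NA, stringsAsFactors = FALSE)
  expect_identical(positional_class(fb, genes),
                   c("intronic", "antisense", "intergenic"))
})

test_that("catalog summaries are normalised percentages", {
  cat1 <- toy_catalog(list("t1", 300, "+", "u"), list("t2", 400, "+", "u"),
                      list("t3", 500, "-", "i"))
  cat1$chrom <- c("chr1", "chr1", "chr2")
  s <- summarize_catalog(cat1)
  expect_equal(s$chrom_dist$percent[s$chrom_dist$chrom == "chr1"], 200 / 3)
  for (tab in s) expect_equal(sum(tab$percent), 100)
  s1 <- summarize_catalog(cat1[1, ])
  expect_true(all(vapply(s1, function(t) sum(t$n == 1) == 1, logical(1))))
  expect_error(summarize_catalog(cat1[0, ]), "empty")
})

test_that("target pairs split into cis and trans by distance", {
  lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
                    start = 100000, end = 101000, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gNear", "gFar", "gOther", "gWeak"),
                      chrom = c("chr1", "chr1", "chr2", "chr1"),
                      start = c(111000, 601000, 100000, 111000),
                      end = c(112000, 602000, 101000, 112000),
                      stringsAsFactors = FALSE)
  n_samp <- 10
  counts <- withr::with_seed(41, {
    base <- rnorm(n_samp)
    mk <- function(x) as.integer(round(2^(x + 6)))
    # constant housekeeping features keep the size factors at 1, so the
    # planted correlations survive normalisation
    hk <- matrix(rep(seq(50, 500, by = 10), each = n_samp),
                 ncol = n_samp, byrow = TRUE,
                 dimnames = list(paste0("hk", 1:46), NULL))
    rbind(L1 = mk(base),
          gNear = mk(base + rnorm(n_samp, sd = 0.01)),
          gFar = mk(-base + rnorm(n_samp, sd = 0.01)),
          gOther = mk(base + rnorm(n_samp, sd = 0.01)),
          gWeak = mk(rnorm(n_samp)),
          hk)
  })
  colnames(counts) <- paste0("s", 1:n_samp)
  pairs <- predict_targets(lnc, genes, counts, window = 1e5, r_min = 0.9)
  expect_setequal(pairs$gene_id, c("gNear", "gFar", "gOther"))
  expect_identical(pairs$mode[pairs$gene_id == "gNear"], "cis")    # 10 kb gap
  expect_identical(pairs$mode[pairs$gene_id == "gFar"], "trans")   # 500 kb gap
  expect_identical(pairs$mode[pairs$gene_id == "gOther"], "trans") # other chrom
  expect_identical(pairs$distance[pairs$gene_id == "gOther"], Inf)
  expect_false("gWeak" %in% pairs$gene_id)                         # |r| below 0.9
  # distance is symmetric in the two partners
  rev_pairs <- predict_targets(
    data.frame(transcript_id = "gNear", chrom = "chr1", start = 111000, end = 112000),
    data.frame(gene_id = "L1", chrom = "chr1", start = 100000, end = 101000),
    counts, window = 1e5, r_min = 0.9)
  expect_identical(rev_pairs$distance, pairs$distance[pairs$gene_id == "gNear"])
  # constant expression rows are skipped with a warning
  counts2 <- rbind(counts, gConst = rep(5L, n_samp))
  genes2 <- rbind(genes, data.frame(gene_id = "gConst", chrom = "chr1",
                                    start = 1, end = 10))
  expect_warning(predict_targets(lnc, genes2, counts2), "constant")
})
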