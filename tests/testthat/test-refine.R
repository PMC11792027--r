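jx_fix <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], donor = as.integer(r[[2]]),
               acceptor = as.integer(r[[3]]), strand = r[[4]],
               support = as.integer(r[[5]]), stringsAsFactors = FALSE)
  }))
}

test_that("deletion filter removes strictly above the threshold", {
  reads <- reads_fix(read_fix("a", "chr1", "+", 0, 100, del = 101),
                     read_fix("b", "chr1", "+", 0, 100, del = 100),
                     read_fix("c", "chr1", "+", 0, 100, del = 0))
  kept <- filter_by_deletion(reads)
  expect_equal(kept$read_id, c("b", "c"))
})

test_that("TSS filter is a half-open point-in-peak test", {
  peaks <- data.frame(chrom = "chr1", start = 500L, end = 700L, name = "p1")
  r_in <- reads_fix(read_fix("in", "chr1", "+", 600, 900))
  r_edge <- reads_fix(read_fix("edge", "chr1", "+", 700, 900))
  r_start <- reads_fix(read_fix("s", "chr1", "+", 500, 900))
  expect_equal(nrow(filter_by_tss(r_in, peaks)), 1L)
  expect_equal(nrow(filter_by_tss(r_edge, peaks)), 0L)
  expect_equal(nrow(filter_by_tss(r_start, peaks)), 1L)
  # minus strand: the 5' end is the right end
  r_minus <- reads_fix(read_fix("m", "chr1", "-", 100, 600))
  expect_equal(nrow(filter_by_tss(r_minus, peaks)), 1L)
  # empty peak set removes everything
  expect_equal(nrow(filter_by_tss(r_in, peaks[0, ])), 0L)
})

test_that("junction correction snaps within the window and rejects outside it", {
  read <- reads_fix(read_fix("r", "chr1", "+", c(900, 2000), c(1000, 2100)))
  # acceptor offset 14 within the default +/-15 window
  cor <- correct_reads(read, jx_fix(list("chr1", 1000, 2014, "+", 5)))
  expect_equal(cor$status, "corrected")
  expect_equal(cor$block_starts[[1]], c(900L, 2014L))
  # boundary: offset exactly 15 still snaps
  cor15 <- correct_reads(read, jx_fix(list("chr1", 1000, 2015, "+", 5)))
  expect_equal(cor15$status, "corrected")
  expect_equal(cor15$block_starts[[1]][2], 2015L)
  # offset 16 has no eligible match -> rejected
  cor16 <- correct_reads(read, jx_fix(list("chr1", 1000, 2016, "+", 5)))
  expect_equal(cor16$status, "rejected")
  # support 2 is below the eligibility floor -> rejected
  cor_lo <- correct_reads(read, jx_fix(list("chr1", 1000, 2014, "+", 2)))
  expect_equal(cor_lo$status, "rejected")
  # support exactly 3 is eligible
  cor3 <- correct_reads(read, jx_fix(list("chr1", 1000, 2014, "+", 3)))
  expect_equal(cor3$status, "corrected")
  # an exact match leaves the read unchanged
  cor_eq <- correct_reads(read, jx_fix(list("chr1", 1000, 2000, "+", 5)))
  expect_equal(cor_eq$status, "unchanged")
})

test_that("snap target minimizes max offset, then support, then donor", {
  read <- reads_fix(read_fix("r", "chr1", "+", c(900, 2000), c(1000, 2100)))
  # candidate at max-offset 4 beats one at 10 despite lower support
  jt <- jx_fix(list("chr1", 1004, 2004, "+", 3), list("chr1", 1010, 2000, "+", 50))
  cor <- correct_reads(read, jt)
  expect_equal(cor$block_ends[[1]][1], 1004L)
  # equal score: higher support wins
  jt2 <- jx_fix(list("chr1", 1005, 2000, "+", 3), list("chr1", 995, 2000, "+", 9))
  cor2 <- correct_reads(read, jt2)
  expect_equal(cor2$block_ends[[1]][1], 995L)
  # equal score and support: smaller donor wins
  jt3 <- jx_fix(list("chr1", 1005, 2000, "+", 7), list("chr1", 995, 2000, "+", 7))
  cor3 <- correct_reads(read, jt3)
  expect_equal(cor3$block_ends[[1]][1], 995L)
})

test_that("correction that would create a degenerate exon rejects the read", {
  # middle exon is 10 bp; snapping both sides inward by > 5 bp inverts it
  read <- reads_fix(read_fix("r", "chr1", "+", c(0, 1000, 1010 + 500),
                             c(900, 1010, 2200)))
  jt <- jx_fix(list("chr1", 900, 1008, "+", 9), list("chr1", 1002, 1510, "+", 9))
  cor <- correct_reads(read, jt)
  expect_equal(cor$status, "rejected")
  expect_match(cor$reject_reason, "degenerate")
})

test_that("mono-exonic reads pass correction unchanged", {
  read <- reads_fix(read_fix("r", "chr1", "+", 100, 600))
  cor <- correct_reads(read, jx_fix(list("chr1", 1000, 2000, "+", 5)))
  expect_equal(cor$status, "unchanged")
})

test_that("collapse groups exact chains, takes median ends, drops weak groups", {
  starts <- c(1000, 1001, 999, 1000, 1000)
  rows <- lapply(seq_along(starts), function(i) {
    read_fix(sprintf("r%d", i), "chr1", "+", c(starts[i], 2000), c(1500, 2600))
  })
  coll <- collapse_reads(do.call(reads_fix, rows))
  tx <- transcripts(coll$annotation)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$start, 1000L)
  expect_equal(unname(coll$support), 5L)

  # two reads are below the default support of 3
  coll2 <- collapse_reads(do.call(reads_fix, rows[1:2]))
  expect_equal(nrow(transcripts(coll2$annotation)), 0L)

  # two chains sharing exons collapse to two transcripts of one gene
  rows_b <- lapply(6:9, function(i) {
    read_fix(sprintf("r%d", i), "chr1", "+", c(1000, 1800, 2300),
             c(1500, 2000, 2600))
  })
  coll3 <- collapse_reads(do.call(reads_fix, c(rows, rows_b)))
  tx3 <- transcripts(coll3$annotation)
  expect_equal(nrow(tx3), 2L)
  expect_equal(length(unique(tx3$gene_id)), 1L)
})

test_that("end clustering ignores a small far-out cluster", {
  starts <- c(1000, 1002, 998, 3000)
  rows <- lapply(seq_along(starts), function(i) {
    read_fix(sprintf("r%d", i), "chr1", "+", c(starts[i], 4000), c(3500, 4600))
  })
  coll <- collapse_reads(do.call(reads_fix, rows))
  expect_equal(transcripts(coll$annotation)$start, 1000L)
})

test_that("filters are idempotent and commute", {
  set.seed(42)
  rows <- lapply(1:40, function(i) {
    s <- sample(0:5000, 1)
    read_fix(sprintf("r%d", i), "chr1", sample(c("+", "-"), 1),
             c(s, s + 600), c(s + 200, s + 900),
             del = sample(0:200, 1))
  })
  reads <- do.call(reads_fix, rows)
  peaks <- data.frame(chrom = "chr1", start = seq(0, 5800, by = 400),
                      end = seq(0, 5800, by = 400) + 150,
                      name = paste0("p", 1:15))
  p <- correction_params()
  a <- filter_by_tss(filter_by_deletion(reads, p), peaks)
  b <- filter_by_deletion(filter_by_tss(reads, peaks), p)
  expect_equal(a$read_id, b$read_id)
  expect_equal(filter_by_deletion(a, p)$read_id, a$read_id)
  expect_equal(filter_by_tss(a, peaks)$read_id, a$read_id)
})

test_that("jittered reads recover the true intron chain after correction", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_genes = 10, psi_n_genes = 2, seed = 5), d)
  reads <- read_reads(sim$paths$reads)
  jt <- read_junctions(sim$paths$junctions)
  cor <- correct_reads(reads, jt)
  ok <- which(cor$status != "rejected" & lengths(cor$block_starts) > 1L)
  expect_gt(length(ok), 1000L)
  truth_key_of_read <- sim$truth$chain_keys[
    sim$truth$read_origin$transcript_id[match(cor$read_id[ok],
                                              sim$truth$read_origin$read_id)]]
  got <- vapply(ok, function(i) read_chain_key(cor, i), character(1))
  expect_equal(unname(got), unname(truth_key_of_read))
})

test_that("collapse of noiseless reads reproduces the simulated chains exactly", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 10, psi_n_genes = 2, junction_jitter_sd = 0,
                    tss_truncation_prob = 0, seed = 6)
  sim <- simulate_dataset(cfg, d)
  reads <- read_reads(sim$paths$reads)
  coll <- collapse_reads(correct_reads(reads, read_junctions(sim$paths$junctions)))
  expect_setequal(unname(intron_chains(coll$annotation)),
                  unname(sim$truth$chain_keys))
})
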