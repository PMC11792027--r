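m6a_fix <- function(site_rows) {
  # site_rows: list of list(site parts..., sample, modified, total)
  do.call(rbind, lapply(site_rows, as.data.frame))
}

test_that("DRACH matching follows the degenerate motif definition", {
  # GGACT: D=G, R=G, A, C, H=T -> match; GGACG fails (H may not be G)
  hit <- drach_sites("TTGGACTTT")
  expect_equal(nrow(hit[hit$strand == "+", ]), 1L)
  expect_equal(hit$pos[hit$strand == "+"], 4L)   # 0-based A position
  expect_equal(hit$motif[hit$strand == "+"], "GGACT")
  miss <- drach_sites("TTGGACGTT")
  expect_equal(nrow(miss[miss$strand == "+", ]), 0L)
  # a minus-strand motif appears as its reverse complement on the forward seq
  rc <- revcomp_chr("GGACT")
  hit_m <- drach_sites(paste0("TTT", rc, "TTT"))
  expect_equal(hit_m$strand, "-")
  expect_equal(hit_m$motif, "GGACT")
  expect_equal(hit_m$pos, 5L)  # centre of the 5-mer at offset 3..7
})

test_that("scanner equals the regex oracle on random sequences, both strands", {
  set.seed(91)
  for (i in 1:10) {
    s <- random_dna(3000)
    got <- drach_sites(s)
    exp <- drach_oracle(s)
    exp <- exp[order(exp$pos, exp$strand), ]
    expect_equal(got$pos, exp$pos, info = paste("seq", i))
    expect_equal(got$strand, exp$strand, info = paste("seq", i))
  }
})

test_that("genome scan is restricted to exons of the matching strand and clips regions", {
  genome <- c(chr1 = paste0("AA", "GGACT", paste(rep("T", 20), collapse = ""),
                            "GGACT", "AA"))
  # exon covers only the first motif; second motif is intronic/intergenic
  ann <- ann_fix(tx_fix("t1", "g1", "chr1", "+", list(c(0, 12))))
  sites <- scan_drach(genome, ann, flank = 10)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 4L)
  expect_equal(sites$region_start, 0L)       # clipped at the chromosome start
  expect_equal(sites$region_end, 15L)
  expect_equal(sites$region_end - sites$region_start, 15L)  # clipped from 21
  # the same exon on the minus strand matches nothing (motif is plus-strand)
  ann_m <- ann_fix(tx_fix("t1", "g1", "chr1", "-", list(c(0, 12))))
  expect_equal(nrow(scan_drach(genome, ann_m)), 0L)
})

test_that("coverage and recurrence filters behave at their boundaries", {
  rows <- function(site, mods, tots) {
    lapply(seq_along(mods), function(i) {
      list(chrom = "chr1", pos = 10L, strand = "+", motif = "GGACT",
           site = site, sample = sprintf("s%d", i),
           modified = mods[i], total = tots[i])
    })
  }
  counts <- m6a_fix(c(
    rows("low_cov", c(1, 1, 1, 1), c(4, 4, 4, 4)),       # coverage 4 everywhere
    rows("one_sample", c(3, 0, 0, 0), c(50, 50, 50, 50)), # modified in 1 sample
    rows("boundary", c(1, 1, 0, 0), c(5, 5, 4, 4)),       # exactly at both floors
    rows("good", c(5, 6, 4, 3), c(50, 50, 50, 50))
  ))
  kept <- unique(filter_m6a_sites(counts)$site)
  expect_setequal(kept, c("boundary", "good"))
  # monotone: raising either threshold never adds sites
  expect_true(all(unique(filter_m6a_sites(counts, min_coverage = 10)$site) %in% kept))
  expect_true(all(unique(filter_m6a_sites(counts, min_samples = 3)$site) %in% kept))
  expect_setequal(unique(filter_m6a_sites(counts, min_samples = 3)$site), "good")
})

test_that("differential modification: fold gate, oracle p and untestable sites", {
  conds <- c(s1 = "fed", s2 = "fed", s3 = "fasting", s4 = "fasting")
  mk <- function(site, mods, tots) {
    m6a_fix(lapply(1:4, function(i) {
      list(chrom = "chr1", pos = 10L, strand = "+", motif = "GGACT",
           site = site, sample = sprintf("s%d", i),
           modified = mods[i], total = tots[i])
    }))
  }
  flat <- diff_m6a(mk("a", c(5, 5, 5, 5), c(50, 50, 50, 50)), conds, "fed", "fasting")
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$significant)

  # frequencies 0.10 vs 0.12: below the fold-change gate regardless of p
  mild <- diff_m6a(mk("b", c(50, 50, 60, 60), c(500, 500, 500, 500)),
                   conds, "fed", "fasting")
  expect_lt(abs(mild$log2fc), 0.5)
  expect_false(mild$significant)

  strong <- diff_m6a(mk("c", c(20, 20, 5, 5), c(50, 50, 50, 50)),
                     conds, "fed", "fasting")
  expect_true(strong$significant)
  expect_equal(strong$p_value, fisher_oracle(40, 60, 10, 90), tolerance = 1e-9)

  # zero coverage in one condition is untestable
  zero <- diff_m6a(mk("d", c(5, 5, 0, 0), c(50, 50, 0, 0)), conds, "fed", "fasting")
  expect_false(zero$testable)
  expect_false(zero$significant)
})

test_that("metagene positions honor the 5UTR/CDS/3UTR segment bases", {
  # plus strand: exons (0,100) and (200,300); transcript length 200
  # 5'UTR = first 40 nt, CDS = 100 nt, 3'UTR = 60 nt
  cds <- data.frame(transcript_id = "t1", start = c(40, 200), end = c(100, 240))
  ann <- ann_fix(tx_fix("t1", "g1", "chr1", "+", list(c(0, 100), c(200, 300))),
                 cds = cds)
  mk_site <- function(pos) data.frame(site = sprintf("chr1:%d:+", pos),
                                      chrom = "chr1", pos = pos, strand = "+")
  # CDS midpoint: transcript coordinate 40 + 50 -> genomic 90
  expect_equal(metagene(mk_site(90), ann)$relative, 1.5)
  expect_equal(metagene(mk_site(90), ann)$segment, "CDS")
  # first base of the 3'UTR: transcript coordinate 140 -> genomic 240
  expect_equal(metagene(mk_site(240), ann)$relative, 2.0)
  expect_equal(metagene(mk_site(240), ann)$segment, "3UTR")
  # 5'UTR midpoint
  expect_equal(metagene(mk_site(20), ann)$relative, 0.5)
  # a site in the intron is skipped and counted
  m <- metagene(mk_site(150), ann)
  expect_equal(nrow(m), 0L)
  expect_equal(attr(m, "n_skipped"), 1L)
})

test_that("metagene positions are correct on the minus strand and stay in [0,3)", {
  # minus strand: transcript runs right-to-left; exons (0,100),(200,300)
  # transcript coords: genomic 299 is position 0
  cds <- data.frame(transcript_id = "t1", start = c(60, 200), end = c(100, 260))
  ann <- ann_fix(tx_fix("t1", "g1", "chr1", "-", list(c(0, 100), c(200, 300))),
                 cds = cds)
  mk_site <- function(pos) data.frame(site = sprintf("chr1:%d:-", pos),
                                      chrom = "chr1", pos = pos, strand = "-")
  # 5'UTR is genomic (260,300): 40 nt; CDS 100 nt; 3'UTR 60 nt
  expect_equal(metagene(mk_site(259), ann)$segment, "CDS")
  expect_equal(metagene(mk_site(259), ann)$relative, 1.0)
  expect_equal(metagene(mk_site(59), ann)$segment, "3UTR")
  expect_equal(metagene(mk_site(59), ann)$relative, 2.0)
  for (pos in c(0, 30, 65, 99, 205, 230, 280, 299)) {
    r <- metagene(mk_site(pos), ann)$relative
    expect_true(r >= 0 && r < 3)
  }
})

test_that("m6A counts table round-trips through disk", {
  counts <- data.frame(chrom = "chr1", pos = c(10L, 10L), strand = "+",
                       motif = "GGACT", sample = c("s1", "s2"),
                       modified = c(3L, 0L), total = c(20L, 25L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_m6a_counts(counts, f)
  back <- read_m6a_counts(f)
  expect_equal(back$modified, counts$modified)
  expect_equal(back$site, rep("chr1:10:+", 2))
})
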