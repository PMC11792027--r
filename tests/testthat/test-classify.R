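# Reference gene used throughout: g-ref on chr1 +, three exons
ref3 <- function() {
  ann_fix(tx_fix("ref1", "gref", "chr1", "+",
                 list(c(100, 200), c(300, 400), c(500, 600))))
}

test_that("self-comparison yields '=' for every transcript, mono-exonic included", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("t3", "g2", "chr1", "-", list(c(1000, 1500)))
  )
  cls <- assign_class_codes(ann, ann)
  expect_true(all(cls$code == "="))
  expect_true(all(cls$category == "matched"))
})

test_that("each class code arises from its defining geometry", {
  ref <- ref3()
  q <- function(...) ann_fix(tx_fix("q", "gq", "chr1", ...))

  # '=': identical chain, different ends
  expect_equal(assign_class_codes(
    ann_fix(tx_fix("q", "gq", "chr1", "+",
                   list(c(120, 200), c(300, 400), c(500, 580)))), ref)$code, "=")
  # 'c': contiguous sub-chain of the reference
  expect_equal(assign_class_codes(
    q("+", list(c(150, 200), c(300, 400))), ref)$code, "c")
  # 'k': reference chain contained in the query chain
  expect_equal(assign_class_codes(
    q("+", list(c(50, 80), c(100, 200), c(300, 400), c(500, 600))),
    ref)$code, "k")
  # 'j': one shared junction, chains differ
  expect_equal(assign_class_codes(
    q("+", list(c(100, 200), c(300, 450), c(500, 600))), ref)$code, "j")
  # 'e': mono-exonic query overlapping a reference exon
  expect_equal(assign_class_codes(q("+", list(c(150, 350))), ref)$code, "e")
  # 'i': query fully inside a reference intron
  expect_equal(assign_class_codes(q("+", list(c(210, 290))), ref)$code, "i")
  # 'o': same-strand exonic overlap not otherwise classified
  expect_equal(assign_class_codes(
    q("+", list(c(150, 250), c(270, 290), c(310, 350))), ref)$code, "o")
  # 'x': opposite-strand exonic overlap
  expect_equal(assign_class_codes(q("-", list(c(150, 350))), ref)$code, "x")
  # 'u': no overlap at all -> novel gene
  cls_u <- assign_class_codes(q("+", list(c(5000, 5400))), ref)
  expect_equal(cls_u$code, "u")
  expect_true(cls_u$novel_gene)
  expect_true(is.na(cls_u$ref_id))
})

test_that("the three categories partition all fifteen accepted codes", {
  codes <- c("=", "c", "j", "e", "i", "o", "x", "y", "u", "m", "n", "k", "s", "p", "r")
  cat <- class_code_category(codes)
  expect_false(anyNA(cat))
  expect_setequal(unique(cat), c("matched", "different", "others"))
  expect_equal(sum(cat == "matched"), 1L)
  expect_equal(sum(cat == "different"), 7L)
  expect_equal(sum(cat == "others"), 7L)
  expect_error(class_code_category("z"), "unknown")
})

test_that("every query receives exactly one code against a randomized reference", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_genes = 8, psi_n_genes = 2, seed = 21), d)
  ref <- sim$truth$annotation
  # query: a mixture of copied, truncated and shifted models
  ex <- ref$exons
  shifted <- ex
  shifted$start <- shifted$start + 50L
  shifted$end <- shifted$end + 50L
  shifted$transcript_id <- paste0(shifted$transcript_id, "_s")
  query <- annotation(rbind(ex, shifted))
  cls <- assign_class_codes(query, ref)
  expect_equal(nrow(cls), length(unique(query$exons$transcript_id)))
  expect_true(all(cls$code %in% c("=", "c", "k", "j", "e", "i", "o", "x", "u")))
  expect_false(anyNA(cls$category))
})

test_that("tissue-specific transcripts occur in exactly one tissue", {
  shared <- tx_fix("s1", "g1", "chr1", "+", list(c(100, 200), c(300, 400)))
  kid_only <- tx_fix("k1", "g1", "chr1", "+", list(c(100, 200), c(350, 400)))
  liv_only <- tx_fix("l1", "g1", "chr1", "+", list(c(100, 250), c(300, 400)))
  kidney <- ann_fix(shared, kid_only)
  liver <- ann_fix(shared, liv_only)
  heart <- ann_fix(shared)
  sp <- find_tissue_specific(list(kidney = kidney, liver = liver, heart = heart))
  expect_equal(lengths(sp), c(kidney = 1L, liver = 1L, heart = 0L))
  expect_match(sp$kidney, "200-350")
  # pairwise disjoint
  expect_length(intersect(sp$kidney, sp$liver), 0L)
  # identical annotations have empty specific sets
  sp2 <- find_tissue_specific(list(a = kidney, b = kidney))
  expect_equal(unname(lengths(sp2)), c(0L, 0L))
  expect_error(find_tissue_specific(list(a = kidney)), "two tissues")
})

test_that("dominant transcript is the most expressed per gene with stated tie rule", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200))),
    tx_fix("t3", "g2", "chr1", "+", list(c(1000, 1200))),
    tx_fix("t4", "g2", "chr1", "+", list(c(1000, 1300))),
    tx_fix("t5", "g3", "chr1", "+", list(c(2000, 2300)))
  )
  counts <- matrix(c(10, 5, 7, 7, 0,
                     2, 1, 3, 3, 0),
                   ncol = 2, dimnames = list(paste0("t", 1:5), c("s1", "s2")))
  dom <- find_dominant(ann, counts, c("s1", "s2"))
  expect_equal(dom[["g1"]], "t1")
  expect_equal(dom[["g2"]], "t3")   # tie 10 vs 10 -> lexicographically smaller
  expect_false("g3" %in% names(dom))  # all-zero gene omitted
})

test_that("longest ORF translation matches direct cases and the brute-force oracle", {
  expect_equal(longest_orf("ATGAAATAG"), list(length = 2L, protein = "MK"))
  expect_equal(longest_orf("CCCCCCCCC")$length, 0L)
  expect_equal(longest_orf("ATGAAACCC")$length, 0L)  # no in-frame stop
  # embedded known ORF in random context
  set.seed(77)
  orf <- paste0("ATG", paste(rep("GCT", 400), collapse = ""), "TAA")
  flank1 <- gsub("A", "C", random_dna(300))  # no ATG, no stop possible
  seq <- paste0(flank1, orf, gsub("A", "C", random_dna(200)))
  res <- longest_orf(seq)
  expect_equal(res$length, 401L)
  expect_equal(substr(res$protein, 1, 1), "M")
  # oracle equality on random sequences
  for (i in 1:15) {
    s <- random_dna(600)
    expect_equal(longest_orf(s)$length, orf_oracle(s), info = paste("seq", i))
  }
})

test_that("transcript sequences are spliced and strand-corrected", {
  genome <- list(chr1 = paste(rep("ACGT", 300), collapse = ""))
  ann <- ann_fix(
    tx_fix("p", "g", "chr1", "+", list(c(0, 4), c(8, 12))),
    tx_fix("m", "g2", "chr1", "-", list(c(0, 4), c(8, 12)))
  )
  expect_equal(transcript_sequence(ann, genome, "p"), "ACGTACGT")
  expect_equal(transcript_sequence(ann, genome, "m"),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTACGT"))))
})
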