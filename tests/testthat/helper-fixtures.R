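# Fixture builders and independent oracles. Oracles are deliberately written
# from first principles (enumeration / brute force) and never call the code
# paths they check.

# -- annotation builder ------------------------------------------------------
tx_fix <- function(tid, gid, chrom, strand, exons) {
  do.call(rbind, lapply(exons, function(e) {
    data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
               strand = strand, start = e[1L], end = e[2L],
               stringsAsFactors = FALSE)
  }))
}

ann_fix <- function(..., cds = NULL) {
  annotation(do.call(rbind, list(...)), cds)
}

# -- reads builder -----------------------------------------------------------
read_fix <- function(id, chrom, strand, starts, ends, del = 0L, mapq = 60L,
                     polya = NA_real_, sample = "s1") {
  data.table::data.table(read_id = id, chrom = chrom, strand = strand,
                         block_starts = list(as.integer(starts)),
                         block_ends = list(as.integer(ends)),
                         total_deletion = as.integer(del),
                         mapq = as.integer(mapq), polya = polya,
                         sample = sample)
}

reads_fix <- function(...) {
  spliced_reads(data.table::rbindlist(list(...)))
}

# -- two-sided Fisher oracle: full hypergeometric enumeration ----------------
# table rows [a, b; c, d]; sums probabilities of all tables with the observed
# margins whose probability does not exceed the observed one (R convention,
# relative tolerance 1e-7).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  ks <- max(0, K - n):min(K, m)
  logp <- lchoose(m, ks) + lchoose(n, K - ks) - lchoose(m + n, K)
  logp_obs <- lchoose(m, a) + lchoose(n, c) - lchoose(m + n, K)
  min(1, sum(exp(logp)[logp <= logp_obs + log(1 + 1e-7)]))
}

# -- longest-ORF oracle: brute force over every ATG --------------------------
orf_oracle <- function(seq) {
  seq <- toupper(seq); n <- nchar(seq); best <- 0L
  if (n < 6L) return(best)
  for (i in seq_len(n - 5L)) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (j - i) %/% 3L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# -- DRACH oracle: overlapping regex matches on both strands -----------------
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

drach_oracle <- function(seq) {
  seq <- toupper(seq); n <- nchar(seq)
  fwd <- as.integer(gregexpr("(?=[AGT][AG]AC[ACT])", seq, perl = TRUE)[[1L]])
  fwd <- fwd[fwd > 0L]
  rc <- revcomp_chr(seq)
  rev <- as.integer(gregexpr("(?=[AGT][AG]AC[ACT])", rc, perl = TRUE)[[1L]])
  rev <- rev[rev > 0L]
  rbind(
    if (length(fwd)) data.frame(pos = fwd + 1L, strand = "+") else NULL,
    if (length(rev)) data.frame(pos = n - (rev + 2L), strand = "-") else NULL
  )
}

# -- exon-skipping oracle over exon structures -------------------------------
# ES(D, A) exists in a gene iff one isoform splices D directly to A while
# another has an exon ending at D, an exon starting at A, and at least one
# exon entirely inside (D, A). Formulated on exon tables, independently of
# the chain-matrix logic in the package.
es_oracle <- function(ann) {
  ex <- ann$exons
  tx <- transcripts(ann)
  out <- character()
  for (g in unique(tx$gene_id)) {
    ids <- tx$transcript_id[tx$gene_id == g]
    if (length(ids) < 2L) next
    exl <- lapply(ids, function(t) ex[ex$transcript_id == t, , drop = FALSE])
    names(exl) <- ids
    chrom <- exl[[1L]]$chrom[1L]; strand <- exl[[1L]]$strand[1L]
    for (t2 in ids) {
      e2 <- exl[[t2]]
      if (nrow(e2) < 2L) next
      for (r in seq_len(nrow(e2) - 1L)) {
        D <- e2$end[r]; A <- e2$start[r + 1L]
        for (t1 in setdiff(ids, t2)) {
          e1 <- exl[[t1]]
          if (any(e1$end == D) && any(e1$start == A) &&
              any(e1$start >= D & e1$end <= A)) {
            out <- c(out, sprintf("ES:%s:%s:%d-%d", chrom, strand, D, A))
          }
        }
      }
    }
  }
  sort(unique(out))
}

# -- misc --------------------------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

read_chain_key <- function(reads, i) {
  s <- reads$block_starts[[i]]; e <- reads$block_ends[[i]]
  if (length(s) == 1L) return(NA_character_)
  chain_key_test(reads$chrom[i], reads$strand[i], e[-length(e)], s[-1L])
}

chain_key_test <- function(chrom, strand, donors, acceptors) {
  sprintf("%s:%s:%s", chrom, strand,
          paste(sprintf("%d-%d", donors, acceptors), collapse = ","))
}

# per-transcript donor/acceptor vectors, recomputed from the exon table
tx_geometry_chains <- function(ann) {
  sp <- split(seq_len(nrow(ann$exons)), ann$exons$transcript_id)
  lapply(sp, function(idx) {
    st <- ann$exons$start[idx]; en <- ann$exons$end[idx]
    list(donors = en[-length(en)], acceptors = st[-1L])
  })
}
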