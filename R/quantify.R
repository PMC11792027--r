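# Read-to-transcript assignment, CPM normalization and the Fisher's-exact
# differential expression layer. The same per-feature 2x2 construction is
# reused by the splicing and m6A layers.

#' Assign reads to transcripts
#'
#' A multi-exon read is assigned to the transcript whose intron chain exactly
#' equals the read's (corrected) chain. A mono-exonic read is assigned to the
#' mono-exonic transcript on the same strand with the best reciprocal overlap
#' (Jaccard), requiring at least 50%. Reads matching nothing get NA.
#'
#' @param reads a [spliced_reads()] table (after correction, typically).
#' @param ann a [annotation()] object.
#' @return data.frame with `read_id`, `sample`, `mapq`, `polya`,
#'   `transcript_id` (NA when unassigned).
#' @export
assign_reads <- function(reads, ann) {
  reads <- data.table::as.data.table(reads)
  keys <- intron_chains(ann)
  tx_of_key <- stats::setNames(names(keys), keys)
  tx <- transcripts(ann)
  mono <- tx[tx$n_exons == 1L, , drop = FALSE]
  if (nrow(mono)) {
    mono_ex <- merge(mono, ann$exons[, c("transcript_id", "start", "end")],
                     by = "transcript_id", suffixes = c(".tx", ""))
  }
  nb <- lengths(reads$block_starts)
  assigned <- rep(NA_character_, nrow(reads))

  mi <- which(nb > 1L)
  if (length(mi)) {
    rkeys <- vapply(mi, function(i) {
      s <- reads$block_starts[[i]]; e <- reads$block_ends[[i]]
      chain_key(reads$chrom[i], reads$strand[i], e[-length(e)], s[-1L])
    }, character(1))
    assigned[mi] <- unname(tx_of_key[rkeys])
  }
  si <- which(nb == 1L)
  if (length(si) && nrow(mono)) {
    for (i in si) {
      s <- reads$block_starts[[i]][1L]; e <- reads$block_ends[[i]][1L]
      cand <- mono_ex[mono_ex$chrom == reads$chrom[i] &
                      mono_ex$strand == reads$strand[i], , drop = FALSE]
      if (!nrow(cand)) next
      ov <- interval_overlap(s, e, cand$start, cand$end)
      jac <- ov / (pmax(e, cand$end) - pmin(s, cand$start))
      best <- order(-jac, cand$transcript_id)[1L]
      if (jac[best] >= 0.5) assigned[i] <- cand$transcript_id[best]
    }
  }
  data.frame(read_id = reads$read_id, sample = reads$sample, mapq = reads$mapq,
             polya = reads$polya, transcript_id = assigned,
             stringsAsFactors = FALSE)
}

#' Count assigned reads per transcript and sample
#'
#' Reads below the mapping-quality floor (default 1, i.e. mapq 0 excluded) or
#' without a transcript assignment are not counted; the number of unassigned
#' reads is attached as attribute `n_unassigned`.
#'
#' @param reads a [spliced_reads()] table carrying `sample` labels.
#' @param ann a [annotation()] object.
#' @param min_mapq minimum mapping quality for counting; default 1.
#' @return Integer matrix, one row per annotation transcript (zeros included),
#'   one column per sample.
#' @export
quantify <- function(reads, ann, min_mapq = 1L) {
  asg <- assign_reads(reads, ann)
  keep <- asg$mapq >= min_mapq & !is.na(asg$transcript_id)
  n_unassigned <- sum(asg$mapq >= min_mapq & is.na(asg$transcript_id))
  tx_ids <- sort(unique(ann$exons$transcript_id))
  samples <- sort(unique(asg$sample))
  m <- table(factor(asg$transcript_id[keep], levels = tx_ids),
             factor(asg$sample[keep], levels = samples))
  m <- matrix(as.integer(m), nrow = length(tx_ids),
              dimnames = list(tx_ids, samples))
  attr(m, "n_unassigned") <- n_unassigned
  m
}

#' Counts-per-million normalization
#'
#' Each column is scaled to sum to one million.
#'
#' @param counts numeric matrix with positive column sums.
#' @return Matrix of the same shape.
#' @export
cpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("cpm: zero column sum; cannot normalize")
  sweep(counts, 2L, cs, "/") * 1e6
}

# Vectorized two-sided Fisher's exact p for per-feature 2x2 tables
# [a, tot_a - a; b, tot_b - b]. Uses stats::fisher.test per row.
fisher_rows <- function(a, b, tot_a, tot_b) {
  vapply(seq_along(a), function(i) {
    if (a[i] + b[i] == 0) return(1)
    stats::fisher.test(matrix(c(a[i], tot_a - a[i], b[i], tot_b - b[i]),
                              nrow = 2L, byrow = TRUE))$p.value
  }, numeric(1))
}

#' Fisher's-exact differential expression
#'
#' Replicate columns within each condition are pooled by summation, then each
#' feature (transcript or gene) is tested with a two-sided Fisher's exact test
#' on the 2x2 table `[count_A, rest_A; count_B, rest_B]` against the rest of
#' the library. Fold change is computed on pooled CPM with a pseudocount:
#' `log2((CPM_B + pseudo) / (CPM_A + pseudo))`. A feature is significant iff
#' `|log2FC| > lfc` (strict) and `p < alpha` (strict); Benjamini-Hochberg
#' q-values are reported alongside but do not gate the calls.
#'
#' @param counts integer matrix, features x samples.
#' @param cond_a,cond_b character vectors of sample (column) names for the two
#'   conditions; fold change is B over A.
#' @param pseudo CPM pseudocount; default 0.01.
#' @param lfc absolute log2 fold-change threshold; default 0.5.
#' @param alpha p-value threshold; default 0.01.
#' @return data.frame with `id`, `count_a`, `count_b`, `cpm_a`, `cpm_b`,
#'   `log2fc`, `p_value`, `q_value`, `significant`.
#' @export
fisher_de <- function(counts, cond_a, cond_b, pseudo = 0.01, lfc = 0.5,
                      alpha = 0.01) {
  stopifnot(all(cond_a %in% colnames(counts)), all(cond_b %in% colnames(counts)))
  a <- rowSums(counts[, cond_a, drop = FALSE])
  b <- rowSums(counts[, cond_b, drop = FALSE])
  tot_a <- sum(a); tot_b <- sum(b)
  if (tot_a == 0 || tot_b == 0) stop("fisher_de: a condition has zero total counts")
  cpm_a <- a / tot_a * 1e6
  cpm_b <- b / tot_b * 1e6
  log2fc <- log2((cpm_b + pseudo) / (cpm_a + pseudo))
  log2fc[a + b == 0] <- 0
  p <- fisher_rows(a, b, tot_a, tot_b)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(id = rownames(counts), count_a = unname(a), count_b = unname(b),
             cpm_a = unname(cpm_a), cpm_b = unname(cpm_b),
             log2fc = unname(log2fc), p_value = unname(p), q_value = unname(q),
             significant = unname(abs(log2fc) > lfc & p < alpha),
             stringsAsFactors = FALSE)
}
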