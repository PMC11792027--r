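# Reference-based transcript classification: a GffCompare-style class-code
# scheme reduced to the codes the downstream analysis consumes, plus
# tissue-specific and dominant transcript calls and a longest-ORF coding
# stand-in.

CODE_PRIORITY <- c("=", "c", "k", "j", "e", "i", "o", "x", "u")

#' Map a class code to its analysis category
#'
#' `=` is a matched transcript (identical intron chain); codes
#' `m, j, o, x, i, y, u` mark novel/different isoform structures; codes
#' `c, k, n, e, s, p, r` are "others" (partial matches). All fifteen
#' GffCompare codes are accepted on input, but only the subset
#' `=, c, k, j, e, i, o, x, u` is ever emitted by [assign_class_codes()];
#' the rare fuzzy/intronic codes are mapped for completeness.
#'
#' @param code character vector of single-character class codes.
#' @return character vector: `matched`, `different` or `others`.
#' @export
class_code_category <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == "="] <- "matched"
  out[code %in% c("m", "j", "o", "x", "i", "y", "u")] <- "different"
  out[code %in% c("c", "k", "n", "e", "s", "p", "r")] <- "others"
  if (anyNA(out)) stop("class_code_category: unknown class code(s): ",
                       paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

# Classify one query transcript against one candidate reference transcript.
# Returns NA when the pair has no relationship that produces a code.
classify_pair <- function(q, r) {
  same_strand <- q$strand == r$strand
  mq <- nrow(q$chain); mr <- nrow(r$chain)
  ov <- sum(vapply(seq_len(length(q$ex_start)), function(i) {
    sum(interval_overlap(q$ex_start[i], q$ex_end[i], r$ex_start, r$ex_end))
  }, numeric(1)))

  code <- NA_character_
  if (same_strand && mq > 0L && mr > 0L && mq == mr && all(q$chain == r$chain)) {
    code <- "="
  } else if (same_strand && mq == 0L && mr == 0L && ov > 0) {
    # mono-exonic vs mono-exonic: overlap on the same strand is a match
    code <- "="
  } else if (same_strand && mq >= 1L && mr > mq &&
             is_contiguous_subchain(q$chain, r$chain)) {
    code <- "c"
  } else if (same_strand && mr >= 1L && mq > mr &&
             is_contiguous_subchain(r$chain, q$chain)) {
    code <- "k"
  } else if (same_strand && mq >= 1L && mr >= 1L &&
             any(paste(q$chain[, 1L], q$chain[, 2L]) %in%
                 paste(r$chain[, 1L], r$chain[, 2L]))) {
    code <- "j"
  } else if (same_strand && mq == 0L && mr >= 1L && ov > 0) {
    code <- "e"
  } else if (mr >= 1L &&
             any(r$chain[, 1L] <= q$ex_start[1L] &
                 q$ex_end[length(q$ex_end)] <= r$chain[, 2L])) {
    code <- "i"   # query fully inside a reference intron
  } else if (same_strand && ov > 0) {
    code <- "o"
  } else if (!same_strand && ov > 0) {
    code <- "x"
  }
  list(code = code, overlap = ov)
}

#' Classify de novo transcripts against a reference annotation
#'
#' Per query transcript the best reference match is selected and a class code
#' assigned from a fixed decision tree, in priority order: `=` exact
#' intron-chain identity; `c` the query chain is a contiguous sub-chain of the
#' reference; `k` the reference chain is a contiguous sub-chain of the query;
#' `j` at least one shared junction but differing chains; `e` mono-exonic
#' query overlapping a reference exon; `i` query fully inside a reference
#' intron; `o` other same-strand exonic overlap; `x` opposite-strand exonic
#' overlap; `u` no overlap with any reference transcript (novel gene).
#' Among multiple candidate references the highest-priority code wins, then
#' the longest exonic overlap, then the lexicographically smallest reference
#' id.
#'
#' @param query,reference [annotation()] objects on the same assembly.
#' @return data.frame with columns `query_id`, `ref_id` (NA for `u`), `code`,
#'   `category` and `novel_gene` (TRUE iff code is `u`).
#' @export
assign_class_codes <- function(query, reference) {
  stopifnot(inherits(query, "tx_annotation"), inherits(reference, "tx_annotation"))
  qm <- tx_geometry(query)
  rm_ <- tx_geometry(reference)
  qids <- names(qm)
  if (!length(qids)) {
    return(data.frame(query_id = character(), ref_id = character(),
                      code = character(), category = character(),
                      novel_gene = logical(), stringsAsFactors = FALSE))
  }
  # candidate pairs: transcript spans within overlap distance on any strand
  # (span overlap is a superset of exonic overlap and covers intronic 'i')
  qgr <- GenomicRanges::GRanges(
    vapply(qm, `[[`, character(1), "chrom"),
    IRanges::IRanges(start = vapply(qm, function(t) t$ex_start[1L], integer(1)) + 1L,
                     end = vapply(qm, function(t) t$ex_end[length(t$ex_end)], integer(1))))
  rgr <- GenomicRanges::GRanges(
    vapply(rm_, `[[`, character(1), "chrom"),
    IRanges::IRanges(start = vapply(rm_, function(t) t$ex_start[1L], integer(1)) + 1L,
                     end = vapply(rm_, function(t) t$ex_end[length(t$ex_end)], integer(1))))
  hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = TRUE)
  cand <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  res <- lapply(seq_along(qids), function(qi) {
    ridx <- cand[[as.character(qi)]]
    if (is.null(ridx)) {
      return(data.frame(query_id = qids[qi], ref_id = NA_character_, code = "u",
                        stringsAsFactors = FALSE))
    }
    rids <- names(rm_)[ridx]
    cls <- lapply(rm_[ridx], function(r) classify_pair(qm[[qi]], r))
    codes <- vapply(cls, `[[`, character(1), "code")
    ovs <- vapply(cls, `[[`, numeric(1), "overlap")
    ok <- !is.na(codes)
    if (!any(ok)) {
      return(data.frame(query_id = qids[qi], ref_id = NA_character_, code = "u",
                        stringsAsFactors = FALSE))
    }
    pr <- match(codes[ok], CODE_PRIORITY)
    pick <- order(pr, -ovs[ok], rids[ok])[1L]
    data.frame(query_id = qids[qi], ref_id = rids[ok][pick],
               code = codes[ok][pick], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$category <- class_code_category(out$code)
  out$novel_gene <- out$code == "u"
  out$ref_id[out$code == "u"] <- NA_character_
  rownames(out) <- NULL
  out
}

# Per-transcript geometry used by the classifier: exon vectors + chain matrix.
tx_geometry <- function(ann) {
  sp <- split(seq_len(nrow(ann$exons)), ann$exons$transcript_id)
  lapply(sp, function(idx) {
    st <- ann$exons$start[idx]; en <- ann$exons$end[idx]
    n <- length(idx)
    list(chrom = ann$exons$chrom[idx[1L]],
         strand = ann$exons$strand[idx[1L]],
         ex_start = st, ex_end = en,
         chain = cbind(donor = if (n > 1L) en[-n] else integer(),
                       acceptor = if (n > 1L) st[-1L] else integer()))
  })
}

#' Find tissue-specific transcripts
#'
#' A transcript (identified by its `(chrom, strand, intron chain)` key, so
#' data-dependent transcript ends are ignored) is specific to a tissue iff its
#' key occurs in that tissue's annotation and in no other tissue.
#'
#' @param tissue_annotations named list (>= 2) of [annotation()] objects.
#' @return Named list, per tissue, of specific chain keys.
#' @export
find_tissue_specific <- function(tissue_annotations) {
  if (length(tissue_annotations) < 2L) {
    stop("find_tissue_specific: need at least two tissues to compare")
  }
  keys <- lapply(tissue_annotations, function(a) unique(unname(intron_chains(a))))
  tab <- table(unlist(keys))
  lapply(keys, function(k) sort(k[tab[k] == 1L]))
}

#' Find the dominant transcript of each gene
#'
#' The dominant transcript is the most highly expressed transcript within its
#' gene, by summed counts over the given samples. Ties break to the
#' lexicographically smaller transcript id; genes with zero total counts are
#' omitted.
#'
#' @param ann a [annotation()] object.
#' @param counts integer matrix, transcripts x samples.
#' @param samples character vector of column names to sum over (e.g. the
#'   samples of one condition); default all columns.
#' @return Named character vector: gene_id -> dominant transcript_id.
#' @export
find_dominant <- function(ann, counts, samples = colnames(counts)) {
  tx <- transcripts(ann)
  tx <- tx[tx$transcript_id %in% rownames(counts), , drop = FALSE]
  tot <- rowSums(counts[tx$transcript_id, samples, drop = FALSE])
  res <- vapply(split(seq_len(nrow(tx)), tx$gene_id), function(idx) {
    tt <- tot[idx]
    if (sum(tt) == 0) return(NA_character_)
    ids <- tx$transcript_id[idx]
    ids[order(-tt, ids)][1L]
  }, character(1))
  res[!is.na(res)]
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans the sense strand in all three frames for the longest ATG-initiated
#' ORF that ends at an in-frame stop codon entirely within the sequence. The
#' reported protein length excludes the stop codon; ties break to the
#' 5'-most start.
#'
#' @param seq a single spliced transcript sequence (character).
#' @return list with `length` (aa, 0 when no ORF) and `protein` (character,
#'   `""` when no ORF).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) return(list(length = 0L, protein = ""))
  codons_at <- function(positions) substring(seq, positions, positions + 2L)
  starts <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  starts <- starts[starts > 0L & starts + 5L <= n]
  if (!length(starts)) return(list(length = 0L, protein = ""))
  best_len <- 0L; best_start <- NA_integer_
  for (frame in 0:2) {
    pos <- seq.int(1L + frame, n - 2L, by = 3L)
    cods <- codons_at(pos)
    stops <- pos[cods %in% c("TAA", "TAG", "TGA")]
    fr_starts <- starts[(starts - 1L) %% 3L == frame]
    if (!length(fr_starts) || !length(stops)) next
    nxt <- stops[findInterval(fr_starts, stops) + 1L]
    ok <- !is.na(nxt)
    len <- (nxt[ok] - fr_starts[ok]) %/% 3L
    if (length(len)) {
      i <- order(-len, fr_starts[ok])[1L]
      if (len[i] > best_len || (len[i] == best_len && !is.na(best_start) &&
                                fr_starts[ok][i] < best_start)) {
        best_len <- len[i]; best_start <- fr_starts[ok][i]
      }
    }
  }
  if (best_len == 0L) return(list(length = 0L, protein = ""))
  orf <- substr(seq, best_start, best_start + 3L * best_len - 1L)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  list(length = best_len, protein = prot)
}

#' Spliced sequence of a transcript
#'
#' @param ann a [annotation()] object.
#' @param genome named character vector from [read_genome()].
#' @param transcript_id transcript to extract.
#' @return Sense-strand spliced sequence (reverse-complemented for `-`).
#' @export
transcript_sequence <- function(ann, genome, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(ex)) stop("transcript_sequence: unknown transcript ", transcript_id)
  chrom_seq <- genome[[ex$chrom[1L]]]
  if (is.null(chrom_seq)) stop("transcript_sequence: chromosome not in genome")
  parts <- substring(chrom_seq, ex$start + 1L, ex$end)
  s <- paste(parts, collapse = "")
  if (ex$strand[1L] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
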