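# Read-level refinement: deletion filter, ATAC-anchored 5' filter, short-read
# junction correction, and collapse of corrected reads into a de novo
# annotation. Mirrors a FLAIR-style correct/collapse workflow operating on the
# neutral read table.

#' Correction and collapse parameters
#'
#' @param max_deletion reads with a summed alignment deletion length strictly
#'   greater than this (nt) are removed; default 100.
#' @param junction_window maximum distance (bp) between a read junction and a
#'   short-read junction for the read junction to be considered valid; both
#'   donor and acceptor must fall within the window. Default 15.
#' @param min_junction_support minimum unique-read support a short-read
#'   junction needs before it can validate/correct long-read splice sites;
#'   default 3.
#' @param end_cluster_window window (bp) for clustering transcript 5'/3' ends
#'   during collapse; default 100.
#' @param min_collapse_support minimum read support for a collapsed group to
#'   be reported as a transcript; default 3.
#' @return list of class `correction_params`.
#' @export
correction_params <- function(max_deletion = 100L, junction_window = 15L,
                              min_junction_support = 3L,
                              end_cluster_window = 100L,
                              min_collapse_support = 3L) {
  p <- list(max_deletion = as.integer(max_deletion),
            junction_window = as.integer(junction_window),
            min_junction_support = as.integer(min_junction_support),
            end_cluster_window = as.integer(end_cluster_window),
            min_collapse_support = as.integer(min_collapse_support))
  if (any(unlist(p) < 0L)) stop("correction_params: all parameters must be >= 0")
  if (p$junction_window < 1L) stop("correction_params: junction_window must be >= 1")
  class(p) <- "correction_params"
  p
}

#' Remove reads with excessive alignment deletions
#'
#' Reads whose summed deletion length exceeds `max_deletion` (strictly) are
#' removed; a read at exactly the threshold is kept. Input order is preserved.
#'
#' @param reads a [spliced_reads()] table.
#' @param params a [correction_params()] object.
#' @export
filter_by_deletion <- function(reads, params = correction_params()) {
  reads[reads$total_deletion <= params$max_deletion, ]
}

#' Keep reads whose 5' ends fall in open chromatin
#'
#' A read survives iff its strand-aware 5' position lies inside at least one
#' ATAC-seq peak (point-in-interval on the half-open peak). Peak strand is
#' ignored.
#'
#' @param reads a [spliced_reads()] table.
#' @param peaks data.frame from [read_peaks()].
#' @export
filter_by_tss <- function(reads, peaks) {
  if (nrow(reads) == 0L) return(reads)
  if (is.null(peaks) || nrow(peaks) == 0L) return(reads[0L, ])
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(start = reads$five_prime + 1L, width = 1L))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hit <- GenomicRanges::countOverlaps(pts, pk, ignore.strand = TRUE) > 0L
  reads[hit, ]
}

#' Correct long-read splice junctions against short-read junctions
#'
#' Each read junction is snapped to the nearest eligible short-read junction
#' (support >= `min_junction_support`) whose donor and acceptor both lie
#' within `junction_window` bp. The snap target minimizes
#' `max(|d_donor|, |d_acceptor|)`; ties go to higher support, then to the
#' smaller donor coordinate. A read is rejected when any of its junctions has
#' no eligible match, or when correction would produce a zero-length or
#' inverted exon. Exon blocks are re-derived from the corrected junctions with
#' the outer read ends fixed. Mono-exonic reads pass through unchanged.
#'
#' @param reads a [spliced_reads()] table.
#' @param junctions data.frame from [read_junctions()].
#' @param params a [correction_params()] object.
#' @return The reads table with corrected `block_starts`/`block_ends`, plus
#'   `status` (one of `corrected`, `unchanged`, `rejected`) and
#'   `reject_reason` columns. Rejected reads keep their original blocks.
#' @export
correct_reads <- function(reads, junctions, params = correction_params()) {
  reads <- data.table::copy(data.table::as.data.table(reads))
  n <- nrow(reads)
  reads[, "status" := "unchanged"]
  reads[, "reject_reason" := NA_character_]
  if (n == 0L) return(restore_reads_class(reads))

  nb <- lengths(reads$block_starts)
  multi <- which(nb > 1L)
  if (!length(multi)) return(restore_reads_class(reads))

  jt <- data.table::as.data.table(junctions)[support >= params$min_junction_support]
  w <- params$junction_window

  # long table of read junctions
  long <- reads[multi, list(
    read_idx = rep(multi, nb[multi] - 1L),
    chrom = rep(chrom, nb[multi] - 1L),
    strand = rep(strand, nb[multi] - 1L),
    donor = unlist(lapply(block_ends, function(x) x[-length(x)])),
    acceptor = unlist(lapply(block_starts, function(x) x[-1L]))
  )]
  long[, "j_idx" := seq_len(.N), by = "read_idx"]

  if (nrow(jt)) {
    cand <- jt[, list(chrom, strand, jd = donor, ja = acceptor, support,
                      dlo = donor - w, dhi = donor + w,
                      alo = acceptor - w, ahi = acceptor + w)]
    m <- cand[long,
              on = c("chrom", "strand", "dlo<=donor", "dhi>=donor",
                     "alo<=acceptor", "ahi>=acceptor"),
              allow.cartesian = TRUE,
              list(read_idx = i.read_idx, j_idx = i.j_idx,
                   donor = i.donor, acceptor = i.acceptor,
                   jd = x.jd, ja = x.ja, support = x.support)]
  } else {
    m <- long[, list(read_idx, j_idx, donor, acceptor,
                     jd = NA_integer_, ja = NA_integer_, support = NA_integer_)]
  }
  m[, "score" := pmax(abs(jd - donor), abs(ja - acceptor))]
  data.table::setorder(m, read_idx, j_idx, score, -support, jd, ja, na.last = TRUE)
  best <- m[, .SD[1L], by = c("read_idx", "j_idx")]
  data.table::setorder(best, read_idx, j_idx)
  best_by_read <- split(best, by = "read_idx")

  for (ri in multi) {
    b <- best_by_read[[as.character(ri)]]
    if (anyNA(b$jd)) {
      bad <- b[is.na(b$jd)][1L]
      reads[ri, `:=`(status = "rejected",
                     reject_reason = sprintf("no eligible junction for %d-%d",
                                             bad$donor, bad$acceptor))]
      next
    }
    os <- reads$block_starts[[ri]]; oe <- reads$block_ends[[ri]]
    ns <- c(os[1L], b$ja)
    ne <- c(b$jd, oe[length(oe)])
    if (any(ne <= ns) || is.unsorted(b$jd, strictly = TRUE) ||
        any(ns[-1L] < ne[-length(ne)])) {
      reads[ri, `:=`(status = "rejected",
                     reject_reason = "correction produced a degenerate exon")]
      next
    }
    changed <- any(b$jd != b$donor) || any(b$ja != b$acceptor)
    if (changed) {
      data.table::set(reads, i = ri, j = "block_starts", value = list(list(as.integer(ns))))
      data.table::set(reads, i = ri, j = "block_ends", value = list(list(as.integer(ne))))
      data.table::set(reads, i = ri, j = "status", value = "corrected")
    }
  }
  # 5' position is end-anchored and unaffected by junction snapping, but keep
  # the derived column consistent with the (possibly replaced) blocks.
  reads[, "five_prime" := ifelse(
    strand == "+",
    vapply(block_starts, function(x) as.integer(x[1L]), integer(1)),
    vapply(block_ends, function(x) as.integer(x[length(x)]), integer(1)))]
  restore_reads_class(reads)
}

restore_reads_class <- function(dt) {
  data.table::setattr(dt, "class", c("spliced_reads", class(data.table::data.table())))
  dt[]
}

#' Collapse corrected reads into a de novo annotation
#'
#' Multi-exon reads are grouped by exact corrected intron chain; mono-exonic
#' reads are grouped on the same strand by single-linkage reciprocal overlap
#' (>= 50% of each read). Groups below `min_collapse_support` reads are
#' dropped. Transcript 5'/3' ends are the per-end medians after clustering
#' read ends within `end_cluster_window` (the largest cluster wins). Genes are
#' assembled by single-linkage exon overlap on the same strand. Rejected reads
#' must not be present; they are excluded (with a message) if they are.
#'
#' Transcript and gene identifiers are deterministic and positional
#' (`iso-00001`, `gene-0001`, ordered by genomic location), so a collapse of
#' the same read set always yields byte-identical output.
#'
#' @param reads corrected [spliced_reads()] (output of [correct_reads()], or
#'   raw reads when no correction is wanted).
#' @param params a [correction_params()] object.
#' @return list with `annotation` (a [annotation()]) and `support` (named
#'   integer vector of read counts per transcript).
#' @export
collapse_reads <- function(reads, params = correction_params()) {
  reads <- data.table::as.data.table(reads)
  if ("status" %in% names(reads) && any(reads$status == "rejected")) {
    message(sprintf("collapse_reads: excluding %d rejected reads",
                    sum(reads$status == "rejected")))
    reads <- reads[reads$status != "rejected"]
  }
  empty <- annotation(data.frame(transcript_id = character(), gene_id = character(),
                                 chrom = character(), strand = character(),
                                 start = integer(), end = integer()))
  if (nrow(reads) == 0L) return(list(annotation = empty, support = integer()))

  nb <- lengths(reads$block_starts)
  groups <- list()   # each: chrom, strand, starts, ends of member reads + chain

  ## multi-exon: exact chain identity
  mi <- which(nb > 1L)
  if (length(mi)) {
    keys <- vapply(mi, function(i) {
      s <- reads$block_starts[[i]]; e <- reads$block_ends[[i]]
      chain_key(reads$chrom[i], reads$strand[i], e[-length(e)], s[-1L])
    }, character(1))
    for (k in unique(keys)) {
      idx <- mi[keys == k]
      i1 <- idx[1L]
      s <- reads$block_starts[[i1]]; e <- reads$block_ends[[i1]]
      groups[[length(groups) + 1L]] <- list(
        chrom = reads$chrom[i1], strand = reads$strand[i1],
        donors = e[-length(e)], acceptors = s[-1L],
        left_ends = vapply(idx, function(i) reads$block_starts[[i]][1L], integer(1)),
        right_ends = vapply(idx, function(i) {
          b <- reads$block_ends[[i]]; b[length(b)]
        }, integer(1)),
        n = length(idx))
    }
  }

  ## mono-exonic: single-linkage reciprocal overlap within chrom/strand
  si <- which(nb == 1L)
  if (length(si)) {
    sdt <- data.table::data.table(
      idx = si,
      chrom = reads$chrom[si],
      strand = reads$strand[si],
      start = vapply(si, function(i) reads$block_starts[[i]][1L], integer(1)),
      end = vapply(si, function(i) reads$block_ends[[i]][1L], integer(1)))
    for (grp in split(seq_len(nrow(sdt)), paste(sdt$chrom, sdt$strand))) {
      sub <- sdt[grp]
      gr <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      hits <- IRanges::findOverlaps(gr, gr)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      keep <- qh < sh
      qh <- qh[keep]; sh <- sh[keep]
      if (length(qh)) {
        ov <- interval_overlap(sub$start[qh], sub$end[qh], sub$start[sh], sub$end[sh])
        recip <- ov >= 0.5 * (sub$end[qh] - sub$start[qh]) &
                 ov >= 0.5 * (sub$end[sh] - sub$start[sh])
        qh <- qh[recip]; sh <- sh[recip]
      }
      comp <- uf_union_pairs(nrow(sub), qh, sh)
      for (cid in unique(comp)) {
        mem <- which(comp == cid)
        groups[[length(groups) + 1L]] <- list(
          chrom = sub$chrom[1L], strand = sub$strand[1L],
          donors = integer(), acceptors = integer(),
          left_ends = sub$start[mem], right_ends = sub$end[mem],
          n = length(mem))
      }
    }
  }

  groups <- Filter(function(g) g$n >= params$min_collapse_support, groups)
  if (!length(groups)) return(list(annotation = empty, support = integer()))

  ## transcript models: cluster + median ends, blocks from chain
  models <- lapply(groups, function(g) {
    start <- cluster_end(g$left_ends, params$end_cluster_window)
    end <- cluster_end(g$right_ends, params$end_cluster_window)
    if (length(g$donors)) {
      start <- min(start, g$donors[1L] - 1L)     # keep first exon non-empty
      end <- max(end, g$acceptors[length(g$acceptors)] + 1L)
      ex_start <- c(start, g$acceptors)
      ex_end <- c(g$donors, end)
    } else {
      ex_start <- start; ex_end <- end
    }
    list(chrom = g$chrom, strand = g$strand, ex_start = ex_start,
         ex_end = ex_end, n = g$n,
         key = chain_key(g$chrom, g$strand, g$donors, g$acceptors,
                         ex_start[1L], ex_end[length(ex_end)]))
  })
  ord <- order(vapply(models, `[[`, character(1), "chrom"),
               vapply(models, function(m) m$ex_start[1L], integer(1)),
               vapply(models, function(m) m$ex_end[length(m$ex_end)], integer(1)),
               vapply(models, `[[`, character(1), "key"))
  models <- models[ord]
  tids <- sprintf("iso-%05d", seq_along(models))

  ## genes: single-linkage exon overlap, same chrom+strand
  exon_tx <- rep(seq_along(models), vapply(models, function(m) length(m$ex_start), integer(1)))
  exon_gr <- GenomicRanges::GRanges(
    rep(vapply(models, `[[`, character(1), "chrom"),
        vapply(models, function(m) length(m$ex_start), integer(1))),
    IRanges::IRanges(start = unlist(lapply(models, `[[`, "ex_start")) + 1L,
                     end = unlist(lapply(models, `[[`, "ex_end"))),
    strand = rep(vapply(models, `[[`, character(1), "strand"),
                 vapply(models, function(m) length(m$ex_start), integer(1))))
  hits <- GenomicRanges::findOverlaps(exon_gr, exon_gr, ignore.strand = FALSE)
  qh <- exon_tx[S4Vectors::queryHits(hits)]
  sh <- exon_tx[S4Vectors::subjectHits(hits)]
  keep <- qh < sh
  comp <- uf_union_pairs(length(models), qh[keep], sh[keep])
  gene_rank <- match(comp, unique(comp))
  gids <- sprintf("gene-%04d", gene_rank)

  exons <- do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[[i]]
    data.frame(transcript_id = tids[i], gene_id = gids[i], chrom = m$chrom,
               strand = m$strand, start = m$ex_start, end = m$ex_end,
               stringsAsFactors = FALSE)
  }))
  support <- stats::setNames(vapply(models, `[[`, integer(1), "n"), tids)
  list(annotation = annotation(exons), support = support)
}
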