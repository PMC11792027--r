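# m6A site layer: DRACH candidate discovery on exonic sequence, the
# coverage/recurrence filters, Fisher differential modification testing and
# MetaPlotR-style metagene positioning over 5'UTR/CDS/3'UTR.

#' DRACH motif matches in a raw sequence
#'
#' Scans both strands of a sequence for the degenerate DRACH 5-mer
#' (D = A/G/T, R = A/G, then A, C, H = A/C/T) using IUPAC ambiguity matching.
#' The reported position is the methylatable A (motif position 3), 0-based on
#' the forward strand for both orientations.
#'
#' @param seq a single DNA sequence (character).
#' @return data.frame with `pos` (0-based A position), `strand`, `motif`
#'   (the 5-mer as read on its own strand).
#' @export
drach_sites <- function(seq) {
  subject <- Biostrings::DNAString(toupper(seq))
  fwd <- Biostrings::matchPattern("DRACH", subject, fixed = FALSE)
  # minus-strand DRACH appears on the forward sequence as its reverse
  # complement; the central A maps to the same forward offset (start + 2)
  rev_pat <- Biostrings::reverseComplement(Biostrings::DNAString("DRACH"))
  rev <- Biostrings::matchPattern(rev_pat, subject, fixed = FALSE)
  out <- data.frame(
    pos = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) + 1L,  # 0-based A
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    motif = c(as.character(fwd),
              as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rev)))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan exonic regions of an annotation for DRACH candidate sites
#'
#' Every A at DRACH position 3 whose 5-mer lies entirely within an exon of a
#' transcript on the matching strand becomes a candidate site. Regions extend
#' `flank` bp on either side of the A, clipped at chromosome ends.
#'
#' @param genome named character vector from [read_genome()].
#' @param ann a [annotation()] object.
#' @param flank region half-width in bp; default 10.
#' @return data.frame with `site` key (`chrom:pos:strand`), `chrom`, `pos`,
#'   `strand`, `motif`, `region_start`, `region_end`.
#' @export
scan_drach <- function(genome, ann, flank = 10L) {
  out <- list()
  for (chrom in intersect(names(genome), unique(ann$exons$chrom))) {
    hits <- drach_sites(genome[[chrom]])
    if (!nrow(hits)) next
    clen <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      ex <- ann$exons[ann$exons$chrom == chrom & ann$exons$strand == strand, ,
                      drop = FALSE]
      h <- hits[hits$strand == strand, , drop = FALSE]
      if (!nrow(ex) || !nrow(h)) next
      # whole 5-mer within a single exon
      ex_gr <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
      mot_gr <- IRanges::IRanges(start = h$pos - 1L, width = 5L)  # 1-based 5-mer
      within <- IRanges::countOverlaps(mot_gr, ex_gr, type = "within") > 0L
      h <- h[within, , drop = FALSE]
      if (!nrow(h)) next
      h <- h[!duplicated(h$pos), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        site = sprintf("%s:%d:%s", chrom, h$pos, strand),
        chrom = chrom, pos = h$pos, strand = strand, motif = h$motif,
        region_start = pmax(0L, h$pos - as.integer(flank)),
        region_end = pmin(clen, h$pos + as.integer(flank) + 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(site = character(), chrom = character(), pos = integer(),
                      strand = character(), motif = character(),
                      region_start = integer(), region_end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coverage and recurrence filtering of m6A sites
#'
#' A site is kept iff coverage (`total >= min_coverage`) holds in at least
#' `min_samples` samples and a modification event (`modified > 0`) occurs in
#' at least `min_samples` samples. Raising either threshold can only remove
#' sites.
#'
#' @param counts long data.frame from [read_m6a_counts()] (columns `site`,
#'   `sample`, `modified`, `total`, ...).
#' @param min_coverage minimum reads per sample; default 5.
#' @param min_samples minimum number of samples; default 2.
#' @return The filtered counts table (all rows of surviving sites).
#' @export
filter_m6a_sites <- function(counts, min_coverage = 5L, min_samples = 2L) {
  dt <- data.table::as.data.table(counts)
  ok <- dt[, list(n_cov = sum(total >= min_coverage),
                  n_mod = sum(modified > 0L)), by = "site"]
  keep <- ok$site[ok$n_cov >= min_samples & ok$n_mod >= min_samples]
  out <- data.table::setDF(dt[dt$site %in% keep])
  rownames(out) <- NULL
  out
}

#' Differential m6A modification between conditions
#'
#' Counts are pooled within each condition, then each site is tested with a
#' two-sided Fisher's exact test on `[mod_A, unmod_A; mod_B, unmod_B]`. The
#' modification-frequency fold change uses a pseudo-frequency:
#' `log2((freq_B + eps) / (freq_A + eps))` with `eps = 0.01`. A site is
#' significant iff `|log2FC| > lfc` (strict) and `p < alpha` (strict). Sites
#' with zero pooled coverage in a condition are flagged untestable.
#'
#' @param counts long counts table (filtered, typically).
#' @param conditions named character vector mapping sample -> condition.
#' @param cond_a,cond_b condition labels (fold change is B over A).
#' @param eps pseudo-frequency; default 0.01.
#' @param lfc absolute log2 fold-change threshold; default 0.5.
#' @param alpha p-value threshold; default 0.01.
#' @return data.frame per site with pooled counts, `freq_a`, `freq_b`,
#'   `log2fc`, `p_value`, `significant`, `testable`.
#' @export
diff_m6a <- function(counts, conditions, cond_a, cond_b, eps = 0.01,
                     lfc = 0.5, alpha = 0.01) {
  dt <- data.table::as.data.table(counts)
  dt[, "condition" := unname(conditions[sample])]
  pooled <- dt[dt$condition %in% c(cond_a, cond_b),
               list(mod = sum(modified), tot = sum(total)),
               by = c("site", "condition")]
  wide <- data.table::dcast(pooled, site ~ condition, value.var = c("mod", "tot"),
                            fill = 0)
  ma <- wide[[paste0("mod_", cond_a)]]; ta <- wide[[paste0("tot_", cond_a)]]
  mb <- wide[[paste0("mod_", cond_b)]]; tb <- wide[[paste0("tot_", cond_b)]]
  testable <- ta > 0 & tb > 0
  freq_a <- ifelse(ta > 0, ma / ta, NA_real_)
  freq_b <- ifelse(tb > 0, mb / tb, NA_real_)
  log2fc <- ifelse(testable, log2((freq_b + eps) / (freq_a + eps)), NA_real_)
  p <- rep(1, nrow(wide))
  for (i in which(testable)) {
    p[i] <- stats::fisher.test(matrix(c(ma[i], ta[i] - ma[i], mb[i], tb[i] - mb[i]),
                                      nrow = 2L, byrow = TRUE))$p.value
  }
  out <- data.frame(site = wide$site, mod_a = ma, tot_a = ta, mod_b = mb,
                    tot_b = tb, freq_a = freq_a, freq_b = freq_b,
                    log2fc = log2fc, p_value = p,
                    significant = testable & !is.na(log2fc) &
                      abs(log2fc) > lfc & p < alpha,
                    testable = testable, stringsAsFactors = FALSE)
  out[order(out$site), , drop = FALSE]
}

#' Metagene positions of m6A sites
#'
#' Maps each site into transcript coordinates of every CDS-bearing transcript
#' whose exons contain it (matching strand), and rescales to the standard
#' metagene axis: 5'UTR spans `[0,1)`, CDS `[1,2)`, 3'UTR `[2,3)`. Sites on
#' transcripts without a CDS partition, or outside all exons, are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param sites data.frame with `site`, `chrom`, `pos`, `strand` (e.g. from
#'   [scan_drach()] or a counts table).
#' @param ann a [annotation()] object with CDS segments.
#' @return data.frame with `site`, `transcript_id`, `segment`
#'   (`5UTR`/`CDS`/`3UTR`) and `relative` in `[0,3)`.
#' @export
metagene <- function(sites, ann) {
  sites <- unique(sites[, c("site", "chrom", "pos", "strand")])
  cds_tx <- unique(ann$cds$transcript_id)
  geo <- tx_geometry(subset_annotation(ann, cds_tx))
  out <- list()
  n_skipped <- 0L
  for (si in seq_len(nrow(sites))) {
    pos <- sites$pos[si]
    mapped <- FALSE
    for (tid in names(geo)) {
      t <- geo[[tid]]
      if (t$chrom != sites$chrom[si] || t$strand != sites$strand[si]) next
      ei <- which(t$ex_start <= pos & pos < t$ex_end)
      if (!length(ei)) next
      exon_lens <- t$ex_end - t$ex_start
      off_plus <- if (ei > 1L) sum(exon_lens[seq_len(ei - 1L)]) else 0L
      off_plus <- off_plus + (pos - t$ex_start[ei])
      total <- sum(exon_lens)
      tpos <- if (t$strand == "+") off_plus else total - 1L - off_plus
      cc <- ann$cds[ann$cds$transcript_id == tid, , drop = FALSE]
      cds_len <- sum(cc$end - cc$start)
      # transcript coordinate of the CDS 5' end
      cds_gstart <- if (t$strand == "+") min(cc$start) else max(cc$end) - 1L
      g_ei <- which(t$ex_start <= cds_gstart & cds_gstart < t$ex_end)
      g_off <- (if (g_ei > 1L) sum(exon_lens[seq_len(g_ei - 1L)]) else 0L) +
        (cds_gstart - t$ex_start[g_ei])
      utr5_len <- if (t$strand == "+") g_off else total - 1L - g_off
      utr3_len <- total - utr5_len - cds_len
      if (tpos < utr5_len) {
        segment <- "5UTR"; rel <- tpos / utr5_len
      } else if (tpos < utr5_len + cds_len) {
        segment <- "CDS"; rel <- 1 + (tpos - utr5_len) / cds_len
      } else {
        segment <- "3UTR"; rel <- 2 + (tpos - utr5_len - cds_len) / utr3_len
      }
      out[[length(out) + 1L]] <- data.frame(
        site = sites$site[si], transcript_id = tid, segment = segment,
        relative = rel, stringsAsFactors = FALSE)
      mapped <- TRUE
    }
    if (!mapped) n_skipped <- n_skipped + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(site = character(), transcript_id = character(),
               segment = character(), relative = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Binned metagene density for plotting
#'
#' @param positions data.frame from [metagene()].
#' @param n_bins bins over the `[0,3)` axis; default 90.
#' @return data.frame with `bin_mid` and `density` (fraction of positions).
#' @export
metagene_density <- function(positions, n_bins = 90L) {
  breaks <- seq(0, 3, length.out = n_bins + 1L)
  h <- hist(positions$relative, breaks = breaks, plot = FALSE)
  data.frame(bin_mid = h$mids, density = h$counts / max(1L, nrow(positions)))
}
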