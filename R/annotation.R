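#' Transcript annotation container
#'
#' An annotation is the unit passed between every stage of the pipeline: a set
#' of strand-aware exon chains grouped into genes, with an optional CDS
#' partition per transcript (needed only for metagene positioning). All
#' coordinates are 0-based half-open.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`; one row per exon. Exons of a transcript must lie
#'   on one chromosome and strand, and must be disjoint. They are sorted on
#'   construction.
#' @param cds optional data.frame with columns `transcript_id`, `start`, `end`
#'   giving the genomic CDS segments; each segment must fall inside the exon
#'   union of its transcript.
#' @return An object of class `tx_annotation` with elements `exons` and `cds`.
#' @export
annotation <- function(exons, cds = NULL) {
  exons <- as.data.frame(exons)
  assert_cols(exons, c("transcript_id", "gene_id", "chrom", "strand", "start", "end"),
              "annotation exons")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
      stop("annotation: exon intervals must satisfy 0 <= start < end")
    }
    if (!all(exons$strand %in% c("+", "-"))) {
      stop("annotation: transcript strand must be '+' or '-'")
    }
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # per-transcript consistency: one chrom/strand/gene, disjoint exons
    sp <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in sp) {
      if (length(unique(exons$chrom[idx])) != 1L ||
          length(unique(exons$strand[idx])) != 1L ||
          length(unique(exons$gene_id[idx])) != 1L) {
        stop(sprintf("annotation: transcript '%s' spans multiple chrom/strand/gene",
                     exons$transcript_id[idx[1L]]))
      }
      if (length(idx) > 1L &&
          any(exons$start[idx][-1L] < exons$end[idx][-length(idx)])) {
        stop(sprintf("annotation: transcript '%s' has overlapping exons",
                     exons$transcript_id[idx[1L]]))
      }
    }
  }
  if (!is.null(cds) && nrow(as.data.frame(cds))) {
    cds <- as.data.frame(cds)
    assert_cols(cds, c("transcript_id", "start", "end"), "annotation cds")
    cds$start <- as.integer(cds$start)
    cds$end <- as.integer(cds$end)
    if (any(!cds$transcript_id %in% exons$transcript_id)) {
      stop("annotation: cds refers to unknown transcript ids")
    }
    cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    # CDS must lie within the exon union of its transcript
    for (tid in unique(cds$transcript_id)) {
      ex <- exons[exons$transcript_id == tid, , drop = FALSE]
      cc <- cds[cds$transcript_id == tid, , drop = FALSE]
      for (i in seq_len(nrow(cc))) {
        inside <- any(ex$start <= cc$start[i] & cc$end[i] <= ex$end)
        if (!inside) {
          stop(sprintf("annotation: CDS segment of '%s' outside exon union", tid))
        }
      }
    }
  } else {
    cds <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(exons = exons, cds = cds), class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  tx <- unique(x$exons$transcript_id)
  gn <- unique(x$exons$gene_id)
  cat(sprintf("<tx_annotation> %d transcripts in %d genes (%d with CDS)\n",
              length(tx), length(gn), length(unique(x$cds$transcript_id))))
  invisible(x)
}

#' Per-transcript summary of an annotation
#'
#' @param ann a [annotation()] object.
#' @return data.frame with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (transcript span) and `n_exons`.
#' @export
transcripts <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  ex <- data.table::as.data.table(ann$exons)
  if (!nrow(ex)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(), n_exons = integer()))
  }
  out <- ex[, list(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
                   start = min(start), end = max(end), n_exons = .N),
            by = "transcript_id"]
  data.table::setDF(out)
  out
}

#' Intron chains of an annotation
#'
#' @param ann a [annotation()] object.
#' @param keys if `TRUE` (default) return a named character vector of identity
#'   keys (see [chain_key()]); otherwise a named list of `(donor, acceptor)`
#'   matrices in genomic order.
#' @export
intron_chains <- function(ann, keys = TRUE) {
  stopifnot(inherits(ann, "tx_annotation"))
  sp <- split(seq_len(nrow(ann$exons)), ann$exons$transcript_id)
  res <- lapply(sp, function(idx) {
    st <- ann$exons$start[idx]; en <- ann$exons$end[idx]
    chrom <- ann$exons$chrom[idx[1L]]; strand <- ann$exons$strand[idx[1L]]
    n <- length(idx)
    donors <- if (n > 1L) en[-n] else integer()
    acceptors <- if (n > 1L) st[-1L] else integer()
    if (keys) {
      chain_key(chrom, strand, donors, acceptors, st[1L], en[n])
    } else {
      cbind(donor = donors, acceptor = acceptors)
    }
  })
  if (keys) unlist(res) else res
}

#' Subset an annotation to a set of transcripts
#'
#' @param ann a [annotation()] object.
#' @param transcript_ids character vector of ids to keep.
#' @export
subset_annotation <- function(ann, transcript_ids) {
  stopifnot(inherits(ann, "tx_annotation"))
  annotation(ann$exons[ann$exons$transcript_id %in% transcript_ids, , drop = FALSE],
             ann$cds[ann$cds$transcript_id %in% transcript_ids, , drop = FALSE])
}
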