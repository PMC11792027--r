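# Readers/writers for every on-disk format the pipeline touches. Parsing of
# the community formats (GTF, BED, FASTA) is delegated to rtracklayer and
# Biostrings; this module only converts between their 1-based closed
# convention and the package-internal 0-based half-open convention, and
# defines the two neutral TSV dialects (spliced reads, splice junctions,
# m6A counts) used in place of alignment files. All readers are
# gzip-transparent.

#' Read a GENCODE-dialect GTF into an annotation
#'
#' Exon and CDS features are consumed; coordinates are converted from GTF's
#' 1-based closed convention to the internal 0-based half-open convention.
#' Transcripts on an unknown strand (`.`) are rejected: strand is load-bearing
#' for junction correction and DRACH scanning.
#'
#' @param path GTF file (optionally gzipped).
#' @return A [annotation()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(meta))) {
    stop("read_gtf: file lacks type/gene_id/transcript_id attributes: ", path)
  }
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(annotation(data.frame(transcript_id = character(), gene_id = character(),
                                 chrom = character(), strand = character(),
                                 start = integer(), end = integer())))
  }
  if (anyNA(meta$transcript_id) || anyNA(meta$gene_id)) {
    stop("read_gtf: exon/CDS feature missing transcript_id or gene_id attribute")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*" & meta$type == "exon")) {
    bad <- meta$transcript_id[strand == "*"][1L]
    stop(sprintf("read_gtf: transcript '%s' has unknown strand '.'", bad))
  }
  df <- data.frame(
    transcript_id = meta$transcript_id,
    gene_id = meta$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    type = as.character(meta$type),
    stringsAsFactors = FALSE
  )
  ex <- df[df$type == "exon", c("transcript_id", "gene_id", "chrom", "strand", "start", "end")]
  cd <- df[df$type == "CDS", c("transcript_id", "start", "end")]
  annotation(ex, if (nrow(cd)) cd else NULL)
}

#' Write an annotation as a GENCODE-dialect GTF
#'
#' The inverse of [read_gtf()]: internal 0-based half-open coordinates become
#' 1-based closed on disk. Exon lines are emitted in transcript order, CDS
#' lines after the exons of their transcript.
#'
#' @param ann a [annotation()] object.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "tx_annotation"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#!isoformatlas GTF (GENCODE dialect)", con)
  ex <- ann$exons
  if (!nrow(ex)) return(invisible(path))
  fmt <- function(chrom, source, type, start, end, strand, gid, tid) {
    sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, source, type, start + 1L, end, strand, gid, tid)
  }
  cds_by_tx <- split(seq_len(nrow(ann$cds)), ann$cds$transcript_id)
  for (idx in split(seq_len(nrow(ex)), factor(ex$transcript_id, levels = unique(ex$transcript_id)))) {
    tid <- ex$transcript_id[idx[1L]]
    gid <- ex$gene_id[idx[1L]]
    chrom <- ex$chrom[idx[1L]]; strand <- ex$strand[idx[1L]]
    writeLines(fmt(chrom, "isoformatlas", "transcript",
                   min(ex$start[idx]), max(ex$end[idx]), strand, gid, tid), con)
    writeLines(fmt(chrom, "isoformatlas", "exon", ex$start[idx], ex$end[idx],
                   strand, gid, tid), con)
    ci <- cds_by_tx[[tid]]
    if (!is.null(ci)) {
      writeLines(fmt(chrom, "isoformatlas", "CDS", ann$cds$start[ci],
                     ann$cds$end[ci], strand, gid, tid), con)
    }
  }
  invisible(path)
}

#' Spliced long-read table
#'
#' Constructs the in-memory representation of long spliced reads: one row per
#' read with exon-block list columns, the summed alignment deletion length,
#' mapping quality, an optional poly(A) tail-length estimate and an optional
#' sample label. The strand-aware 5' position is derived on construction:
#' first block start on `+`, last block end on `-`.
#'
#' @param df data.frame with columns `read_id`, `chrom`, `strand`,
#'   `block_starts`, `block_ends` (list columns of integer vectors, 0-based
#'   half-open, sorted, disjoint), `total_deletion`, `mapq`, and optionally
#'   `polya` (NA when no tail estimate) and `sample`.
#' @return A `spliced_reads` data.table.
#' @export
spliced_reads <- function(df) {
  dt <- data.table::as.data.table(df)
  assert_cols(dt, c("read_id", "chrom", "strand", "block_starts", "block_ends",
                    "total_deletion", "mapq"), "spliced_reads")
  if (!"polya" %in% names(dt)) dt[, "polya" := NA_real_]
  if (!"sample" %in% names(dt)) dt[, "sample" := NA_character_]
  ns <- lengths(dt$block_starts); ne <- lengths(dt$block_ends)
  if (any(ns != ne) || any(ns == 0L)) {
    stop("spliced_reads: ragged or empty block lists")
  }
  ok <- mapply(function(s, e) {
    s <- as.integer(s); e <- as.integer(e)
    all(e > s) && all(s >= 0L) && (length(s) == 1L || all(s[-1L] >= e[-length(e)]))
  }, dt$block_starts, dt$block_ends)
  if (!all(ok)) {
    stop(sprintf("spliced_reads: unsorted/overlapping/negative blocks for read '%s'",
                 dt$read_id[!ok][1L]))
  }
  if (any(dt$total_deletion < 0L) || any(dt$mapq < 0L)) {
    stop("spliced_reads: total_deletion and mapq must be non-negative")
  }
  if (!all(dt$strand %in% c("+", "-"))) {
    stop("spliced_reads: strand must be '+' or '-'")
  }
  dt[, "five_prime" := ifelse(
    strand == "+",
    vapply(block_starts, function(x) as.integer(x[1L]), integer(1)),
    vapply(block_ends, function(x) as.integer(x[length(x)]), integer(1)))]
  data.table::setattr(dt, "class", c("spliced_reads", class(data.table::data.table())))
  dt[]
}

#' Read the neutral spliced-read TSV
#'
#' Tab-separated dialect standing in for BAM: columns `read_id`, `chrom`,
#' `strand`, `block_starts`, `block_ends` (comma-joined, 0-based half-open),
#' `total_deletion`, `mapq`, `polya` (empty allowed), and optionally `sample`.
#'
#' @param path TSV file (optionally gzipped).
#' @return A [spliced_reads()] table.
#' @export
read_reads <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("block_starts", "block_ends")))
  req <- c("read_id", "chrom", "strand", "block_starts", "block_ends",
           "total_deletion", "mapq")
  assert_cols(dt, req, sprintf("reads TSV '%s'", path))
  parse_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    out <- suppressWarnings(as.integer(v))
    if (anyNA(out)) stop("read_reads: non-integer block coordinate in ", path)
    out
  })
  dt[, "block_starts" := parse_ints(block_starts)]
  dt[, "block_ends" := parse_ints(block_ends)]
  if ("polya" %in% names(dt)) {
    dt[, "polya" := suppressWarnings(as.numeric(polya))]
  }
  spliced_reads(dt)
}

#' Write the neutral spliced-read TSV
#'
#' @param reads a [spliced_reads()] table.
#' @param path output path.
#' @export
write_reads <- function(reads, path) {
  out <- data.table::data.table(
    read_id = reads$read_id,
    chrom = reads$chrom,
    strand = reads$strand,
    block_starts = vapply(reads$block_starts, paste, character(1), collapse = ","),
    block_ends = vapply(reads$block_ends, paste, character(1), collapse = ","),
    total_deletion = reads$total_deletion,
    mapq = reads$mapq,
    polya = ifelse(is.na(reads$polya), "", format(reads$polya, trim = TRUE)),
    sample = ifelse(is.na(reads$sample), "", reads$sample)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a short-read splice-junction table
#'
#' TSV with columns `chrom`, `donor`, `acceptor`, `strand`, `support`
#' (unique-read support count). Coordinates are intron boundaries, 0-based
#' half-open, `donor < acceptor` in genomic orientation.
#'
#' @param path TSV file.
#' @return data.frame of junctions.
#' @export
read_junctions <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  assert_cols(dt, c("chrom", "donor", "acceptor", "strand", "support"),
              sprintf("junction TSV '%s'", path))
  if (any(dt$donor >= dt$acceptor)) stop("read_junctions: requires donor < acceptor")
  if (any(dt$support < 0L)) stop("read_junctions: negative support")
  data.table::setDF(dt)
  dt
}

#' @rdname read_junctions
#' @param junctions data.frame as returned by [read_junctions()].
#' @export
write_junctions <- function(junctions, path) {
  data.table::fwrite(data.table::as.data.table(junctions), path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read ATAC-seq peaks from BED
#'
#' Standard BED (0-based half-open) via rtracklayer. Strand is not required:
#' open-chromatin peaks anchor transcription start sites on either strand.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name)) as.character(S4Vectors::mcols(gr)$name)
           else sprintf("peak_%d", seq_along(gr)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_peaks
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @export
write_peaks <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    name = peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of uppercased sequences, one per chromosome.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @rdname read_genome
#' @param genome named character vector of sequences.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read/write the per-site per-sample m6A counts table
#'
#' Long TSV with columns `chrom`, `pos` (0-based position of the methylatable
#' A), `strand`, `motif` (DRACH 5-mer), `sample`, `modified`, `total`.
#'
#' @param path TSV file.
#' @return data.frame with a derived `site` key column (`chrom:pos:strand`).
#' @export
read_m6a_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  assert_cols(dt, c("chrom", "pos", "strand", "motif", "sample", "modified", "total"),
              sprintf("m6A counts TSV '%s'", path))
  if (any(dt$modified > dt$total)) stop("read_m6a_counts: modified > total")
  if (any(dt$modified < 0L)) stop("read_m6a_counts: negative counts")
  dt[, "site" := sprintf("%s:%d:%s", chrom, as.integer(pos), strand)]
  data.table::setDF(dt)
  dt
}

#' @rdname read_m6a_counts
#' @param counts data.frame as returned by [read_m6a_counts()].
#' @export
write_m6a_counts <- function(counts, path) {
  keep <- c("chrom", "pos", "strand", "motif", "sample", "modified", "total")
  data.table::fwrite(data.table::as.data.table(counts)[, keep, with = FALSE],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
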