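# Seeded synthetic-data generator: a miniature genome, a multi-isoform truth
# annotation with CDS partitions, spliced long reads with junction jitter and
# 5' truncation, short-read junction support, ATAC peaks at true TSSs,
# gamma-distributed poly(A) tails and binomial m6A counts at DRACH sites --
# each layer with a planted, recorded truth so every downstream stage can be
# scored for parameter recovery.

#' Simulation configuration
#'
#' Defaults describe a desk-scale two-condition experiment (fed vs fasting,
#' two pooled pseudo-replicates each, ~20k long reads): 4-fold expression
#' changes on ~10% of transcripts, exon-skipping PSI shifts of 0.4, +20 nt
#' poly(A) tail shifts, and m6A modification-fraction changes from 0.10 to
#' 0.40, with tail means spanning 70-100 nt across transcripts. Junction
#' jitter is truncated-normal and never exceeds `max_jitter` (the correction
#' window).
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene,exons_per_gene,exon_length,intron_length,
#'   intergenic_gap integer ranges `c(min, max)`.
#' @param n_chroms chromosomes to spread genes over.
#' @param conditions two condition labels; effects apply to the second.
#' @param replicates samples per condition.
#' @param reads_per_transcript mean reads per transcript per sample.
#' @param junction_jitter_sd,max_jitter junction jitter (bp): normal sd,
#'   hard clip.
#' @param end_jitter transcript-end jitter half-range (bp) for non-truncated
#'   reads; must stay inside the ATAC peak.
#' @param tss_truncation_prob probability a read is 5'-truncated (its 5' end
#'   then falls outside the TSS peak).
#' @param mean_deletion mean summed deletion (nt) of ordinary reads.
#' @param long_deletion_prob probability of a pathological read with summed
#'   deletions > 100 nt.
#' @param mapq_zero_prob,mapq_low_prob probabilities of mapq 0 and mapq 1-4.
#' @param missing_tail_prob probability a read lacks a tail estimate.
#' @param peak_halfwidth ATAC peak half-width (bp) around each true TSS.
#' @param junction_support range of unique-read support for true junctions.
#' @param decoy_junction_prob probability of emitting a nearby decoy junction
#'   with support 2 (below the eligibility floor).
#' @param de_gene_fraction,de_fold fraction of genes (all their isoforms, so
#'   isoform proportions stay fixed) regulated by `de_fold` in condition B,
#'   half up and half down so library composition stays balanced.
#' @param psi_n_genes,psi_base,psi_delta,psi_gene_reads genes carrying a
#'   planted exon-skipping shift: inclusion PSI `psi_base` in condition A,
#'   `psi_base - psi_delta` in B, at `psi_gene_reads` mean reads per sample.
#' @param tail_mean_range,tail_shape,tail_shift_fraction,tail_shift gamma
#'   tail model: per-transcript means, common shape, and a `+tail_shift` nt
#'   mean shift in condition B for the selected fraction of transcripts.
#' @param n_m6a_sites,m6a_baseline,m6a_diff_fraction,m6a_diff_level,
#'   m6a_total_mean m6A layer: number of DRACH sites carrying signal, the
#'   baseline modification fraction, and the fraction of sites raised to
#'   `m6a_diff_level` in condition B, at `m6a_total_mean` mean coverage.
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(150L, 300L),
                       intron_length = c(80L, 400L),
                       intergenic_gap = c(800L, 2000L),
                       n_chroms = 2L,
                       conditions = c("fed", "fasting"),
                       replicates = 2L,
                       reads_per_transcript = 33,
                       junction_jitter_sd = 4,
                       max_jitter = 15L,
                       end_jitter = 30L,
                       tss_truncation_prob = 0.1,
                       mean_deletion = 12,
                       long_deletion_prob = 0.05,
                       mapq_zero_prob = 0.05,
                       mapq_low_prob = 0.05,
                       missing_tail_prob = 0.05,
                       peak_halfwidth = 50L,
                       junction_support = c(5L, 40L),
                       decoy_junction_prob = 0.1,
                       de_gene_fraction = 0.1,
                       de_fold = 4,
                       psi_n_genes = 12L,
                       psi_base = 0.7,
                       psi_delta = 0.4,
                       psi_gene_reads = 100,
                       tail_mean_range = c(70, 100),
                       tail_shape = 30,
                       tail_shift_fraction = 0.1,
                       tail_shift = 20,
                       n_m6a_sites = 150L,
                       m6a_baseline = 0.1,
                       m6a_diff_fraction = 0.2,
                       m6a_diff_level = 0.4,
                       m6a_total_mean = 50,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$conditions) != 2L) stop("sim_config: exactly two conditions")
  rngs <- c("isoforms_per_gene", "exons_per_gene", "exon_length",
            "intron_length", "intergenic_gap", "junction_support",
            "tail_mean_range")
  for (r in rngs) {
    v <- cfg[[r]]
    if (length(v) != 2L || any(v <= 0) || v[1L] > v[2L]) {
      stop("sim_config: ", r, " must be a positive c(min, max) range")
    }
  }
  fr <- c("tss_truncation_prob", "long_deletion_prob", "mapq_zero_prob",
          "mapq_low_prob", "missing_tail_prob", "de_gene_fraction",
          "decoy_junction_prob", "psi_base", "psi_delta", "tail_shift_fraction",
          "m6a_baseline", "m6a_diff_fraction", "m6a_diff_level")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1) {
    stop("sim_config: ", f, " must be in [0, 1]")
  }
  if (cfg$exon_length[1L] <= 2L * cfg$max_jitter ||
      cfg$intron_length[1L] <= 2L * cfg$max_jitter) {
    stop("sim_config: exons/introns must be longer than twice the jitter bound")
  }
  if (cfg$exon_length[1L] < cfg$peak_halfwidth + cfg$end_jitter + 40L) {
    stop("sim_config: terminal exons too short to separate truncated reads from the TSS peak")
  }
  if (cfg$psi_base - cfg$psi_delta < 0) {
    stop("sim_config: psi_base - psi_delta must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Map a transcript-coordinate interval [t0, t1) onto genomic segments of a
# transcript (exon starts/ends in genomic order, strand-aware).
tx_interval_to_genomic <- function(ex_start, ex_end, strand, t0, t1) {
  lens <- ex_end - ex_start
  # exon order in transcript orientation
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  segs <- list()
  cum <- 0L
  for (i in ord) {
    l <- lens[i]
    s_t <- max(t0, cum); e_t <- min(t1, cum + l)
    if (s_t < e_t) {
      if (strand == "+") {
        segs[[length(segs) + 1L]] <- c(ex_start[i] + (s_t - cum),
                                       ex_start[i] + (e_t - cum))
      } else {
        segs[[length(segs) + 1L]] <- c(ex_end[i] - (e_t - cum),
                                       ex_end[i] - (s_t - cum))
      }
    }
    cum <- cum + l
  }
  do.call(rbind, segs)
}

#' Simulate a complete miniature dataset
#'
#' Writes `genome.fa`, `annotation.gtf` (truth models with CDS),
#' `reads.tsv`, `junctions.tsv`, `peaks.bed`, `m6a_counts.tsv` and
#' `truth.json` under `out_dir` and returns the truth set in memory.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`
#'   (annotation, read origins, true counts, planted DE / AS / tail-shift /
#'   m6A labels, sample-condition map).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rint <- function(n, rng) if (rng[1L] == rng[2L]) rep(rng[1L], n) else
    sample(rng[1L]:rng[2L], n, replace = TRUE)

  ## ---- gene structures -------------------------------------------------
  chrom_of <- rep(sprintf("chr%d", seq_len(cfg$n_chroms)), length.out = cfg$n_genes)
  cursor <- stats::setNames(rep(0L, cfg$n_chroms), sprintf("chr%d", seq_len(cfg$n_chroms)))
  genes <- vector("list", cfg$n_genes)
  n_psi <- min(cfg$psi_n_genes, cfg$n_genes)
  psi_gene_idx <- if (n_psi > 0L) sort(sample(cfg$n_genes, n_psi)) else integer()
  for (gi in seq_len(cfg$n_genes)) {
    chrom <- chrom_of[gi]
    n_ex <- max(rint(1L, cfg$exons_per_gene), 4L)
    ex_len <- rint(n_ex, cfg$exon_length)
    in_len <- rint(n_ex - 1L, cfg$intron_length)
    gstart <- cursor[chrom] + rint(1L, cfg$intergenic_gap)
    starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    cursor[chrom] <- ends[n_ex]
    genes[[gi]] <- list(gene_id = sprintf("g-%03d", gi), chrom = chrom,
                        strand = sample(c("+", "-"), 1L),
                        ex_start = starts, ex_end = ends, n_ex = n_ex,
                        is_psi = gi %in% psi_gene_idx)
  }
  chrom_len <- cursor + 1000L

  ## ---- isoforms ---------------------------------------------------------
  exon_rows <- list(); cds_rows <- list()
  tx_meta <- list()
  truth_as <- list()
  for (gi in seq_len(cfg$n_genes)) {
    g <- genes[[gi]]
    internal <- 2:(g$n_ex - 1L)
    iso_sets <- list(seq_len(g$n_ex))       # isoform 1: full chain
    if (g$is_psi) {
      skip <- sample(internal, 1L)
      iso_sets[[2L]] <- setdiff(seq_len(g$n_ex), skip)
      # the planted exon-skipping event, keyed like enumerate_events()
      D <- g$ex_end[skip - 1L]; A <- g$ex_start[skip + 1L]
      truth_as[[length(truth_as) + 1L]] <- data.frame(
        event_id = sprintf("ES:%s:%s:%d-%d", g$chrom, g$strand, D, A),
        gene_id = g$gene_id, psi_a = cfg$psi_base,
        psi_b = cfg$psi_base - cfg$psi_delta, stringsAsFactors = FALSE)
    } else {
      # exon-skipping dominated isoform structure: each alternative isoform
      # skips one distinct internal exon of the full chain
      n_iso <- min(rint(1L, cfg$isoforms_per_gene), 1L + length(internal))
      skips <- sample(internal, n_iso - 1L)
      for (sk in skips) {
        iso_sets[[length(iso_sets) + 1L]] <- setdiff(seq_len(g$n_ex), sk)
      }
    }
    for (ii in seq_along(iso_sets)) {
      keep <- iso_sets[[ii]]
      tid <- sprintf("tx-%03d-%d", gi, ii)
      es <- g$ex_start[keep]; ee <- g$ex_end[keep]
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = g$gene_id, chrom = g$chrom,
        strand = g$strand, start = es, end = ee, stringsAsFactors = FALSE)
      # CDS partition: ~20% 5'UTR, ~50% CDS (multiple of 3), rest 3'UTR
      total <- sum(ee - es)
      utr5 <- as.integer(round(0.2 * total))
      cds_len <- (as.integer(round(0.5 * total)) %/% 3L) * 3L
      segs <- tx_interval_to_genomic(es, ee, g$strand, utr5, utr5 + cds_len)
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        transcript_id = tid, start = segs[, 1L], end = segs[, 2L],
        stringsAsFactors = FALSE)
      tx_meta[[length(tx_meta) + 1L]] <- list(
        transcript_id = tid, gene_idx = gi, iso_idx = ii,
        ex_start = es, ex_end = ee, chrom = g$chrom, strand = g$strand)
    }
  }
  truth_ann <- annotation(do.call(rbind, exon_rows), do.call(rbind, cds_rows))
  tx_ids <- vapply(tx_meta, `[[`, character(1), "transcript_id")
  names(tx_meta) <- tx_ids
  truth_keys <- intron_chains(truth_ann)

  ## ---- expression design -----------------------------------------------
  samples <- as.vector(t(outer(cfg$conditions, seq_len(cfg$replicates),
                               function(c, r) sprintf("%s_%d", c, r))))
  cond_of <- stats::setNames(rep(cfg$conditions, each = cfg$replicates), samples)
  n_de <- ceiling(cfg$de_gene_fraction * cfg$n_genes)
  de_pool <- setdiff(seq_len(cfg$n_genes), psi_gene_idx)
  de_gene_idx <- sort(sample(de_pool, min(n_de, length(de_pool))))
  # bidirectional regulation: alternate up/down so that library composition
  # stays balanced between conditions
  de_dir <- stats::setNames(rep_len(c(1, -1), length(de_gene_idx)), de_gene_idx)

  mu <- matrix(0, nrow = length(tx_ids), ncol = length(samples),
               dimnames = list(tx_ids, samples))
  for (gi in seq_len(cfg$n_genes)) {
    g <- genes[[gi]]
    g_tx <- tx_ids[vapply(tx_meta, function(t) t$gene_idx == gi, logical(1))]
    n_iso <- length(g_tx)
    if (g$is_psi) {
      gene_mean <- cfg$psi_gene_reads
      w_a <- c(cfg$psi_base, 1 - cfg$psi_base)
      w_b <- c(cfg$psi_base - cfg$psi_delta, 1 - cfg$psi_base + cfg$psi_delta)
    } else {
      gene_mean <- cfg$reads_per_transcript * n_iso
      w <- stats::rgamma(n_iso, shape = 5)
      w_a <- w_b <- w / sum(w)
    }
    fold <- if (gi %in% de_gene_idx) {
      if (de_dir[[as.character(gi)]] > 0) cfg$de_fold else 1 / cfg$de_fold
    } else 1
    for (s in samples) {
      w_s <- if (cond_of[[s]] == cfg$conditions[1L]) w_a else w_b
      f_s <- if (cond_of[[s]] == cfg$conditions[1L]) 1 else fold
      mu[g_tx, s] <- gene_mean * w_s * f_s
    }
  }
  true_counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                        dimnames = dimnames(mu))

  ## ---- tail model -------------------------------------------------------
  tail_mean <- stats::setNames(
    stats::runif(length(tx_ids), cfg$tail_mean_range[1L], cfg$tail_mean_range[2L]),
    tx_ids)
  n_shift <- round(cfg$tail_shift_fraction * length(tx_ids))
  tail_shift_ids <- sort(sample(tx_ids, n_shift))

  ## ---- reads ------------------------------------------------------------
  clip <- function(x, b) pmax(-b, pmin(b, x))
  read_rows <- list(); origin <- list()
  read_no <- 0L
  for (ti in seq_along(tx_ids)) {
    t <- tx_meta[[ti]]
    m <- length(t$ex_start)
    first_len <- if (t$strand == "+") t$ex_end[1L] - t$ex_start[1L] else
      t$ex_end[m] - t$ex_start[m]
    trunc_lo <- cfg$peak_halfwidth + cfg$end_jitter + 10L
    trunc_hi <- max(trunc_lo, first_len - 20L)
    for (s in samples) {
      k <- true_counts[ti, s]
      if (k == 0L) next
      shift_here <- tx_ids[ti] %in% tail_shift_ids &&
        cond_of[[s]] == cfg$conditions[2L]
      mean_s <- tail_mean[ti] + if (shift_here) cfg$tail_shift else 0
      for (r in seq_len(k)) {
        read_no <- read_no + 1L
        st <- t$ex_start; en <- t$ex_end
        if (m > 1L) {
          jd <- en[-m] + clip(round(stats::rnorm(m - 1L, 0, cfg$junction_jitter_sd)),
                              cfg$max_jitter)
          ja <- st[-1L] + clip(round(stats::rnorm(m - 1L, 0, cfg$junction_jitter_sd)),
                               cfg$max_jitter)
          en[-m] <- as.integer(jd); st[-1L] <- as.integer(ja)
        }
        truncated <- stats::runif(1) < cfg$tss_truncation_prob
        d5 <- if (truncated) sample(trunc_lo:trunc_hi, 1L) else
          sample(-cfg$end_jitter:cfg$end_jitter, 1L)
        d3 <- sample(-cfg$end_jitter:cfg$end_jitter, 1L)
        if (t$strand == "+") {
          st[1L] <- st[1L] + d5
          en[m] <- en[m] + d3
        } else {
          en[m] <- en[m] - d5
          st[1L] <- st[1L] - d3
        }
        deletion <- if (stats::runif(1) < cfg$long_deletion_prob)
          101L + stats::rpois(1L, 50) else stats::rpois(1L, cfg$mean_deletion)
        u <- stats::runif(1)
        mapq <- if (u < cfg$mapq_zero_prob) 0L else
          if (u < cfg$mapq_zero_prob + cfg$mapq_low_prob) sample(1:4, 1L) else 60L
        tail <- if (stats::runif(1) < cfg$missing_tail_prob) NA_real_ else
          round(stats::rgamma(1L, shape = cfg$tail_shape,
                              rate = cfg$tail_shape / mean_s), 1)
        rid <- sprintf("read-%06d", read_no)
        read_rows[[read_no]] <- list(read_id = rid, chrom = t$chrom,
                                     strand = t$strand,
                                     block_starts = list(as.integer(st)),
                                     block_ends = list(as.integer(en)),
                                     total_deletion = as.integer(deletion),
                                     mapq = mapq, polya = tail, sample = s)
        origin[[read_no]] <- list(read_id = rid, sample = s,
                                  transcript_id = tx_ids[ti],
                                  truncated = truncated)
      }
    }
  }
  reads <- spliced_reads(data.table::rbindlist(read_rows))
  read_origin <- data.table::setDF(data.table::rbindlist(origin))

  ## ---- junction support table -------------------------------------------
  jx <- unique(do.call(rbind, lapply(tx_meta, function(t) {
    m <- length(t$ex_start)
    if (m < 2L) return(NULL)
    data.frame(chrom = t$chrom, donor = t$ex_end[-m], acceptor = t$ex_start[-1L],
               strand = t$strand, stringsAsFactors = FALSE)
  })))
  jx$support <- rint(nrow(jx), cfg$junction_support)
  decoy <- jx[stats::runif(nrow(jx)) < cfg$decoy_junction_prob, , drop = FALSE]
  if (nrow(decoy)) {
    decoy$donor <- decoy$donor + 7L
    decoy$acceptor <- decoy$acceptor + 7L
    decoy$support <- 2L
    jx <- rbind(jx, decoy)
  }
  jx <- jx[order(jx$chrom, jx$donor, jx$acceptor), , drop = FALSE]

  ## ---- ATAC peaks at true TSSs -------------------------------------------
  tss <- vapply(tx_meta, function(t) {
    if (t$strand == "+") t$ex_start[1L] else t$ex_end[length(t$ex_end)] - 1L
  }, integer(1))
  pk <- data.frame(chrom = vapply(tx_meta, `[[`, character(1), "chrom"),
                   start = pmax(0L, tss - cfg$peak_halfwidth),
                   end = tss + cfg$peak_halfwidth + 1L, stringsAsFactors = FALSE)
  pk_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(start = pk$start + 1L, end = pk$end)))
  peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(pk_gr)),
                      start = BiocGenerics::start(pk_gr) - 1L,
                      end = BiocGenerics::end(pk_gr),
                      name = sprintf("peak_%d", seq_along(pk_gr)),
                      stringsAsFactors = FALSE)

  ## ---- genome sequence ---------------------------------------------------
  genome <- vapply(names(chrom_len), function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_len[[ch]], replace = TRUE),
          collapse = "")
  }, character(1))

  ## ---- m6A counts ---------------------------------------------------------
  cand_sites <- scan_drach(genome, truth_ann)
  n_sites <- min(cfg$n_m6a_sites, nrow(cand_sites))
  sites <- cand_sites[sort(sample(nrow(cand_sites), n_sites)), , drop = FALSE]
  n_diff <- round(cfg$m6a_diff_fraction * n_sites)
  m6a_diff_sites <- sort(sample(sites$site, n_diff))
  m6a_rows <- list()
  for (si in seq_len(nrow(sites))) {
    for (s in samples) {
      frac <- if (sites$site[si] %in% m6a_diff_sites &&
                  cond_of[[s]] == cfg$conditions[2L]) cfg$m6a_diff_level
              else cfg$m6a_baseline
      tot <- max(1L, stats::rpois(1L, cfg$m6a_total_mean))
      m6a_rows[[length(m6a_rows) + 1L]] <- data.frame(
        chrom = sites$chrom[si], pos = sites$pos[si], strand = sites$strand[si],
        motif = sites$motif[si], sample = s,
        modified = stats::rbinom(1L, tot, frac), total = tot,
        stringsAsFactors = FALSE)
    }
  }
  m6a_counts <- do.call(rbind, m6a_rows)

  ## ---- write --------------------------------------------------------------
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                annotation = file.path(out_dir, "annotation.gtf"),
                reads = file.path(out_dir, "reads.tsv"),
                junctions = file.path(out_dir, "junctions.tsv"),
                peaks = file.path(out_dir, "peaks.bed"),
                m6a = file.path(out_dir, "m6a_counts.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_genome(genome, paths$genome)
  write_gtf(truth_ann, paths$annotation)
  write_reads(reads, paths$reads)
  write_junctions(jx, paths$junctions)
  write_peaks(peaks, paths$peaks)
  write_m6a_counts(m6a_counts, paths$m6a)

  truth_as_df <- if (length(truth_as)) do.call(rbind, truth_as) else
    data.frame(event_id = character(), gene_id = character(),
               psi_a = numeric(), psi_b = numeric(), stringsAsFactors = FALSE)
  # transcripts with a designed expression change: all isoforms of DE genes,
  # plus the isoforms of PSI genes (a PSI shift at constant gene output is a
  # genuine transcript-level expression change in both isoforms)
  de_tx <- sort(tx_ids[vapply(tx_meta, function(t) {
    t$gene_idx %in% de_gene_idx || t$gene_idx %in% psi_gene_idx
  }, logical(1))])
  truth <- list(
    annotation = truth_ann,
    chain_keys = truth_keys,
    read_origin = read_origin,
    counts = true_counts,
    conditions = cond_of,
    de_transcripts = de_tx,
    as_events = truth_as_df,
    tail_shift_transcripts = tail_shift_ids,
    m6a_diff_sites = m6a_diff_sites
  )
  jsonlite::write_json(list(
    samples = samples, conditions = as.list(cond_of),
    de_transcripts = de_tx, as_events = truth_as_df,
    tail_shift_transcripts = tail_shift_ids, m6a_diff_sites = m6a_diff_sites,
    chain_keys = as.list(truth_keys),
    read_origin = read_origin,
    counts = as.data.frame(true_counts)
  ), paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = paths, truth = truth))
}

#' Simulate related tissue annotations
#'
#' Produces per-tissue annotations sharing a common transcript core, with a
#' recorded set of tissue-unique intron chains, for exercising
#' tissue-specific transcript detection.
#'
#' @param config a [sim_config()] object (only the gene-structure fields are
#'   used).
#' @param n_tissues number of tissues (>= 2).
#' @param shared_fraction fraction of transcripts present in every tissue.
#' @return list with `annotations` (named list) and `unique_keys` (named list
#'   of truly tissue-unique chain keys).
#' @export
simulate_tissue_annotations <- function(config = sim_config(), n_tissues = 3L,
                                        shared_fraction = 0.6) {
  stopifnot(n_tissues >= 2L)
  set.seed(config$seed)
  tmp <- withr_local_tempdir_fallback()
  sim <- simulate_dataset(config, tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  ann <- sim$truth$annotation
  ids <- unique(ann$exons$transcript_id)
  n_shared <- round(shared_fraction * length(ids))
  shared <- sample(ids, n_shared)
  rest <- setdiff(ids, shared)
  # deal remaining transcripts round-robin: each goes to exactly one tissue
  owner <- rep(seq_len(n_tissues), length.out = length(rest))
  tissues <- sprintf("tissue_%d", seq_len(n_tissues))
  annotations <- stats::setNames(lapply(seq_len(n_tissues), function(i) {
    subset_annotation(ann, c(shared, rest[owner == i]))
  }), tissues)
  keys <- intron_chains(ann)
  unique_keys <- stats::setNames(lapply(seq_len(n_tissues), function(i) {
    sort(unname(keys[rest[owner == i]]))
  }), tissues)
  list(annotations = annotations, unique_keys = unique_keys)
}

# tempdir helper that avoids collisions without adding a dependency
withr_local_tempdir_fallback <- function() {
  d <- tempfile("isoformatlas_sim_")
  dir.create(d, recursive = TRUE)
  d
}
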