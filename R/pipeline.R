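# End-to-end driver chaining simulate -> refine -> classify -> diffexp ->
# diffsplice -> polya -> m6a -> evaluate over a run directory, with a JSON
# manifest recording parameters, per-stage record counts and output hashes.
# Stages never mutate their inputs; every output is written once.

#' Aggregate transcript counts to gene level
#'
#' The differential-expression test is the same per-feature Fisher
#' construction at either level; this helper sums transcript rows by gene so
#' [fisher_de()] can be applied gene-by-gene.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param ann a [annotation()] object supplying the transcript -> gene map.
#' @export
gene_counts <- function(counts, ann) {
  tx <- transcripts(ann)
  gid <- tx$gene_id[match(rownames(counts), tx$transcript_id)]
  rowsum(counts, group = gid)
}

#' Run the full pipeline on a simulated dataset
#'
#' Simulates a dataset, reads every input back through the on-disk formats,
#' refines and collapses the long reads into a de novo annotation, classifies
#' it against the truth annotation, runs the four differential layers
#' (transcript expression, splicing events, poly(A) tail shifts, m6A sites),
#' scores all layers against the recorded truth, and writes result tables
#' plus a run manifest under `out_dir`.
#'
#' @param out_dir run directory (created; inputs under `inputs/`, outputs
#'   under `results/`).
#' @param config a [sim_config()] object.
#' @param params a [correction_params()] object.
#' @return Invisibly, a list with the collapsed annotation, all result
#'   tables, the evaluation metrics and the manifest.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         params = correction_params()) {
  dir.create(file.path(out_dir, "results"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "isoformatlas",
                   version = as.character(utils::packageVersion("isoformatlas")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## simulate ---------------------------------------------------------------
  sim <- simulate_dataset(config, file.path(out_dir, "inputs"))
  truth <- sim$truth
  note("simulate", n_reads = nrow(truth$read_origin),
       n_transcripts = length(truth$chain_keys))

  ## load inputs back through the readers ------------------------------------
  reads <- read_reads(sim$paths$reads)
  junctions <- read_junctions(sim$paths$junctions)
  peaks <- read_peaks(sim$paths$peaks)
  ref_ann <- read_gtf(sim$paths$annotation)
  m6a_counts <- read_m6a_counts(sim$paths$m6a)

  cond <- truth$conditions
  cond_a_samples <- names(cond)[cond == config$conditions[1L]]
  cond_b_samples <- names(cond)[cond == config$conditions[2L]]

  ## refine ------------------------------------------------------------------
  kept <- filter_by_deletion(reads, params)
  n_del <- nrow(reads) - nrow(kept)
  kept2 <- filter_by_tss(kept, peaks)
  n_tss <- nrow(kept) - nrow(kept2)
  corrected <- correct_reads(kept2, junctions, params)
  n_rej <- sum(corrected$status == "rejected")
  usable <- corrected[corrected$status != "rejected", ]
  coll <- collapse_reads(usable, params)
  denovo <- coll$annotation
  write_gtf(denovo, file.path(out_dir, "results", "denovo.gtf"))
  utils::write.table(
    data.frame(transcript_id = names(coll$support), support = coll$support),
    file.path(out_dir, "results", "support.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("refine", removed_deletion = n_del, removed_tss = n_tss,
       rejected_correction = n_rej,
       n_transcripts = length(unique(denovo$exons$transcript_id)))

  ## classify ----------------------------------------------------------------
  classes <- assign_class_codes(denovo, ref_ann)
  utils::write.table(classes, file.path(out_dir, "results", "class_codes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("classify", n_matched = sum(classes$category == "matched"),
       n_different = sum(classes$category == "different"),
       n_others = sum(classes$category == "others"),
       n_novel_genes = sum(classes$novel_gene))

  ## quantify + differential expression --------------------------------------
  counts <- quantify(usable, denovo, min_mapq = 1L)
  de <- fisher_de(counts, cond_a_samples, cond_b_samples)
  utils::write.table(de, file.path(out_dir, "results", "diffexp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dominant <- find_dominant(denovo, counts, cond_a_samples)
  note("diffexp", n_features = nrow(de), n_significant = sum(de$significant),
       n_dominant = length(dominant))

  ## splicing events ----------------------------------------------------------
  events <- enumerate_events(denovo)
  as_res <- test_events(events, counts, cond_a_samples, cond_b_samples)
  utils::write.table(as_res, file.path(out_dir, "results", "diffsplice.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("diffsplice", n_events = nrow(events),
       n_significant = sum(as_res$significant))

  ## poly(A) tails -------------------------------------------------------------
  asg <- assign_reads(usable, denovo)
  tails <- collect_tails(usable, asg, cond)
  polya <- diff_polya(tails, config$conditions[1L], config$conditions[2L])
  utils::write.table(polya, file.path(out_dir, "results", "polya.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("polya", n_tested = sum(polya$testable),
       n_significant = sum(polya$significant))

  ## m6A ------------------------------------------------------------------------
  m6a_f <- filter_m6a_sites(m6a_counts)
  m6a_res <- diff_m6a(m6a_f, cond, config$conditions[1L], config$conditions[2L])
  utils::write.table(m6a_res, file.path(out_dir, "results", "m6a_diff.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- metagene(unique(m6a_f[, c("site", "chrom", "pos", "strand")]), ref_ann)
  utils::write.table(meta, file.path(out_dir, "results", "metagene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("m6a", n_sites = length(unique(m6a_f$site)),
       n_significant = sum(m6a_res$significant),
       n_metagene_positions = nrow(meta))

  ## evaluate --------------------------------------------------------------------
  denovo_keys <- intron_chains(denovo)
  calls <- list(
    isoform_keys = unname(denovo_keys),
    de_keys = unname(denovo_keys[de$id[de$significant]]),
    as_ids = as_res$event_id[as_res$significant],
    tail_keys = unname(denovo_keys[polya$transcript_id[polya$significant]]),
    m6a_sites = m6a_res$site[m6a_res$significant]
  )
  metrics <- evaluate_calls(truth, calls)
  utils::write.table(metrics, file.path(out_dir, "results", "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("evaluate", layers = nrow(metrics))

  result_files <- list.files(file.path(out_dir, "results"), full.names = TRUE)
  manifest$output_md5 <- as.list(tools::md5sum(result_files))
  names(manifest$output_md5) <- basename(result_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, denovo = denovo, support = coll$support,
                 classes = classes, counts = counts, de = de,
                 dominant = dominant, events = events, as_res = as_res,
                 polya = polya, m6a = m6a_res, metagene = meta,
                 metrics = metrics, manifest = manifest))
}
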