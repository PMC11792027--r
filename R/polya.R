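# Poly(A) tail-length dynamics: per-transcript tail collections and the
# condition-shift test (|delta median| > 10 nt and p < 0.05 by default).

#' Collect per-transcript poly(A) tail lengths
#'
#' Reads below the tail-analysis mapping-quality floor (default 5, i.e. mapq 4
#' excluded, mapq 5 kept) or without a tail estimate are skipped; the skipped
#' counts are attached as attributes `n_low_mapq` and `n_no_tail`.
#'
#' @param reads a [spliced_reads()] table.
#' @param assignments data.frame from [assign_reads()] (read -> transcript).
#' @param conditions named character vector mapping sample -> condition.
#' @param min_mapq minimum mapping quality; default 5.
#' @return data.frame with `transcript_id`, `condition`, `sample`, `tail`.
#' @export
collect_tails <- function(reads, assignments, conditions, min_mapq = 5L) {
  asg <- assignments
  low <- asg$mapq < min_mapq
  no_tail <- is.na(asg$polya)
  keep <- !low & !no_tail & !is.na(asg$transcript_id)
  out <- data.frame(transcript_id = asg$transcript_id[keep],
                    condition = unname(conditions[asg$sample[keep]]),
                    sample = asg$sample[keep],
                    tail = asg$polya[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_low_mapq") <- sum(low)
  attr(out, "n_no_tail") <- sum(!low & no_tail)
  out
}

#' Test one transcript's tail-length shift between conditions
#'
#' Delta is the difference of medians (`b - a`); the p-value comes from a
#' two-sided rank-based two-sample test (Mann-Whitney U by default,
#' Kolmogorov-Smirnov switchable). A shift is significant iff
#' `|delta| > min_delta` (strict) and `p < alpha` (strict). With fewer than
#' `min_reads` tails in either condition the result is marked untestable.
#'
#' @param tails_a,tails_b numeric vectors of per-read tail lengths (nt).
#' @param min_delta minimum absolute median change (nt); default 10.
#' @param alpha p-value threshold; default 0.05.
#' @param min_reads minimum reads per condition; default 10.
#' @param test `"wilcoxon"` (default) or `"ks"`.
#' @return list with `n_a`, `n_b`, `median_a`, `median_b`, `delta`, `p_value`,
#'   `significant`, `testable`.
#' @export
test_tail_shift <- function(tails_a, tails_b, min_delta = 10, alpha = 0.05,
                            min_reads = 10L, test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  n_a <- length(tails_a); n_b <- length(tails_b)
  if (n_a < min_reads || n_b < min_reads) {
    return(list(n_a = n_a, n_b = n_b, median_a = NA_real_, median_b = NA_real_,
                delta = NA_real_, p_value = NA_real_, significant = FALSE,
                testable = FALSE))
  }
  med_a <- stats::median(tails_a); med_b <- stats::median(tails_b)
  delta <- med_b - med_a
  p <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(tails_b, tails_a, exact = FALSE)$p.value)
  } else {
    suppressWarnings(stats::ks.test(tails_b, tails_a)$p.value)
  }
  list(n_a = n_a, n_b = n_b, median_a = med_a, median_b = med_b, delta = delta,
       p_value = p, significant = abs(delta) > min_delta && p < alpha,
       testable = TRUE)
}

#' Tail-length shift test over all transcripts
#'
#' @param tails data.frame from [collect_tails()].
#' @param cond_a,cond_b condition labels to compare (delta is `b - a`).
#' @inheritParams test_tail_shift
#' @return data.frame with one row per transcript seen in either condition.
#' @export
diff_polya <- function(tails, cond_a, cond_b, min_delta = 10, alpha = 0.05,
                       min_reads = 10L, test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  ids <- sort(unique(tails$transcript_id))
  rows <- lapply(ids, function(tid) {
    ta <- tails$tail[tails$transcript_id == tid & tails$condition == cond_a]
    tb <- tails$tail[tails$transcript_id == tid & tails$condition == cond_b]
    r <- test_tail_shift(ta, tb, min_delta = min_delta, alpha = alpha,
                         min_reads = min_reads, test = test)
    data.frame(transcript_id = tid, n_a = r$n_a, n_b = r$n_b,
               median_a = r$median_a, median_b = r$median_b, delta = r$delta,
               p_value = r$p_value, significant = r$significant,
               testable = r$testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
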