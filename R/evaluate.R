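# Parameter-recovery scoring against the simulator's recorded truth.
# Calls are compared in stable identity spaces: intron-chain keys for
# transcripts (de novo ids are data-dependent), event ids for splicing
# events, site keys for m6A.

#' Score pipeline calls against a simulation truth set
#'
#' @param truth the `truth` component returned by [simulate_dataset()].
#' @param calls list with any of:
#'   * `isoform_keys` - chain keys of collapsed transcripts;
#'   * `de_keys` - chain keys of transcripts called differentially expressed;
#'   * `as_ids` - event ids called significantly altered;
#'   * `tail_keys` - chain keys of transcripts with called tail shifts;
#'   * `m6a_sites` - site keys called differentially modified.
#' @return data.frame with one row per provided layer: `layer`, `n_true`,
#'   `n_called`, `tp`, `precision`, `recall`.
#' @export
evaluate_calls <- function(truth, calls) {
  score <- function(layer, true_set, called_set) {
    true_set <- unique(true_set); called_set <- unique(called_set)
    tp <- length(intersect(true_set, called_set))
    data.frame(layer = layer, n_true = length(true_set),
               n_called = length(called_set), tp = tp,
               precision = if (length(called_set)) tp / length(called_set) else NA_real_,
               recall = if (length(true_set)) tp / length(true_set) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(calls$isoform_keys)) {
    out[[length(out) + 1L]] <- score("isoforms", unname(truth$chain_keys),
                                     calls$isoform_keys)
  }
  if (!is.null(calls$de_keys)) {
    out[[length(out) + 1L]] <- score(
      "de", unname(truth$chain_keys[truth$de_transcripts]), calls$de_keys)
  }
  if (!is.null(calls$as_ids)) {
    out[[length(out) + 1L]] <- score("as", truth$as_events$event_id, calls$as_ids)
  }
  if (!is.null(calls$tail_keys)) {
    out[[length(out) + 1L]] <- score(
      "polya", unname(truth$chain_keys[truth$tail_shift_transcripts]),
      calls$tail_keys)
  }
  if (!is.null(calls$m6a_sites)) {
    out[[length(out) + 1L]] <- score("m6a", truth$m6a_diff_sites, calls$m6a_sites)
  }
  if (!length(out)) stop("evaluate_calls: no call layers provided")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
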