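# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion to/from 1-based closed happens only
# at the GTF boundary (see io.R).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an intron-chain identity key
#'
#' Transcript identity throughout the package is keyed by
#' `(chrom, strand, intron chain)`: the ordered donor/acceptor pairs, not the
#' transcript ends, because collapsed transcript ends are data-dependent.
#' Mono-exonic models have no chain, so their single exon's coordinates are
#' used instead (prefixed `SE`).
#'
#' @param chrom,strand character scalars.
#' @param donors,acceptors integer vectors of intron starts/ends (0-based
#'   half-open); both empty for a mono-exonic model.
#' @param se_start,se_end exon coordinates, used only when the chain is empty.
#' @return A single string usable as a dictionary key.
#' @keywords internal
chain_key <- function(chrom, strand, donors, acceptors,
                      se_start = NULL, se_end = NULL) {
  if (length(donors) == 0L) {
    stopifnot(!is.null(se_start), !is.null(se_end))
    return(sprintf("%s:%s:SE:%d-%d", chrom, strand,
                   as.integer(se_start), as.integer(se_end)))
  }
  sprintf("%s:%s:%s", chrom, strand,
          paste(sprintf("%d-%d", as.integer(donors), as.integer(acceptors)),
                collapse = ","))
}

# Cluster a 1-d set of end coordinates: sort, split where the gap between
# consecutive values exceeds `window`, keep the largest cluster (leftmost on
# ties) and return the rounded median. Used for transcript start/end calling
# during collapse.
cluster_end <- function(x, window) {
  x <- sort(as.integer(x))
  if (length(x) == 1L) return(x)
  grp <- cumsum(c(0L, as.integer(diff(x) > window)))
  sizes <- tabulate(grp + 1L)
  best <- which.max(sizes) - 1L
  as.integer(round(stats::median(x[grp == best])))
}

# Minimal union-find over 1..n, used for gene assembly (single-linkage exon
# overlap) and mono-exonic read grouping.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union_pairs <- function(n, from, to) {
  parent <- uf_new(n)
  for (k in seq_along(from)) {
    ri <- uf_find(parent, from[k])
    rj <- uf_find(parent, to[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Overlap width of [s1,e1) and [s2,e2); 0 when disjoint.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# TRUE when `sub` is a contiguous sub-chain of `full`. Chains are two-column
# (donor, acceptor) integer matrices in genomic order.
is_contiguous_subchain <- function(sub, full) {
  m <- nrow(sub); n <- nrow(full)
  if (m == 0L || m > n) return(FALSE)
  for (off in 0:(n - m)) {
    if (all(full[(off + 1L):(off + m), , drop = FALSE] == sub)) return(TRUE)
  }
  FALSE
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
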