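#' Pairwise nucleotide identity (shorter-sequence convention)
#'
#' Identity between two sequences is the number of identical aligned bases in
#' the optimal fit alignment of the shorter sequence against the longer one,
#' divided by the length of the shorter sequence (the convention of greedy
#' incremental clusterers such as CD-HIT). The alignment is scored with
#' match +1, mismatch -1, gap -2 and free end gaps on the longer sequence;
#' among co-optimal alignments the one with the most identical bases is used,
#' so the value is well defined.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  .nw_identity_cpp(toupper(seq_a), toupper(seq_b))
}

# conservative minimum shared-kmer count implied by an identity threshold:
# an alignment with identity >= t over the shorter length Ls has at most
# (1-t)*Ls edited positions, each destroying at most k k-mers, so at least
# t*Ls - (k-1)*((1-t)*Ls + 1) k-mer positions of the shorter sequence must
# occur in the other sequence. Counts below that bound cannot reach t.
kmer_bound <- function(len_short, threshold, k) {
  max(0, ceiling(threshold * len_short - (k - 1) * ((1 - threshold) * len_short + 1)))
}

#' Greedy identity clustering
#'
#' Greedy incremental clustering at a fixed identity threshold: sequences are
#' sorted by decreasing length (ties broken by id, ascending); each sequence
#' joins the first existing cluster whose representative it matches at
#' `pairwise_identity() >= threshold`, otherwise it founds a new cluster.
#' Representatives are therefore always the longest member of their cluster
#' and the procedure is deterministic for a fixed input set.
#'
#' A shared k-mer prescreen (default `k = 8`) skips alignments that provably
#' cannot reach the threshold; it never changes the result.
#'
#' @param sequences Named character vector (or tibble with `read_id`,
#'   `sequence` columns, or `DNAStringSet`) of nucleotide sequences.
#' @param threshold Identity threshold in `(0, 1]`; default 0.95.
#' @param k Prescreen k-mer size; `k = 0` disables the prescreen.
#' @return A tibble with columns `read_id`, `cluster_id` (integer, in founding
#'   order), `is_representative`; attribute `threshold` records the setting.
#' @export
greedy_cluster <- function(sequences, threshold = 0.95, k = 8) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  seqs <- as_named_seqs(sequences)
  if (!length(seqs)) abort("at least one sequence is required")
  seqs[] <- toupper(seqs)
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  ids <- names(seqs)
  lens <- nchar(seqs)

  rep_idx <- integer(0)        # indices (into seqs) of representatives
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    found <- 0L
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (k > 0) {
        bound <- kmer_bound(lens[i], threshold, k)
        if (bound > 0 && .shared_kmers_cpp(seqs[i], seqs[r], k) < bound) next
      }
      if (.nw_identity_cpp(seqs[i], seqs[r]) >= threshold) { found <- ci; break }
    }
    if (found == 0L) {
      rep_idx <- c(rep_idx, i)
      found <- length(rep_idx)
    }
    assign[i] <- found
  }
  out <- tibble::tibble(
    read_id = ids,
    cluster_id = assign,
    is_representative = seq_along(seqs) %in% rep_idx
  )
  attr(out, "threshold") <- threshold
  out
}

as_named_seqs <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    s <- as.character(sequences)
  } else if (is.data.frame(sequences)) {
    stopifnot(all(c("read_id", "sequence") %in% names(sequences)))
    s <- setNames(sequences$sequence, sequences$read_id)
  } else if (is.character(sequences)) {
    s <- sequences
    if (is.null(names(s))) names(s) <- paste0("seq_", seq_along(s))
  } else {
    abort("sequences must be a named character vector, tibble or DNAStringSet")
  }
  if (anyDuplicated(names(s))) abort("sequence ids must be unique")
  s
}

#' Write clusters in a CD-HIT-like .clstr layout
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param sequences The clustered sequences (for lengths).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, sequences, path) {
  seqs <- as_named_seqs(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in sort(unique(clusters$cluster_id))) {
    writeLines(paste0(">Cluster ", cid - 1L), con)
    members <- clusters[clusters$cluster_id == cid, ]
    for (j in seq_len(nrow(members))) {
      id <- members$read_id[j]
      tag <- if (members$is_representative[j]) "*" else "at"
      writeLines(sprintf("%d\t%dnt, >%s... %s", j - 1L, nchar(seqs[[id]]), id, tag), con)
    }
  }
  invisible(path)
}

#' Subsample-and-cluster richness estimate
#'
#' For each sample, reads are repeatedly subsampled without replacement at a
#' fixed depth, each subsample is clustered at the identity threshold, and the
#' per-sample median cluster count is reported. This measures sequence
#' richness independent of taxonomy at a common sequencing depth.
#'
#' @param reads_by_sample Named list of per-sample sequence sets (each
#'   anything [greedy_cluster()] accepts).
#' @param depth Reads drawn per subsample; every sample must hold at least
#'   `depth` reads.
#' @param n_subsamples Number of subsampling exercises per sample.
#' @param threshold Clustering identity threshold.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Tibble with one row per sample: `sample_id`, `subsample_depth`,
#'   `n_subsamples`, `median_clusters`, and a list-column `cluster_counts`
#'   with the per-subsample counts.
#' @export
subsampled_richness <- function(reads_by_sample, depth, n_subsamples = 100,
                                threshold = 0.95, seed = NULL) {
  if (depth < 1) abort("depth must be >= 1")
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  with_seed_(seed, {
    purrr::imap_dfr(reads_by_sample, function(reads, sid) {
      seqs <- as_named_seqs(reads)
      if (length(seqs) < depth)
        abort(paste0("sample ", sid, " has ", length(seqs),
                     " reads, fewer than depth ", depth))
      counts <- vapply(seq_len(n_subsamples), function(b) {
        sub <- seqs[sample.int(length(seqs), depth)]
        max(greedy_cluster(sub, threshold = threshold)$cluster_id)
      }, numeric(1))
      tibble::tibble(
        sample_id = sid, subsample_depth = as.integer(depth),
        n_subsamples = as.integer(n_subsamples),
        median_clusters = median(counts),
        cluster_counts = list(counts)
      )
    })
  })
}
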