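#' Filter alignments by identity and aligned fraction
#'
#' Retains exactly the records with `identity >= min_identity` and
#' `aligned_fraction >= min_aligned_fraction` (both bounds inclusive) — the
#' read-recruitment criterion of at least 90% identity over at least 80% of
#' the read length.
#'
#' @param alignments Alignment tibble from [parse_alignments()].
#' @param min_identity Minimum NM-based identity (default 0.90).
#' @param min_aligned_fraction Minimum aligned query fraction (default 0.80).
#' @return The retained rows, same columns.
#' @export
filter_alignments <- function(alignments, min_identity = 0.90,
                              min_aligned_fraction = 0.80) {
  dplyr::filter(alignments,
                .data$identity >= min_identity,
                .data$aligned_fraction >= min_aligned_fraction)
}

#' Per contig-sample coverage profiles
#'
#' Computes, for every contig and sample, the fraction of contig positions
#' covered by at least one retained read (union of alignment intervals, so
#' overlaps are not double counted) and the retained read count.
#'
#' @param alignments Filtered alignment tibble; must carry `sample_id`.
#' @param catalog Contig catalog.
#' @return Tibble `contig_id`, `sample_id`, `covered_fraction`,
#'   `mapped_read_count`. Contig-sample pairs with no reads are omitted
#'   (their coverage is zero by definition).
#' @export
coverage_profiles <- function(alignments, catalog) {
  validate_catalog(catalog)
  if (!"sample_id" %in% names(alignments))
    abort("alignments must carry a sample_id column")
  len <- setNames(catalog$length, catalog$contig_id)
  bad <- alignments$contig_end > len[alignments$contig_id]
  if (any(bad))
    abort(paste0("alignment extends past contig end (corrupt record) on ",
                 alignments$contig_id[which(bad)[1]]))
  if (!nrow(alignments)) {
    return(tibble::tibble(contig_id = character(), sample_id = character(),
                          covered_fraction = double(),
                          mapped_read_count = integer()))
  }
  alignments |>
    dplyr::group_by(.data$contig_id, .data$sample_id) |>
    dplyr::summarise(
      covered_fraction = {
        ir <- IRanges::reduce(IRanges::IRanges(start = .data$contig_start + 1L,
                                               end = .data$contig_end))
        sum(IRanges::width(ir)) / len[[.data$contig_id[1]]]
      },
      mapped_read_count = dplyr::n(),
      .groups = "drop"
    )
}

#' Chimera filter: require near-full coverage in at least one sample
#'
#' A contig is kept only if, in at least one sample, reads cover at least
#' `min_covered_fraction` of its length — assembled contigs never attaining
#' that in any single sample are treated as likely chimeric and removed.
#'
#' @param profiles Coverage tibble from [coverage_profiles()].
#' @param catalog Contig catalog (contigs absent from `profiles` have zero
#'   coverage and are removed).
#' @param min_covered_fraction Default 0.80 (inclusive).
#' @return Character vector of retained contig ids, in catalog order.
#' @export
chimera_filter <- function(profiles, catalog, min_covered_fraction = 0.80) {
  validate_catalog(catalog)
  best <- profiles |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(max_cov = max(.data$covered_fraction), .groups = "drop")
  keep <- best$contig_id[best$max_cov >= min_covered_fraction]
  catalog$contig_id[catalog$contig_id %in% keep]
}

#' Length filter: drop short contigs
#'
#' Removes contigs shorter than `min_length` (a contig of exactly
#' `min_length` nt is retained). The 4 kb default excludes fragmented viral
#' genomes and most small eukaryotic viruses while keeping the shortest
#' complete phage genomes.
#'
#' @param catalog Contig catalog.
#' @param min_length Minimum length in nt (default 4000).
#' @return Character vector of retained contig ids, in catalog order.
#' @export
length_filter <- function(catalog, min_length = 4000) {
  validate_catalog(catalog)
  catalog$contig_id[catalog$length >= min_length]
}

#' Dereplicate contigs at 95% identity
#'
#' Greedy clustering of contig sequences, keeping cluster representatives
#' (the longest member of each cluster).
#'
#' @param catalog Contig catalog with a `sequence` column.
#' @param threshold Identity threshold, default 0.95.
#' @return Character vector of representative contig ids.
#' @export
dereplicate_contigs <- function(catalog, threshold = 0.95) {
  validate_catalog(catalog)
  if (!"sequence" %in% names(catalog))
    abort("catalog must carry sequences for dereplication")
  cl <- greedy_cluster(setNames(catalog$sequence, catalog$contig_id),
                       threshold = threshold)
  cl$read_id[cl$is_representative]
}

#' Build the contig-by-sample abundance matrix
#'
#' Counts retained alignments per contig and sample and normalizes to RPKM:
#' `rpkm = count / (length/1000) / (sample_total/1e6)`, with `sample_total`
#' the per-sample library size (total quality-filtered reads, not mapped
#' reads).
#'
#' @param alignments Filtered alignment tibble with `sample_id`.
#' @param contigs Character vector of retained contig ids (rows of the
#'   matrix); alignments to other contigs are ignored.
#' @param catalog Contig catalog (for lengths).
#' @param sample_totals Named numeric vector of per-sample library sizes;
#'   must cover every sample present in `alignments`.
#' @return A `phg_abundance` object: list with integer `counts` and numeric
#'   `rpkm` matrices (contig x sample), `lengths`, `sample_totals`.
#' @export
build_abundance <- function(alignments, contigs, catalog, sample_totals) {
  validate_catalog(catalog)
  samples <- names(sample_totals)
  if (is.null(samples)) abort("sample_totals must be named")
  if (any(sample_totals <= 0)) abort("sample totals must be positive")
  have <- unique(alignments$sample_id)
  missing <- setdiff(have, samples)
  if (length(missing))
    abort(paste0("missing sample total for: ", missing[1]))
  aln <- alignments[alignments$contig_id %in% contigs, ]
  counts <- matrix(0L, nrow = length(contigs), ncol = length(samples),
                   dimnames = list(contigs, samples))
  if (nrow(aln)) {
    tab <- table(factor(aln$contig_id, levels = contigs),
                 factor(aln$sample_id, levels = samples))
    counts[] <- as.integer(tab)
  }
  lengths <- setNames(catalog$length, catalog$contig_id)[contigs]
  new_abundance(counts, lengths, sample_totals)
}

#' Construct a `phg_abundance` from a count matrix
#'
#' @param counts Integer contig-by-sample count matrix (dimnames required).
#' @param lengths Named contig lengths in nt.
#' @param sample_totals Named per-sample library sizes.
#' @return A `phg_abundance` object.
#' @export
new_abundance <- function(counts, lengths, sample_totals) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  lengths <- lengths[rownames(counts)]
  sample_totals <- sample_totals[colnames(counts)]
  if (anyNA(lengths)) abort("missing contig length")
  if (anyNA(sample_totals)) abort("missing sample total")
  if (any(counts < 0)) abort("counts must be non-negative")
  rpkm <- sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, sample_totals / 1e6, "/")
  structure(
    list(counts = counts, rpkm = rpkm,
         lengths = lengths, sample_totals = sample_totals),
    class = "phg_abundance"
  )
}

#' @export
print.phg_abundance <- function(x, ...) {
  cat("<phg_abundance> ", nrow(x$counts), " contigs x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  total counts: ", sum(x$counts),
      "; median contig length: ", median(x$lengths), " nt\n", sep = "")
  invisible(x)
}

#' Tidy an abundance matrix into long form
#'
#' @param x A `phg_abundance`.
#' @param ... Unused.
#' @return Long tibble: `contig_id`, `sample_id`, `count`, `rpkm`.
#' @export
tidy.phg_abundance <- function(x, ...) {
  tibble::tibble(
    contig_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts),
    rpkm = as.vector(x$rpkm)
  )
}

#' Subset an abundance matrix by contig ids
#'
#' @param x A `phg_abundance`.
#' @param contigs Contig ids to keep.
#' @return A `phg_abundance` restricted to those contigs.
#' @export
subset_abundance <- function(x, contigs) {
  new_abundance(x$counts[contigs, , drop = FALSE], x$lengths, x$sample_totals)
}
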